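test_that("min-inference fires the expected rules", {
  ze <- c(nb = 0, ns = 0, ze = 255, ps = 0, pb = 0)
  s <- infer_rules(ze, ze)
  expect_equal(which(s > 0), 13)       # single rule, full strength
  expect_equal(s[13], 255)

  nb <- c(nb = 255, ns = 0, ze = 0, ps = 0, pb = 0)
  s <- infer_rules(nb, nb)
  expect_equal(which(s > 0), 1)
  expect_equal(s[1], 255)

  # the worked bench scenario: E saturated positive, dE between NS and ZE
  pb <- c(nb = 0, ns = 0, ze = 0, ps = 0, pb = 255)
  de <- c(nb = 0, ns = 99, ze = 155, ps = 0, pb = 0)
  s <- infer_rules(pb, de)
  expect_equal(which(s > 0), c(10, 15))
  expect_equal(s[c(10, 15)], c(99, 155))
})

test_that("defuzzification takes the floored weighted singleton average", {
  tab70 <- default_singleton_tables()[["70"]]
  s <- numeric(25); s[13] <- 255
  expect_identical(defuzzify(s, tab70)$defuzzy, 38)   # lone ME rule

  s <- numeric(25); s[10] <- 99; s[15] <- 155
  r <- defuzzify(s, tab70)
  expect_identical(r$defuzzy, 43)                     # floor(11133/254)
  expect_identical(r$pulse, 430)
  expect_equal(r$fired_rules$rule, c(10, 15))

  # all rules equal: floor of the mean over label multiplicities 6/4/5/4/6
  expect_identical(defuzzify(rep(7, 25), tab70)$defuzzy, 31)

  expect_error(defuzzify(numeric(25), tab70), "all rule strengths")
})

test_that("defuzzify output is bounded by the singleton range everywhere", {
  tabs <- default_singleton_tables()
  set.seed(42)
  for (i in 1:200) {
    s <- numeric(25)
    idx <- sample(25, sample(1:6, 1))
    s[idx] <- sample(0:255, length(idx), replace = TRUE)
    if (sum(s) == 0) s[idx[1]] <- 1
    for (tab in tabs) {
      d <- defuzzify(s, tab)$defuzzy
      expect_gte(d, min(tab$positions))
      expect_lte(d, max(tab$positions))
    }
  }
})

test_that("rule-path defuzzification matches the literal grid loop (strided grid)", {
  tab70 <- default_singleton_tables()[["70"]]
  M <- t(vapply(0:255, fuzzify, numeric(5)))
  for (i in seq(1, 256, by = 3)) {
    e <- M[i, ]
    for (j in seq(1, 256, by = 3)) {
      impl <- defuzzify(infer_rules(e, M[j, ]), tab70)$defuzzy
      expect_identical(impl, oracle_defuzzy(i - 1, j - 1, oracle_positions_70),
                       info = sprintf("e=%d de=%d", i - 1, j - 1))
    }
  }
})

test_that("defuzzy is monotone in error when change-in-error is at its zero peak", {
  cfg <- flc_config()
  de <- fuzzify(127)
  for (tab in default_singleton_tables()) {
    d <- vapply(-20:20, function(e) {
      defuzzify(infer_rules(fuzzify(scale_to_digital(e)), de), tab)$defuzzy
    }, numeric(1))
    expect_true(all(diff(d) >= 0))
  }
})
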