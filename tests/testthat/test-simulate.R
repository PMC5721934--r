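test_that("the generator is reproducible and honours strata probabilities", {
  d1 <- simulate_cohort(400, seed = 71)
  d2 <- simulate_cohort(400, seed = 71)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(400, seed = 72)
  expect_false(identical(d1$bmi, d3$bmi))

  expect_named(d1, c("id", "smoking", "sex", "age", "age_c", "alcohol",
                     "fruitveg", "activity", "education", "nationality",
                     "region", "bmi", "height", "weight", "reported_height",
                     "reported_weight"))

  # stratum frequencies within exact binomial 99% bands
  n <- 20000
  d <- simulate_cohort(n, seed = 73)
  pr <- colreg:::default_strata_probs(bmi_preset())
  counts <- table(interaction(d$smoking, d$sex, sep = ":", lex.order = TRUE))
  for (s in names(pr)) {
    lo <- qbinom(0.005, n, pr[[s]])
    hi <- qbinom(0.995, n, pr[[s]])
    expect_true(counts[[s]] >= lo && counts[[s]] <= hi, label = s)
  }
  expect_error(simulate_cohort(100, strata_probs = c(a = 1)), "named by")
})

test_that("sampled outcomes follow the generating distribution", {
  m <- toy_model(beta = NULL)
  th <- m$theta["A", , drop = FALSE]
  m1 <- colreg_model(th, m$basis)
  d <- simulate_cohort(50000, m1, seed = 74)
  grid <- seq(14, 44, length.out = 300)
  emp <- ecdf(d$bmi)(grid)
  expect_lt(max(abs(emp - model_cdf(m1, grid, rownames(th)))), 0.01)
})

test_that("WHO categorisation uses half-open intervals", {
  expect_equal(who_interval(27), tibble::tibble(lower = 25, upper = 30))
  expect_equal(who_interval(25), tibble::tibble(lower = 18.5, upper = 25))
  expect_equal(who_interval(17), tibble::tibble(lower = NA_real_,
                                                upper = 18.5))
  expect_equal(who_interval(31)$upper, NA_real_)
  expect_error(who_interval(-1), "positive")
})

test_that("the fixed-width grid reproduces the 21-category scheme", {
  expect_equal(fixed_width_interval(19.5), tibble::tibble(lower = 19,
                                                          upper = 21))
  expect_equal(fixed_width_interval(16)$upper, 17)
  expect_true(is.na(fixed_width_interval(16)$lower))
  expect_true(is.na(fixed_width_interval(40)$upper))
  expect_equal(fixed_width_interval(40)$lower, 37)
  # a boundary value belongs to the lower category
  expect_equal(fixed_width_interval(21)$lower, 19)
})

test_that("rounding intervals reproduce the reported-measurement arithmetic", {
  iv <- rounding_interval(1.75, 76)
  expect_equal(round(iv$lower, 2), 24.51)
  expect_equal(round(iv$upper, 2), 25.12)

  set.seed(75)
  h <- runif(20, 1.5, 2.0)
  w <- runif(20, 50, 110)
  iv <- rounding_interval(h, w)
  # independent re-derivation of the two quotients
  expect_equal(iv$lower, (w - 0.5) / (h + 0.005)^2, tolerance = 1e-14)
  expect_equal(iv$upper, (w + 0.5) / (h - 0.005)^2, tolerance = 1e-14)
  expect_true(all(iv$lower < w / h^2 & w / h^2 < iv$upper))
  expect_error(rounding_interval(-1, 70), "positive")
})

test_that("every scheme's interval contains the true value", {
  d <- simulate_cohort(10000, seed = 76)
  for (sch in c("who", "fixed_width", "rounding")) {
    ds <- apply_scheme(d, sch)
    lo <- ifelse(is.na(ds$lower), 0, ds$lower)
    hi <- ifelse(is.na(ds$upper), Inf, ds$upper)
    b <- ds$bmi
    expect_true(all(lo <= b + 1e-12 & b <= hi + 1e-12), label = sch)
  }
  de <- apply_scheme(d, "exact")
  expect_equal(de$exact, d$bmi)
  expect_true(all(is.na(de$lower) & is.na(de$upper)))

  dw <- apply_scheme(d, "who")
  cats <- unique(paste(dw$lower, dw$upper))
  expect_true(all(cats %in% c("NA 18.5", "18.5 25", "25 30", "30 NA")))
})

test_that("the WHO and fixed-width grids do not align", {
  # 18.5 and 30 are not nodes of the 17,19,...,37 grid, so WHO categories
  # are never unions of fixed-width cells; both schemes must therefore be
  # applied to the underlying values independently
  grid <- seq(17, 37, by = 2)
  expect_false(18.5 %in% grid)
  expect_false(30 %in% grid)
  b <- 29.5  # same value, incompatible intervals
  expect_equal(who_interval(b)$lower, 25)
  expect_equal(fixed_width_interval(b)$lower, 29)
})

test_that("fitting exact-scale synthetic data recovers the generating CDFs", {
  m <- bmi_preset(beta = NULL)
  d <- apply_scheme(simulate_cohort(20000, m, seed = 77), "exact")
  f <- colreg_fit(d, strata = c("smoking", "sex"))
  expect_true(f$converged)
  at <- c(18.5, 25, 30)
  slab <- interaction(d$smoking, d$sex, sep = ":", lex.order = TRUE)
  for (s in f$strata_levels) {
    p_true <- model_cdf(m, at, s)
    n_s <- sum(slab == s)
    # sampling-noise floor of the stratum: small survey strata (~1000
    # subjects) cannot pin a probability tighter than a few binomial SEs
    band <- pmax(0.02, 3.5 * sqrt(p_true * (1 - p_true) / n_s))
    dev <- abs(model_cdf(f$model, at, s) - p_true)
    expect_true(all(dev < band), label = s)
    if (n_s >= 2000) expect_lt(max(dev), 0.02)
  }
})

test_that("invalid scheme requests fail loudly", {
  d <- simulate_cohort(20, seed = 78)
  expect_error(apply_scheme(d, "banana"), "unknown scheme")
  d2 <- d[, setdiff(names(d), c("reported_height", "reported_weight"))]
  expect_error(apply_scheme(d2, "rounding"), "needs columns")
  expect_error(apply_scheme(d, rep("who", 3)), "length 1 or nrow")
})
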