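test_that("interval log-likelihood contributions follow the probability rule", {
  m <- toy_model()
  b_half <- model_quantile(m, 0.5, "A")

  d <- tibble::tibble(
    stratum = "A",
    exact = NA_real_,
    lower = c(0, 0),
    upper = c(NA, b_half)  # (0, Inf] and (0, b_half]
  )
  ll <- obs_loglik(d, m, strata = "stratum")
  expect_equal(ll$loglik[1], 0)                 # total probability
  expect_equal(ll$loglik[2], log(0.5), tolerance = 1e-10)

  # naive one-by-one summation oracle on random mixed observations
  set.seed(41)
  mb <- toy_model(beta = c(x1 = 0.4, x2 = -0.3))
  n <- 100
  dd <- tibble::tibble(
    stratum = sample(c("A", "B"), n, TRUE),
    x1 = rnorm(n), x2 = rbinom(n, 1, 0.5),
    exact = ifelse(runif(n) < 0.5, runif(n, 16, 35), NA),
    w = runif(n, 0.5, 2)
  )
  dd$lower <- ifelse(is.na(dd$exact), runif(n, 15, 25), NA)
  dd$upper <- ifelse(is.na(dd$exact), dd$lower + runif(n, 0.5, 5), NA)
  got <- obs_loglik(dd, mb, strata = "stratum", covariates = ~ x1 + x2,
                    weight_col = "w")
  oracle <- vapply(seq_len(n), function(i) {
    xb <- 0.4 * dd$x1[i] - 0.3 * dd$x2[i]
    a <- function(b) drop(basis_eval(mb$basis, b) %*% mb$theta[dd$stratum[i], ])
    if (!is.na(dd$exact[i])) {
      eta <- a(dd$exact[i]) + xb
      ap <- drop(basis_deriv(mb$basis, dd$exact[i]) %*% mb$theta[dd$stratum[i], ])
      dd$w[i] * (dlogis(eta, log = TRUE) + log(ap))
    } else {
      dd$w[i] * log(plogis(a(dd$upper[i]) + xb) - plogis(a(dd$lower[i]) + xb))
    }
  }, numeric(1))
  expect_equal(got$loglik, oracle, tolerance = 1e-10)

  # doubling the weights exactly doubles the total
  dd2 <- dd; dd2$w <- dd$w * 2
  got2 <- obs_loglik(dd2, mb, strata = "stratum", covariates = ~ x1 + x2,
                     weight_col = "w")
  expect_equal(sum(got2$loglik), 2 * sum(got$loglik), tolerance = 1e-12)
})

test_that("exact contributions approximate narrow-interval contributions", {
  m <- toy_model(beta = c(x1 = 0.2, x2 = 0.1))
  set.seed(42)
  b <- runif(25, 16, 38)
  h <- 1e-4
  d_ex <- tibble::tibble(stratum = rep(c("A", "B"), length.out = 25),
                         x1 = rnorm(25), x2 = rbinom(25, 1, 0.5),
                         exact = b)
  d_iv <- d_ex
  d_iv$exact <- NA_real_
  d_iv$lower <- b - h
  d_iv$upper <- b + h
  ll_ex <- obs_loglik(d_ex, m, strata = "stratum", covariates = ~ x1 + x2)
  ll_iv <- obs_loglik(d_iv, m, strata = "stratum", covariates = ~ x1 + x2)
  expect_lt(max(abs(ll_ex$loglik - (ll_iv$loglik - log(2 * h)))), 1e-4)
})

test_that("single-stratum fit reproduces the empirical distribution", {
  d <- sim_toy(2000, beta = NULL, seed = 43)
  d <- d[d$stratum == "A", ]
  d$stratum <- droplevels(d$stratum)
  d <- apply_scheme(d, "exact")
  f <- colreg_fit(d, strata = "stratum")
  expect_true(f$converged)
  grid <- seq(f$model$basis$window$lower, f$model$basis$window$upper,
              length.out = 200)
  emp <- ecdf(d$bmi)(grid)
  fitted <- model_cdf(f$model, grid, "A")
  expect_lt(max(abs(fitted - emp)), 0.05)
})

test_that("fitted coefficient blocks satisfy the monotonicity constraints", {
  d <- apply_scheme(sim_toy(800, seed = 44), "exact")
  f <- colreg_fit(d, strata = "stratum", covariates = ~ x1 + x2)
  expect_true(all(apply(f$model$theta, 1, function(r) all(diff(r) >= -1e-10))))
  expect_gte(f$loglik, -Inf)
})

test_that("shuffling row order leaves the fitted distributions unchanged", {
  d <- apply_scheme(sim_toy(600, seed = 45), "exact")
  f1 <- colreg_fit(d, strata = "stratum", covariates = ~ x1 + x2)
  set.seed(46)
  f2 <- colreg_fit(d[sample(nrow(d)), ], strata = "stratum",
                   covariates = ~ x1 + x2)
  # identified quantities: shift coefficients and the distribution functions
  # (tail intercept coefficients beyond the data are flat likelihood
  # directions and only pinned to optimizer precision)
  expect_lt(max(abs(f1$model$beta - f2$model$beta)), 1e-5)
  grid <- seq(13, 45, length.out = 100)
  for (s in c("A", "B")) {
    expect_lt(max(abs(model_cdf(f1$model, grid, s) -
                        model_cdf(f2$model, grid, s))), 1e-4)
  }
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("step-basis fit on WHO categories matches the brute-force
           proportional-odds MLE", {
  m <- who_friendly_model()
  d <- simulate_cohort(2000, m, covariate_sampler = toy_sampler,
                       formula = ~ x1 + x2, seed = 47)
  dw <- apply_scheme(d, "who")
  f <- colreg_fit(dw, strata = "stratum", covariates = ~ x1 + x2,
                  basis = "step", cutoffs = c(18.5, 25, 30))
  orc <- po_oracle(d)
  expect_lt(max(abs(f$model$theta - orc$theta)), 1e-4)
  expect_lt(max(abs(f$model$beta - orc$beta)), 1e-4)
})

test_that("single-cutoff fit equals binary logistic regression", {
  m <- who_friendly_model()
  d <- simulate_cohort(1000, m, covariate_sampler = toy_sampler,
                       formula = ~ x1 + x2, seed = 48)
  de <- apply_scheme(d, "exact")
  f <- colreg_fit_binary(de, 25, strata = "stratum", covariates = ~ x1 + x2)
  g <- glm(I(bmi <= 25) ~ 0 + stratum + x1 + x2, data = d, family = binomial,
           control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(coef(f) - coef(g))), 1e-5)

  # covariate-free version is the saturated per-stratum proportion
  f0 <- colreg_fit_binary(de, 25, strata = "stratum")
  p_fit <- plogis(f0$model$theta[, 1])
  p_emp <- tapply(d$bmi <= 25, d$stratum, mean)[rownames(f0$model$theta)]
  expect_lt(max(abs(p_fit - c(p_emp))), 1e-8)
})

test_that("a cut-off with no events in a stratum is flagged, not silent", {
  m <- who_friendly_model(beta = NULL)
  d <- simulate_cohort(300, m, seed = 49)
  d <- apply_scheme(d, "exact")
  d$bmi <- pmax(d$bmi, 19)  # no events below 18.5 anywhere
  d <- apply_scheme(d, "exact")
  f <- colreg_fit_binary(d, 18.5, strata = "stratum")
  expect_false(f$converged)
  expect_true(f$diverged)
})

test_that("the optimizer converges under all four measurement scales", {
  d <- sim_toy(1500, seed = 50)
  for (sch in c("exact", "rounding", "fixed_width", "who")) {
    ds <- apply_scheme(d, sch)
    f <- colreg_fit(ds, strata = "stratum", covariates = ~ x1 + x2,
                    basis = if (sch == "who") "step" else "bernstein")
    expect_true(f$converged, label = paste("converged under", sch))
    expect_true(is.finite(f$loglik))
  }
})

test_that("logit and cloglog stratified fits give the same distributions", {
  d <- apply_scheme(sim_toy(3000, beta = NULL, seed = 51), "exact")
  fl <- colreg_fit(d, strata = "stratum", link = "logit")
  fc <- colreg_fit(d, strata = "stratum", link = "cloglog")
  at <- c(18.5, 22, 25, 28, 30, 34)
  for (s in c("A", "B")) {
    expect_lt(max(abs(model_cdf(fl$model, at, s) -
                        model_cdf(fc$model, at, s))), 0.01)
  }
})

test_that("mixed measurement scales are pooled in one likelihood", {
  d <- sim_toy(4000, seed = 52)
  d$sch <- rep(c("who", "exact"), length.out = nrow(d))
  dm <- apply_scheme(d, "sch")
  expect_setequal(unique(dm$scheme), c("who", "exact"))
  f <- colreg_fit(dm, strata = "stratum", covariates = ~ x1 + x2)
  expect_true(f$converged)
  td <- tidy(f)
  truth <- c(log(1.25), log(0.8))
  expect_true(all(abs(td$estimate - truth) < 3 * td$std.error))
})

test_that("rank-deficient designs and empty strata raise errors", {
  d <- apply_scheme(sim_toy(200, seed = 53), "exact")
  d$x3 <- d$x1 * 2
  expect_error(colreg_fit(d, strata = "stratum", covariates = ~ x1 + x3),
               "rank deficient")
  d$stratum <- factor(as.character(d$stratum), levels = c("A", "B", "C"))
  expect_error(colreg_fit(d, strata = "stratum"), "without observations")
})
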