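fit_small <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      d <- apply_scheme(sim_toy(1500, seed = 61), "exact")
      val <<- colreg_fit(d, strata = "stratum", covariates = ~ x1 + x2)
    }
    val
  }
})

test_that("tidy/glance expose broom-style summaries", {
  f <- fit_small()
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$term, c("x1", "x2"))
  te <- tidy(f, exponentiate = TRUE)
  expect_equal(te$estimate, exp(td$estimate))
  g <- glance(f)
  expect_equal(g$nobs, 1500L)
  expect_true(g$converged)
})

test_that("proportional odds ratios are cutoff-free with Wald intervals", {
  f <- fit_small()
  por <- proportional_or(f)
  td <- tidy(f, exponentiate = TRUE)
  expect_equal(por$or, td$estimate)
  expect_equal(por$conf.low, td$conf.low)
  expect_true(all(por$cutoff == "all"))
  expect_match(por$label[1], "^\\d+\\.\\d{3} \\(\\d+\\.\\d{3}-\\d+\\.\\d{3}\\)$")
  expect_error(proportional_or(f, "nope"), "unknown covariate")

  # true shift log(1.25), log(0.8): recovered within 3 SE
  tdl <- tidy(f)
  expect_true(all(abs(tdl$estimate - c(log(1.25), log(0.8))) <
                    3 * tdl$std.error))

  # 99% intervals contain 95% intervals
  p95 <- proportional_or(f, level = 0.95)
  p99 <- proportional_or(f, level = 0.99)
  expect_true(all(p99$conf.low <= p95$conf.low))
  expect_true(all(p99$conf.high >= p95$conf.high))
})

test_that("stratum odds ratios obey the contrast algebra", {
  f <- fit_small()
  self <- stratum_or(f, "A", "A", at = 25)
  expect_identical(self$or, 1)
  expect_identical(self$conf.low, 1)
  expect_identical(self$conf.high, 1)

  ab <- stratum_or(f, "A", "B", at = c(20, 25, 33.3))
  ba <- stratum_or(f, "B", "A", at = c(20, 25, 33.3))
  expect_equal(ab$or * ba$or, rep(1, 3), tolerance = 1e-12)
  expect_error(stratum_or(f, "Z", "A", at = 25), "unknown stratum")

  o95 <- stratum_or(f, "A", "B", at = 25, level = 0.95)
  o99 <- stratum_or(f, "A", "B", at = 25, level = 0.99)
  expect_lt(o99$conf.low, o95$conf.low)
  expect_gt(o99$conf.high, o95$conf.high)
})

test_that("step-basis stratum ORs equal the categorical coefficient contrasts", {
  d <- apply_scheme(sim_toy(1200, seed = 62), "who")
  f <- colreg_fit(d, strata = "stratum", covariates = ~ x1 + x2,
                  basis = "step", cutoffs = c(18.5, 25, 30))
  so <- stratum_or(f, "B", "A", at = c(18.5, 25, 30))
  direct <- exp(f$model$theta["B", ] - f$model$theta["A", ])
  expect_equal(so$or, unname(direct), tolerance = 1e-10)
})

test_that("delta-method stratum OR standard errors match a parametric bootstrap", {
  m0 <- toy_model(beta = NULL)
  d <- apply_scheme(simulate_cohort(400, m0, seed = 63), "exact")
  f <- colreg_fit(d, strata = "stratum")
  so <- stratum_or(f, "B", "A", at = 25)
  delta_se <- (log(so$conf.high) - log(so$conf.low)) / (2 * qnorm(0.975))

  set.seed(64)
  a25 <- basis_eval(f$model$basis, 25)[1, ]
  boot <- replicate(500, {
    db <- apply_scheme(simulate_cohort(400, f$model), "exact")
    fb <- colreg_fit(db, strata = "stratum",
                     control = colreg_control(vcov = FALSE))
    sum(a25 * (fb$model$theta["B", ] - fb$model$theta["A", ]))
  })
  expect_lt(abs(delta_se - sd(boot)) / sd(boot), 0.15)
})

test_that("the probability table is monotone and equals direct cdf calls", {
  f <- fit_small()
  tab <- cdf_table(f)
  expect_equal(names(tab), c("stratum", "18.5", "25", "30"))
  probs <- as.matrix(tab[, -1])
  rownames(probs) <- tab$stratum
  expect_true(all(diff(t(probs)) >= 0))
  expect_equal(unname(probs["A", "25"]), model_cdf(f$model, 25, "A"),
               tolerance = 1e-12)
  long <- cdf_table(f, at = c(20, 30), wide = FALSE)
  expect_equal(nrow(long), 4L)
  expect_equal(long$probability[long$stratum == "B" & long$cutoff == 30],
               model_cdf(f$model, 30, "B"))
  expect_error(cdf_table(f, at = -1), "hard bounds")
})

test_that("distribution and density curves behave like a distribution", {
  f <- fit_small()
  grid <- seq(13, 45, length.out = 801)
  dc <- colreg_curve(f, "distribution", grid = grid, strata = "A")
  expect_true(all(dc$value >= 0 & dc$value <= 1))
  expect_true(all(diff(dc$value) >= -1e-12))
  expect_lt(dc$value[1], 0.01)
  expect_gt(dc$value[nrow(dc)], 0.99)

  pc <- colreg_curve(f, "density", grid = grid, strata = "A")
  h <- diff(grid[1:2])
  trap <- sum((pc$value[-1] + pc$value[-801]) / 2 * h)
  expect_equal(trap, 1, tolerance = 5e-3)

  fd <- diff(dc$value) / h
  mid <- (pc$value[-1] + pc$value[-801]) / 2
  expect_lt(max(abs(fd - mid)), 1e-3)

  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})

test_that("PIT residuals are uniform under the fitted model", {
  f <- fit_small()
  r <- colreg_residuals(f)
  expect_true(all(r$u >= 0 & r$u <= 1))
  expect_false(any(r$approximate))
  ks <- pit_test(f)
  expect_gt(ks$p.value, 0.01)

  # interval rows are evaluated at interval midpoints and flagged
  dw <- apply_scheme(sim_toy(500, seed = 65), "who")
  fw <- colreg_fit(dw, strata = "stratum", covariates = ~ x1 + x2,
                   basis = "step")
  rw <- colreg_residuals(fw)
  expect_true(all(rw$approximate))
})

test_that("omitting a strong covariate degrades subgroup PIT uniformity", {
  # the stratified intercepts absorb the covariate-marginalised mixture, so
  # the misfit shows up in the residuals *within* a covariate subgroup
  ks_high_x1 <- function(f, d) {
    u <- colreg_residuals(f)$u[d$x1 > 0]
    unname(suppressWarnings(ks.test(u, "punif"))$statistic)
  }
  set.seed(66)
  stat_pair <- replicate(8, {
    d <- apply_scheme(sim_toy(800, beta = c(x1 = log(3), x2 = 0)), "exact")
    ctl <- colreg_control(vcov = FALSE)
    f_ok <- colreg_fit(d, strata = "stratum", covariates = ~ x1,
                       control = ctl)
    f_bad <- colreg_fit(d, strata = "stratum", control = ctl)
    c(ok = ks_high_x1(f_ok, d), bad = ks_high_x1(f_bad, d))
  })
  expect_gt(median(stat_pair["bad", ]), median(stat_pair["ok", ]))
})
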