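#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

z_crit <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Tidy the shift coefficients of a fit
#'
#' Returns the constant-shift (proportional odds) coefficients in broom
#' layout. Because the model is for `P(Y <= b)`, `exp(estimate) > 1` means
#' higher odds of lower outcome values at every cut-off `b`.
#'
#' @param x A `colreg_fit`.
#' @param exponentiate If `TRUE`, report odds ratios `exp(beta)` with
#'   exponentiated Wald limits.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns term, estimate, std.error, statistic,
#'   p.value, conf.low, conf.high.
#' @method tidy colreg_fit
#' @export
tidy.colreg_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  beta <- x$model$beta
  if (is.null(beta) || !length(beta)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric(), conf.low = numeric(),
                          conf.high = numeric()))
  }
  idx <- length(x$free) - length(beta) + seq_along(beta)
  se <- sqrt(pmax(diag(x$vcov)[idx], 0))
  z <- beta / se
  zc <- z_crit(conf.level)
  out <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(beta - zc * se), conf.high = unname(beta + zc * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-row fit summary
#'
#' @param x A `colreg_fit`.
#' @param ... Unused.
#' @return A tibble with the log-likelihood, parameter count, observation
#'   counts by measurement type, convergence flag, iteration count and the
#'   number of floored likelihood evaluations at the optimum.
#' @method glance colreg_fit
#' @export
glance.colreg_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = length(x$free), nobs = x$n_obs,
    n_exact = x$n_exact, n_interval = x$n_obs - x$n_exact,
    n_strata = length(x$strata_levels),
    converged = x$converged, n_iter = unname(x$n_iter),
    floored = x$floored
  )
}

#' Proportional odds ratios of the shift covariates
#'
#' The shift coefficients `beta` are log odds ratios of the event
#' `Y <= b` for *every* cut-off `b` simultaneously (the proportional odds
#' property), so a single odds ratio per covariate summarises the whole
#' distribution shift.
#'
#' @param fit A `colreg_fit`.
#' @param covariate Optional character vector restricting to some design
#'   columns; default all.
#' @param level Confidence level.
#' @return A tibble with term, or, conf.low, conf.high, cutoff (`"all"`), and
#'   a formatted `label` such as `"0.968 (0.966-0.970)"`.
#' @export
proportional_or <- function(fit, covariate = NULL, level = 0.95) {
  td <- tidy(fit, exponentiate = TRUE, conf.level = level)
  if (!is.null(covariate)) {
    bad <- setdiff(covariate, td$term)
    if (length(bad)) {
      stop("unknown covariate: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    td <- td[td$term %in% covariate, , drop = FALSE]
  }
  tibble::tibble(
    term = td$term, or = td$estimate,
    conf.low = td$conf.low, conf.high = td$conf.high,
    cutoff = "all", level = level,
    label = sprintf("%.3f (%.3f-%.3f)", td$estimate, td$conf.low, td$conf.high)
  )
}

#' Stratum odds ratios at arbitrary cut-offs
#'
#' Compares the intercept functions of two strata at outcome value(s) `at`:
#' the log odds ratio of the event `Y <= b` for `stratum` versus `reference`
#' is `alpha_stratum(b) - alpha_reference(b)`, which — unlike the shift
#' coefficients — may vary freely with `b`. Because the intercept functions
#' are smooth, the contrast is available at *any* cut-off, not just the
#' category boundaries used during fitting. Standard errors come from the
#' delta method: the contrast is linear in the natural coefficients, and the
#' free-parameterisation covariance is propagated through the softplus chain
#' rule.
#'
#' @param fit A `colreg_fit`.
#' @param stratum,reference Stratum labels (vectors are recycled against
#'   `at`); defaults: every stratum against the first.
#' @param at Outcome cut-off(s) at which to evaluate the contrast.
#' @param level Confidence level.
#' @return A tibble with stratum, reference, cutoff, or, conf.low, conf.high,
#'   and a formatted label.
#' @export
stratum_or <- function(fit, stratum = NULL, reference = NULL,
                       at = c(18.5, 25, 30), level = 0.95) {
  labs <- fit$strata_levels
  reference <- reference %||% labs[1]
  stratum <- stratum %||% labs
  check_stratum(fit$model, c(stratum, reference))
  J <- full_jacobian(fit)
  K <- n_coef(fit$model$basis)
  zc <- z_crit(level)
  grid <- tidyr::expand_grid(stratum = stratum, cutoff = at)
  res <- purrr::pmap_dfr(grid, function(stratum, cutoff) {
    a_row <- basis_eval(fit$model$basis, cutoff)[1, ]
    ia <- match(stratum, labs); ir <- match(reference, labs)
    lor <- sum(a_row * (fit$model$theta[ia, ] - fit$model$theta[ir, ]))
    g <- numeric(length(fit$free))
    g[(ia - 1L) * K + seq_len(K)] <- a_row
    g[(ir - 1L) * K + seq_len(K)] <- g[(ir - 1L) * K + seq_len(K)] - a_row
    gf <- drop(g %*% J)          # chain to the free parameterisation
    se <- sqrt(max(drop(gf %*% fit$vcov %*% gf), 0))
    tibble::tibble(
      stratum = stratum, reference = reference, cutoff = cutoff,
      or = exp(lor), conf.low = exp(lor - zc * se),
      conf.high = exp(lor + zc * se), level = level,
      label = sprintf("%.3f (%.3f-%.3f)", exp(lor), exp(lor - zc * se),
                      exp(lor + zc * se))
    )
  })
  res
}

baseline_design <- function(fit, newdata = NULL) {
  p <- length(fit$model$beta)
  if (!p) return(numeric(0))
  if (is.null(newdata)) return(numeric(p))
  mf <- stats::model.frame(stats::delete.response(fit$terms), newdata,
                           xlev = fit$xlevels)
  X <- stats::model.matrix(stats::delete.response(fit$terms), mf)
  X <- X[, attr(X, "assign") != 0, drop = FALSE]
  drop(X[1, ])
}

#' Conditional distribution table per stratum
#'
#' Evaluates the fitted conditional distribution function at the requested
#' cut-offs (WHO category boundaries by default) for each stratum, at baseline
#' covariates (all design columns zero, i.e. reference categories and
#' zero/centered continuous covariates) unless a one-row `newdata` is given.
#'
#' @param fit A `colreg_fit`.
#' @param at Cut-offs (columns of the table).
#' @param newdata Optional one-row data frame of covariate values.
#' @param wide If `TRUE` (default) return strata as rows and one column per
#'   cut-off; otherwise a long tibble (stratum, cutoff, probability).
#' @return A tibble; each stratum's probabilities are non-decreasing across
#'   cut-offs.
#' @export
cdf_table <- function(fit, at = c(18.5, 25, 30), newdata = NULL, wide = TRUE) {
  w <- fit$model$basis$window
  if (any(at < w$hard_lower | at > w$hard_upper)) {
    stop("cut-offs must lie inside the hard bounds", call. = FALSE)
  }
  x <- baseline_design(fit, newdata)
  long <- purrr::map_dfr(fit$strata_levels, function(s) {
    tibble::tibble(stratum = s, cutoff = at,
                   probability = model_cdf(fit$model, at, s, x))
  })
  if (!wide) return(long)
  tidyr::pivot_wider(long, names_from = "cutoff", values_from = "probability")
}

#' Fitted distribution and density curves
#'
#' Pointwise evaluations of the conditional distribution function or density
#' over a grid of outcome values, per stratum at baseline covariates, in a
#' long tibble ready for plotting or export.
#'
#' @param fit A `colreg_fit`.
#' @param kind `"distribution"` or `"density"`.
#' @param grid Outcome grid; default 200 points spanning the support window.
#' @param strata Strata to include (default all).
#' @param newdata Optional one-row data frame of covariate values.
#' @return A tibble with columns stratum, b, value, kind.
#' @export
colreg_curve <- function(fit, kind = c("distribution", "density"),
                         grid = NULL, strata = NULL, newdata = NULL) {
  kind <- match.arg(kind)
  w <- fit$model$basis$window
  if (is.null(grid)) grid <- seq(w$lower, w$upper, length.out = 200L)
  if (any(grid < w$hard_lower | grid > w$hard_upper)) {
    stop("grid must lie inside the hard bounds", call. = FALSE)
  }
  strata <- strata %||% fit$strata_levels
  x <- baseline_design(fit, newdata)
  f <- if (kind == "distribution") model_cdf else model_pdf
  purrr::map_dfr(strata, function(s) {
    tibble::tibble(stratum = s, b = grid,
                   value = f(fit$model, grid, s, x), kind = kind)
  })
}

#' Plot fitted conditional distributions
#'
#' @param object A `colreg_fit`.
#' @param kind `"distribution"` or `"density"`.
#' @param ... Passed to [colreg_curve()].
#' @return A ggplot object with one curve per stratum.
#' @method autoplot colreg_fit
#' @export
autoplot.colreg_fit <- function(object, kind = c("distribution", "density"),
                                ...) {
  kind <- match.arg(kind)
  cd <- colreg_curve(object, kind = kind, ...)
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$b, y = .data$value,
                                   colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "outcome", colour = "stratum",
                  y = if (kind == "distribution")
                    "P(Y ≤ b | stratum, baseline x)" else
                      "conditional density") +
    ggplot2::theme_minimal()
}

#' @export
plot.colreg_fit <- function(x, y, ...) print(autoplot.colreg_fit(x, ...))

#' Probability-integral-transform residuals
#'
#' Evaluates the fitted conditional distribution function at each subject's
#' outcome: `U = P(Y <= b | stratum, x)`. Under a correctly specified model
#' the `U` are standard uniform (the analogue of Cox–Snell residuals), so
#' departures from uniformity flag misspecification. Interval-censored rows
#' use the interval midpoint (finite-endpoint fallback at the tails; the
#' finite category boundary for step-basis fits) and are flagged as
#' approximate. Note the global KS summary has no power against an omitted
#' covariate when the model is stratified — the flexible intercepts absorb
#' the marginal mixture — so covariate misspecification should be probed by
#' testing uniformity of `u` *within* covariate subgroups. A one-sample Kolmogorov–Smirnov comparison against
#' the uniform is attached; [pit_test()] returns it directly.
#'
#' @param fit A `colreg_fit`.
#' @return A tibble with columns stratum, b (the evaluation point), u, and
#'   approximate (TRUE for interval rows); the KS summary is in
#'   `attr(, "ks")`.
#' @export
colreg_residuals <- function(fit) {
  obs <- fit$obs
  w <- fit$model$basis$window
  b <- if (fit$model$basis$kind == "step") {
    # a step basis is only defined at its cutoffs: use the finite interval
    # endpoint (every category boundary is a cutoff)
    ifelse(obs$is_exact, obs$exact,
           ifelse(is.finite(obs$upper) & obs$upper < w$hard_upper,
                  obs$upper, obs$lower))
  } else {
    ifelse(obs$is_exact, obs$exact,
           ifelse(!is.finite(obs$upper), obs$lower,
                  ifelse(obs$lower <= w$hard_lower, obs$upper,
                         (obs$lower + obs$upper) / 2)))
  }
  x_all <- if (is.null(fit$X)) NULL else fit$X
  u <- numeric(length(b))
  for (s in seq_along(fit$strata_levels)) {
    rows <- which(as.integer(fit$stratum) == s)
    if (!length(rows)) next
    if (is.null(x_all)) {
      u[rows] <- model_cdf(fit$model, b[rows], fit$strata_levels[s])
    } else {
      eta <- drop(basis_eval(fit$model$basis, b[rows]) %*%
                    fit$model$theta[s, ]) +
        drop(x_all[rows, , drop = FALSE] %*% fit$model$beta)
      u[rows] <- colreg_link(fit$model$link)$F(eta)
    }
  }
  out <- tibble::tibble(stratum = as.character(fit$stratum), b = b, u = u,
                        approximate = !obs$is_exact)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  attr(out, "ks") <- tibble::tibble(statistic = unname(ks$statistic),
                                    p.value = ks$p.value)
  out
}

#' @rdname colreg_residuals
#' @export
pit_test <- function(fit) {
  attr(colreg_residuals(fit), "ks")
}
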