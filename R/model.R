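#' @importFrom rlang .data
#' @importFrom stats plogis qlogis dlogis
NULL

# link machinery: F = inverse link applied to the transformation, f = its
# density, dlogf = d/d eta log f (needed for exact-scale score contributions),
# q = forward link (quantile of the error distribution)
colreg_link <- function(name = c("logit", "cloglog")) {
  name <- match.arg(name)
  if (name == "logit") {
    list(name = "logit",
         F = stats::plogis,
         f = stats::dlogis,
         logf = function(eta) stats::dlogis(eta, log = TRUE),
         dlogf = function(eta) 1 - 2 * stats::plogis(eta),
         q = stats::qlogis)
  } else {
    # minimum extreme value: F(eta) = 1 - exp(-exp(eta)) (Cox / proportional
    # hazards connection)
    list(name = "cloglog",
         F = function(eta) -expm1(-exp(eta)),
         f = function(eta) exp(eta - exp(eta)),
         logf = function(eta) eta - exp(eta),
         dlogf = function(eta) 1 - exp(eta),
         q = function(p) log(-log1p(-p)))
  }
}

#' Construct a continuous outcome logistic regression model
#'
#' Builds a model object from known parameters: one non-decreasing coefficient
#' block of the monotone intercept function per stratum, plus an optional
#' constant covariate shift `beta`. The model states
#' `link(P(Y <= b | stratum, x)) = alpha_stratum(b) + x' beta`, so positive
#' `beta` entries shift probability mass towards *lower* outcome values
#' (`exp(beta)` is an odds ratio for the event `Y <= b`, for every `b`).
#' This is the object the synthetic cohort generator samples from, and the
#' object a fit estimates.
#'
#' @param theta Numeric matrix of intercept coefficients, one row per stratum
#'   (row names label the strata), one column per basis coefficient; each row
#'   must be non-decreasing.
#' @param basis A [bernstein_basis()] or [step_basis()].
#' @param beta Named numeric vector of shift coefficients (may be `NULL`).
#' @param link `"logit"` (default, odds-ratio scale) or `"cloglog"`
#'   (hazard-ratio scale).
#' @return An object of class `colreg_model`.
#' @examples
#' bb <- bernstein_basis(5, support_window(13, 45))
#' th <- rbind(Female = qlogis(pnorm(seq(13, 45, length.out = 6), 23, 4)),
#'             Male   = qlogis(pnorm(seq(13, 45, length.out = 6), 25.5, 4)))
#' m <- colreg_model(th, bb, beta = c(age = log(0.97)))
#' model_cdf(m, c(18.5, 25, 30), stratum = "Female")
#' @export
colreg_model <- function(theta, basis, beta = NULL, link = c("logit", "cloglog")) {
  stopifnot(inherits(basis, "colreg_basis"))
  theta <- as.matrix(theta)
  if (ncol(theta) != n_coef(basis)) {
    stop(sprintf("theta must have %d columns to match the basis", n_coef(basis)),
         call. = FALSE)
  }
  if (is.null(rownames(theta))) {
    rownames(theta) <- if (nrow(theta) == 1L) "all" else
      paste0("stratum", seq_len(nrow(theta)))
  }
  bad <- apply(theta, 1L, function(r) any(diff(r) < -1e-10))
  if (any(bad)) {
    stop("each stratum coefficient block must be non-decreasing: ",
         paste(rownames(theta)[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(beta)) {
    beta <- stats::setNames(as.numeric(beta),
                            names(beta) %||% paste0("x", seq_along(beta)))
  }
  structure(
    list(theta = theta, beta = beta, basis = basis,
         link = match.arg(link)),
    class = "colreg_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strata_labels <- function(model) rownames(model$theta)

#' @export
print.colreg_model <- function(x, ...) {
  cat(sprintf("<colreg model: %d strata, %s link, %s>\n",
              nrow(x$theta), x$link,
              if (x$basis$kind == "bernstein")
                sprintf("Bernstein order %d on [%.4g, %.4g]",
                        x$basis$order, x$basis$window$lower, x$basis$window$upper)
              else sprintf("step basis at %s",
                           paste(format(x$basis$cutoffs), collapse = ", "))))
  if (!is.null(x$beta)) {
    cat("shift coefficients (log odds of Y <= b):\n")
    print(round(x$beta, 4))
  }
  invisible(x)
}

check_stratum <- function(model, stratum) {
  labs <- strata_labels(model)
  stratum <- as.character(stratum)
  bad <- setdiff(unique(stratum), labs)
  if (length(bad)) {
    stop("unknown stratum: ", paste(bad, collapse = ", "),
         " (known: ", paste(labs, collapse = ", "), ")", call. = FALSE)
  }
  stratum
}

shift_value <- function(model, x) {
  if (is.null(model$beta) || !length(model$beta)) return(0)
  if (is.null(x)) return(0)
  x <- as.numeric(x)
  if (length(x) != length(model$beta)) {
    stop(sprintf("covariate vector must have length %d", length(model$beta)),
         call. = FALSE)
  }
  sum(x * model$beta)
}

#' Evaluate a model's transformation, distribution, density and quantiles
#'
#' `model_transform()` returns the linear predictor
#' `alpha_stratum(b) + x' beta`; `model_cdf()` its inverse-link, the
#' conditional distribution function `P(Y <= b | stratum, x)`, pinned to 0 at
#' the hard lower bound and 1 at the hard upper bound; `model_pdf()` the
#' conditional density (link density times the derivative of the
#' transformation); `model_quantile()` the inverse of the conditional
#' distribution function, found by bracketed root-finding.
#'
#' @param model A [colreg_model()] or fitted model.
#' @param b Numeric vector of outcome values (`model_quantile()` takes `p`,
#'   probabilities strictly between 0 and 1, instead).
#' @param p Probabilities in (0, 1).
#' @param stratum A single stratum label (one of `rownames(model$theta)`).
#' @param x Covariate vector matching `model$beta` (default: all zero, the
#'   baseline).
#' @return Numeric vector, same length as `b` (or `p`).
#' @export
model_transform <- function(model, b, stratum, x = NULL) {
  stratum <- check_stratum(model, stratum)
  stopifnot(length(stratum) == 1L)
  A <- basis_eval(model$basis, b)
  drop(A %*% model$theta[stratum, ]) + shift_value(model, x)
}

#' @rdname model_transform
#' @export
model_cdf <- function(model, b, stratum, x = NULL) {
  w <- model$basis$window
  lnk <- colreg_link(model$link)
  out <- numeric(length(b))
  at_lo <- b <= w$hard_lower
  at_hi <- b >= w$hard_upper
  mid <- !(at_lo | at_hi)
  out[at_lo] <- 0
  out[at_hi] <- 1
  if (any(mid)) {
    out[mid] <- lnk$F(model_transform(model, b[mid], stratum, x))
  }
  out
}

#' @rdname model_transform
#' @export
model_pdf <- function(model, b, stratum, x = NULL) {
  w <- model$basis$window
  if (any(b <= w$hard_lower | b >= w$hard_upper)) {
    stop("density is defined strictly inside the hard bounds", call. = FALSE)
  }
  stratum <- check_stratum(model, stratum)
  stopifnot(length(stratum) == 1L)
  lnk <- colreg_link(model$link)
  eta <- model_transform(model, b, stratum, x)
  # log-scale assembly: log f_link(eta) + log alpha'(b)
  D <- basis_deriv_extrap(model$basis, b)
  ap <- pmax(drop(D %*% model$theta[stratum, ]), 0)
  exp(lnk$logf(eta) + log(ap))
}

# derivative rows with the linear-continuation convention outside the window:
# constant endpoint derivative
basis_deriv_extrap <- function(basis, b) {
  w <- basis$window
  basis_deriv(basis, pmin(pmax(b, w$lower), w$upper))
}

#' @rdname model_transform
#' @export
model_quantile <- function(model, p, stratum, x = NULL) {
  if (any(p <= 0 | p >= 1)) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  stratum <- check_stratum(model, stratum)
  stopifnot(length(stratum) == 1L)
  lnk <- colreg_link(model$link)
  target <- lnk$q(p) - shift_value(model, x)
  alpha_inverse(model$basis, model$theta[stratum, ], target)
}

# invert the monotone transformation alpha(b) = t by bracket expansion +
# uniroot; alpha is linear outside the window so a bracket always exists
# unless the endpoint slope is zero (flat tail), which admissible but
# degenerate coefficient blocks can produce — report that clearly.
alpha_inverse <- function(basis, theta_s, target) {
  alpha <- function(b) drop(basis_eval(basis, b) %*% theta_s)
  w <- basis$window
  vapply(target, function(t1) {
    lo <- w$lower; hi <- w$upper
    span <- hi - lo
    for (i in 1:60) {
      if (alpha(lo) <= t1) break
      lo <- lo - span
      if (w$hard_lower > -Inf && lo < w$hard_lower) { lo <- w$hard_lower; break }
    }
    if (alpha(lo) > t1) {
      if (abs(lo - w$hard_lower) < 1e-12) return(w$hard_lower)
      stop("quantile bracket failed below the window (flat lower tail)",
           call. = FALSE)
    }
    for (i in 1:60) {
      if (alpha(hi) >= t1) break
      hi <- hi + span
    }
    if (alpha(hi) < t1) {
      stop("quantile bracket failed above the window (flat upper tail)",
           call. = FALSE)
    }
    stats::uniroot(function(b) alpha(b) - t1, lower = lo, upper = hi,
                   tol = 1e-12)$root
  }, numeric(1))
}

# vectorised inverse for the simulator: dense grid + monotone interpolation,
# then Newton polish on the smooth transformation (exact in the linear tails)
alpha_inverse_fast <- function(basis, theta_s, target, n_grid = 2048L) {
  w <- basis$window
  grid <- seq(w$lower, w$upper, length.out = n_grid)
  ag <- drop(basis_eval(basis, grid) %*% theta_s)
  # strictly increasing grid values required by approx(); collapse flat spots
  keep <- c(TRUE, diff(ag) > 1e-12)
  b <- stats::approx(ag[keep], grid[keep], xout = target, rule = 2)$y
  slope_lo <- drop(basis_deriv(basis, w$lower) %*% theta_s)
  slope_hi <- drop(basis_deriv(basis, w$upper) %*% theta_s)
  below <- target < ag[1]
  above <- target > ag[length(ag)]
  if (any(below)) b[below] <- w$lower + (target[below] - ag[1]) / slope_lo
  if (any(above)) b[above] <- w$upper + (target[above] - ag[length(ag)]) / slope_hi
  inside <- !(below | above)
  for (i in 1:4) {
    if (!any(inside)) break
    fb <- drop(basis_eval(basis, b[inside]) %*% theta_s) - target[inside]
    db <- pmax(drop(basis_deriv(basis, b[inside]) %*% theta_s), 1e-12)
    b[inside] <- pmin(pmax(b[inside] - fb / db, w$lower), w$upper)
  }
  b
}
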