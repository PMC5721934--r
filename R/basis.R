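#' Support window for a positive continuous outcome
#'
#' A fit operates on a finite support window `[lower, upper]` inside hard
#' theoretical bounds (for BMI: 0 and infinity). The monotone basis is defined
#' on the window; outside it the transformation is continued linearly, and the
#' distribution function is pinned to 0 at `hard_lower` and 1 at `hard_upper`.
#'
#' @param lower,upper Finite endpoints of the support window, in outcome units.
#' @param hard_lower,hard_upper Theoretical bounds of the outcome; the
#'   conditional distribution function is 0 at `hard_lower` and 1 at
#'   `hard_upper`. Defaults suit a positive outcome such as BMI.
#' @return An object of class `colreg_window`.
#' @examples
#' support_window(13, 45)
#' @export
support_window <- function(lower, upper, hard_lower = 0, hard_upper = Inf) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("support window must be finite with lower < upper", call. = FALSE)
  }
  if (hard_lower > lower || upper > hard_upper) {
    stop("support window must lie inside the hard bounds", call. = FALSE)
  }
  structure(
    list(lower = lower, upper = upper,
         hard_lower = hard_lower, hard_upper = hard_upper),
    class = "colreg_window"
  )
}

#' Choose a support window from observed outcomes
#'
#' The window spans the empirical 1st and 99th percentiles of the observation
#' midpoints, widened by `add` outcome units on each side and clamped to the
#' hard bounds.
#'
#' @param midpoints Numeric vector of outcome midpoints (exact values, or
#'   interval midpoints / finite endpoints for censored rows).
#' @param prob Two probabilities defining the central span (default 1st and
#'   99th percentiles).
#' @param add Widening applied to the two percentiles, in outcome units.
#' @inheritParams support_window
#' @return A `colreg_window`.
#' @export
support_from_data <- function(midpoints, prob = c(0.01, 0.99), add = c(-5, 5),
                              hard_lower = 0, hard_upper = Inf) {
  midpoints <- midpoints[is.finite(midpoints)]
  if (length(midpoints) < 2L) {
    stop("need at least two finite outcome values to choose a support window",
         call. = FALSE)
  }
  qs <- stats::quantile(midpoints, probs = prob, names = FALSE) + add
  lo <- max(hard_lower, qs[1])
  hi <- min(hard_upper, qs[2])
  support_window(lo, hi, hard_lower = hard_lower, hard_upper = hard_upper)
}

#' Monotone bases over the outcome
#'
#' `bernstein_basis()` builds a Bernstein polynomial basis of a given order on
#' a support window: with non-decreasing coefficients the resulting
#' transformation is smooth and monotone, which is what makes it usable as a
#' stratum intercept function of a distribution-regression model.
#' `step_basis()` builds the step-function alternative used when the outcome is
#' only ever evaluated at a fixed set of category boundaries (e.g. the WHO BMI
#' cut-offs), reproducing a proportional-odds parameterisation.
#'
#' @param order Polynomial order (number of coefficients is `order + 1`).
#' @param window A [support_window()].
#' @param cutoffs Strictly increasing category boundaries, inside the open
#'   hard-bound interval.
#' @return An object of class `colreg_basis`.
#' @examples
#' bernstein_basis(5, support_window(13, 45))
#' step_basis(c(18.5, 25, 30))
#' @export
bernstein_basis <- function(order = 5, window) {
  stopifnot(inherits(window, "colreg_window"))
  order <- as.integer(order)
  if (is.na(order) || order < 1L || order > 20L) {
    stop("bernstein order must be an integer in 1..20", call. = FALSE)
  }
  structure(
    list(kind = "bernstein", order = order, cutoffs = NULL, window = window),
    class = "colreg_basis"
  )
}

#' @rdname bernstein_basis
#' @export
step_basis <- function(cutoffs = c(18.5, 25, 30), window = NULL) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1L || any(!is.finite(cutoffs)) ||
      is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be finite and strictly increasing", call. = FALSE)
  }
  if (is.null(window)) {
    pad <- max(1, diff(range(cutoffs)) / 2)
    window <- support_window(max(0, min(cutoffs) - pad), max(cutoffs) + pad)
  }
  if (any(cutoffs <= window$hard_lower) || any(cutoffs >= window$hard_upper)) {
    stop("cutoffs must lie strictly inside the hard bounds", call. = FALSE)
  }
  structure(
    list(kind = "step", order = NULL, cutoffs = cutoffs, window = window),
    class = "colreg_basis"
  )
}

n_coef <- function(basis) {
  if (basis$kind == "bernstein") basis$order + 1L else length(basis$cutoffs)
}

#' @export
print.colreg_basis <- function(x, ...) {
  if (x$kind == "bernstein") {
    cat(sprintf("<Bernstein basis, order %d, support [%.6g, %.6g]>\n",
                x$order, x$window$lower, x$window$upper))
  } else {
    cat(sprintf("<step basis at cutoffs %s>\n",
                paste(format(x$cutoffs), collapse = ", ")))
  }
  invisible(x)
}

# raw Bernstein rows on u in [0,1]: B_{k,n}(u) = choose(n,k) u^k (1-u)^(n-k)
bernstein_rows <- function(u, order) {
  k <- 0:order
  outer(u, k, function(u, k) {
    choose(order, k) * u^k * (1 - u)^(order - k)
  })
}

# derivative rows with respect to u
bernstein_deriv_rows <- function(u, order) {
  k <- 0:order
  outer(u, k, function(u, k) {
    choose(order, k) *
      (ifelse(k == 0, 0, k * u^pmax(k - 1, 0) * (1 - u)^(order - k)) -
         ifelse(k == order, 0,
                (order - k) * u^k * (1 - u)^pmax(order - k - 1, 0)))
  })
}

#' Evaluate a monotone basis
#'
#' `basis_eval()` returns, for each outcome value `b`, the row of basis weights
#' whose inner product with a coefficient vector gives the transformation
#' value; `basis_deriv()` returns the corresponding derivative weights with
#' respect to `b`. For a Bernstein basis, values inside the window are the
#' standard Bernstein weights on the rescaled outcome (non-negative, summing
#' to one); outside the window the weights continue the transformation
#' linearly from the nearest endpoint (endpoint value plus endpoint slope),
#' so monotonicity is preserved for all `b`. A step basis may only be
#' evaluated exactly at its cutoffs, where it yields a one-hot row.
#'
#' @param basis A [bernstein_basis()] or [step_basis()].
#' @param b Numeric vector of outcome values (all finite).
#' @return A numeric matrix with `length(b)` rows and one column per basis
#'   coefficient.
#' @examples
#' bb <- bernstein_basis(5, support_window(0, 1))
#' basis_eval(bb, c(0, 0.3, 1))
#' @export
basis_eval <- function(basis, b) {
  stopifnot(inherits(basis, "colreg_basis"))
  if (length(b) && (!is.numeric(b) || any(!is.finite(b)))) {
    stop("outcome values must be finite numbers", call. = FALSE)
  }
  if (basis$kind == "step") {
    return(step_rows(basis, b))
  }
  w <- basis$window
  rng <- w$upper - w$lower
  u <- (b - w$lower) / rng
  A <- bernstein_rows(pmin(pmax(u, 0), 1), basis$order)
  lo <- which(u < 0)
  hi <- which(u > 1)
  if (length(lo)) {
    A0 <- bernstein_rows(0, basis$order)
    D0 <- bernstein_deriv_rows(0, basis$order) / rng
    A[lo, ] <- rep(1, length(lo)) %o% A0[1, ] +
      (b[lo] - w$lower) %o% D0[1, ]
  }
  if (length(hi)) {
    A1 <- bernstein_rows(1, basis$order)
    D1 <- bernstein_deriv_rows(1, basis$order) / rng
    A[hi, ] <- rep(1, length(hi)) %o% A1[1, ] +
      (b[hi] - w$upper) %o% D1[1, ]
  }
  A
}

#' @rdname basis_eval
#' @export
basis_deriv <- function(basis, b) {
  stopifnot(inherits(basis, "colreg_basis"))
  if (basis$kind == "step") {
    stop("a step basis has no derivative; it is evaluated only at cutoffs",
         call. = FALSE)
  }
  if (length(b) && (!is.numeric(b) || any(!is.finite(b)))) {
    stop("outcome values must be finite numbers", call. = FALSE)
  }
  w <- basis$window
  rng <- w$upper - w$lower
  u <- pmin(pmax((b - w$lower) / rng, 0), 1)
  bernstein_deriv_rows(u, basis$order) / rng
}

step_rows <- function(basis, b, tol = 1e-8) {
  idx <- vapply(b, function(bi) {
    j <- which(abs(basis$cutoffs - bi) <= tol)
    if (length(j) != 1L) {
      stop(sprintf(
        "step basis evaluated at %g, which is not one of its cutoffs (%s)",
        bi, paste(format(basis$cutoffs), collapse = ", ")), call. = FALSE)
    }
    j
  }, integer(1))
  A <- matrix(0, length(b), length(basis$cutoffs))
  A[cbind(seq_along(b), idx)] <- 1
  A
}

#' Linear monotonicity constraints of a basis
#'
#' Returns the constraint matrix `C` such that a coefficient vector `theta` is
#' admissible (the fitted transformation non-decreasing in the outcome) iff
#' `C %*% theta >= 0`. For both basis kinds these are the consecutive
#' differences `theta[k+1] - theta[k]`; ties are permitted and correspond to
#' locally flat transformations (zero density there).
#'
#' @param basis A `colreg_basis`.
#' @return A `(p - 1) x p` matrix of difference constraints, where `p` is the
#'   number of basis coefficients.
#' @export
monotonicity_constraints <- function(basis) {
  p <- n_coef(basis)
  C <- matrix(0, p - 1L, p)
  C[cbind(seq_len(p - 1L), seq_len(p - 1L))] <- -1
  C[cbind(seq_len(p - 1L), seq_len(p - 1L) + 1L)] <- 1
  C
}
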