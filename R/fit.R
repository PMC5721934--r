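#' Control options for model fitting
#'
#' @param max_iter Maximum quasi-Newton iterations.
#' @param tol_grad Convergence tolerance: the fit is flagged converged when the
#'   sup-norm of the score in the free parameterisation falls below
#'   `tol_grad * (1 + |negative log-likelihood|)`.
#' @param reltol Relative tolerance passed to the optimizer.
#' @param restarts Number of times the optimizer is restarted from its current
#'   point when the gradient criterion is not yet met.
#' @param floor_eps Lower floor applied to interval probabilities and to the
#'   transformation derivative before taking logs; floored evaluations are
#'   counted and reported in the fit.
#' @param hessian_step Relative step for the central-difference Hessian used
#'   for the covariance of the estimates.
#' @param divergence_bound Absolute coefficient size beyond which the fit is
#'   flagged as divergent (e.g. complete separation at a cut-off).
#' @param vcov If `FALSE`, skip the Hessian-based covariance (useful in
#'   bootstrap loops where only point estimates are needed).
#' @return A list of class `colreg_control`.
#' @export
colreg_control <- function(max_iter = 500L, tol_grad = 1e-6, reltol = 1e-12,
                           restarts = 2L, floor_eps = 1e-12,
                           hessian_step = 1e-5, divergence_bound = 25,
                           vcov = TRUE) {
  structure(list(max_iter = as.integer(max_iter), tol_grad = tol_grad,
                 reltol = reltol, restarts = as.integer(restarts),
                 floor_eps = floor_eps, hessian_step = hessian_step,
                 divergence_bound = divergence_bound, vcov = isTRUE(vcov)),
            class = "colreg_control")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
inv_softplus <- function(y) ifelse(y > 20, y, log(expm1(pmax(y, 1e-12))))

# free parameterisation: per stratum, theta_1 is free and subsequent
# coefficients add softplus increments, so every admissible (non-decreasing)
# block maps to an unconstrained vector and back
free_to_theta <- function(gam) {
  if (ncol(gam) == 1L) return(gam)
  inc <- softplus(gam[, -1, drop = FALSE])
  theta <- cbind(gam[, 1], inc)
  t(apply(theta, 1L, cumsum))
}

theta_to_free <- function(theta) {
  if (ncol(theta) == 1L) return(theta)
  d <- t(apply(theta, 1L, diff))
  if (ncol(theta) == 2L) d <- matrix(d, ncol = 1L)
  cbind(theta[, 1], inv_softplus(pmax(d, 1e-6)))
}

# jacobian d theta_s / d gamma_s for one stratum (lower triangular)
free_jacobian_block <- function(gam_s) {
  K <- length(gam_s)
  J <- matrix(0, K, K)
  J[, 1] <- 1
  if (K > 1L) {
    sig <- stats::plogis(gam_s[-1])
    for (j in 2:K) J[j:K, j] <- sig[j - 1]
  }
  J
}

split_par <- function(par, S, K, p) {
  gam <- matrix(par[seq_len(S * K)], S, K, byrow = TRUE)
  beta <- if (p) par[S * K + seq_len(p)] else numeric(0)
  list(gam = gam, theta = free_to_theta(gam), beta = beta)
}

# ---- likelihood engine -----------------------------------------------------

# precomputed structures for one dataset: basis rows at every finite interval
# endpoint and at every exact value, plus index bookkeeping
build_fit_data <- function(obs, s_idx, X, basis, link, S, floor_eps) {
  w <- basis$window
  is_ex <- obs$is_exact
  int <- which(!is_ex)
  ex <- which(is_ex)
  up_fin <- int[obs$upper[int] < w$hard_upper]
  lo_fin <- int[obs$lower[int] > w$hard_lower]
  list(
    n = nrow(obs), S = S, K = n_coef(basis),
    p = if (is.null(X)) 0L else ncol(X),
    weight = obs$weight, s = s_idx, X = X,
    int = int, ex = ex, up_fin = up_fin, lo_fin = lo_fin,
    pos_up = match(up_fin, int), pos_lo = match(lo_fin, int),
    A_up = basis_eval(basis, obs$upper[up_fin]),
    A_lo = basis_eval(basis, obs$lower[lo_fin]),
    A_ex = if (length(ex)) basis_eval(basis, obs$exact[ex]) else NULL,
    D_ex = if (length(ex)) basis_deriv_extrap(basis, obs$exact[ex]) else NULL,
    lnk = colreg_link(link), eps = floor_eps
  )
}

block_eta <- function(A, theta, s_set, xb, rows) {
  if (!length(s_set)) return(numeric(0))
  drop(rowSums(A * theta[s_set, , drop = FALSE])) + xb[rows]
}

# negative log-likelihood plus score; state$floored records how many
# probability/derivative evaluations hit the floor at the queried parameters
negloglik_pieces <- function(par, fd, want_grad = FALSE) {
  if (any(!is.finite(par))) stop("non-finite parameters", call. = FALSE)
  sp <- split_par(par, fd$S, fd$K, fd$p)
  xb <- if (fd$p) drop(fd$X %*% sp$beta) else numeric(fd$n)
  if (!fd$p) xb <- rep(0, fd$n)
  lnk <- fd$lnk

  eta_up <- block_eta(fd$A_up, sp$theta, fd$s[fd$up_fin], xb, fd$up_fin)
  eta_lo <- block_eta(fd$A_lo, sp$theta, fd$s[fd$lo_fin], xb, fd$lo_fin)

  F_up <- rep(1, length(fd$int))
  F_lo <- rep(0, length(fd$int))
  if (length(fd$up_fin)) F_up[fd$pos_up] <- lnk$F(eta_up)
  if (length(fd$lo_fin)) F_lo[fd$pos_lo] <- lnk$F(eta_lo)
  P <- F_up - F_lo
  floored_int <- P < fd$eps
  Pf <- pmax(P, fd$eps)
  ll <- sum(fd$weight[fd$int] * log(Pf))

  floored_ex <- logical(0)
  if (length(fd$ex)) {
    eta_ex <- block_eta(fd$A_ex, sp$theta, fd$s[fd$ex], xb, fd$ex)
    ap <- drop(rowSums(fd$D_ex * sp$theta[fd$s[fd$ex], , drop = FALSE]))
    floored_ex <- ap < fd$eps
    apf <- pmax(ap, fd$eps)
    ll <- ll + sum(fd$weight[fd$ex] * (lnk$logf(eta_ex) + log(apf)))
  }

  out <- list(nll = -ll, floored = sum(floored_int) + sum(floored_ex))
  if (!want_grad) return(out)

  gt <- matrix(0, fd$S, fd$K)
  coef_row <- numeric(fd$n)
  add_block <- function(A, coefs, s_set) {
    if (!length(s_set)) return(invisible())
    gb <- rowsum(A * coefs, group = s_set)
    r <- as.integer(rownames(gb))
    gt[r, ] <<- gt[r, , drop = FALSE] + gb
    invisible()
  }
  if (length(fd$up_fin)) {
    c_up <- fd$weight[fd$up_fin] * lnk$f(eta_up) / Pf[fd$pos_up]
    c_up[floored_int[fd$pos_up]] <- 0
    add_block(fd$A_up, c_up, fd$s[fd$up_fin])
    coef_row[fd$up_fin] <- coef_row[fd$up_fin] + c_up
  }
  if (length(fd$lo_fin)) {
    c_lo <- -fd$weight[fd$lo_fin] * lnk$f(eta_lo) / Pf[fd$pos_lo]
    c_lo[floored_int[fd$pos_lo]] <- 0
    add_block(fd$A_lo, c_lo, fd$s[fd$lo_fin])
    coef_row[fd$lo_fin] <- coef_row[fd$lo_fin] + c_lo
  }
  if (length(fd$ex)) {
    c_ex <- fd$weight[fd$ex] * lnk$dlogf(eta_ex)
    add_block(fd$A_ex, c_ex, fd$s[fd$ex])
    coef_row[fd$ex] <- coef_row[fd$ex] + c_ex
    c_ap <- fd$weight[fd$ex] / pmax(ap, fd$eps)
    c_ap[floored_ex] <- 0
    add_block(fd$D_ex, c_ap, fd$s[fd$ex])
  }
  # chain rule through the softplus reparameterisation, per stratum block
  g_free <- numeric(fd$S * fd$K)
  for (srow in seq_len(fd$S)) {
    gts <- gt[srow, ]
    rc <- rev(cumsum(rev(gts)))
    gg <- if (fd$K > 1L) {
      c(rc[1], stats::plogis(sp$gam[srow, -1]) * rc[-1])
    } else rc
    g_free[(srow - 1L) * fd$K + seq_len(fd$K)] <- gg
  }
  g_beta <- if (fd$p) drop(crossprod(fd$X, coef_row)) else numeric(0)
  out$grad <- -c(g_free, g_beta)
  out
}

hessian_central <- function(par, fd, step_rel) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- step_rel * (1 + abs(par[j]))
    ej <- numeric(p); ej[j] <- h
    gp <- negloglik_pieces(par + ej, fd, want_grad = TRUE)$grad
    gm <- negloglik_pieces(par - ej, fd, want_grad = TRUE)$grad
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

safe_inverse <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && all(is.finite(V)) && all(diag(V) > -1e-8)) {
    return((V + t(V)) / 2)
  }
  es <- eigen(H, symmetric = TRUE)
  lam <- es$values
  tol <- max(abs(lam)) * 1e-10
  inv <- ifelse(lam > tol, 1 / lam, 0)
  V <- es$vectors %*% (inv * t(es$vectors))
  (V + t(V)) / 2
}

# ---- observation handling --------------------------------------------------

# normalise outcome columns into (exact | half-open interval (lower, upper])
# form; NA/empty interval ends stand for the hard bounds
standardize_observations <- function(data, exact_col = "exact",
                                     lower_col = "lower", upper_col = "upper",
                                     weight_col = NULL,
                                     hard_lower = 0, hard_upper = Inf) {
  n <- nrow(data)
  getcol <- function(nm) {
    if (!is.null(nm) && nm %in% names(data)) as.numeric(data[[nm]])
    else rep(NA_real_, n)
  }
  exact <- getcol(exact_col)
  lower <- getcol(lower_col)
  upper <- getcol(upper_col)
  weight <- if (!is.null(weight_col)) {
    if (!weight_col %in% names(data)) {
      stop("weight column '", weight_col, "' not found", call. = FALSE)
    }
    as.numeric(data[[weight_col]])
  } else rep(1, n)

  has_exact <- !is.na(exact)
  has_int <- !is.na(lower) | !is.na(upper)
  lo <- ifelse(is.na(lower), hard_lower, lower)
  up <- ifelse(is.na(upper), hard_upper, upper)

  bad <- (has_exact & has_int) | (!has_exact & !has_int) |
    (has_exact & (exact <= hard_lower | exact >= hard_upper | !is.finite(exact))) |
    (!has_exact & (lo >= up | lo < hard_lower | up > hard_upper)) |
    is.na(weight) | weight < 0
  bad[is.na(bad)] <- TRUE

  tbl <- tibble::tibble(
    exact = ifelse(has_exact, exact, NA_real_),
    lower = ifelse(has_exact, NA_real_, lo),
    upper = ifelse(has_exact, NA_real_, up),
    weight = weight,
    is_exact = has_exact
  )
  list(obs = tbl, bad = which(bad))
}

make_strata <- function(data, strata) {
  missing_cols <- setdiff(strata, names(data))
  if (length(missing_cols)) {
    stop("strata column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fs <- lapply(strata, function(v) {
    f <- data[[v]]
    if (!is.factor(f)) f <- factor(f)
    f
  })
  lab <- if (length(fs) == 1L) fs[[1]] else
    interaction(fs, sep = ":", lex.order = TRUE)
  lab <- factor(lab, levels = levels(lab))
  empty <- setdiff(levels(lab), unique(as.character(lab)))
  if (length(empty)) {
    stop("stratum without observations: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  lab
}

covariate_design <- function(data, covariates) {
  if (is.null(covariates)) {
    return(list(X = NULL, terms = NULL, xlevels = NULL))
  }
  if (is.character(covariates)) {
    covariates <- stats::reformulate(covariates)
  }
  mf <- stats::model.frame(covariates, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  asgn <- attr(X, "assign")
  X <- X[, asgn != 0, drop = FALSE]
  if (ncol(X) && qr(X)$rank < ncol(X)) {
    stop("covariate design matrix is rank deficient", call. = FALSE)
  }
  list(X = X, terms = tt, xlevels = stats::.getXlevels(tt, mf))
}

# data-adaptive feasible start: pooled weighted empirical CDF at the basis
# knots (or cutoffs), pushed through the link, increments floored
initial_free <- function(obs, s_idx, basis, link, S) {
  lnk <- colreg_link(link)
  mids <- ifelse(obs$is_exact, obs$exact,
                 ifelse(!is.finite(obs$upper), obs$lower,
                        ifelse(obs$lower <= basis$window$hard_lower, obs$upper,
                               (obs$lower + obs$upper) / 2)))
  pts <- if (basis$kind == "bernstein") {
    seq(basis$window$lower, basis$window$upper, length.out = n_coef(basis))
  } else basis$cutoffs
  Fhat <- stats::ecdf(mids)
  p <- pmin(pmax(Fhat(pts), 5e-3), 1 - 5e-3)
  th <- lnk$q(p)
  th <- th[1] + cumsum(c(0, pmax(diff(th), 0.05)))
  theta0 <- matrix(rep(th, each = S), S, length(th))
  c(t(theta_to_free(theta0)))
}

# ---- the fitting front end -------------------------------------------------

#' Fit a continuous outcome logistic regression model
#'
#' Maximum likelihood estimation of the distribution-regression model
#' `link(P(Y <= b | stratum, x)) = alpha_stratum(b) + x' beta` from per-subject
#' data whose outcome may be recorded as an exact value or as a half-open
#' interval `(lower, upper]` — exact measurements, rounding intervals, fixed
#' category grids and any mixture of them enter one joint likelihood. Interval
#' rows contribute `P(lower < Y <= upper)`; exact rows contribute the
#' conditional density. All parameters (stratum intercept blocks, kept
#' non-decreasing by a softplus reparameterisation, and shift coefficients
#' `beta`) are estimated simultaneously by unconstrained quasi-Newton
#' optimisation with an analytic score; the covariance of the estimates is the
#' inverse of a central-difference Hessian in the free parameterisation.
#'
#' Sign convention: the model describes `P(Y <= b)`, so `exp(beta) > 1` means
#' higher odds of *lower* outcome values.
#'
#' @param data A data frame with one row per subject. Outcome columns: either
#'   `exact_col` is non-missing (exact measurement) or at least one of
#'   `lower_col`/`upper_col` is (interval `(lower, upper]`; a missing end
#'   stands for the corresponding hard bound).
#' @param strata Character vector naming the stratifying factor columns (e.g.
#'   `c("smoking", "sex")`); one monotone intercept function is fitted per
#'   observed combination.
#' @param covariates A one-sided formula (or character vector of column names)
#'   for the constant-shift covariates; categorical covariates are
#'   dummy-encoded against their first level. `NULL` for a stratified model
#'   without covariates.
#' @param exact_col,lower_col,upper_col,weight_col Column names for the outcome
#'   representation and optional non-negative per-row weights.
#' @param basis `"bernstein"` (default), `"step"`, or a prebuilt
#'   [bernstein_basis()] / [step_basis()] object.
#' @param order Bernstein polynomial order when `basis = "bernstein"`.
#' @param cutoffs Cut-offs when `basis = "step"`.
#' @param support Optional [support_window()]; by default the window spans the
#'   1st–99th percentile of outcome midpoints widened by 5 units each side.
#' @param bounds Hard theoretical bounds of the outcome (default `c(0, Inf)`).
#' @param link `"logit"` (odds ratios) or `"cloglog"` (hazard ratios).
#' @param init Optional list with starting values `theta` (strata x
#'   coefficients matrix) and `beta`.
#' @param control A [colreg_control()] list.
#' @return An object of class `colreg_fit` (which inherits the fitted
#'   [colreg_model()] in `$model`), with log-likelihood, covariance,
#'   convergence diagnostics, and the data bookkeeping needed by
#'   [cdf_table()], [stratum_or()], [proportional_or()] and
#'   [colreg_residuals()].
#' @examples
#' d <- simulate_cohort(500, seed = 1)
#' d <- apply_scheme(d, "exact")
#' f <- colreg_fit(d, strata = "sex", covariates = ~ age_c)
#' glance(f)
#' @export
colreg_fit <- function(data, strata, covariates = NULL,
                       exact_col = "exact", lower_col = "lower",
                       upper_col = "upper", weight_col = NULL,
                       basis = c("bernstein", "step"), order = 5,
                       cutoffs = c(18.5, 25, 30), support = NULL,
                       bounds = c(0, Inf), link = c("logit", "cloglog"),
                       init = NULL, control = colreg_control()) {
  link <- match.arg(link)
  data <- as.data.frame(data)
  std <- standardize_observations(data, exact_col, lower_col, upper_col,
                                  weight_col, bounds[1], bounds[2])
  if (length(std$bad)) {
    stop("invalid outcome encoding in row(s): ",
         paste(utils::head(std$bad, 20), collapse = ", "),
         if (length(std$bad) > 20) " ...", call. = FALSE)
  }
  obs <- std$obs
  if (!nrow(obs)) stop("no observations", call. = FALSE)

  slab <- make_strata(data, strata)
  S <- nlevels(slab)
  s_idx <- as.integer(slab)

  des <- covariate_design(data, covariates)

  if (!inherits(basis, "colreg_basis")) {
    kind <- match.arg(basis)
    if (kind == "bernstein") {
      if (is.null(support)) {
        mids <- ifelse(obs$is_exact, obs$exact,
                       ifelse(!is.finite(obs$upper), obs$lower,
                              ifelse(obs$lower <= bounds[1], obs$upper,
                                     (obs$lower + obs$upper) / 2)))
        support <- support_from_data(mids, hard_lower = bounds[1],
                                     hard_upper = bounds[2])
      }
      basis <- bernstein_basis(order, support)
    } else {
      w <- support_window(max(bounds[1], min(cutoffs) - 1), max(cutoffs) + 1,
                          hard_lower = bounds[1], hard_upper = bounds[2])
      basis <- step_basis(cutoffs, w)
    }
  }
  if (basis$kind == "step" && any(obs$is_exact)) {
    stop("a step basis cannot absorb exact observations; use the Bernstein basis",
         call. = FALSE)
  }

  fd <- build_fit_data(obs, s_idx, des$X, basis, link, S, control$floor_eps)

  par0 <- if (!is.null(init)) {
    th0 <- as.matrix(init$theta)
    c(c(t(theta_to_free(th0))),
      if (fd$p) (init$beta %||% numeric(fd$p)) else numeric(0))
  } else {
    c(initial_free(obs, s_idx, basis, link, S), numeric(fd$p))
  }

  fn <- function(par) negloglik_pieces(par, fd)$nll
  gr <- function(par) negloglik_pieces(par, fd, want_grad = TRUE)$grad

  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = control$max_iter,
                                     reltol = control$reltol))
  tries <- 0L
  repeat {
    fin <- negloglik_pieces(opt$par, fd, want_grad = TRUE)
    gnorm <- max(abs(fin$grad))
    ok <- gnorm <= control$tol_grad * (1 + abs(fin$nll))
    if (ok || tries >= control$restarts) break
    tries <- tries + 1L
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = control$max_iter,
                                       reltol = control$reltol))
  }

  sp <- split_par(opt$par, S, fd$K, fd$p)
  # step-basis intercepts are per-category log odds, so huge values signal
  # separation; Bernstein tail coefficients may be legitimately extreme in
  # data-free regions and are not policed
  diverged <- (basis$kind == "step" &&
                 any(abs(sp$theta) > control$divergence_bound)) ||
    (fd$p > 0 && any(abs(sp$beta) > control$divergence_bound))
  converged <- ok && !diverged

  V <- if (control$vcov) {
    safe_inverse(hessian_central(opt$par, fd, control$hessian_step))
  } else {
    matrix(NA_real_, length(opt$par), length(opt$par))
  }

  theta <- sp$theta
  rownames(theta) <- levels(slab)
  beta <- if (fd$p) stats::setNames(sp$beta, colnames(des$X)) else NULL
  model <- colreg_model(theta, basis, beta = beta, link = link)

  par_names <- c(
    as.vector(t(outer(levels(slab), seq_len(fd$K),
                      function(s, k) paste0("theta[", s, ",", k, "]")))),
    if (fd$p) colnames(des$X)
  )

  structure(
    list(model = model, free = stats::setNames(opt$par, par_names),
         vcov = structure(V, dimnames = list(par_names, par_names)),
         loglik = -fin$nll, converged = converged, diverged = diverged,
         gradient_norm = gnorm, n_iter = opt$counts[["function"]],
         n_obs = nrow(obs), n_exact = sum(obs$is_exact),
         floored = fin$floored,
         strata_vars = strata, strata_levels = levels(slab),
         terms = des$terms, xlevels = des$xlevels,
         obs = obs, stratum = slab, X = des$X,
         control = control),
    class = "colreg_fit"
  )
}

#' Fit a binary logistic reduction at a single cut-off
#'
#' Dichotomises the outcome at `cutoff` (event `Y <= cutoff`) and fits the
#' single-cut-off step model, which is exactly a binary logistic regression
#' with one intercept per stratum plus the covariate shift. Interval rows that
#' straddle the cut-off cannot be dichotomised and raise an error.
#'
#' @inheritParams colreg_fit
#' @param cutoff The outcome cut-off defining the binary event.
#' @return A `colreg_fit` with a one-cut-off step basis.
#' @export
colreg_fit_binary <- function(data, cutoff, strata, covariates = NULL,
                              exact_col = "exact", lower_col = "lower",
                              upper_col = "upper", weight_col = NULL,
                              bounds = c(0, Inf), link = c("logit", "cloglog"),
                              control = colreg_control()) {
  data <- as.data.frame(data)
  std <- standardize_observations(data, exact_col, lower_col, upper_col,
                                  weight_col, bounds[1], bounds[2])
  if (length(std$bad)) {
    stop("invalid outcome encoding in row(s): ",
         paste(utils::head(std$bad, 20), collapse = ", "), call. = FALSE)
  }
  obs <- std$obs
  below <- ifelse(obs$is_exact, obs$exact <= cutoff,
                  ifelse(obs$upper <= cutoff, TRUE,
                         ifelse(obs$lower >= cutoff, FALSE, NA)))
  if (any(is.na(below))) {
    stop("observation interval straddles the cut-off in row(s): ",
         paste(utils::head(which(is.na(below)), 20), collapse = ", "),
         call. = FALSE)
  }
  data[[lower_col]] <- ifelse(below, NA_real_, cutoff)
  data[[upper_col]] <- ifelse(below, cutoff, NA_real_)
  if (!is.null(exact_col) && exact_col %in% names(data)) {
    data[[exact_col]] <- NA_real_
  }
  colreg_fit(data, strata = strata, covariates = covariates,
             exact_col = exact_col, lower_col = lower_col,
             upper_col = upper_col, weight_col = weight_col,
             basis = "step", cutoffs = cutoff, bounds = bounds,
             link = link, control = control)
}

# ---- standard methods ------------------------------------------------------

#' @export
print.colreg_fit <- function(x, ...) {
  cat("Continuous outcome logistic regression fit\n")
  cat(sprintf("  %d observations (%d exact, %d interval), %d strata, %s link\n",
              x$n_obs, x$n_exact, x$n_obs - x$n_exact,
              length(x$strata_levels), x$model$link))
  cat(sprintf("  log-likelihood %.3f, %s (max |score| %.2e)\n",
              x$loglik,
              if (x$converged) "converged" else
                if (x$diverged) "DIVERGED (possible separation)" else
                  "NOT converged",
              x$gradient_norm))
  if (!is.null(x$model$beta)) {
    cat("  shift odds ratios exp(beta) for the event Y <= b:\n")
    print(round(exp(x$model$beta), 4))
  }
  invisible(x)
}

#' @export
logLik.colreg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free), nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.colreg_fit <- function(object, ...) {
  c(stats::setNames(as.vector(t(object$model$theta)),
                    names(object$free)[seq_len(length(object$free) -
                                                 length(object$model$beta))]),
    object$model$beta)
}

#' Covariance of the estimates
#'
#' @param object A `colreg_fit`.
#' @param parameterization `"free"` returns the covariance in the
#'   unconstrained (softplus-increment) parameterisation used by the
#'   optimizer; `"natural"` maps it to the natural coefficients
#'   (theta blocks and beta) by the delta method.
#' @param ... Unused.
#' @export
vcov.colreg_fit <- function(object, parameterization = c("free", "natural"),
                            ...) {
  parameterization <- match.arg(parameterization)
  if (parameterization == "free") return(object$vcov)
  J <- full_jacobian(object)
  V <- J %*% object$vcov %*% t(J)
  dimnames(V) <- dimnames(object$vcov)
  (V + t(V)) / 2
}

# block-diagonal jacobian d(natural)/d(free) over all strata plus identity
# for beta
full_jacobian <- function(fit) {
  S <- length(fit$strata_levels)
  K <- n_coef(fit$model$basis)
  p <- length(fit$model$beta)
  gam <- matrix(fit$free[seq_len(S * K)], S, K, byrow = TRUE)
  J <- matrix(0, S * K + p, S * K + p)
  for (s in seq_len(S)) {
    idx <- (s - 1L) * K + seq_len(K)
    J[idx, idx] <- free_jacobian_block(gam[s, ])
  }
  if (p) {
    idx <- S * K + seq_len(p)
    J[idx, idx] <- diag(p)
  }
  J
}

#' Per-observation log-likelihood contributions under a known model
#'
#' Evaluates the mixed-scale likelihood at fixed parameters: an interval row
#' `(lower, upper]` contributes `weight * log(P(lower < Y <= upper))` (hard
#' bounds contributing 0 and 1), and an exact row contributes
#' `weight * log(density)`. Probabilities and transformation derivatives are
#' floored at `floor_eps` before the log; the number of floored rows is
#' attached as `attr(, "floored")`.
#'
#' @param data Per-subject data frame (see [colreg_fit()] for the outcome
#'   encoding).
#' @param model A `colreg_model` whose strata cover the data's strata and
#'   whose `beta` names match the covariate design columns.
#' @param strata Character vector of stratifying columns.
#' @param covariates One-sided formula or character vector (as in
#'   [colreg_fit()]); must produce design columns matching
#'   `names(model$beta)`.
#' @inheritParams colreg_fit
#' @param floor_eps Probability floor applied before taking logs.
#' @return A tibble with one row per observation: stratum, type
#'   (`"exact"`/`"interval"`), weight, loglik.
#' @export
obs_loglik <- function(data, model, strata, covariates = NULL,
                       exact_col = "exact", lower_col = "lower",
                       upper_col = "upper", weight_col = NULL,
                       floor_eps = 1e-12) {
  data <- as.data.frame(data)
  w <- model$basis$window
  std <- standardize_observations(data, exact_col, lower_col, upper_col,
                                  weight_col, w$hard_lower, w$hard_upper)
  if (length(std$bad)) {
    stop("invalid outcome encoding in row(s): ",
         paste(utils::head(std$bad, 20), collapse = ", "), call. = FALSE)
  }
  obs <- std$obs
  slab <- as.character(make_strata(data, strata))
  check_stratum(model, slab)
  des <- covariate_design(data, covariates)
  xb <- rep(0, nrow(obs))
  if (!is.null(model$beta) && length(model$beta)) {
    if (is.null(des$X) || !identical(colnames(des$X), names(model$beta))) {
      stop("covariate design columns must match names(model$beta)",
           call. = FALSE)
    }
    xb <- drop(des$X %*% model$beta)
  }
  lnk <- colreg_link(model$link)
  ll <- numeric(nrow(obs))
  floored <- logical(nrow(obs))
  for (s in unique(slab)) {
    rows <- which(slab == s)
    th <- model$theta[s, ]
    ex <- rows[obs$is_exact[rows]]
    if (length(ex)) {
      eta <- drop(basis_eval(model$basis, obs$exact[ex]) %*% th) + xb[ex]
      ap <- drop(basis_deriv_extrap(model$basis, obs$exact[ex]) %*% th)
      floored[ex] <- ap < floor_eps
      ll[ex] <- obs$weight[ex] * (lnk$logf(eta) + log(pmax(ap, floor_eps)))
    }
    int <- rows[!obs$is_exact[rows]]
    if (length(int)) {
      Fu <- rep(1, length(int))
      Fl <- rep(0, length(int))
      fin_u <- which(obs$upper[int] < w$hard_upper)
      fin_l <- which(obs$lower[int] > w$hard_lower)
      if (length(fin_u)) {
        Fu[fin_u] <- lnk$F(drop(basis_eval(model$basis,
                                           obs$upper[int][fin_u]) %*% th) +
                             xb[int][fin_u])
      }
      if (length(fin_l)) {
        Fl[fin_l] <- lnk$F(drop(basis_eval(model$basis,
                                           obs$lower[int][fin_l]) %*% th) +
                             xb[int][fin_l])
      }
      P <- Fu - Fl
      floored[int] <- P < floor_eps
      ll[int] <- obs$weight[int] * log(pmax(P, floor_eps))
    }
  }
  out <- tibble::tibble(
    stratum = slab,
    type = ifelse(obs$is_exact, "exact", "interval"),
    weight = obs$weight, loglik = ll
  )
  attr(out, "floored") <- sum(floored)
  out
}
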