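# shared fixtures: a small two-stratum ground-truth model whose intercept
# blocks are exact members of the Bernstein family, plus a two-covariate
# sampler used by the recovery and coverage checks

toy_window <- function() support_window(13, 45, hard_lower = 0,
                                        hard_upper = Inf)

toy_theta <- function(order = 5, link = "logit",
                      med = c(A = 22, B = 25), sdl = c(A = 0.15, B = 0.13)) {
  bb <- bernstein_basis(order, toy_window())
  knots <- seq(13, 45, length.out = order + 1)
  lnk_q <- if (link == "logit") stats::qlogis else
    function(p) log(-log1p(-p))
  th <- t(vapply(names(med), function(s) {
    lnk_q(pmin(pmax(plnorm(knots, log(med[s]), sdl[s]), 1e-9), 1 - 1e-9))
  }, numeric(order + 1)))
  rownames(th) <- names(med)
  th
}

toy_model <- function(beta = NULL, order = 5, link = "logit") {
  colreg_model(toy_theta(order, link), bernstein_basis(order, toy_window()),
               beta = beta, link = link)
}

# x1 continuous, x2 binary; design columns are the raw columns
toy_sampler <- function(n) {
  tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
}

sim_toy <- function(n, beta = c(x1 = log(1.25), x2 = log(0.8)), seed = NULL,
                    link = "logit") {
  m <- toy_model(beta = beta, link = link)
  simulate_cohort(n, m, covariate_sampler = if (!is.null(beta)) toy_sampler,
                  formula = if (!is.null(beta)) ~ x1 + x2, seed = seed)
}

# random admissible coefficient block: increasing with random start/steps
random_increasing <- function(k, rng_start = c(-8, -2), rng_step = c(0, 2)) {
  cumsum(c(stats::runif(1, rng_start[1], rng_start[2]),
           stats::runif(k - 1, rng_step[1], rng_step[2])))
}

# model with appreciable mass in every WHO category for both strata, so
# categorical likelihoods are well conditioned
who_friendly_model <- function(beta = c(x1 = log(1.25), x2 = log(0.8))) {
  colreg_model(toy_theta(med = c(A = 22, B = 24.5),
                         sdl = c(A = 0.17, B = 0.18)),
               bernstein_basis(5, toy_window()), beta = beta)
}

# independent proportional-odds oracle: direct categorical likelihood,
# unconstrained parameters, generic optimizer (no shared code with the
# package's likelihood engine)
po_oracle <- function(d, cutoffs = c(18.5, 25, 30)) {
  s <- as.integer(factor(d$stratum))
  X <- cbind(x1 = d$x1, x2 = d$x2)
  cat_idx <- findInterval(d$bmi, cutoffs, left.open = TRUE) + 1L
  S <- max(s); K <- length(cutoffs)
  nll <- function(par) {
    zeta <- matrix(par[1:(S * K)], S, K, byrow = TRUE)
    beta <- par[S * K + 1:2]
    xb <- drop(X %*% beta)
    Fmat <- cbind(0, plogis(zeta[s, , drop = FALSE] + xb), 1)
    pr <- Fmat[cbind(seq_len(nrow(d)), cat_idx + 1L)] -
      Fmat[cbind(seq_len(nrow(d)), cat_idx)]
    if (any(pr <= 0)) return(1e10)   # infeasible ordering: hard wall
    -sum(log(pr))
  }
  # feasible start: per-stratum empirical cumulative logits (stratum-major)
  start <- c(sapply(seq_len(S), function(si) {
    qlogis(pmin(pmax(sapply(cutoffs, function(co) mean(d$bmi[s == si] <= co)),
                     1e-3), 1 - 1e-3))
  }), 0, 0)
  o <- optim(start, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  for (i in 1:3) {
    o <- optim(o$par, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  }
  list(theta = matrix(o$par[1:(S * K)], S, K, byrow = TRUE),
       beta = o$par[S * K + 1:2], value = o$value)
}

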