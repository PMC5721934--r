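#' Built-in ground-truth model for a survey-style BMI cohort
#'
#' A `colreg_model` over the ten strata formed by five smoking levels (never,
#' former, light, moderate(= medium), heavy) and two sexes. Each stratum's
#' intercept coefficients are the logit of a right-skewed target distribution
#' evaluated at the Bernstein knots on a [13, 45] support window (hard bounds
#' 0 and infinity), giving BMI distributions with medians near 22.3 kg/m^2 for
#' females and 24.8 for males, skewed to the right; the resulting model is an
#' exact member of the fitted family. The default shift coefficients cover
#' age (centered at 40 years), alcohol intake (g/day), and dummy-encoded
#' fruit/vegetable consumption, physical activity, education, nationality and
#' language region, with odds-ratio magnitudes typical of population BMI
#' surveys.
#'
#' @param order Bernstein order of the true intercept functions.
#' @param link `"logit"` or `"cloglog"`.
#' @param beta Shift coefficients; `NULL` for the stratified model without
#'   covariates; the default covers the survey covariate set.
#' @return A `colreg_model` carrying the covariate formula and factor levels
#'   used by [simulate_cohort()] as attributes.
#' @export
bmi_preset <- function(order = 5, link = "logit", beta = bmi_preset_beta()) {
  smoking <- c("Never", "Former", "Light", "Medium", "Heavy")
  sex <- c("Female", "Male")
  window <- support_window(13, 45, hard_lower = 0, hard_upper = Inf)
  basis <- bernstein_basis(order, window)
  knots <- seq(window$lower, window$upper, length.out = n_coef(basis))
  med <- c(Female = 22.3, Male = 24.8)
  sdl <- c(Female = 0.155, Male = 0.135)
  smk_shift <- c(Never = 1, Former = 1.02, Light = 0.98, Medium = 0.99,
                 Heavy = 1.0)
  labs <- as.vector(t(outer(smoking, sex, paste, sep = ":")))
  theta <- t(vapply(labs, function(l) {
    parts <- strsplit(l, ":", fixed = TRUE)[[1]]
    m <- med[parts[2]] * smk_shift[parts[1]]
    p <- pmin(pmax(stats::plnorm(knots, log(m), sdl[parts[2]]), 1e-9), 1 - 1e-9)
    colreg_link(link)$q(p)
  }, numeric(length(knots))))
  m <- colreg_model(theta, basis, beta = beta, link = link)
  attr(m, "strata_vars") <- c("smoking", "sex")
  attr(m, "strata_levels") <- list(smoking = smoking, sex = sex)
  attr(m, "covariate_formula") <-
    ~ age_c + alcohol + fruitveg + activity + education + nationality + region
  m
}

#' @rdname bmi_preset
#' @export
bmi_preset_beta <- function() {
  c(age_c = log(0.968), alcohol = log(1.002),
    fruitvegLow = log(0.93),
    activityModerate = log(0.86), activityLow = log(0.77),
    educationSecondary = log(1.25), educationTertiary = log(1.78),
    nationalityForeign = log(0.81),
    regionFrench = log(1.13), regionItalian = log(1.23))
}

default_strata_probs <- function(model) {
  labs <- strata_labels(model)
  lv <- attr(model, "strata_levels")
  if (!is.null(lv) && identical(names(lv), c("smoking", "sex"))) {
    smk <- c(Never = 0.45, Former = 0.23, Light = 0.12, Medium = 0.11,
             Heavy = 0.09)
    sx <- c(Female = 0.51, Male = 0.49)
    pr <- as.vector(t(outer(smk, sx)))
    names(pr) <- as.vector(t(outer(names(smk), names(sx), paste, sep = ":")))
    return(pr[labs])
  }
  stats::setNames(rep(1 / length(labs), length(labs)), labs)
}

default_covariate_sampler <- function(model) {
  lv <- attr(model, "strata_levels")
  function(n) {
    age <- stats::runif(n, 18, 74)
    tibble::tibble(
      age = age, age_c = age - 40,
      alcohol = stats::rexp(n, rate = 1 / 8),
      fruitveg = factor(sample(c("High", "Low"), n, TRUE, c(0.55, 0.45)),
                        levels = c("High", "Low")),
      activity = factor(sample(c("High", "Moderate", "Low"), n, TRUE,
                               c(0.45, 0.30, 0.25)),
                        levels = c("High", "Moderate", "Low")),
      education = factor(sample(c("Mandatory", "Secondary", "Tertiary"), n,
                                TRUE, c(0.15, 0.50, 0.35)),
                         levels = c("Mandatory", "Secondary", "Tertiary")),
      nationality = factor(sample(c("Swiss", "Foreign"), n, TRUE,
                                  c(0.75, 0.25)),
                           levels = c("Swiss", "Foreign")),
      region = factor(sample(c("German", "French", "Italian"), n, TRUE,
                             c(0.70, 0.25, 0.05)),
                      levels = c("German", "French", "Italian"))
    )
  }
}

#' Simulate a cohort from a known model
#'
#' Draws per-subject strata, covariates and exact outcomes from a
#' `colreg_model` by inverse-CDF sampling: a uniform draw is pushed through
#' the conditional quantile function of the subject's stratum and covariates.
#' True continuous height and weight consistent with the outcome are added
#' (height drawn by sex), together with reported height (rounded to 2
#' decimals, metres) and reported weight (rounded to integer kilograms) for
#' the rounding measurement scheme. Draw order per block is fixed (stratum,
#' covariates, uniform, height), so runs are reproducible given `seed`.
#'
#' @param n Number of subjects.
#' @param model The generating `colreg_model`; default [bmi_preset()].
#' @param strata_probs Named probabilities over the model's strata; must sum
#'   to 1. Default: survey-like smoking x sex frequencies for the preset,
#'   uniform otherwise.
#' @param covariate_sampler Optional `function(n)` returning a tibble of raw
#'   covariates; paired with `formula`, whose design columns (intercept
#'   dropped) must match `names(model$beta)`.
#' @param formula One-sided formula building the design from the sampled
#'   covariates.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return A tibble with id, the stratum columns (e.g. smoking, sex),
#'   covariates, the true outcome `bmi`, true `height`/`weight`, and
#'   `reported_height`/`reported_weight`.
#' @export
simulate_cohort <- function(n, model = bmi_preset(), strata_probs = NULL,
                            covariate_sampler = NULL, formula = NULL,
                            seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  labs <- strata_labels(model)
  pr <- strata_probs %||% default_strata_probs(model)
  if (is.null(names(pr)) || !setequal(names(pr), labs)) {
    stop("strata_probs must be named by the model's strata", call. = FALSE)
  }
  pr <- pr[labs]
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
    stop("strata_probs must be nonnegative and sum to 1", call. = FALSE)
  }

  s_idx <- sample.int(length(labs), n, replace = TRUE, prob = pr)

  if (is.null(covariate_sampler) && !is.null(model$beta) &&
      !is.null(attr(model, "covariate_formula"))) {
    covariate_sampler <- default_covariate_sampler(model)
    formula <- attr(model, "covariate_formula")
  }
  has_cov <- !is.null(model$beta) && length(model$beta) > 0
  if (has_cov && is.null(covariate_sampler)) {
    stop("model has shift coefficients; supply covariate_sampler and formula",
         call. = FALSE)
  }

  covs <- if (!is.null(covariate_sampler)) covariate_sampler(n) else NULL
  xb <- rep(0, n)
  if (has_cov) {
    X <- stats::model.matrix(formula, covs)
    X <- X[, attr(X, "assign") != 0, drop = FALSE]
    if (!identical(colnames(X), names(model$beta))) {
      stop("design columns (", paste(colnames(X), collapse = ", "),
           ") do not match names(model$beta)", call. = FALSE)
    }
    xb <- drop(X %*% model$beta)
  }

  u <- stats::runif(n)
  lnk <- colreg_link(model$link)
  target <- lnk$q(u) - xb
  b <- numeric(n)
  for (s in unique(s_idx)) {
    rows <- which(s_idx == s)
    b[rows] <- alpha_inverse_fast(model$basis, model$theta[s, ], target[rows])
  }
  b <- pmax(b, model$basis$window$hard_lower + 1e-6)

  lab <- labs[s_idx]
  svars <- attr(model, "strata_vars")
  slv <- attr(model, "strata_levels")
  strata_tbl <- if (!is.null(svars) && all(grepl(":", lab, fixed = TRUE))) {
    parts <- do.call(rbind, strsplit(lab, ":", fixed = TRUE))
    out <- tibble::as_tibble(stats::setNames(as.data.frame(parts,
                                                           stringsAsFactors = FALSE),
                                             svars))
    for (j in seq_along(svars)) {
      out[[svars[j]]] <- factor(out[[svars[j]]],
                                levels = slv[[svars[j]]] %||%
                                  unique(out[[svars[j]]]))
    }
    out
  } else {
    tibble::tibble(stratum = factor(lab, levels = labs))
  }

  sex_col <- if ("sex" %in% names(strata_tbl)) as.character(strata_tbl$sex)
  h_mean <- if (!is.null(sex_col)) {
    ifelse(sex_col == "Female", 1.66, 1.79)
  } else rep(1.70, n)
  height <- stats::rnorm(n, h_mean, 0.065)
  height <- pmax(height, 1.3)
  weight <- b * height^2

  dplyr::bind_cols(
    tibble::tibble(id = seq_len(n)),
    strata_tbl,
    covs %||% tibble::tibble(.rows = n),
    tibble::tibble(
      bmi = b, height = height, weight = weight,
      reported_height = round(height, 2),
      reported_weight = round(weight, 0)
    )
  )
}

# ---- measurement schemes ---------------------------------------------------

#' Coarsen outcomes to a measurement scale
#'
#' `who_interval()` maps a positive outcome to its WHO BMI category interval
#' (one of (0, 18.5], (18.5, 25], (25, 30], (30, Inf]); a value exactly on a
#' boundary belongs to the lower category (half-open convention).
#' `fixed_width_interval()` maps to the 21-category fixed-width grid
#' <= 17, (17, 19], ..., (35, 37], > 37 (configurable width and range).
#' `rounding_interval()` returns the set of outcome values consistent with a
#' reported height and weight given their rounding resolution: the interval
#' `((w - ws/2)/(h + hs/2)^2, (w + ws/2)/(h - hs/2)^2]` for reported weight
#' `w` (resolution `ws`) and height `h` (resolution `hs`).
#'
#' @param b Positive outcome values.
#' @param width,first,last Fixed-width grid geometry.
#' @param height,weight Reported height (m) and weight (kg).
#' @param height_step,weight_step Rounding resolution of the reports
#'   (defaults: 0.01 m and 1 kg).
#' @return A tibble with columns lower and upper; infinite/hard ends are `NA`
#'   (the file and fit convention for "no bound").
#' @examples
#' who_interval(c(17, 25, 27, 40))
#' rounding_interval(1.75, 76)
#' @export
who_interval <- function(b) {
  if (any(!is.finite(b) | b <= 0)) {
    stop("outcome values must be positive", call. = FALSE)
  }
  breaks <- c(18.5, 25, 30)
  j <- findInterval(b, breaks, left.open = TRUE)
  tibble::tibble(
    lower = ifelse(j == 0, NA_real_, breaks[pmax(j, 1)]),
    upper = ifelse(j == length(breaks), NA_real_, breaks[pmin(j + 1, 3)])
  )
}

#' @rdname who_interval
#' @export
fixed_width_interval <- function(b, width = 2, first = 17, last = 37) {
  if (any(!is.finite(b) | b <= 0)) {
    stop("outcome values must be positive", call. = FALSE)
  }
  stopifnot(width > 0, first < last)
  breaks <- seq(first, last, by = width)
  j <- findInterval(b, breaks, left.open = TRUE)
  tibble::tibble(
    lower = ifelse(j == 0, NA_real_, breaks[pmax(j, 1)]),
    upper = ifelse(j == length(breaks), NA_real_,
                   breaks[pmin(j + 1, length(breaks))])
  )
}

#' @rdname who_interval
#' @export
rounding_interval <- function(height, weight, height_step = 0.01,
                              weight_step = 1) {
  if (any(!is.finite(height) | height <= 0) ||
      any(!is.finite(weight) | weight <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  tibble::tibble(
    lower = (weight - weight_step / 2) / (height + height_step / 2)^2,
    upper = (weight + weight_step / 2) / (height - height_step / 2)^2
  )
}

#' Apply a measurement scheme to a simulated cohort
#'
#' Replaces the exact outcome column by the observation actually recorded
#' under a measurement scheme, writing the standard `exact`/`lower`/`upper`
#' columns consumed by [colreg_fit()]. Schemes can differ per subject (mixed
#' measurement scales), either by passing a vector or by naming a column of
#' `data` holding the per-row scheme.
#'
#' @param data A data frame with the exact outcome (and, for the rounding
#'   scheme, reported height and weight).
#' @param scheme One of `"exact"`, `"who"`, `"fixed_width"`, `"rounding"`; a
#'   vector of these (length `nrow(data)`); or the name of a column of `data`.
#' @param exact_col Column holding the exact outcome (default `"bmi"`).
#' @param height_col,weight_col Reported height/weight columns for the
#'   rounding scheme.
#' @param width Fixed-width grid width.
#' @return `data` with columns `exact`, `lower`, `upper` set per scheme.
#' @export
apply_scheme <- function(data, scheme, exact_col = "bmi",
                         height_col = "reported_height",
                         weight_col = "reported_weight", width = 2) {
  n <- nrow(data)
  known <- c("exact", "who", "fixed_width", "rounding")
  if (length(scheme) == 1L && !scheme %in% known && scheme %in% names(data)) {
    scheme <- as.character(data[[scheme]])
  }
  if (length(scheme) == 1L) scheme <- rep(scheme, n)
  if (length(scheme) != n) {
    stop("scheme must have length 1 or nrow(data)", call. = FALSE)
  }
  bad <- setdiff(unique(scheme), known)
  if (length(bad)) {
    stop("unknown scheme(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!exact_col %in% names(data)) {
    stop("column '", exact_col, "' not found", call. = FALSE)
  }
  b <- as.numeric(data[[exact_col]])
  exact <- rep(NA_real_, n)
  lower <- rep(NA_real_, n)
  upper <- rep(NA_real_, n)
  idx <- which(scheme == "exact")
  exact[idx] <- b[idx]
  idx <- which(scheme == "who")
  if (length(idx)) {
    iv <- who_interval(b[idx])
    lower[idx] <- iv$lower; upper[idx] <- iv$upper
  }
  idx <- which(scheme == "fixed_width")
  if (length(idx)) {
    iv <- fixed_width_interval(b[idx], width = width)
    lower[idx] <- iv$lower; upper[idx] <- iv$upper
  }
  idx <- which(scheme == "rounding")
  if (length(idx)) {
    if (!all(c(height_col, weight_col) %in% names(data))) {
      stop("rounding scheme needs columns '", height_col, "' and '",
           weight_col, "'", call. = FALSE)
    }
    iv <- rounding_interval(as.numeric(data[[height_col]][idx]),
                            as.numeric(data[[weight_col]][idx]))
    lower[idx] <- iv$lower; upper[idx] <- iv$upper
  }
  data <- tibble::as_tibble(data)
  data$exact <- exact
  data$lower <- lower
  data$upper <- upper
  data$scheme <- scheme
  data
}
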