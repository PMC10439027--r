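#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Two-alternative forced-choice model with guess rate fixed at 0.5:
#' \deqn{\Psi(x) = 0.5 + (0.5 - \lambda)\,\Phi(s (x - \mu) / \sigma_s)}
#' where `s = +1` for an abscissa along which accuracy increases (e.g. tilt
#' angle) and `s = -1` for one along which it decreases (e.g. orientation
#' filter width). Parameters `mu` (threshold location) and `slope_sd`
#' (spread) are estimated by maximizing the Bernoulli likelihood of the
#' per-trial responses, with multi-start bounded quasi-Newton optimization
#' (10 starts over a coarse grid, L-BFGS-B, factr tuned to about 1e-8
#' relative on the log-likelihood). At `criterion = 0.75` with `lapse = 0`
#' the threshold equals `mu` analytically.
#'
#' Degenerate data (all correct, all wrong, at-chance everywhere) drive the
#' optimizer to a parameter bound; such fits return `converged = FALSE`
#' with a diagnostic note rather than a silent estimate.
#'
#' @param table Data frame with a binary `correct` column (0/1 or logical)
#'   and the abscissa column.
#' @param abscissa Name of the abscissa column (default `"sigma"`, the
#'   orientation filter width in degrees).
#' @param orientation `"decreasing"` (accuracy falls as x grows; default
#'   for `sigma`) or `"increasing"` (default for any other abscissa, e.g.
#'   tilt `beta`).
#' @param lapse Fixed lapse rate in `[0, 0.1]`; default 0.
#' @return An object of class `psychometric_fit`: `mu`, `slope_sd`, `th75`,
#'   `loglik`, `n_trials`, `n_levels`, `sign`, `lapse`, `converged`,
#'   `note`.
#' @export
fit_cumulative_gaussian <- function(table, abscissa = "sigma",
                                    orientation = NULL, lapse = 0) {
  stopifnot(is.data.frame(table), "correct" %in% names(table),
            abscissa %in% names(table))
  if (lapse < 0 || lapse > 0.1) stop("`lapse` must be in [0, 0.1]", call. = FALSE)
  if (is.null(orientation)) {
    orientation <- if (abscissa == "sigma") "decreasing" else "increasing"
  }
  orientation <- match.arg(orientation, c("increasing", "decreasing"))
  s <- if (orientation == "increasing") 1 else -1

  x <- table[[abscissa]]
  y <- as.numeric(table$correct)
  stopifnot(all(y %in% c(0, 1)))
  lev <- sort(unique(x))
  if (length(lev) < 2) {
    stop("need responses at >= 2 distinct abscissa levels", call. = FALSE)
  }
  n <- as.numeric(tapply(y, factor(x, lev), length))
  k <- as.numeric(tapply(y, factor(x, lev), sum))

  rg <- diff(range(lev))
  upper_asym <- 0.5 - lapse
  nll <- function(par) {
    mu <- par[1]; sd <- exp(par[2])
    p <- 0.5 + upper_asym * stats::pnorm(s * (lev - mu) / sd)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  lower <- c(min(lev) - 2 * rg, log(rg * 1e-3))
  upper <- c(max(lev) + 2 * rg, log(rg * 1e2))
  starts <- expand.grid(
    mu = seq(min(lev), max(lev), length.out = 5),
    lsd = log(c(rg / 4, rg / 2))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$mu[i], starts$lsd[i]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("psychometric optimization failed at every start", call. = FALSE)
  }
  mu <- best$par[1]
  sd <- exp(best$par[2])
  at_bound <- mu <= lower[1] + 1e-6 || mu >= upper[1] - 1e-6 ||
    best$par[2] <= lower[2] + 1e-6 || best$par[2] >= upper[2] - 1e-6
  note <- NULL
  converged <- best$convergence == 0 && !at_bound
  if (!converged) {
    note <- if (at_bound) {
      "estimate at parameter bound (data degenerate: at-chance, saturated, or threshold outside the tested range)"
    } else {
      sprintf("optimizer did not converge (code %d)", best$convergence)
    }
  }
  if (converged && (mu < min(lev) || mu > max(lev))) {
    converged <- FALSE
    note <- sprintf(
      "fitted threshold %.3g lies outside the tested abscissa range [%g, %g] (data near chance or saturated over the sampled levels)",
      mu, min(lev), max(lev))
  }
  structure(
    list(mu = mu, slope_sd = sd, th75 = mu, loglik = -best$value,
         n_trials = sum(n), n_levels = length(lev), sign = s, lapse = lapse,
         converged = converged, note = note),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit mu = %.3f, slope_sd = %.3f, th75 = %.3f, n = %d, %s>\n",
              x$mu, x$slope_sd, x$th75, x$n_trials,
              if (x$converged) "converged" else paste0("NOT converged: ", x$note)))
  invisible(x)
}

#' Predicted accuracy from a psychometric fit
#'
#' @param fit A `psychometric_fit`.
#' @param x Abscissa values.
#' @return Predicted proportion correct.
#' @export
predict_accuracy <- function(fit, x) {
  0.5 + (0.5 - fit$lapse) * stats::pnorm(fit$sign * (x - fit$mu) / fit$slope_sd)
}

#' Invert a psychometric fit at a criterion accuracy
#'
#' Abscissa value where the fitted function predicts the given proportion
#' correct. At `criterion = 0.75` with zero lapse this is exactly `mu` (the
#' Th75 of the protocol).
#'
#' @param fit A converged `psychometric_fit`.
#' @param criterion Proportion correct in `(0.5, 1)`.
#' @return Abscissa value (same units as the fit's abscissa).
#' @export
threshold_at <- function(fit, criterion = 0.75) {
  if (!inherits(fit, "psychometric_fit")) stop("`fit` must be a psychometric_fit", call. = FALSE)
  if (criterion <= 0.5 || criterion >= 1) {
    stop("`criterion` must lie in (0.5, 1)", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("cannot invert a non-converged fit: ", fit$note, call. = FALSE)
  }
  z <- (criterion - 0.5) / (0.5 - fit$lapse)
  if (z >= 1) stop("criterion unreachable under the fitted lapse rate", call. = FALSE)
  fit$mu + fit$sign * fit$slope_sd * stats::qnorm(z)
}

#' Within-observer label-permutation test for a condition difference
#'
#' Compares two conditions' mean accuracies by permutation: per observer,
#' the two condition labels are randomly exchanged (sign-flipping the
#' observer's paired difference); the null distribution collects the
#' group-mean difference over `iterations` resamples, and the two-sided
#' p-value is the proportion of null differences at least as extreme in
#' magnitude as the observed one. By default the small-sample correction
#' `p = (1 + #extreme) / (iterations + 1)` is applied so p is never 0;
#' `plus_one = FALSE` gives the raw proportion. Bonferroni correction
#' multiplies by `n_comparisons` (capped at 1).
#'
#' @param table Data frame with observer, group and value columns.
#' @param group_key Name of the two-level grouping column (default
#'   `"condition"`).
#' @param value Name of the numeric response column (default `"correct"`).
#' @param observer Name of the observer column (default `"observer"`).
#' @param iterations Number of resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @param n_comparisons Bonferroni family size `m` (default 1).
#' @param plus_one Apply the +1 small-sample correction (default TRUE).
#' @return An object of class `permutation_result`: `observed_diff`
#'   (group 1 minus group 2, groups in sorted label order), `null_diffs`,
#'   `p_raw`, `p_bonferroni`, `iterations`, `seed`, `groups`.
#' @export
permutation_test <- function(table, group_key = "condition", value = "correct",
                             observer = "observer", iterations = 1000, seed = 1,
                             n_comparisons = 1, plus_one = TRUE) {
  stopifnot(is.data.frame(table),
            all(c(group_key, value, observer) %in% names(table)))
  g <- as.character(table[[group_key]])
  groups <- sort(unique(g))
  if (length(groups) != 2) {
    stop(sprintf("`%s` must have exactly 2 levels, got %d", group_key, length(groups)),
         call. = FALSE)
  }
  if (!all(table(g) > 0)) stop("both groups must be non-empty", call. = FALSE)
  obs_means <- tapply(table[[value]],
                      list(factor(table[[observer]]), factor(g, groups)),
                      mean)
  if (anyNA(obs_means)) {
    stop("every observer needs data in both groups (within-observer pairing)",
         call. = FALSE)
  }
  d <- obs_means[, 1] - obs_means[, 2]
  n_obs <- length(d)
  observed <- mean(d)
  signs <- with_seed(substream_seed(seed, "permutation"),
                     matrix(sample(c(-1, 1), iterations * n_obs, replace = TRUE),
                            iterations, n_obs))
  null_diffs <- as.numeric(signs %*% d) / n_obs
  extreme <- sum(abs(null_diffs) >= abs(observed) - 1e-15)
  p_raw <- if (plus_one) (1 + extreme) / (iterations + 1) else extreme / iterations
  structure(
    list(observed_diff = observed, null_diffs = null_diffs,
         p_raw = p_raw, p_bonferroni = min(1, n_comparisons * p_raw),
         iterations = iterations, seed = seed, groups = groups,
         n_observers = n_obs),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result %s - %s: diff = %.4f, p_raw = %.4g, p_bonf = %.4g (%d iterations, %d observers)>\n",
              x$groups[1], x$groups[2], x$observed_diff, x$p_raw, x$p_bonferroni,
              x$iterations, x$n_observers))
  invisible(x)
}

#' Per-location accuracy summary with linear interpolation
#'
#' Group mean and SEM of accuracy per test location (mean of per-observer
#' means; SEM across observers), plus a piecewise-linear interpolant across
#' locations for plotting accuracy profiles over space.
#'
#' @param table Data frame with observer, location and value columns.
#' @param location Name of the location column (default `"position"`).
#' @param value Name of the response column (default `"correct"`).
#' @param observer Name of the observer column (default `"observer"`).
#' @return List with `summary` (data frame: location, mean, sem,
#'   n_observers) and `interpolate` (function of location).
#' @export
summarize_by_location <- function(table, location = "position",
                                  value = "correct", observer = "observer") {
  stopifnot(is.data.frame(table),
            all(c(location, value, observer) %in% names(table)))
  per_obs <- tapply(table[[value]],
                    list(factor(table[[observer]]),
                         factor(table[[location]],
                                sort(unique(table[[location]])))),
                    mean)
  mn <- apply(per_obs, 2, mean, na.rm = TRUE)
  n_o <- apply(per_obs, 2, function(v) sum(!is.na(v)))
  sem <- apply(per_obs, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  })
  locs <- as.numeric(colnames(per_obs))
  summary <- data.frame(location = locs, mean = as.numeric(mn),
                        sem = as.numeric(sem), n_observers = as.integer(n_o))
  interp <- if (length(locs) >= 2) {
    stats::approxfun(locs, summary$mean, rule = 1)
  } else {
    function(x) ifelse(x == locs, summary$mean, NA_real_)
  }
  list(summary = summary, interpolate = interp)
}

#' Read / write a response table as CSV
#'
#' Plain-CSV serialization of per-trial response records. The header is
#' free-form but must include `correct` plus whatever grouping columns the
#' analysis uses (typically `observer`, `condition`, `eccentricity` or
#' `position`, `sigma` or `beta`, `tilt`).
#'
#' @param path CSV file path.
#' @return `read_response_table`: a data frame.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_response_table
#' @param table Data frame of per-trial records.
#' @export
write_response_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
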