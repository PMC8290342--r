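# Derive one sub-seed per replicate set from the root seed, so each set has
# its own deterministic stream regardless of evaluation order.
derive_set_seeds <- function(seed, n_sets) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_sets)
}

resample_summaries <- function(summaries, truncate) {
  lapply(summaries, function(s) {
    draws <- stats::rnorm(length(s$means), mean = s$means, sd = s$sds)
    if (truncate) draws <- pmax(draws, 0)
    out <- s
    out$means <- draws  # weights, sds, ns retained from the original summary
    out
  })
}

#' Gaussian resampling of a replicate-summary dataset
#'
#' Generates synthetic datasets by drawing each per-timepoint value from
#' Normal(mean_i, sd_i), using the observed per-day mean and standard
#' deviation. This is a parametric resampling of the summary statistics, not a
#' bootstrap of individual replicates; the original inverse-variance weights
#' are retained in every resampled set. Negative draws are truncated at zero
#' by default (concentrations cannot be negative); set
#' \code{truncate = FALSE} to keep raw Gaussian draws for sensitivity
#' analysis.
#'
#' @param summaries a \code{\link{ts_summary}} or list of them (resampled
#'   jointly, one draw per timepoint per set).
#' @param n_sets number of replicate datasets.
#' @param seed root RNG seed; each set receives its own derived sub-stream.
#' @param truncate truncate negative draws at 0.
#' @return a list of length \code{n_sets}; each element is a list of resampled
#'   summaries parallel to the input.
#' @export
mc_generate_replicates <- function(summaries, n_sets, seed = NULL,
                                   truncate = TRUE) {
  summaries <- as_summary_list(summaries)
  stopifnot(n_sets >= 1)
  seeds <- derive_set_seeds(seed, n_sets)
  lapply(seq_len(n_sets), function(j) {
    set.seed(seeds[j])
    resample_summaries(summaries, truncate)
  })
}

mc_loop <- function(summaries, n_sets, seed, truncate, fit_one) {
  seeds <- derive_set_seeds(seed, n_sets)
  values <- vector("list", n_sets)
  failures <- 0L
  for (j in seq_len(n_sets)) {
    set.seed(seeds[j])
    rep_j <- resample_summaries(summaries, truncate)
    values[[j]] <- tryCatch(fit_one(rep_j), error = function(e) NULL)
    if (is.null(values[[j]])) failures <- failures + 1L
  }
  if (failures > 0.05 * n_sets) {
    warning(sprintf("%d of %d Monte-Carlo fits failed (> 5%%)", failures, n_sets),
            call. = FALSE)
  }
  list(values = values, failures = failures)
}

new_mc_result <- function(...) structure(list(...), class = "mc_result")

#' Monte-Carlo uncertainty of the first-order rate constant
#'
#' Draws \code{n_sets} Gaussian-resampled datasets from the per-timepoint
#' means and SDs, refits the pooled first-order model to each, and reports the
#' mean and standard deviation of the resulting k_f sample together with the
#' point estimate on the original data. Replicate fits that fail to converge
#' are dropped and counted (retrying with fresh draws would bias the sample);
#' a warning is raised when more than 5% fail.
#'
#' @param summaries a \code{\link{ts_summary}} or list of them.
#' @param n_sets number of resampled datasets (study-scale default 10,000).
#' @param seed root RNG seed.
#' @param truncate truncate negative draws at 0.
#' @return an \code{mc_result} with \code{kf_point}, \code{kf_samples},
#'   \code{kf_mean}, \code{kf_sd}, \code{n_sets}, \code{failures},
#'   \code{seed}.
#' @export
mc_first_order_uncertainty <- function(summaries, n_sets = 10000L,
                                       seed = NULL, truncate = TRUE) {
  summaries <- as_summary_list(summaries)
  stopifnot(n_sets >= 1)
  point <- fit_first_order(summaries)
  res <- mc_loop(summaries, n_sets, seed, truncate,
                 function(rep) fit_first_order(rep)$kf_hat)
  kf_samples <- unlist(res$values[!vapply(res$values, is.null, logical(1))])
  new_mc_result(
    study = "kf_uncertainty", n_sets = n_sets, seed = seed,
    kf_point = point$kf_hat, kf_samples = kf_samples,
    kf_mean = mean(kf_samples),
    kf_sd = if (length(kf_samples) > 1) stats::sd(kf_samples) else 0,
    failures = res$failures
  )
}

#' Monte-Carlo frequency of first-order degeneracy under the saturable model
#'
#' For each Gaussian-resampled dataset, minimizes the Michaelis-Menten
#' weighted square error over the K_M grid (nested one-dimensional scheme) and
#' classifies the resulting error surface. The degenerate fraction is the
#' share of sets for which the error keeps decreasing as K_M grows while
#' k_cat/K_M plateaus — i.e. the data are explained by first-order kinetics.
#' Sets with a genuine interior minimum contribute their argmin K_M to
#' \code{finite_km_samples}; because such estimates are often near-boundary
#' and heavily skewed, the summary reports median and IQR alongside mean and
#' SD.
#'
#' @param summaries a \code{\link{ts_summary}} or list of them.
#' @param n_sets number of resampled datasets (study-scale default 1,000).
#' @param seed root RNG seed.
#' @param km_grid K_M grid (see \code{\link{km_grid_default}}).
#' @param tol_e,tol_ratio,alpha classification controls
#'   (see \code{\link{classify_kinetics}}).
#' @param truncate truncate negative draws at 0.
#' @return an \code{mc_result} with \code{degenerate_fraction}, per-class
#'   counts, \code{finite_km_samples} and their summary, \code{failures}.
#' @export
mc_mm_degeneracy_fraction <- function(summaries, n_sets = 1000L, seed = NULL,
                                      km_grid = km_grid_default(),
                                      tol_e = 1e-3, tol_ratio = 1e-3,
                                      alpha = 0.05, truncate = TRUE) {
  summaries <- as_summary_list(summaries)
  stopifnot(n_sets >= 1)
  res <- mc_loop(summaries, n_sets, seed, truncate, function(rep) {
    surf <- km_error_surface(rep, km_grid)
    cls <- classify_kinetics(surf, tol_e, tol_ratio, alpha)
    list(class = cls, km_min = surf$km_grid[which.min(surf$e_values)])
  })
  ok <- res$values[!vapply(res$values, is.null, logical(1))]
  classes <- vapply(ok, function(v) v$class, character(1))
  finite_km <- vapply(ok[classes == "michaelis_menten"],
                      function(v) v$km_min, numeric(1))
  n_ok <- length(classes)
  new_mc_result(
    study = "mm_degeneracy", n_sets = n_sets, seed = seed,
    counts = table(factor(classes, levels = c("first_order_limit",
                                              "michaelis_menten", "ambiguous"))),
    degenerate_fraction = if (n_ok) mean(classes == "first_order_limit") else NA_real_,
    finite_km_samples = finite_km,
    finite_km_mean = if (length(finite_km)) mean(finite_km) else NA_real_,
    finite_km_sd = if (length(finite_km) > 1) stats::sd(finite_km) else NA_real_,
    finite_km_median = if (length(finite_km)) stats::median(finite_km) else NA_real_,
    finite_km_iqr = if (length(finite_km)) stats::IQR(finite_km) else NA_real_,
    failures = res$failures
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result: %s> %d sets (seed %s), %d failed\n",
              x$study, x$n_sets, format(x$seed), x$failures))
  if (x$study == "kf_uncertainty") {
    cat(sprintf("  kf point = %.4g; Monte-Carlo kf = %.4g +/- %.4g mL/(U day)\n",
                x$kf_point, x$kf_mean, x$kf_sd))
  } else {
    cat(sprintf("  first-order degenerate fraction = %.3f\n",
                x$degenerate_fraction))
    if (length(x$finite_km_samples)) {
      cat(sprintf("  finite K_M: %.3g +/- %.3g mg/mL (median %.3g, IQR %.3g)\n",
                  x$finite_km_mean, x$finite_km_sd, x$finite_km_median,
                  x$finite_km_iqr))
    }
  }
  invisible(x)
}
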