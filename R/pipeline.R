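#' Earliest day at which remaining mass is statistically indistinguishable from zero
#'
#' For each sampling day of one condition, runs a two-sided one-sample t-test
#' of the replicate percent-remaining values against 0%. The comparison is
#' against the fixed value zero (not a second sample group), so no equal
#' variance assumption arises. A day is flagged "similar to zero" when the
#' test fails to reject at level \code{alpha} (p > alpha) — absence of
#' evidence of remaining mass, not a formal equivalence test. Two degenerate
#' cases are resolved by convention: replicates that are all exactly zero are
#' similar to zero (p recorded as NA), and zero-scatter replicates with a
#' positive mean are not (p recorded as 0).
#'
#' @param measurements measurement table for a single condition (or pass
#'   \code{condition_id}).
#' @param alpha significance level in (0, 1).
#' @param condition_id optional condition filter.
#' @param adjust p-value adjustment across days, passed to
#'   \code{\link[stats]{p.adjust}}; the default \code{"none"} matches the
#'   usual uncorrected multiple-t-test reporting, \code{"holm"} is available.
#' @return list with \code{day} (earliest similar-to-zero day, or NA), and
#'   \code{table}: data.frame of day, n, mean_percent, sd_percent, p_value,
#'   similar_to_zero.
#' @export
day_of_zero_mass <- function(measurements, alpha = 0.05,
                             condition_id = NULL, adjust = "none") {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(condition_id)) {
    measurements <- measurements[measurements$condition_id == condition_id, ,
                                 drop = FALSE]
  }
  if (nrow(measurements) == 0) stop("no data", call. = FALSE)
  days <- sort(unique(measurements$day))
  n <- means <- sds <- p <- numeric(length(days))
  for (i in seq_along(days)) {
    x <- measurements$percent_mass_remaining[measurements$day == days[i]]
    n[i] <- length(x)
    means[i] <- mean(x)
    sds[i] <- if (length(x) > 1) stats::sd(x) else NA_real_
    p[i] <- if (length(x) < 2) {
      NA_real_
    } else if (all(x == 0)) {
      NA_real_  # degenerate: exactly zero mass, similar to zero by convention
    } else if (stats::sd(x) == 0) {
      0         # degenerate: no scatter around a positive mean
    } else {
      stats::t.test(x, mu = 0, alternative = "two.sided")$p.value
    }
  }
  if (all(n < 2)) {
    stop("insufficient replicates: every day has fewer than 2 values",
         call. = FALSE)
  }
  testable <- !is.na(p)
  p[testable] <- stats::p.adjust(p[testable], method = adjust)
  similar <- (means == 0 & !is.na(sds) & sds == 0) | (!is.na(p) & p > alpha)
  tab <- data.frame(day = days, n = n, mean_percent = means, sd_percent = sds,
                    p_value = p, similar_to_zero = similar)
  hit <- which(similar & n >= 2)
  list(day = if (length(hit)) days[min(hit)] else NA_real_, table = tab)
}

#' Assemble an analysis configuration
#'
#' @param scenario preset scenario name (see \code{\link{scenario_presets}});
#'   ignored when \code{input_csv} is given.
#' @param input_csv path to a measurement CSV.
#' @param pooling list of character vectors of condition_ids; each group
#'   shares one fitted k_f. Default: one group containing every condition.
#' @param model_set which models to run: \code{"first_order"},
#'   \code{"michaelis_menten"}, or \code{"both"}.
#' @param km_grid K_M grid for the error surface.
#' @param mc_kf_sets,mc_mm_sets Monte-Carlo set counts (0 disables a study).
#' @param alpha level for the zero-mass t-tests.
#' @param noise noise model used when simulating a scenario.
#' @param seed root RNG seed for simulation and Monte-Carlo.
#' @param outdir optional output directory for CSV/JSON reports.
#' @return an \code{analysis_config} list.
#' @export
analysis_config <- function(scenario = NULL, input_csv = NULL, pooling = NULL,
                            model_set = c("both", "first_order", "michaelis_menten"),
                            km_grid = km_grid_default(),
                            mc_kf_sets = 1000L, mc_mm_sets = 0L,
                            alpha = 0.05, noise = noise_model(), seed = 1L,
                            outdir = NULL) {
  model_set <- match.arg(model_set)
  if (is.null(scenario) && is.null(input_csv)) {
    stop("config must name a scenario or an input CSV", call. = FALSE)
  }
  structure(list(scenario = scenario, input_csv = input_csv, pooling = pooling,
                 model_set = model_set, km_grid = km_grid,
                 mc_kf_sets = mc_kf_sets, mc_mm_sets = mc_mm_sets,
                 alpha = alpha, noise = noise, seed = seed, outdir = outdir),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Recognized keys: scenario, input_csv, pooling, model_set,
#' km_grid: \{min, max, n\}, mc_kf_sets, mc_mm_sets, alpha,
#' noise: \{kind, scale\}, seed, outdir.
#'
#' @param path YAML file.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$km_grid)) {
    g <- y$km_grid
    # YAML 1.1 reads a bare `n` key as a boolean; accept either spelling
    n <- if (!is.null(g[["n"]])) g[["n"]] else g[["FALSE"]]
    km_grid_default(g$min, g$max, if (is.null(n)) 100L else n)
  } else {
    km_grid_default()
  }
  nm <- if (!is.null(y$noise)) {
    noise_model(y$noise$kind, unlist(y$noise$scale))
  } else {
    noise_model()
  }
  analysis_config(
    scenario = y$scenario, input_csv = y$input_csv, pooling = y$pooling,
    model_set = if (is.null(y$model_set)) "both" else y$model_set,
    km_grid = grid,
    mc_kf_sets = if (is.null(y$mc_kf_sets)) 1000L else y$mc_kf_sets,
    mc_mm_sets = if (is.null(y$mc_mm_sets)) 0L else y$mc_mm_sets,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    noise = nm,
    seed = if (is.null(y$seed)) 1L else y$seed,
    outdir = y$outdir
  )
}

#' Run the full degradation-kinetics analysis pipeline
#'
#' Sequences the analysis end to end: obtain measurements (simulate a preset
#' scenario or read a CSV), summarize replicates per condition, fit the
#' pooled first-order model per pooling group, optionally sweep the K_M error
#' surface and classify the supported model class, run the Monte-Carlo
#' uncertainty studies, and tabulate per-day t-tests against zero remaining
#' mass. All randomness derives from \code{config$seed}, so re-running a
#' config reproduces every number.
#'
#' @param config an \code{\link{analysis_config}} or path to a YAML config.
#' @return (invisibly) a \code{pipeline_result} list: \code{measurements},
#'   \code{summaries}, \code{fit_report} (one row per pooling group, with k_f
#'   in mL/(U day)), \code{mc_reports}, \code{surfaces}, \code{zero_mass}
#'   (one row per condition), and \code{manifest}. When \code{config$outdir}
#'   is set, writes fit_report.csv, zero_mass.csv, mc_report.json,
#'   error_surface_<group>.csv and manifest.json there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))

  # ingest ------------------------------------------------------------
  if (!is.null(config$input_csv)) {
    measurements <- read_measurements(config$input_csv)
    truth_kf <- NA_real_
    source_label <- config$input_csv
  } else {
    sc <- scenario_presets(config$scenario)
    measurements <- simulate_study(sc$design, sc$truth, config$noise,
                                   seed = config$seed)
    truth_kf <- sc$truth$kf
    source_label <- paste0("scenario:", config$scenario)
  }
  ids <- unique(measurements$condition_id)
  summaries <- lapply(ids, function(id) summarize_replicates(measurements, id))
  names(summaries) <- ids

  pooling <- config$pooling
  if (is.null(pooling)) pooling <- list(all = ids)
  if (is.null(names(pooling))) {
    names(pooling) <- vapply(pooling, paste, character(1), collapse = "+")
  }
  if (!setequal(unlist(pooling), ids) || anyDuplicated(unlist(pooling))) {
    stop("invalid pooling: groups must partition the conditions", call. = FALSE)
  }

  # fits ---------------------------------------------------------------
  fit_rows <- list()
  surfaces <- list()
  mc_reports <- list()
  for (g in names(pooling)) {
    grp <- summaries[pooling[[g]]]
    meta <- measurements[measurements$condition_id %in% pooling[[g]], , drop = FALSE]
    ce_pooled <- paste(sort(unique(meta$enzyme_conc_U_per_mL)), collapse = ";")
    surf_class <- NA_character_
    if (config$model_set %in% c("both", "michaelis_menten")) {
      surfaces[[g]] <- km_error_surface(grp, config$km_grid)
      surf_class <- classify_kinetics(surfaces[[g]])
    }
    fo <- fit_first_order(grp)
    mc <- NULL
    if (config$mc_kf_sets > 0) {
      mc <- mc_first_order_uncertainty(grp, n_sets = config$mc_kf_sets,
                                       seed = config$seed + 1L)
      mc_reports[[g]] <- list(study = "kf_uncertainty", n_sets = mc$n_sets,
                              seed = mc$seed, kf_point = mc$kf_point,
                              kf_mean = mc$kf_mean, kf_sd = mc$kf_sd,
                              failures = mc$failures)
    }
    if (config$mc_mm_sets > 0 && config$model_set != "first_order") {
      mm <- mc_mm_degeneracy_fraction(grp, n_sets = config$mc_mm_sets,
                                      seed = config$seed + 2L,
                                      km_grid = config$km_grid)
      mc_reports[[paste0(g, "_mm")]] <- list(
        study = "mm_degeneracy", n_sets = mm$n_sets, seed = mm$seed,
        degenerate_fraction = mm$degenerate_fraction,
        finite_km_mean = mm$finite_km_mean, finite_km_sd = mm$finite_km_sd,
        failures = mm$failures)
    }
    fit_rows[[g]] <- data.frame(
      group = g,
      method = paste(sort(unique(meta$method)), collapse = ";"),
      enzyme = paste(sort(unique(meta$enzyme)), collapse = ";"),
      enzyme_conc_U_per_mL = ce_pooled,
      model_class = if (is.na(surf_class)) "first_order_limit" else surf_class,
      kf_mL_per_U_day = fo$kf_hat,
      kf_mc_mean = if (is.null(mc)) NA_real_ else mc$kf_mean,
      kf_mc_sd = if (is.null(mc)) NA_real_ else mc$kf_sd,
      e_min = fo$e_min,
      n_points = fo$n_points,
      stringsAsFactors = FALSE
    )
  }
  fit_report <- do.call(rbind, fit_rows)
  rownames(fit_report) <- NULL

  # zero-mass table -----------------------------------------------------
  zm_rows <- lapply(ids, function(id) {
    z <- day_of_zero_mass(measurements, alpha = config$alpha, condition_id = id)
    meta <- measurements[measurements$condition_id == id, ][1, ]
    data.frame(condition_id = id, method = meta$method, enzyme = meta$enzyme,
               enzyme_conc_U_per_mL = meta$enzyme_conc_U_per_mL,
               wa_hours = meta$wa_hours,
               zero_mass_day = z$day,
               p_value = if (is.na(z$day)) NA_real_ else
                 z$table$p_value[z$table$day == z$day],
               stringsAsFactors = FALSE)
  })
  zero_mass <- do.call(rbind, zm_rows)
  rownames(zero_mass) <- NULL

  manifest <- list(
    source = source_label, seed = config$seed,
    truth_kf = truth_kf, model_set = config$model_set,
    km_grid = list(min = min(config$km_grid), max = max(config$km_grid),
                   n = length(config$km_grid)),
    mc_kf_sets = config$mc_kf_sets, mc_mm_sets = config$mc_mm_sets,
    alpha = config$alpha,
    package_version = as.character(utils::packageVersion("silkdeg")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  result <- structure(
    list(measurements = measurements, summaries = summaries,
         fit_report = fit_report, mc_reports = mc_reports,
         surfaces = surfaces, zero_mass = zero_mass, manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(config$outdir)) write_reports(result, config$outdir)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n\nFit report (kf in mL/(U day)):\n")
  print(x$fit_report)
  cat("\nZero-mass days:\n")
  print(x$zero_mass)
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' @param result a \code{pipeline_result}.
#' @param outdir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_reports <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fit = file.path(outdir, "fit_report.csv"),
    zero = file.path(outdir, "zero_mass.csv"),
    mc = file.path(outdir, "mc_report.json"),
    manifest = file.path(outdir, "manifest.json")
  )
  utils::write.csv(result$fit_report, paths["fit"], row.names = FALSE)
  utils::write.csv(result$zero_mass, paths["zero"], row.names = FALSE)
  jsonlite::write_json(result$mc_reports, paths["mc"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (g in names(result$surfaces)) {
    s <- result$surfaces[[g]]
    p <- file.path(outdir, paste0("error_surface_", g, ".csv"))
    utils::write.csv(
      data.frame(km_mg_per_mL = s$km_grid, kcat_mg_per_U_day = s$best_kcat,
                 e_value = s$e_values, ratio_mL_per_U_day = s$ratio),
      p, row.names = FALSE)
    paths[paste0("surface_", g)] <- p
  }
  invisible(paths)
}
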