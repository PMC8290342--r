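#' Degradation study design
#'
#' Bundles the experimental cells with the sampling schedule. The defaults
#' follow the study layout this package emulates: sampling on days 1-7, 11,
#' 14, 21 and 28; three biological replicates per day for the continuous
#' method (repeated weighing of the same sponge) and five for the discrete
#' method (destructive sampling); initial silk concentration 30 mg/mL
#' (a 3% wt./v formulation).
#'
#' @param conditions list of \code{\link{condition}} objects.
#' @param sampling_days sampling schedule, days.
#' @param replicates named vector of replicate counts per method.
#' @param cs0 initial substrate concentration, mg/mL.
#' @return an object of class \code{study_design}.
#' @export
study_design <- function(conditions,
                         sampling_days = c(1:7, 11, 14, 21, 28),
                         replicates = c(continuous = 3L, discrete = 5L),
                         cs0 = 30) {
  stopifnot(length(conditions) >= 1,
            all(vapply(conditions, inherits, logical(1), "silk_condition")),
            all(sampling_days > 0), !is.unsorted(sampling_days, strictly = TRUE),
            all(replicates >= 1), cs0 > 0)
  ids <- vapply(conditions, function(x) x$condition_id, character(1))
  if (anyDuplicated(ids)) stop("condition_id values must be unique", call. = FALSE)
  structure(list(conditions = conditions, sampling_days = sampling_days,
                 replicates = replicates, cs0 = cs0),
            class = "study_design")
}

#' Replicate-noise model for simulated studies
#'
#' Gaussian replicate scatter around the model curve. \code{"proportional_sd"}
#' uses a constant SD equal to \code{scale} times the initial concentration at
#' every day (default 10% of cs0, matching the scatter scale of published
#' degradation curves); \code{"constant_sd"} takes \code{scale} in mg/mL;
#' \code{"per_day_sd"} takes a vector of per-day SDs in mg/mL aligned with the
#' sampling schedule, for emulating time-varying scatter.
#'
#' @param kind noise kind.
#' @param scale fraction of cs0, an SD in mg/mL, or a per-day SD vector.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(kind = c("proportional_sd", "constant_sd", "per_day_sd"),
                        scale = 0.1) {
  kind <- match.arg(kind)
  stopifnot(all(scale >= 0))
  if (kind != "per_day_sd" && length(scale) != 1) {
    stop("scale must be a scalar for this noise kind", call. = FALSE)
  }
  structure(list(kind = kind, scale = scale), class = "noise_model")
}

noise_sds <- function(noise, days, cs0) {
  switch(noise$kind,
    proportional_sd = rep(noise$scale * cs0, length(days)),
    constant_sd = rep(noise$scale, length(days)),
    per_day_sd = {
      if (length(noise$scale) != length(days)) {
        stop("per_day_sd scale must match the number of sampling days",
             call. = FALSE)
      }
      noise$scale
    }
  )
}

truth_curve <- function(truth, days, cs0, ce) {
  if (inherits(truth, "first_order_params")) {
    first_order_concentration(days, truth$kf, cs0, ce)
  } else if (inherits(truth, "mm_params")) {
    integrate_mm(days, truth$kcat, truth$km, cs0, ce)
  } else {
    stop("truth must be first_order_params or mm_params", call. = FALSE)
  }
}

#' Simulate a degradation study
#'
#' Generates one measurement row per condition x sampling day x replicate by
#' evaluating each condition's true kinetic model and adding Gaussian
#' replicate noise truncated at zero. Output follows the measurement-table
#' dialect used throughout the package (percent remaining on the 0-100 scale,
#' plus the equivalent sponge mass for the condition's geometry).
#'
#' @param design a \code{\link{study_design}}.
#' @param truth a single parameter object (recycled across conditions) or a
#'   list named by \code{condition_id}, each a
#'   \code{\link{first_order_params}} or \code{\link{mm_params}}.
#' @param noise a \code{\link{noise_model}}.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return data.frame with columns condition_id, enzyme, enzyme_conc_U_per_mL,
#'   wa_hours, method, radius_mm, height_mm, day, replicate,
#'   percent_mass_remaining, mass_mg; attribute \code{cs0} carries the design
#'   concentration.
#' @export
simulate_study <- function(design, truth, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  if (inherits(truth, c("first_order_params", "mm_params"))) {
    truth <- stats::setNames(
      rep(list(truth), length(design$conditions)),
      vapply(design$conditions, function(x) x$condition_id, character(1)))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(design$conditions, function(cond) {
    tr <- truth[[cond$condition_id]]
    if (is.null(tr)) {
      stop(sprintf("configuration error: no truth parameters for condition '%s'",
                   cond$condition_id), call. = FALSE)
    }
    days <- design$sampling_days
    n_rep <- design$replicates[[cond$method]]
    curve <- truth_curve(tr, days, design$cs0, cond$enzyme_conc)
    sds <- noise_sds(noise, days, design$cs0)
    conc <- pmax(0, stats::rnorm(length(days) * n_rep,
                                 mean = rep(curve, each = n_rep),
                                 sd = rep(sds, each = n_rep)))
    vol <- cylinder_volume_ml(cond$radius, cond$height)
    data.frame(
      condition_id = cond$condition_id, enzyme = cond$enzyme,
      enzyme_conc_U_per_mL = cond$enzyme_conc, wa_hours = cond$wa_hours,
      method = cond$method, radius_mm = cond$radius, height_mm = cond$height,
      day = rep(days, each = n_rep), replicate = rep(seq_len(n_rep), length(days)),
      percent_mass_remaining = 100 * conc / design$cs0,
      mass_mg = conc * vol,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cs0") <- design$cs0
  out
}

#' Summarize replicate measurements into a fitting-ready time series
#'
#' Computes the per-day mean concentration, replicate SD (n-1 denominator),
#' replicate count and inverse-variance weight for one condition. When a
#' \code{mass_mg} column is present, masses are converted to concentration via
#' the initial cylinder volume; otherwise percent remaining is rescaled by
#' cs0. Days with a single replicate or zero scatter receive the floored
#' variance and are flagged (see \code{\link{ts_summary}}).
#'
#' @param measurements measurement table (as from \code{\link{simulate_study}}
#'   or \code{\link{read_measurements}}).
#' @param condition_id which condition to summarize; may be omitted when the
#'   table holds a single condition.
#' @param cs0 initial concentration, mg/mL; defaults to the table's
#'   \code{cs0} attribute, else 30.
#' @param var_floor_frac SD floor as a fraction of cs0.
#' @return a \code{\link{ts_summary}}.
#' @export
summarize_replicates <- function(measurements, condition_id = NULL,
                                 cs0 = NULL, var_floor_frac = 0.01) {
  if (is.null(cs0)) cs0 <- attr(measurements, "cs0")
  if (is.null(cs0)) cs0 <- 30
  if (is.null(condition_id)) {
    ids <- unique(measurements$condition_id)
    if (length(ids) != 1) {
      stop("condition_id must be given when the table holds several conditions",
           call. = FALSE)
    }
    condition_id <- ids
  }
  m <- measurements[measurements$condition_id == condition_id, , drop = FALSE]
  if (nrow(m) == 0) {
    stop(sprintf("no data for condition '%s'", condition_id), call. = FALSE)
  }
  conc <- if (!is.null(m$mass_mg) && !anyNA(m$mass_mg)) {
    concentration_from_mass(m$mass_mg, m$radius_mm, m$height_mm)
  } else {
    m$percent_mass_remaining / 100 * cs0
  }
  days <- sort(unique(m$day))
  means <- sds <- numeric(length(days))
  ns <- integer(length(days))
  for (i in seq_along(days)) {
    v <- conc[m$day == days[i]]
    means[i] <- mean(v)
    sds[i] <- if (length(v) > 1) stats::sd(v) else NA_real_
    ns[i] <- length(v)
  }
  ts_summary(days, means, sds, ns, cs0 = cs0, ce = m$enzyme_conc_U_per_mL[1],
             condition_id = condition_id, var_floor_frac = var_floor_frac)
}

#' Read / write the measurement CSV dialect
#'
#' One row per replicate-timepoint with columns condition_id, enzyme,
#' enzyme_conc_U_per_mL, wa_hours, method, radius_mm, height_mm, day,
#' replicate, percent_mass_remaining and optionally mass_mg. Percent values
#' are on the 0-100 scale; all numbers plain decimal.
#'
#' @param path CSV file path.
#' @return \code{read_measurements}: the measurement data.frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition_id", "enzyme", "enzyme_conc_U_per_mL", "wa_hours",
                "method", "radius_mm", "height_mm", "day", "replicate",
                "percent_mass_remaining")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("measurement CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(m$percent_mass_remaining < 0)) {
    stop("percent_mass_remaining must be non-negative", call. = FALSE)
  }
  m
}

#' @rdname read_measurements
#' @param measurements measurement data.frame.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study-shaped scenario presets
#'
#' Named simulation scenarios mirroring the reported experimental cells
#' (enzyme, concentration, method, water annealing) with the published
#' first-order rate constants used as synthetic truth. These are
#' demonstration inputs for the pipeline, not reconstructions of the original
#' raw data.
#'
#' @param name optional scenario name; with no argument, the preset table is
#'   returned.
#' @return a data.frame of presets, or for a single \code{name} a list with a
#'   ready-made \code{design}, \code{truth} and the preset row.
#' @export
scenario_presets <- function(name = NULL) {
  path <- system.file("extdata", "scenarios.yaml", package = "silkdeg")
  raw <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(raw$scenarios, function(s) {
    data.frame(name = s$name, method = s$method, enzyme = s$enzyme,
               wa_hours = s$wa_hours,
               enzyme_conc = paste(unlist(s$enzyme_conc), collapse = ";"),
               kf_true = s$kf_true, stringsAsFactors = FALSE)
  }))
  if (is.null(name)) return(tab)
  hit <- Filter(function(s) identical(s$name, name), raw$scenarios)
  if (!length(hit)) stop(sprintf("unknown scenario '%s'", name), call. = FALSE)
  s <- hit[[1]]
  ce <- unlist(s$enzyme_conc)
  conds <- lapply(ce, function(c_e) {
    condition(sprintf("%s_%s_%g", s$method, s$enzyme, c_e),
              enzyme = s$enzyme, enzyme_conc = c_e, wa_hours = s$wa_hours,
              method = s$method)
  })
  list(design = study_design(conds),
       truth = first_order_params(s$kf_true),
       preset = s)
}
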