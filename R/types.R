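#' Experimental condition descriptor
#'
#' One cell of the degradation study design: which enzyme, at what activity
#' concentration, on sponges water-annealed for how long, sampled by which
#' method, and with what scaffold geometry. The default geometries follow the
#' two sampling methods: repeated weighing of one sponge ("continuous",
#' 3 mm radius x 4 mm height) and destructive sampling of separate sponges
#' ("discrete", 1 mm radius x 2 mm height).
#'
#' @param condition_id unique label for the condition.
#' @param enzyme enzyme label, e.g. "ProteinaseK" or "ProteaseXIV".
#' @param enzyme_conc enzyme activity concentration C_E, U/mL.
#' @param wa_hours water-annealing duration, hours (a crystallinity label; it
#'   does not enter the kinetics).
#' @param method sampling method, "continuous" or "discrete".
#' @param radius,height cylinder dimensions in mm; defaulted from the method.
#' @return an object of class \code{silk_condition}.
#' @export
condition <- function(condition_id, enzyme, enzyme_conc,
                      wa_hours = 12, method = c("continuous", "discrete"),
                      radius = NULL, height = NULL) {
  method <- match.arg(method)
  if (is.null(radius)) radius <- if (method == "continuous") 3 else 1
  if (is.null(height)) height <- if (method == "continuous") 4 else 2
  stopifnot(enzyme_conc >= 0, radius > 0, height > 0, wa_hours >= 0)
  structure(
    list(condition_id = as.character(condition_id), enzyme = as.character(enzyme),
         enzyme_conc = enzyme_conc, wa_hours = wa_hours, method = method,
         radius = radius, height = height),
    class = "silk_condition"
  )
}

#' @export
print.silk_condition <- function(x, ...) {
  cat(sprintf("<condition %s> %s %g U/mL, %g h WA, %s method, %g x %g mm cylinder\n",
              x$condition_id, x$enzyme, x$enzyme_conc, x$wa_hours, x$method,
              x$radius, x$height))
  invisible(x)
}

#' Modified first-order model parameters
#'
#' @param kf rate constant, mL/(U day); equals k_cat/K_M in the saturable model.
#' @param cs0 initial substrate concentration, mg/mL.
#' @return an object of class \code{first_order_params}.
#' @export
first_order_params <- function(kf, cs0 = 30) {
  stopifnot(kf >= 0, cs0 > 0)
  structure(list(kf = kf, cs0 = cs0), class = "first_order_params")
}

#' Michaelis-Menten model parameters
#'
#' Holds the catalytic rate constant and Michaelis constant
#' K_M = (k_-1 + k_cat)/k_1. The underlying binding constants k_1 and k_-1 are
#' never individually identifiable from degradation time courses; only their
#' combination K_M (and the first-order-equivalent ratio k_cat/K_M) is.
#'
#' @param kcat catalytic rate constant, mg/(U day).
#' @param km Michaelis constant, mg/mL.
#' @param cs0 initial substrate concentration, mg/mL.
#' @return an object of class \code{mm_params}.
#' @export
mm_params <- function(kcat, km, cs0 = 30) {
  stopifnot(kcat >= 0, km > 0, cs0 > 0)
  structure(list(kcat = kcat, km = km, cs0 = cs0), class = "mm_params")
}

#' Per-timepoint summary of replicate measurements
#'
#' The weighted least-squares objective works on the per-day mean
#' concentration, its replicate variance, and the inverse-variance weight
#' w_i = 1/var_i. Because variances can be zero (identical replicates, or a
#' fully degraded sponge measured as exactly 0), the standard deviation is
#' floored at \code{var_floor_frac * cs0} (default 1% of the initial
#' concentration) before inversion; floored timepoints are flagged in the
#' \code{floored} field.
#'
#' @param times sampling days, strictly increasing.
#' @param means per-day mean concentration, mg/mL.
#' @param sds per-day replicate standard deviation, mg/mL (NA allowed for
#'   single-replicate days; treated as floored).
#' @param ns per-day replicate counts.
#' @param cs0 initial concentration for the condition, mg/mL.
#' @param ce enzyme concentration for the condition, U/mL.
#' @param condition_id optional label.
#' @param var_floor_frac SD floor as a fraction of \code{cs0}.
#' @return an object of class \code{ts_summary} with fields \code{times},
#'   \code{means}, \code{sds}, \code{ns}, \code{weights}, \code{floored},
#'   \code{cs0}, \code{ce}, \code{condition_id}.
#' @export
ts_summary <- function(times, means, sds, ns, cs0, ce,
                       condition_id = NULL, var_floor_frac = 0.01) {
  n <- length(times)
  if (length(means) != n || length(sds) != n || length(ns) != n) {
    stop("times, means, sds, ns must have equal length", call. = FALSE)
  }
  if (n == 0) stop("no data: summary must contain at least one timepoint", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(sds < 0, na.rm = TRUE)) stop("sds must be non-negative", call. = FALSE)
  if (cs0 <= 0) stop("cs0 must be positive", call. = FALSE)
  sd_floor <- max(sqrt(.Machine$double.eps), var_floor_frac * cs0)
  floored <- is.na(sds) | sds < sd_floor
  sds_eff <- ifelse(floored, sd_floor, sds)
  weights <- 1 / sds_eff^2
  structure(
    list(times = as.numeric(times), means = as.numeric(means),
         sds = as.numeric(sds), ns = as.integer(ns), weights = weights,
         floored = floored, cs0 = cs0, ce = ce,
         condition_id = condition_id),
    class = "ts_summary"
  )
}

#' @export
print.ts_summary <- function(x, ...) {
  cat(sprintf("<ts_summary%s> %d timepoints (day %g-%g), cs0 = %g mg/mL, ce = %g U/mL\n",
              if (is.null(x$condition_id)) "" else paste0(" ", x$condition_id),
              length(x$times), min(x$times), max(x$times), x$cs0, x$ce))
  if (any(x$floored)) {
    cat(sprintf("  %d timepoint(s) with floored variance\n", sum(x$floored)))
  }
  invisible(x)
}

# normalize a ts_summary or list of them into a list
as_summary_list <- function(x) {
  if (inherits(x, "ts_summary")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ts_summary"))) return(x)
  stop("expected a ts_summary or a list of ts_summary objects", call. = FALSE)
}
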