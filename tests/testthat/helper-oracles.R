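# Independent oracles and small fixture builders used across the suite.

# Bisection oracle for the integrated Michaelis-Menten relation:
# km*ln(cs0/cs) + (cs0 - cs) = kcat*ce*t, solved with stats::uniroot
# (Brent bracketing), independent of the package's Newton solve.
mm_bisection_oracle <- function(times, kcat, km, cs0, ce) {
  vapply(times, function(t) {
    s <- kcat * ce * t
    if (s == 0) return(cs0)
    if (s / km > 500) return(0)  # root below representable range: depleted
    f <- function(cs) km * log(cs0 / cs) + (cs0 - cs) - s
    lower <- max(cs0 * exp(-s / km) / 2, 1e-300)
    stats::uniroot(f, c(lower, cs0), tol = 1e-14)$root
  }, numeric(1))
}

# Study-shaped discrete design: days 1-7, 11, 14, 21, 28; n = 5;
# C_E = 0.01 and 0.1 U/mL; cs0 = 30 mg/mL.
discrete_design <- function(ce = c(0.01, 0.1)) {
  conds <- lapply(ce, function(c_e) {
    condition(paste0("d", c_e), enzyme = "ProteinaseK", enzyme_conc = c_e,
              wa_hours = 12, method = "discrete")
  })
  study_design(conds)
}

# Noise-free summaries from a given truth on the discrete design.
noise_free_summaries <- function(truth, ce = c(0.01, 0.1)) {
  d <- discrete_design(ce)
  m <- simulate_study(d, truth, noise_model(scale = 0), seed = 1)
  lapply(unique(m$condition_id), function(id) summarize_replicates(m, id))
}

# Hand-built summary from explicit vectors (weights via the standard floor).
make_summary <- function(times, means, sds = NULL, cs0 = 30, ce = 0.1) {
  if (is.null(sds)) sds <- rep(0.05 * cs0, length(times))
  ts_summary(times, means, sds, ns = rep(3L, length(times)),
             cs0 = cs0, ce = ce)
}
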