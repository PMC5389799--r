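# Shared fixtures built in code.

# A preset stripped of all between-subject and measurement noise, for
# exact pipeline-closure checks.
noiseless_preset <- function(preset) {
  preset$glu_slope_sd <- 0
  preset$gln_slope_sd <- 0
  preset$glu_baseline_sd <- 0
  preset$gln_baseline_sd <- 0
  preset$noise <- list(enrichment_cv = 0, conc_cv = 0, area_cv = 0)
  ecflux:::validate_preset(preset)
}

# Heavy shared computations are cached so several test blocks can reuse
# one simulation pass.
.ecflux_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ecflux_cache)) {
    assign(key, force(expr), envir = .ecflux_cache)
  }
  get(key, envir = .ecflux_cache)
}

# 200 replicate cohorts of the three packaged groups under master seed 1:
# the parameter-recovery surface for the acceptance checks.
shared_recovery <- function() {
  cached("recovery200", recovery_summary(
    recovery_study(group_presets(), n_reps = 200, seed = 1)))
}
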