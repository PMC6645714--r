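# parameter helpers shared across test files

# deterministic configuration: all SDs zero, no lapses, chosen pieces
# overridable.  Starts from the high-luminance pooled values.
det_params <- function(...) {
  p <- unclass(pooled_params("high"))
  p$sigma_b <- 0
  p$sigma_go_aff <- 0
  p$sigma_cue_aff <- 0
  p$sigma_eri <- 0
  p$lambda <- 0
  mod <- list(...)
  p[names(mod)] <- mod
  do.call(luminance_params, p)
}

# modified copy of any luminance_params
mod_params <- function(base, ...) {
  p <- unclass(base)
  mod <- list(...)
  p[names(mod)] <- mod
  do.call(luminance_params, p)
}

urgent_gaps <- c(0, 75, 100, 125, 150, 175, 200, 250, 350)
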