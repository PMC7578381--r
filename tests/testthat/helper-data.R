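# Shared fixtures: generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_dataset(sim_config(seed = 1))
  }
  .fixture_env$default
}

# Fully deterministic dataset: no beta/expression noise, no latent
# coupling, no design-type bias, no label swaps.
noisefree_config <- function(seed = 1, ...) {
  sim_config(beta_noise_sd = 0, coupling_sd = 0, expr_noise_sd = 0,
             type2_bias = 1, n_swapped_pairs = 0, seed = seed, ...)
}

noisefree_dataset <- function() {
  if (is.null(.fixture_env$noisefree)) {
    .fixture_env$noisefree <- generate_dataset(noisefree_config())
  }
  .fixture_env$noisefree
}

# Minimal sample sheet for hand-built matrices: n tumor/normal pairs.
toy_sheet <- function(n) {
  patients <- sprintf("P%02d", seq_len(n))
  data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "normal"), each = n),
    cohort = "discovery", stringsAsFactors = FALSE)
}

# Beta matrix for toy_sheet(n): baseline plus per-probe tumor effect.
toy_beta <- function(n_probes, n_pairs, effect = 0, noise = 0, seed = 42) {
  set.seed(seed)
  sheet <- toy_sheet(n_pairs)
  base <- matrix(runif(n_probes * 2 * n_pairs, 0.3, 0.5),
                 n_probes, 2 * n_pairs,
                 dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                                 sheet$sample_id))
  tumor <- sheet$tissue == "tumor"
  base[, tumor] <- base[, tumor] + effect
  if (noise > 0) base <- base + matrix(rnorm(length(base), 0, noise),
                                       nrow(base))
  pmin(pmax(base, 0.001), 0.999)
}
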