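# Small fixtures built in code; all seeded and cheap.

# A fast optimizer configuration for tests that exercise plumbing rather
# than classification quality.
quick_control <- function(seed = 1L, max_iter = 60L) {
  gmlvq_control(max_iter = max_iter, seed = seed)
}

# Two tight clusters in antipodal directions along e1: perfectly separable
# by angle, with small isotropic noise.
antipodal_clusters <- function(n_per_class = 30, nfeat = 20, noise_sd = 0.05,
                               seed = 1) {
  set.seed(seed)
  ids <- feature_schema()$feature_id[seq_len(nfeat)]
  dir <- c(1, rep(0, nfeat - 1))
  X <- rbind(
    matrix(rep(dir, n_per_class), ncol = nfeat, byrow = TRUE),
    matrix(rep(-dir, n_per_class), ncol = nfeat, byrow = TRUE)) +
    matrix(rnorm(2 * n_per_class * nfeat, sd = noise_sd), ncol = nfeat)
  colnames(X) <- ids
  out <- tibble::as_tibble(X)
  out$group <- rep(c("CD", "control"), each = n_per_class)
  out$subject_id <- sprintf("A%03d", seq_len(2 * n_per_class))
  out
}

# A null stratum: labels independent of all features (z-scored noise).
null_stratum <- function(n_cd = 40, n_control = 60, seed = 1) {
  set.seed(seed)
  ids <- feature_schema()$feature_id
  X <- matrix(rnorm((n_cd + n_control) * length(ids)), ncol = length(ids))
  X <- scale(X)
  colnames(X) <- ids
  out <- tibble::as_tibble(X)
  out$group <- rep(c("CD", "control"), c(n_cd, n_control))
  out$subject_id <- sprintf("N%04d", seq_len(n_cd + n_control))
  out
}

# A generator config with no group signal at all: zero deficits and zero
# covariate-group shifts.
null_config <- function(...) {
  generator_config(
    deficit_patterns = list(female = numeric(), male = numeric()),
    covariate_group_shifts = c(age = 0, iq = 0, ses = 0),
    ...)
}

# Small default-calibration cohort config for pipeline plumbing tests.
small_config <- function(...) {
  generator_config(stratum_sizes = c(female_cd = 40, female_control = 60,
                                     male_cd = 35, male_control = 35), ...)
}
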