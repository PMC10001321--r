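# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic cohort (4 patients x 7 regions) written to a session
# tempdir; reused by imageio / fatfrac / pipeline tests.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- file.path(tempdir(), "pancqta-small-cohort")
    manifest <- generate_cohort(dir, n_patients = 4, rng_seed = 421)
    .fixture_env$small <- list(dir = dir, manifest = manifest)
  }
  .fixture_env$small
}

# Closed-form standard skew-normal moments, written out independently of
# the package's sampler so they can serve as its oracle.
sn_oracle <- function(alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  bd <- delta * sqrt(2 / pi)
  list(mean = bd,
       sd = sqrt(1 - bd^2),
       skewness = (4 - pi) / 2 * bd^3 / (1 - bd^2)^1.5,
       ex_kurtosis = 2 * (pi - 3) * bd^4 / (1 - bd^2)^2)
}

# Exhaustive positive-negative pair counting: the brute-force AUC oracle.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
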