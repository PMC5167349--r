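# Shared fixtures: parameter sets at the fitted scale of real libraries
# (processivities of a few kb, moderate end effects) and small simulations.

default_params <- function(alpha = 0.5) {
  model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150, alpha = alpha)
}

# Parameter grid exercising both h-branches, zero-rate limits and skewed
# rate ratios (alpha1/alpha2 > 0 keeps model E evaluable when theta1 = 0).
param_grid <- function() {
  list(
    default_params(),
    model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 0),
    model_params(theta1 = 1e-3, theta2 = 1e-4, d = 0.5, h = 400,
                 alpha = 0.2),
    model_params(theta1 = 5e-5, theta2 = 2e-3, d = 10, h = 50, alpha = 0.9),
    model_params(theta1 = 0, theta2 = 5e-4, d = 2, h = 100,
                 alpha1 = 1e-4, alpha2 = 1e-4)
  )
}

# Piecewise adaptive quadrature of the coverage density (independent oracle
# for the closed-form areas).
quad_area <- function(model, p, l, rel.tol = 1e-9) {
  f <- function(x) coverage_density(model, p, x, l)
  br <- sort(unique(pmin(pmax(c(0, p$h, l - p$h, l), 0), l)))
  s <- 0
  for (i in seq_len(length(br) - 1)) {
    if (br[i + 1] > br[i]) {
      s <- s + stats::integrate(f, br[i], br[i + 1], rel.tol = rel.tol,
                                subdivisions = 400L)$value
    }
  }
  s
}

small_sim <- function(model, p, n_transcripts, reads, seed,
                      length_range = c(500, 20000)) {
  simulate_dataset(sim_config(model, p, n_transcripts = n_transcripts,
                              length_range = length_range,
                              reads_per_transcript = reads, seed = seed))
}

# Fraction of histogram bins of simulated read starts within 3 binomial
# standard errors of the closed-form bin probabilities.
oracle_bin_agreement <- function(model, p, l, n_reads, n_bins, seed) {
  set.seed(seed)
  x <- sample_read(model, p, l, n_reads)
  brk <- seq(0, l, length.out = n_bins + 1)
  obs <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                  nbins = n_bins) / n_reads
  area <- coverage_area(model, p, l)
  pexp <- vapply(seq_len(n_bins), function(i) {
    stats::integrate(function(z) coverage_density(model, p, z, l),
                     brk[i], brk[i + 1], rel.tol = 1e-9)$value / area
  }, numeric(1))
  se <- sqrt(pexp * (1 - pexp) / n_reads)
  mean(abs(obs - pexp) <= 3 * se)
}
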