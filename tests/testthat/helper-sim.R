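# Shared fixtures: small simulated experiments, cached per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .sim_cache))
    assign(name, build(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

small_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_transcripts = 40, expr_meanlog = log(400), ...)
}

small_experiment <- function() {
  cached("small_exp", function() {
    suppressWarnings(simulate_experiment(
      small_config(n_het_sites = 2, n_biased_sites = 2)))
  })
}

# brute-force two-sided Fisher p by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(supp, c1, n - c1, r1)
  p0 <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# brute-force Holm adjustment
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
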