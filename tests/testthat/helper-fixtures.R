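# Shared fixtures. Tests that only exercise plumbing use a 0.5-s grid for
# speed; accuracy-sensitive checks build their own finer grids.

test_idif <- function(step = 0.5) {
  synthetic_idif(bolus_params(), t_s = seq(0, 300, by = step))
}

default_truth <- function() kinetic_params(k1 = 0.506, k2 = 0.150, vb = 0.05)

all_study_schedules <- function() {
  c(blood_phase_schedules(), tissue_phase_schedules())
}

# Brute-force discrete convolution oracle: double-loop Riemann sum of
# e^(-k2 (t_j - t_i)) x_i h, independent of the package's recursion.
riemann_convolve <- function(t_s, x, k2_per_s, at = seq_along(t_s)) {
  h <- t_s[2] - t_s[1]
  vapply(at, function(j) {
    if (j == 1L) return(0)
    i <- seq_len(j - 1L)
    sum(exp(-k2_per_s * (t_s[j] - (t_s[i] + h / 2))) * (x[i] + x[i + 1L]) / 2) * h
  }, numeric(1))
}

# Exhaustive signed-rank oracle: enumerates sign assignments directly from
# the differences, independent of the package implementation.
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  tot <- sum(r)
  n <- length(d)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    w <- sum(r[signs == 1L])
    if (min(w, tot - w) <= w_obs) count <- count + 1L
  }
  count / 2^n
}
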