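# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: loops instead of cumsums, pair enumeration
# instead of closed forms.

# brute-force trailing mean: average of samples with t - window <= time < t,
# missing until the window is fully covered by the record
brute_trailing_mean <- function(times, values, window_sec) {
  sapply(seq_along(times), function(i) {
    if (times[i] - window_sec < times[1]) return(NA_real_)
    in_win <- times >= times[i] - window_sec & times < times[i]
    mean(values[in_win])
  })
}

# brute-force Mann-Kendall S by explicit double loop
brute_mk_S <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  as.integer(s)
}

# two-sided permutation p-value of S by full enumeration (small n only)
perm_mk_p <- function(x) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  s_obs <- abs(brute_mk_S(x))
  ss <- vapply(perms(x), brute_mk_S, 1L)
  mean(abs(ss) >= s_obs)
}

# direct transcription of the default short-term activity factor, kept
# separate from the package implementation
oracle_gamma_default <- function(T, T24, T240) {
  R <- 0.008314
  Topt <- 313 + 0.6 * (T240 - 297.15)
  Eopt <- 2 * exp(0.05 * (T24 - 297.15)) * exp(0.05 * (T240 - 297.15))
  x <- 1 / Topt - 1 / T
  Eopt * 230 * exp(95 / R * x) / (230 - 95 * (1 - exp(230 / R * x)))
}
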