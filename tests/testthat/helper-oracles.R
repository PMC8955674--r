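# Independent reference implementations used as oracles.

# naive double-loop time-domain metrics on a plain numeric interval vector
ref_time_metrics <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  m <- s / length(x)
  if (length(x) < 2L) return(list(mean_rri = m, rmssd = NA, pnn5 = NA))
  ssq <- 0
  cnt <- 0L
  npairs <- 0L
  for (i in seq_len(length(x) - 1L)) {
    d <- x[i + 1L] - x[i]
    ssq <- ssq + d * d
    if (abs(d) > 5) cnt <- cnt + 1L
    npairs <- npairs + 1L
  }
  list(mean_rri = m, rmssd = sqrt(ssq / npairs), pnn5 = 100 * cnt / npairs)
}

# random but valid RR series for property tests
random_rri <- function(n, mean_rr = 100) {
  rri_series(pmax(1, mean_rr + stats::rnorm(n, 0, 10)))
}

# a small cached synthetic recording shared by detector/pipeline tests
synth_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- rr_synth_config(mean_rr = 100, lf_amp = 3, lf_freq = 0.4,
                             hf_amp = 3, hf_freq = 2.5, jitter_sd = 2,
                             duration = 60, seed = 101L)
      g <- generate_rri(cfg)
      e <- generate_ecg(g$series, ecg_synth_config(noise_sd = 0.02,
                                                   baseline_wander_amp = 0.05,
                                                   seed = 7L))
      cache <<- list(config = cfg, rri = g, ecg = e)
    }
    cache
  }
})
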