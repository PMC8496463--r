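# Small campaigns shared across test files; built once per test run.

small_campaign <- local({
  cache <- new.env()
  function(seed = 3, noise = TRUE, n_stations = 3) {
    key <- paste(seed, noise, n_stations, sep = "_")
    if (is.null(cache[[key]])) {
      tr <- if (noise) {
        synthetic_truth(seed = seed)
      } else {
        synthetic_truth(seed = seed,
                        noise_sd = list(fluorescence = 0, induction = 0))
      }
      cache[[key]] <- simulate_campaign(tr, n_stations = n_stations)
    }
    cache[[key]]
  }
})
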