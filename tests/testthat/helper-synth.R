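# Desk-scale synthetic dataset shared across test files (generated once
# per session). Noiseless so planted labels are exact.
tiny_config <- function(seed = 7L, ...) {
  synth_config(n_enhancer_peaks = 60L, n_planted_SE_clusters = 5L,
               n_circRNAs = 40L, n_planted_candidates = 3L,
               chrom_length = 1.6e7, rpm_noise_cv = 0, seed = seed, ...)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "secirc_tiny")
      cache <<- generate_dataset(tiny_config(), dir)
    }
    cache
  }
})

expect_frame_equal <- function(got, want, cols) {
  got <- got[do.call(order, got[cols]), cols, drop = FALSE]
  want <- want[do.call(order, want[cols]), cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
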