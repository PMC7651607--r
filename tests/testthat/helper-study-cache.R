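# One scaled-down simulation study shared across test files: the full
# 4-dose scenario grid (3 time-courses x 7 ED50) with all three analysis
# methods at 150 replicates per scenario.  Computed on first use and cached
# for the session; the unbiasedness band and Monte-Carlo allowances are
# recomputed for the 150-replicate scale wherever it is audited.
scaled_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- uacr_design()
      g <- scenario_grid(d, n_reps = 150, master_seed = 515)
      cache <<- run_study(g, d, methods = c("dreos", "mmrm", "drmmrm"))
    }
    cache
  }
})
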