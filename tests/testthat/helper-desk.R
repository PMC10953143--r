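# One desk-scale end-to-end training run (32^3 grid, 20 training pairs,
# 8 held-out good-quality pairs, attention-gated generator), shared by the
# acceptance tests that assess the directional synthesis and segmentation
# findings.  Cached so the run happens at most once per test session.
desk_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(seed = 1,
                        out_dir = file.path(tempdir(), "desk_run"))
      cache <<- run_pipeline(cfg, quiet = TRUE)
    }
    cache
  }
})
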