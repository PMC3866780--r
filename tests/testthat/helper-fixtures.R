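# Bundled study compounds, loaded once per test run.
fixture_compounds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- study_compounds()
    cache
  }
})

round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
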