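# The end-to-end twin experiment is expensive and several checks read the
# same run (held-out accuracy per section, convergence dynamics, section
# insensitivity). The first test that needs it triggers the computation; the
# result is cached for the rest of the session.
#
# The run uses the full study conditions: a training pool of 620 clips/class
# so each channel section trains on a shuffled 992/248 split (the emulated
# five-batches-of-248 structure), with a balanced test set of 100 clips per
# class held out at clip level. On one CPU this is the dominant cost of the
# suite, so it is executed once at a fixed seed rather than repeated across
# seeds; scripts/acceptance.R runs the identical protocol at the caller's
# seed.

twin_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- twinExperiment(seed = 42, nPerClass = 720L,
                               nTestPerClass = 100L)
    cache
  }
})
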