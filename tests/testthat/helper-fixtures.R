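# Shared fixtures. Small clips use faster cells so that every cell clears
# both crop windows within the shortened sequence (the default speed range is
# tuned to the 40-frame sequences of the full study conditions).

fast_pop <- function(...) {
  populationParams(speedMean = 3.6, speedSd = 0.3, speedRange = c(3.2, 4.2),
                   ...)
}

# a small noise-free, in-focus study for exactness checks
clean_study <- function(n_per_class = 2, seed = 11, noise = 0,
                        frames = 40L) {
  generateStudy(1, 1, n_per_class,
                render = renderConfig(noiseSigma = noise,
                                      framesPerSequence = frames),
                pop = populationParams(blurLevels = 0),
                seed = seed)
}

# one defaults-rendered clip reused across detection/background tests
default_clip <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- clean_study(1, seed = 101)$clips[[1]]
    cache
  }
})

# independent contour-area oracle: EBImage labelling + boundary tracing,
# shoelace area over the traced polygon
ebimage_area <- function(mask) {
  lb <- EBImage::bwlabel(mask)
  if (max(lb) == 0) return(0)
  ct <- EBImage::ocontour(lb)
  max(vapply(ct, function(xy) {
    n <- nrow(xy)
    if (n < 3) return(0)
    x <- xy[, 1]; y <- xy[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1)))
}
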