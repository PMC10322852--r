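# Brute-force oracles, independent of the package's vectorised sectioning
# path: walk the block-faces one by one and apply the attenuation and
# threshold rules directly.

oracle_detected <- function(depths, intensity, attenuation, slice_thickness,
                            threshold) {
  detected <- rep(FALSE, length(depths))
  z <- 0
  top <- max(depths)
  while (z <= top) {
    x <- depths - z
    vis <- x >= 0
    inten <- intensity * exp(-attenuation * x * 1e-4)
    detected <- detected | (vis & inten >= threshold)
    z <- z + slice_thickness
  }
  detected
}

oracle_count <- function(depths, intensity, attenuation, slice_thickness,
                         threshold) {
  sum(oracle_detected(depths, intensity, attenuation, slice_thickness, threshold))
}

# Dense-grid trapezoidal quadrature for distribution sensitivities.
oracle_partial <- function(f, upper, n = 200001) {
  g <- seq(0, upper, length.out = n)
  y <- f(g)
  sum((y[-1] + y[-n]) * diff(g)) / 2
}
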