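# fixtures built in code, shared across test files

# write an SWC file from a node table and return its path
write_swc_lines <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# unbranched collinear 3-node trace: (0,0,0)-(10,0,0)-(20,0,0)
swc_unbranched <- function() {
  write_swc_lines(c("# comment line",
                    "1 2 0 0 0 0.5 -1",
                    "2 2 10 0 0 0.5 1",
                    "3 2 20 0 0 0.5 2"))
}

# root chain of 2 segments, then a bifurcation into two 1-segment children
swc_bifurcated <- function() {
  write_swc_lines(c("1 2 0 0 0 0.5 -1",
                    "2 2 10 0 0 0.5 1",
                    "3 2 20 0 0 0.5 2",
                    "4 2 20 10 0 0.5 3",
                    "5 2 20 0 10 0.5 3"))
}

# straight unbranched axon of given length along x
straight_axon <- function(length_um = 200, axon_id = "a1", subtype = "PV",
                          region = "SS", step = 10) {
  xs <- unique(c(seq(0, length_um, by = step), length_um))
  axon_trace(axon_id, subtype, region,
             list(b1 = polyline3d(cbind(xs, 0, 0))))
}

ann_df <- function(axon_id, s_start, s_end, branch_id = "b1") {
  data.frame(axon_id = axon_id, branch_id = branch_id,
             s_start_um = s_start, s_end_um = s_end)
}

# dense Gaussian bump profile for FWHM tests
gaussian_profile <- function(sigma = 0.2, spacing = sigma / 5, baseline = 0,
                             amplitude = 1, extent = 6 * sigma) {
  x <- seq(-extent, extent, by = spacing)
  intensity_profile(x, baseline + amplitude * exp(-x^2 / (2 * sigma^2)))
}

# independent brute-force Bernoulli log-likelihood for the diameter+subtype
# logit model; used as the grid-search oracle against fitted maxima
bernoulli_loglik <- function(b0, bd, bt, diam, is_alt, y) {
  eta <- b0 + bd * diam + bt * is_alt
  p <- 1 / (1 + exp(-eta))
  sum(y * log(p) + (1 - y) * log(1 - p))
}
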