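test_that("generators are reproducible given a seed and restore RNG state", {
  a <- gen_axon_population(n_per_subtype = 20, seed = 7)
  b <- gen_axon_population(n_per_subtype = 20, seed = 7)
  expect_identical(a$axons, b$axons)
  expect_identical(a$annotations, b$annotations)
  c_ <- gen_axon_population(n_per_subtype = 20, seed = 8)
  expect_false(identical(a$axons$diameter_um, c_$axons$diameter_um))
  # library calls do not perturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(gen_axon_population(n_per_subtype = 5, seed = 9))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("an empty population request returns empty, well-formed outputs", {
  out <- gen_axon_population(n_per_subtype = 0, seed = 1)
  expect_length(out$traces, 0L)
  expect_equal(nrow(out$annotations), 0L)
  expect_equal(nrow(out$axons), 0L)
})

test_that("a steep diameter effect saturates myelination", {
  params <- list(subtype_params("PV", diameter_mean = 0.6, beta_type = 0),
                 subtype_params("VM", diameter_mean = 0.6, beta_type = 0))
  out <- gen_axon_population(params,
                             glm_coef = c("(Intercept)" = 0, diam = 100),
                             n_per_subtype = 50, seed = 2)
  expect_true(all(out$axons$myelinated))
  expect_true(all(table(out$annotations$axon_id) >= 1))
})

test_that("empirical myelination proportions are monotone in the subtype offsets", {
  out <- gen_axon_population(n_per_subtype = 2000, seed = 10)
  prop <- tapply(out$axons$myelinated, out$axons$subtype, mean)
  # PV ~ VM at the top (PV has the larger diameters), then decreasing offsets
  expect_gt(prop[["PV"]], prop[["VM"]] - 0.03)
  expect_gt(prop[["VM"]], prop[["PO"]])
  expect_gt(prop[["PO"]], prop[["RBP4"]])
  expect_gt(prop[["RBP4"]], prop[["NXPH4"]])
})

test_that("generated gaps respect the nodal/non-nodal construction", {
  out <- gen_axon_population(n_per_subtype = 300, seed = 21)
  gaps <- do.call(rbind, lapply(split(out$annotations, out$annotations$axon_id),
                                function(a) extract_gaps(a)))
  expect_true(all(gaps$length_um > 0))
  expect_true(all(gaps$length_um[!gaps$nodal] <= 150))
  # nodal fraction reproduces the generative p_nodal within binomial error
  p_hat <- mean(gaps$nodal)
  n <- nrow(gaps)
  expect_lt(abs(p_hat - 0.7), 4 * sqrt(0.7 * 0.3 / n) + 0.01)
})

test_that("jitter injection produces raw PLM above 100% that the cap clips to 99", {
  out <- gen_axon_population(n_per_subtype = 400, seed = 31, jitter_sd = 0.25)
  plms <- vapply(out$axons$axon_id, function(aid) {
    ann <- out$annotations[out$annotations$axon_id == aid, , drop = FALSE]
    compute_plm(out$traces[[aid]], ann, allow_overrun = TRUE)$plm
  }, numeric(1))
  raws <- vapply(out$axons$axon_id, function(aid) {
    ann <- out$annotations[out$annotations$axon_id == aid, , drop = FALSE]
    compute_plm(out$traces[[aid]], ann, allow_overrun = TRUE)$plm_raw
  }, numeric(1))
  expect_true(any(raws > 100))
  expect_true(all(plms[raws > 100] == 99))
  expect_true(all(plms[raws <= 100] == raws[raws <= 100]))
})

test_that("without jitter the cap never fires on generated populations", {
  out <- gen_axon_population(n_per_subtype = 200, seed = 41)
  for (aid in out$axons$axon_id[out$axons$myelinated]) {
    ann <- out$annotations[out$annotations$axon_id == aid, , drop = FALSE]
    p <- compute_plm(out$traces[[aid]], ann)
    expect_lte(p$plm_raw, 100)
    expect_false(p$capped)
  }
})

test_that("noiseless profiles recover the diameter and the PSF-limited width", {
  profs <- gen_intensity_profiles(c(0.4, 0.6, 0.9), psf_sigma = 0,
                                  noise_sd = 0, samples_per_um = 100, seed = 1)
  w <- vapply(profs, fwhm, numeric(1))
  expect_equal(w, c(0.4, 0.6, 0.9), tolerance = 0.02)
  # a box much narrower than the PSF approaches the Gaussian FWHM
  narrow <- gen_intensity_profiles(0.01, psf_sigma = 0.2, noise_sd = 0,
                                   samples_per_um = 200, seed = 1)
  expect_equal(fwhm(narrow[[1]]), 2 * sqrt(2 * log(2)) * 0.2, tolerance = 0.01)
})

test_that("noisy PSF-blurred profiles agree with a numerical convolution oracle", {
  psf <- 0.1; d <- 0.6
  # oracle: dense numerical convolution of the box with the Gaussian kernel,
  # then exact half-max search by linear interpolation
  dx <- 0.0005
  x <- seq(-2, 2, by = dx)
  box <- as.numeric(abs(x) <= d / 2)
  kern <- dnorm(seq(-5 * psf, 5 * psf, by = dx), 0, psf)
  kern <- kern / sum(kern)
  conv <- stats::convolve(box, rev(kern), type = "open")
  nk <- (length(kern) - 1) / 2
  conv <- conv[(nk + 1):(nk + length(x))]
  half <- (min(conv) + max(conv)) / 2
  above <- which(conv >= half)
  li <- above[1]; ri <- above[length(above)]
  interp <- function(i, j) x[i] + (half - conv[i]) * (x[j] - x[i]) / (conv[j] - conv[i])
  w_oracle <- interp(ri, ri + 1) - interp(li, li - 1)
  profs <- gen_intensity_profiles(rep(d, 50), psf_sigma = psf, noise_sd = 0.05,
                                  samples_per_um = 50, seed = 14)
  w_mean <- mean(vapply(profs, fwhm, numeric(1)))
  expect_lt(abs(w_mean - w_oracle) / w_oracle, 0.10)
})

test_that("longitudinal remodeling follows the stated piecewise-linear form", {
  rem <- remodeling_params(gain_at_zero = 20, loss_at_full = 10,
                           noise_sd = 0, pivot = 50)
  out <- gen_longitudinal(c(0, 25, 50, 99), rem, seed = 3)
  expect_equal(out$plm_recovery, c(20, 25 + 10, 50, 99 - 10 * 49 / 50),
               tolerance = 1e-9)
  # gain = loss = 0 with no noise: recovery equals baseline
  flat <- gen_longitudinal(c(5, 40, 80), remodeling_params(0, 0, 0), seed = 3)
  expect_equal(flat$plm_recovery, flat$plm_baseline)
  # determinism
  base <- runif(50, 0, 99)
  expect_identical(gen_longitudinal(base, seed = 12),
                   gen_longitudinal(base, seed = 12))
})

test_that("always-unmyelinated records are statused for model exclusion", {
  long <- gen_longitudinal(c(0, 0, 30, 60),
                           remodeling_params(gain_at_zero = 0, loss_at_full = 5,
                                             noise_sd = 0),
                           seed = 6)
  expect_equal(long$status,
               c("excluded_always_unmyelinated", "excluded_always_unmyelinated",
                 "present", "present"))
  expect_silent(validate_longitudinal(long))
})
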