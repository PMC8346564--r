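# reference coefficient set used throughout (treatment coding, PV reference)
ref_coef <- default_glm_coefficients()

test_that("d50 reproduces the expected ratios from a coefficient table", {
  fit <- logistic_fit(ref_coef)
  expect_equal(d50(fit, "PV")$d50, 3.044 / 5.836, tolerance = 1e-12)
  expect_equal(d50(fit, "PO")$d50, (3.044 + 0.481) / 5.836, tolerance = 1e-12)
  # algebraic identity: beta_type = -b0 - bd * 1  =>  d50 exactly 1 um
  fit1 <- logistic_fit(c("(Intercept)" = -3.044, diam = 5.836,
                         type_VM = 3.044 - 5.836))
  expect_equal(d50(fit1, "VM")$d50, 1, tolerance = 1e-12)
})

test_that("d50 ordering over subtypes follows the coefficient offsets", {
  fit <- logistic_fit(ref_coef, separation_flags = "type_NTSR1")
  d <- vapply(c("PV", "VM", "PO", "RBP4", "NXPH4"),
              function(s) d50(fit, s)$d50, numeric(1))
  expect_lt(abs(d[["PV"]] - d[["VM"]]), 0.02)  # PV ~ VM
  expect_true(all(diff(d[c("VM", "PO", "RBP4", "NXPH4")]) > 0))
})

test_that("predicted probability is logistic and has its fixed point at d50", {
  fit <- logistic_fit(ref_coef)
  expect_equal(predict_probability(fit, d50(fit, "PV")$d50, "PV"), 0.5,
               tolerance = 1e-12)
  expect_equal(predict_probability(fit, 1e-12, "PV"), plogis(-3.044),
               tolerance = 1e-6)
  expect_gt(predict_probability(fit, 2, "PV"), 0.99)
  # strictly increasing in diameter for positive slope
  dd <- seq(0.1, 1.5, by = 0.05)
  expect_true(all(diff(predict_probability(fit, dd, "VM")) > 0))
})

test_that("the GLM fit maximizes the Bernoulli likelihood (grid-search oracle)", {
  set.seed(301)
  n <- 30
  diam <- runif(n, 0.2, 1.2)
  sub <- rep(c("PV", "VM"), length.out = n)
  y <- rbinom(n, 1, plogis(-3 + 5.5 * diam + 0.2 * (sub == "VM")))
  # keep both classes in both subtypes so the tiny fit is well-posed
  y[1:2] <- c(0, 1); y[3:4] <- c(0, 1)
  fit <- fit_myelination_glm(data.frame(mean_diameter_um = diam, subtype = sub,
                                        myelination_fraction = y))
  cf <- fit$coefficients
  ll_fit <- bernoulli_loglik(cf[["(Intercept)"]], cf[["diam"]], cf[["type_VM"]],
                             diam, sub == "VM", y)
  expect_equal(ll_fit, fit$loglik, tolerance = 1e-6)
  # no grid point around the fit may beat the fitted maximum
  grid <- expand.grid(b0 = cf[["(Intercept)"]] + seq(-1, 1, by = 0.1),
                      bd = cf[["diam"]] + seq(-1, 1, by = 0.1),
                      bt = cf[["type_VM"]] + seq(-1, 1, by = 0.1))
  ll_grid <- mapply(bernoulli_loglik, grid$b0, grid$bd, grid$bt,
                    MoreArgs = list(diam = diam, is_alt = sub == "VM", y = y))
  expect_lte(max(ll_grid), ll_fit + 1e-3)
})

test_that("coefficient bias shrinks as the sample grows", {
  sim_bias <- function(n, seed) {
    set.seed(seed)
    subs <- c("PV", "VM", "PO", "RBP4", "NXPH4")
    diam <- runif(n, 0.2, 1.2)
    sub <- sample(subs, n, replace = TRUE)
    bt <- ifelse(sub == "PV", 0, ref_coef[paste0("type_", sub)])
    y <- rbinom(n, 1, plogis(ref_coef[["(Intercept)"]] +
                               ref_coef[["diam"]] * diam + bt))
    fit <- fit_myelination_glm(data.frame(mean_diameter_um = diam,
                                          subtype = sub,
                                          myelination_fraction = y))
    abs(fit$coefficients[["diam"]] - ref_coef[["diam"]])
  }
  seeds <- 401:403
  bias_small <- mean(vapply(seeds, function(s) sim_bias(2000, s), numeric(1)))
  bias_large <- mean(vapply(seeds, function(s) sim_bias(20000, s), numeric(1)))
  expect_lt(bias_large, bias_small)
  expect_lt(bias_large, 0.15)
})

test_that("site-fraction responses enter as weighted binomial proportions", {
  set.seed(77)
  n <- 400
  diam <- runif(n, 0.2, 1.2)
  sub <- rep(c("PV", "VM"), length.out = n)
  k <- sample(2:3, n, replace = TRUE)
  p <- plogis(-3 + 5.8 * diam)
  frac <- rbinom(n, k, p) / k
  fit <- fit_myelination_glm(data.frame(mean_diameter_um = diam, subtype = sub,
                                        myelination_fraction = frac,
                                        n_sites = k))
  expect_true(fit$converged)
  expect_equal(fit$coefficients[["diam"]], 5.8, tolerance = 1.2)
})

test_that("complete separation is flagged, not regularized", {
  set.seed(19)
  n <- 300
  diam <- runif(n, 0.2, 1.2)
  sub <- rep(c("PV", "VM", "NTSR1"), length.out = n)
  y <- rbinom(n, 1, plogis(-3 + 5.8 * diam))
  y[sub == "NTSR1"] <- 0  # a subtype with zero myelinated axons
  fit <- fit_myelination_glm(data.frame(mean_diameter_um = diam, subtype = sub,
                                        myelination_fraction = y))
  expect_true("type_NTSR1" %in% fit$separation_flags)
  expect_lt(fit$coefficients[["type_NTSR1"]], -10)
  expect_gt(fit$standard_errors[["type_NTSR1"]], 100)
  expect_error(d50(fit, "NTSR1"), class = "myelo_separation_error")
  # the non-separated terms are still usable
  expect_false("type_VM" %in% fit$separation_flags)
  expect_true(is.finite(d50(fit, "VM")$d50))
})

test_that("degenerate designs raise the documented errors", {
  df <- data.frame(mean_diameter_um = runif(20, 0.2, 1), subtype = "PV",
                   myelination_fraction = rbinom(20, 1, 0.5))
  expect_error(fit_myelination_glm(df), class = "myelo_argument_error")
  df2 <- data.frame(mean_diameter_um = runif(20, 0.2, 1),
                    subtype = rep(c("PV", "VM"), 10),
                    myelination_fraction = 0)
  expect_error(fit_myelination_glm(df2), class = "myelo_no_information_error")
})

test_that("delta-method intervals bracket the d50 point estimate", {
  set.seed(5150)
  n <- 2000
  diam <- runif(n, 0.2, 1.2)
  sub <- sample(c("PV", "VM"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-3.044 + 5.836 * diam + 0.047 * (sub == "VM")))
  fit <- fit_myelination_glm(data.frame(mean_diameter_um = diam, subtype = sub,
                                        myelination_fraction = y))
  for (s in c("PV", "VM")) {
    est <- d50(fit, s)
    expect_lte(est$lower, est$d50)
    expect_gte(est$upper, est$d50)
    expect_lt(est$upper - est$lower, 0.5)
  }
})

test_that("constructed fits validate coefficient naming and reference coding", {
  expect_error(logistic_fit(c(a = 1)), class = "myelo_argument_error")
  expect_error(logistic_fit(c("(Intercept)" = -3, diam = 5, type_PV = 1),
                            reference = "PV"),
               class = "myelo_argument_error")
  fit <- logistic_fit(ref_coef)
  expect_error(d50(fit, "SOM"), class = "myelo_argument_error")
})
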