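#' Reference coefficients for the diameter + subtype myelination model
#'
#' The coefficient set of the binomial GLM
#' `P(myelinated) ~ 1 + diameter + subtype` (treatment coding, PV
#' reference) estimated on layer I cortical axons, used as the generative
#' truth by [gen_axon_population()] and as the default model in worked
#' examples. The NTSR1 term is a separated estimate (essentially no NTSR1
#' axon is myelinated in layer I), which downstream code must treat as
#' flagged rather than as a finite effect.
#'
#' @return Named numeric vector with elements `"(Intercept)"`, `"diam"`
#'   and `"type_<subtype>"` offsets.
#' @export
default_glm_coefficients <- function() {
  c("(Intercept)" = -3.044, diam = 5.836,
    type_VM = 0.047, type_PO = -0.481, type_RBP4 = -1.014,
    type_NXPH4 = -1.470, type_NTSR1 = -15.215)
}

#' Per-subtype generative parameters
#'
#' Bundles what the generator needs to emulate one subtype's axons:
#' the diameter distribution (lognormal matched to a mean and sd), the
#' subtype's logit offset, and the internode/gap geometry. Internode and
#' gap parameters are synthetic defaults chosen to reproduce the
#' qualitative structure of cortical myelin (internodes tens of um;
#' nodal gaps below 5 um dominating; non-nodal gaps broadly spread over
#' 5-150 um); they are not measured values.
#'
#' @param subtype One of [MYELO_SUBTYPES].
#' @param diameter_mean,diameter_sd Axon diameter mean and sd in um.
#' @param beta_type Logit offset relative to the reference subtype.
#' @param internode_mean,internode_sd Internode length mean / sd in um
#'   (truncated below at 10 um).
#' @param nodal_gap_range Length-2 range (um) of nodal gaps; within (0, 5].
#' @param nonnodal_gap_logmean,nonnodal_gap_logsd Lognormal parameters of
#'   non-nodal gaps, truncated to \[5, 150\] um.
#' @param p_nodal Probability that a gap is nodal.
#' @return A `subtype_params` list.
#' @export
subtype_params <- function(subtype, diameter_mean, diameter_sd = 0.15,
                           beta_type = 0, internode_mean = 50,
                           internode_sd = 15, nodal_gap_range = c(1, 5),
                           nonnodal_gap_logmean = log(30),
                           nonnodal_gap_logsd = 0.8, p_nodal = 0.7) {
  check_subtype(subtype)
  stopifnot(diameter_mean > 0, diameter_sd > 0,
            internode_mean > 0, internode_sd >= 0,
            length(nodal_gap_range) == 2L,
            nodal_gap_range[1] > 0, nodal_gap_range[2] <= 5,
            nodal_gap_range[1] <= nodal_gap_range[2],
            p_nodal >= 0, p_nodal <= 1)
  structure(list(subtype = subtype, diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd, beta_type = beta_type,
                 internode_mean = internode_mean, internode_sd = internode_sd,
                 nodal_gap_range = nodal_gap_range,
                 nonnodal_gap_logmean = nonnodal_gap_logmean,
                 nonnodal_gap_logsd = nonnodal_gap_logsd,
                 p_nodal = p_nodal),
            class = "subtype_params")
}

#' Default generative parameter set
#'
#' One [subtype_params()] per modelled subtype, with logit offsets from
#' [default_glm_coefficients()], diameter means of 0.6 um (PV) and 0.5 um
#' (all others, matching the reported VM mean; subtype-specific means for
#' the remaining populations are not published, so the VM value is reused
#' as a plausible default).
#'
#' @param include_ntsr1 Include the NTSR1 population (whose separated
#'   offset makes essentially every axon unmyelinated)? Default `FALSE`,
#'   the configuration appropriate for model-recovery work.
#' @return Named list of `subtype_params`.
#' @export
default_subtype_params <- function(include_ntsr1 = FALSE) {
  cf <- default_glm_coefficients()
  subs <- c("PV", "VM", "PO", "RBP4", "NXPH4", if (include_ntsr1) "NTSR1")
  out <- lapply(subs, function(s) {
    subtype_params(s,
                   diameter_mean = if (s == "PV") 0.6 else 0.5,
                   beta_type = if (s == "PV") 0 else cf[[paste0("type_", s)]])
  })
  stats::setNames(out, subs)
}

# lognormal parameters matched to an arithmetic mean and sd
lognormal_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:100) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(out, lower), upper)
}

#' Generate a synthetic axon population
#'
#' For each axon: a diameter is drawn from the subtype's lognormal; the
#' axon is an unbranched straight trace whose length is truncated normal;
#' myelination status is Bernoulli with probability
#' `logistic(b0 + bd * diameter + beta_type)`; and, if myelinated,
#' internodes alternate with gaps (nodal with probability `p_nodal`,
#' uniform in the nodal range, otherwise truncated lognormal on
#' \[5, 150\] um) from a uniformly drawn start offset until the trace ends.
#' An optional multiplicative jitter inflates annotated internode lengths,
#' emulating the two-channel trace jitter that pushes raw PLM above 100%
#' on continuously myelinated axons.
#'
#' @param params Named list of [subtype_params()]; default
#'   [default_subtype_params()].
#' @param glm_coef Named coefficient vector with `"(Intercept)"` and
#'   `"diam"`; default [default_glm_coefficients()].
#' @param n_per_subtype Axons per subtype.
#' @param seed RNG seed (results are reproducible given seed + params).
#' @param trace_length_mean,trace_length_sd,trace_length_min Trace length
#'   distribution in um (truncated normal); defaults 400 / 150 / 100 (the
#'   tracing protocol only keeps axons at least 100 um long).
#' @param point_spacing Spacing of trace points in um; default 10.
#' @param jitter_sd Standard deviation of the multiplicative internode
#'   length jitter (0 disables; jittered annotations may overrun their
#'   branch, see `allow_overrun` in [compute_plm()]).
#' @param start_offset_max Upper bound (um) of the uniform start offset of
#'   the first internode; default 30.
#' @return List with `traces` (list of [axon_trace()]), `annotations`
#'   (data frame `axon_id branch_id s_start_um s_end_um`), and `axons`
#'   (data frame `axon_id subtype diameter_um p_myelinated myelinated`).
#' @export
gen_axon_population <- function(params = default_subtype_params(),
                                glm_coef = default_glm_coefficients(),
                                n_per_subtype = 100, seed = 1,
                                trace_length_mean = 400,
                                trace_length_sd = 150,
                                trace_length_min = 100,
                                point_spacing = 10,
                                jitter_sd = 0,
                                start_offset_max = 30) {
  stopifnot(all(c("(Intercept)", "diam") %in% names(glm_coef)))
  for (p in params) stopifnot(inherits(p, "subtype_params"))
  if (n_per_subtype == 0L) {
    return(list(traces = list(),
                annotations = data.frame(axon_id = character(),
                                         branch_id = character(),
                                         s_start_um = numeric(),
                                         s_end_um = numeric()),
                axons = data.frame(axon_id = character(), subtype = character(),
                                   diameter_um = numeric(),
                                   p_myelinated = numeric(),
                                   myelinated = logical())))
  }
  with_seed(seed, {
    traces <- list()
    ann <- list()
    meta <- list()
    for (p in params) {
      lp <- lognormal_pars(p$diameter_mean, p$diameter_sd)
      for (i in seq_len(n_per_subtype)) {
        aid <- sprintf("%s_%04d", p$subtype, i)
        diam <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
        L <- rtrunc_norm(1, trace_length_mean, trace_length_sd, trace_length_min)
        xs <- unique(c(seq(0, L, by = point_spacing), L))
        tr <- axon_trace(aid, p$subtype, "other",
                         list(b1 = polyline3d(cbind(xs, 0, 0))))
        prob <- stats::plogis(glm_coef[["(Intercept)"]] +
                                glm_coef[["diam"]] * diam + p$beta_type)
        myel <- stats::runif(1) < prob
        if (myel) {
          starts <- numeric(); ends <- numeric()
          s <- stats::runif(1, 0, min(start_offset_max, L / 2))
          while (s < L) {
            ilen <- rtrunc_norm(1, p$internode_mean, p$internode_sd, 10)
            starts <- c(starts, s)
            ends <- c(ends, min(s + ilen, L))
            if (s + ilen >= L) break
            gap <- if (stats::runif(1) < p$p_nodal) {
              stats::runif(1, p$nodal_gap_range[1], p$nodal_gap_range[2])
            } else {
              rtrunc_lnorm(1, p$nonnodal_gap_logmean, p$nonnodal_gap_logsd, 5, 150)
            }
            s <- s + ilen + gap
          }
          if (jitter_sd > 0 && length(starts) > 0L) {
            # inflate sheath-trace lengths as two-channel trace jitter does;
            # interior internodes stop at the next internode's start, the
            # last one may overrun the branch end (raw PLM can exceed 100%)
            infl <- ends + (ends - starts) * abs(stats::rnorm(length(ends), 0, jitter_sd))
            k <- length(ends)
            if (k > 1L) ends[-k] <- pmin(infl[-k], starts[-1L])
            ends[k] <- infl[k]
          }
          if (length(starts) > 0L) {
            ann[[length(ann) + 1L]] <-
              data.frame(axon_id = aid, branch_id = "b1",
                         s_start_um = starts, s_end_um = ends)
          }
        }
        traces[[aid]] <- tr
        meta[[length(meta) + 1L]] <-
          data.frame(axon_id = aid, subtype = p$subtype, diameter_um = diam,
                     p_myelinated = unname(prob), myelinated = myel)
      }
    }
    list(traces = traces,
         annotations = if (length(ann) > 0L) do.call(rbind, ann) else
           data.frame(axon_id = character(), branch_id = character(),
                      s_start_um = numeric(), s_end_um = numeric()),
         axons = do.call(rbind, meta))
  })
}

#' Generate synthetic transverse intensity profiles
#'
#' Each profile is a box of width equal to the axon diameter convolved
#' with a Gaussian point-spread function of `psf_sigma` (computed in
#' closed form as a difference of normal CDFs), on a constant baseline,
#' with i.i.d. Gaussian noise proportional to the peak amplitude.
#'
#' @param diameters Numeric vector of axon diameters in um.
#' @param psf_sigma PSF standard deviation in um (0 = ideal optics).
#' @param noise_sd Noise sd as a fraction of the amplitude; default 0.05.
#' @param samples_per_um Sampling density; default 50.
#' @param baseline,amplitude Background level and box height in gray
#'   values; defaults 10 and 100.
#' @param myelinated Optional logical vector of site flags (default all
#'   `NA`).
#' @param seed RNG seed.
#' @return List of [intensity_profile()] objects, one per diameter.
#' @export
gen_intensity_profiles <- function(diameters, psf_sigma = 0.1,
                                   noise_sd = 0.05, samples_per_um = 50,
                                   baseline = 10, amplitude = 100,
                                   myelinated = NULL, seed = 1) {
  stopifnot(psf_sigma >= 0, all(diameters > 0))
  if (is.null(myelinated)) myelinated <- rep(NA, length(diameters))
  with_seed(seed, {
    lapply(seq_along(diameters), function(i) {
      w <- diameters[i]
      half_extent <- w / 2 + 4 * psf_sigma + 0.5
      x <- seq(-half_extent, half_extent, by = 1 / samples_per_um)
      signal <- if (psf_sigma == 0) {
        amplitude * as.numeric(abs(x) <= w / 2)
      } else {
        amplitude * (stats::pnorm((x + w / 2) / psf_sigma) -
                       stats::pnorm((x - w / 2) / psf_sigma))
      }
      v <- baseline + signal +
        stats::rnorm(length(x), 0, noise_sd * amplitude)
      intensity_profile(x, v, site_myelinated = myelinated[i])
    })
  })
}

#' Longitudinal remodeling parameters
#'
#' Expected remodeling is piecewise linear in baseline PLM: axons at
#' baseline 0 gain `gain_at_zero` points on average, the expected change
#' falls to 0 at `pivot`, and declines further to `-loss_at_full` at
#' baseline 100 -- weakly myelinated axons tend to gain myelin during
#' recovery while continuously myelinated axons tend to lose some.
#' Defaults (gain 25, loss 10, pivot 45, noise sd 10) reproduce that
#' qualitative pattern at magnitudes consistent with reported medians.
#'
#' @param gain_at_zero Expected delta-PLM at baseline 0 (percent).
#' @param loss_at_full Expected loss at baseline 100 (percent, positive).
#' @param noise_sd Gaussian noise sd in PLM points.
#' @param pivot Baseline PLM at which expected change is 0; in (0, 100).
#' @return A `remodeling_params` list.
#' @export
remodeling_params <- function(gain_at_zero = 25, loss_at_full = 10,
                              noise_sd = 10, pivot = 45) {
  stopifnot(noise_sd >= 0, pivot > 0, pivot < 100)
  structure(list(gain_at_zero = gain_at_zero, loss_at_full = loss_at_full,
                 noise_sd = noise_sd, pivot = pivot),
            class = "remodeling_params")
}

#' Generate longitudinal remyelination records
#'
#' Applies the [remodeling_params()] expectation to each baseline PLM,
#' adds Gaussian noise, and clips recovery to \[0, 99\]. Records
#' unmyelinated at both timepoints get status
#' `excluded_always_unmyelinated`; all others are `present`.
#'
#' @param baseline_plms Numeric vector of baseline PLM values in \[0, 99\].
#' @param remodeling A [remodeling_params()]; default defaults.
#' @param subtype Subtype label for all records; default "PV".
#' @param seed RNG seed.
#' @return Longitudinal data frame (see [read_longitudinal()]).
#' @export
gen_longitudinal <- function(baseline_plms, remodeling = remodeling_params(),
                             subtype = "PV", seed = 1) {
  stopifnot(inherits(remodeling, "remodeling_params"),
            all(baseline_plms >= 0), all(baseline_plms <= 99))
  check_subtype(subtype)
  with_seed(seed, {
    b <- baseline_plms
    expected <- ifelse(
      b < remodeling$pivot,
      remodeling$gain_at_zero * (1 - b / remodeling$pivot),
      -remodeling$loss_at_full * (b - remodeling$pivot) / (100 - remodeling$pivot))
    delta <- expected + stats::rnorm(length(b), 0, remodeling$noise_sd)
    recovery <- pmin(99, pmax(0, b + delta))
    status <- ifelse(b == 0 & recovery == 0, "excluded_always_unmyelinated",
                     "present")
    data.frame(axon_id = sprintf("%s_long_%04d", subtype, seq_along(b)),
               subtype = subtype, plm_baseline = b, plm_recovery = recovery,
               status = status)
  })
}
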