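#' Default pipeline configuration
#'
#' A run configuration is a plain list (serializable to YAML) with one
#' master seed: every stochastic stage derives its own seed from it, so a
#' single integer reproduces an entire run. Thresholds mirror the
#' analysis defaults: nodal gaps at most 5 um, PLM cap 99, PV reference
#' for the GLM, smoothing window 3.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("myelorun"), seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "metrics", "diameter", "model", "remyelination"),
    n_per_subtype = 50,
    nodal_threshold = 5,
    cap_percent = 99,
    smooth_window = 3,
    glm_reference = "PV",
    separation_coef_threshold = 10,
    separation_se_threshold = 100,
    jitter_sd = 0,
    psf_sigma = 0.1,
    profile_noise_sd = 0.05,
    n_longitudinal = 200,
    remodeling = list(gain_at_zero = 25, loss_at_full = 10,
                      noise_sd = 10, pivot = 45)
  )
}

#' Validate a pipeline configuration
#'
#' Checks ranges, stage names and the reference subtype before any stage
#' runs, so a bad configuration fails fast.
#'
#' @param config A configuration list (see [default_run_config()]), or a
#'   path to a YAML file holding one.
#' @return The validated (and YAML-loaded, if applicable) config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop_myelo("unknown config field(s): %s", "myelo_config_error",
               paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed) || !is.finite(config$seed)) {
    stop_myelo("config must set a seed", "myelo_config_error")
  }
  bad_stage <- setdiff(config$stages, defaults$stages)
  if (length(bad_stage) > 0L) {
    stop_myelo("unknown stage(s): %s", "myelo_config_error",
               paste(bad_stage, collapse = ", "))
  }
  check_subtype(config$glm_reference)
  if (config$nodal_threshold <= 0 || config$cap_percent <= 0 ||
      config$cap_percent > 100) {
    stop_myelo("thresholds out of range", "myelo_config_error")
  }
  if (config$smooth_window < 1 || config$smooth_window %% 2 == 0) {
    stop_myelo("smooth_window must be a positive odd integer", "myelo_config_error")
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs:
#' `simulate` writes SWC traces, internode annotations and the
#' longitudinal table; `metrics` reads them back, smooths the traces and
#' computes per-axon PLM and gap tables; `diameter` generates intensity
#' profiles at 2-3 sites per axon and estimates diameters by FWHM;
#' `model` fits the myelination GLM and tabulates per-subtype d50;
#' `remyelination` fits the simple and adjusted recovery models. All
#' stage outputs are written under `config$out_dir` together with a JSON
#' run report. Given an identical config (including seed) a rerun
#' produces identical numbers.
#'
#' @param config A config list or YAML path (see [validate_run_config()]).
#' @return The run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("myelotrace")),
                 seed = config$seed, stages = list())
  seed_of <- function(stage) {
    config$seed + c(simulate = 101L, diameter = 202L,
                    remyelination = 303L)[[stage]]
  }
  sim <- NULL
  profiles_tab <- NULL

  if ("simulate" %in% config$stages) {
    sim <- gen_axon_population(n_per_subtype = config$n_per_subtype,
                               seed = seed_of("simulate"),
                               jitter_sd = config$jitter_sd)
    swc_dir <- file.path(config$out_dir, "swc")
    dir.create(swc_dir, showWarnings = FALSE)
    for (tr in sim$traces) {
      write_swc(tr, file.path(swc_dir, paste0(tr$axon_id, ".swc")))
    }
    write_tsv(sim$annotations, file.path(config$out_dir, "annotations.tsv"))
    write_tsv(sim$axons, file.path(config$out_dir, "axons.tsv"))
    report$stages$simulate <- list(status = "ok", n_axons = nrow(sim$axons),
                                   n_annotations = nrow(sim$annotations))
  }

  if ("metrics" %in% config$stages) {
    if (is.null(sim)) {
      stop_myelo("metrics stage needs the simulate stage", "myelo_dependency_error")
    }
    swc_dir <- file.path(config$out_dir, "swc")
    ann <- read_annotations(file.path(config$out_dir, "annotations.tsv"))
    profs <- lapply(sim$axons$axon_id, function(aid) {
      tr <- read_swc(file.path(swc_dir, paste0(aid, ".swc")), axon_id = aid,
                     subtype = sim$axons$subtype[sim$axons$axon_id == aid])
      tr <- smooth_axon(tr, window = config$smooth_window)
      compute_plm(tr, ann[ann$axon_id == aid, , drop = FALSE],
                  cap_percent = config$cap_percent,
                  nodal_threshold = config$nodal_threshold,
                  allow_overrun = config$jitter_sd > 0)
    })
    tabs <- profiles_table(profs)
    profiles_tab <- tabs$profiles
    write_tsv(tabs$profiles, file.path(config$out_dir, "profiles.tsv"))
    write_tsv(tabs$gaps, file.path(config$out_dir, "gaps.tsv"))
    report$stages$metrics <- list(
      status = "ok", n_profiles = nrow(tabs$profiles),
      proportion_myelinated = proportion_myelinated(tabs$profiles$plm),
      n_gaps = nrow(tabs$gaps),
      nodal_fraction = if (nrow(tabs$gaps) > 0) mean(tabs$gaps$nodal) else NA)
  }

  diam_tab <- NULL
  if ("diameter" %in% config$stages) {
    if (is.null(sim)) {
      stop_myelo("diameter stage needs the simulate stage", "myelo_dependency_error")
    }
    recs <- with_seed(seed_of("diameter"), {
      lapply(seq_len(nrow(sim$axons)), function(i) {
        n_sites <- sample(2:3, 1)  # two to three measurement sites per axon
        profs <- gen_intensity_profiles(
          rep(sim$axons$diameter_um[i], n_sites),
          psf_sigma = config$psf_sigma, noise_sd = config$profile_noise_sd,
          myelinated = rep(sim$axons$myelinated[i], n_sites),
          seed = NULL)
        axon_diameter(profs, axon_id = sim$axons$axon_id[i],
                      subtype = sim$axons$subtype[i])
      })
    })
    diam_tab <- diameter_table(recs)
    write_tsv(diam_tab, file.path(config$out_dir, "diam.tsv"))
    report$stages$diameter <- list(status = "ok", n_axons = nrow(diam_tab),
                                   mean_diameter_um = mean(diam_tab$mean_diameter_um))
  }

  if ("model" %in% config$stages) {
    if (is.null(diam_tab)) {
      stop_myelo("model stage needs the diameter stage", "myelo_dependency_error")
    }
    fit <- fit_myelination_glm(diam_tab, reference = config$glm_reference,
                               coef_threshold = config$separation_coef_threshold,
                               se_threshold = config$separation_se_threshold)
    d50s <- d50_table(fit)
    write_tsv(d50s, file.path(config$out_dir, "d50.tsv"))
    jsonlite::write_json(
      list(coefficients = as.list(fit$coefficients),
           standard_errors = as.list(fit$standard_errors),
           covariance = fit$covariance, loglik = fit$loglik,
           converged = fit$converged,
           separation_flags = fit$separation_flags,
           reference = fit$reference),
      file.path(config$out_dir, "fit.json"),
      auto_unbox = TRUE, digits = NA)
    report$stages$model <- list(status = "ok",
                                coefficients = as.list(round(fit$coefficients, 4)),
                                separation_flags = fit$separation_flags,
                                d50 = stats::setNames(round(d50s$d50_um, 3),
                                                      d50s$subtype))
  }

  if ("remyelination" %in% config$stages) {
    if (is.null(profiles_tab)) {
      stop_myelo("remyelination stage needs the metrics stage",
                 "myelo_dependency_error")
    }
    base <- profiles_tab$plm[profiles_tab$subtype %in% c("PV", "VM")]
    base <- base[seq_len(min(length(base), config$n_longitudinal))]
    rem <- do.call(remodeling_params, config$remodeling)
    long <- gen_longitudinal(base, remodeling = rem,
                             seed = seed_of("remyelination"))
    write_tsv(long, file.path(config$out_dir, "longitudinal.tsv"))
    fit_s <- fit_recovery_model(long, "simple")
    fit_a <- fit_recovery_model(long, "adjusted")
    long_present <- long[long$status != "lost", , drop = FALSE]
    dtab <- data.frame(axon_id = long_present$axon_id,
                       delta_plm = delta_plm(long_present))
    write_tsv(dtab, file.path(config$out_dir, "delta_plm.tsv"))
    jsonlite::write_json(
      list(simple = list(coefficients = as.list(fit_s$coefficients),
                         r_squared = fit_s$r_squared,
                         p_value = fit_s$p_value, n = fit_s$n,
                         identity_crossing = tryCatch(identity_crossing(fit_s),
                                                      error = function(e) NULL)),
           adjusted = list(coefficients = as.list(fit_a$coefficients),
                           r_squared = fit_a$r_squared,
                           p_value = fit_a$p_value, n = fit_a$n)),
      file.path(config$out_dir, "remyel.json"),
      auto_unbox = TRUE, digits = NA)
    report$stages$remyelination <- list(
      status = "ok", n = fit_s$n,
      simple_r2 = fit_s$r_squared, adjusted_r2 = fit_a$r_squared)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
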