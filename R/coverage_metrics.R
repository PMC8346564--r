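#' Per-axon myelination profile
#'
#' Computes the percent length myelinated (PLM) of one axon from its trace
#' and its internode annotations:
#' `PLM = 100 * (summed internode length) / (total axon length)`, over the
#' pooled branch tree. Manual two-channel tracing can yield summed sheath
#' length slightly above the axon length (trace jitter); when the raw
#' quotient exceeds 100% the PLM is set to `cap_percent` (99 by default).
#' Internode lengths are reported in branch-then-arc-length order and the
#' unmyelinated-gap spectrum is extracted per branch via [extract_gaps()]
#' and pooled.
#'
#' @param axon An [axon_trace()].
#' @param annotations Data frame with columns `axon_id`, `branch_id`,
#'   `s_start_um`, `s_end_um` (see [read_annotations()]); may be empty.
#' @param cap_percent PLM value assigned when the raw quotient exceeds
#'   100%. Default 99.
#' @param nodal_threshold Gap length (um) at or below which a gap is
#'   classified as a node of Ranvier. Default 5.
#' @param merge_tol Overlap tolerance (um) for merging annotations that
#'   share a rounded boundary. Default 0.5.
#' @param allow_overrun If `TRUE`, an annotation may extend past the end of
#'   its branch (as jittered sheath traces do); the overhang still counts
#'   as myelin, which is what makes the raw quotient exceed 100%. Default
#'   `FALSE` (strict geometry).
#' @return An object of class `myelination_profile`: a list with
#'   `axon_id`, `subtype`, `region`, `total_length`, `myelinated_length`,
#'   `plm`, `plm_raw` (uncapped), `capped`, `internode_lengths`, and
#'   `gaps` (data frame `length_um`, `nodal`).
#' @examples
#' tr <- axon_trace("a1", "PV", "SS",
#'                  list(b1 = polyline3d(cbind(c(0, 200), 0, 0))))
#' ann <- data.frame(axon_id = "a1", branch_id = "b1",
#'                   s_start_um = c(0, 100), s_end_um = c(50, 150))
#' compute_plm(tr, ann)$plm  # 50
#' @export
compute_plm <- function(axon, annotations, cap_percent = 99,
                        nodal_threshold = 5, merge_tol = 0.5,
                        allow_overrun = FALSE) {
  stopifnot(inherits(axon, "axon_trace"))
  if (is.null(annotations) || nrow(annotations) == 0L) {
    annotations <- data.frame(axon_id = character(), branch_id = character(),
                              s_start_um = numeric(), s_end_um = numeric())
  }
  foreign <- setdiff(unique(annotations$axon_id), axon$axon_id)
  if (length(foreign) > 0L) {
    stop_myelo("annotations reference foreign axon(s): %s",
               "myelo_consistency_error", paste(foreign, collapse = ", "))
  }
  bad_branch <- setdiff(unique(annotations$branch_id), names(axon$branches))
  if (length(bad_branch) > 0L) {
    stop_myelo("annotations reference unknown branch(es): %s",
               "myelo_consistency_error", paste(bad_branch, collapse = ", "))
  }
  total_length <- axon$total_length
  internode_lengths <- numeric()
  gap_len <- numeric(); gap_nodal <- logical()
  for (bid in names(axon$branches)) {  # branch-then-arclength order
    rows <- annotations$branch_id == bid
    if (!any(rows)) next
    blen <- polyline_length(axon$branches[[bid]])
    merged <- merge_branch_annotations(annotations$s_start_um[rows],
                                       annotations$s_end_um[rows],
                                       tol = merge_tol)
    over <- max(merged$s_end_um) - blen
    if (over > 1e-9 && !allow_overrun) {
      stop_myelo("annotation ends %.3f um past branch %s (length %.3f um)",
                 "myelo_annotation_error", over, bid, blen)
    }
    internode_lengths <- c(internode_lengths,
                           merged$s_end_um - merged$s_start_um)
    g <- extract_gaps(merged, nodal_threshold = nodal_threshold)
    gap_len <- c(gap_len, g$length_um)
    gap_nodal <- c(gap_nodal, g$nodal)
  }
  myelinated_length <- sum(internode_lengths)
  plm_raw <- 100 * myelinated_length / total_length
  capped <- plm_raw > 100
  structure(list(axon_id = axon$axon_id, subtype = axon$subtype,
                 region = axon$region, total_length = total_length,
                 myelinated_length = myelinated_length,
                 plm = if (capped) cap_percent else plm_raw,
                 plm_raw = plm_raw, capped = capped,
                 internode_lengths = internode_lengths,
                 gaps = data.frame(length_um = gap_len, nodal = gap_nodal)),
            class = "myelination_profile")
}

#' @export
print.myelination_profile <- function(x, ...) {
  cat(sprintf("<myelination_profile %s: PLM %.1f%%%s, %d internode(s), %d gap(s)>\n",
              x$axon_id, x$plm, if (x$capped) " (capped)" else "",
              length(x$internode_lengths), nrow(x$gaps)))
  invisible(x)
}

#' Unmyelinated gaps between consecutive internodes on one branch
#'
#' A gap is the stretch of bare axon between two consecutive internodes on
#' the same branch. Terminal unmyelinated stretches (before the first and
#' after the last internode) are not gaps. Gaps of length at most
#' `nodal_threshold` are classified as nodes of Ranvier; longer gaps are
#' non-nodal.
#'
#' @param intervals Data frame with columns `s_start_um`, `s_end_um`,
#'   sorted and non-overlapping on a single branch.
#' @param nodal_threshold Nodal classification bound in um; default 5.
#' @return Data frame with columns `length_um` and `nodal` (one row per
#'   gap; empty for 0 or 1 internodes).
#' @examples
#' iv <- data.frame(s_start_um = c(10, 55), s_end_um = c(50, 90))
#' extract_gaps(iv)  # one 5-um nodal gap
#' @export
extract_gaps <- function(intervals, nodal_threshold = 5) {
  k <- nrow(intervals)
  if (is.null(k) || k < 2L) {
    return(data.frame(length_um = numeric(), nodal = logical()))
  }
  o <- order(intervals$s_start_um)
  s <- intervals$s_start_um[o]; e <- intervals$s_end_um[o]
  if (any(s[-1] < e[-k])) {
    stop_myelo("intervals must be non-overlapping (merge annotations first)",
               "myelo_annotation_error")
  }
  len <- s[-1] - e[-k]
  keep <- len > 0  # abutting internodes leave no gap
  data.frame(length_um = len[keep], nodal = len[keep] <= nodal_threshold)
}

#' Proportion of axons myelinated
#'
#' Fraction of axons with PLM > 0. When an animal grouping is supplied the
#' per-animal fractions are averaged and the standard error of the mean is
#' taken across animals (N = animals), matching how population proportions
#' are reported in this literature.
#'
#' @param plm Numeric vector of per-axon PLM values, or a list of
#'   [compute_plm()] profiles.
#' @param animal Optional vector of animal identifiers, same length as
#'   `plm`.
#' @return Without grouping, a single fraction in \[0, 1\]. With grouping, a
#'   list with `mean`, `sem`, `per_animal` (named vector) and `n_animals`.
#' @export
proportion_myelinated <- function(plm, animal = NULL) {
  if (is.list(plm)) plm <- vapply(plm, function(p) p$plm, numeric(1))
  if (length(plm) == 0L) stop_myelo("empty group", "myelo_argument_error")
  if (is.null(animal)) return(mean(plm > 0))
  stopifnot(length(animal) == length(plm))
  per <- tapply(plm > 0, as.character(animal), mean)
  per <- per[!is.na(per)]
  if (length(per) == 0L) stop_myelo("empty group", "myelo_argument_error")
  list(mean = mean(per),
       sem = if (length(per) > 1L) sem(as.numeric(per)) else NA_real_,
       per_animal = per, n_animals = length(per))
}

#' Scaled myelination prevalence
#'
#' Regional myelin density scaled to how many of a subtype's axons are
#' myelinated there: average binarized MBP intensity divided by the
#' proportion of axons myelinated. Comparable across cortical regions with
#' very different overall myelin content.
#'
#' @param mbp_intensity Mean gray value of the binarized MBP projection
#'   (arbitrary units).
#' @param proportion_myelinated Fraction of axons myelinated, in (0, 1\].
#' @return `mbp_intensity / proportion_myelinated` (arbitrary units).
#' @examples
#' scaled_prevalence(50, 0.7)  # 71.43
#' @export
scaled_prevalence <- function(mbp_intensity, proportion_myelinated) {
  if (any(proportion_myelinated <= 0)) {
    stop_myelo("scaled prevalence undefined when no axons are myelinated",
               "myelo_argument_error")
  }
  mbp_intensity / proportion_myelinated
}

#' Randomly select grid cells as axon seeds
#'
#' Emulates unbiased axon selection: a square grid of pitch `grid_pitch`
#' is placed across the image with cells anchored at multiples of the
#' pitch from the origin (a partially covered edge cell counts), and `n`
#' distinct cells are drawn uniformly without replacement. Deterministic
#' for a given seed.
#'
#' @param image_extent Numeric length-2 vector `(width_um, height_um)`.
#' @param grid_pitch Grid cell size in um; default 100.
#' @param n Number of cells to draw.
#' @param seed RNG seed (required for reproducibility).
#' @return Data frame with columns `x_um`, `y_um`: the anchor (lower-left
#'   corner) of each selected cell.
#' @export
select_axon_seeds <- function(image_extent, grid_pitch = 100, n, seed) {
  stopifnot(length(image_extent) == 2L, all(image_extent > 0), grid_pitch > 0)
  nx <- length(seq(0, image_extent[1] - 1e-9, by = grid_pitch))
  ny <- length(seq(0, image_extent[2] - 1e-9, by = grid_pitch))
  ncells <- nx * ny
  if (n > ncells) {
    stop_myelo("requested %d seeds but the grid has only %d cells",
               "myelo_argument_error", n, ncells)
  }
  idx <- with_seed(seed, sample.int(ncells, n, replace = FALSE))
  data.frame(x_um = ((idx - 1L) %% nx) * grid_pitch,
             y_um = ((idx - 1L) %/% nx) * grid_pitch)
}

#' Tabulate myelination profiles
#'
#' Flattens a list of [compute_plm()] profiles into the per-axon summary
#' table and the pooled gap table used by downstream analyses and written
#' by the pipeline.
#'
#' @param profiles List of `myelination_profile` objects.
#' @return List of two data frames: `profiles` (`axon_id`, `subtype`,
#'   `region`, `total_length_um`, `plm`, `n_internodes`) and `gaps`
#'   (`axon_id`, `gap_um`, `nodal`).
#' @export
profiles_table <- function(profiles) {
  prof <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(axon_id = p$axon_id, subtype = p$subtype, region = p$region,
               total_length_um = p$total_length, plm = p$plm,
               n_internodes = length(p$internode_lengths))
  }))
  gaps <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$gaps) == 0L) return(NULL)
    data.frame(axon_id = p$axon_id, gap_um = p$gaps$length_um,
               nodal = p$gaps$nodal)
  }))
  if (is.null(gaps)) {
    gaps <- data.frame(axon_id = character(), gap_um = numeric(),
                       nodal = logical())
  }
  list(profiles = prof, gaps = gaps)
}
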