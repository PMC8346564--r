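#' Construct a 3D polyline
#'
#' A branch of an axon trace: an ordered sequence of 3D points (coordinates
#' in micrometres) with precomputed cumulative arc length.
#'
#' @param points Numeric matrix with columns x, y, z (one row per point).
#' @return An object of class `polyline3d` with elements `points` (n x 3
#'   matrix) and `arclength` (cumulative arc length, starting at 0).
#' @examples
#' p <- polyline3d(cbind(c(0, 10, 20), 0, 0))
#' polyline_length(p)  # 20
#' @export
polyline3d <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop_myelo("polyline points must have 3 columns (x, y, z)", "myelo_geometry_error")
  }
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) {
    stop_myelo("a polyline needs at least 2 points", "myelo_degenerate_error")
  }
  if (!all(is.finite(points))) {
    stop_myelo("polyline coordinates must be finite", "myelo_geometry_error")
  }
  colnames(points) <- c("x", "y", "z")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "polyline3d")
}

#' @rdname polyline3d
#' @param poly A `polyline3d`.
#' @return `polyline_length()`: total arc length in micrometres.
#' @export
polyline_length <- function(poly) {
  stopifnot(inherits(poly, "polyline3d"))
  poly$arclength[length(poly$arclength)]
}

#' @export
print.polyline3d <- function(x, ...) {
  cat(sprintf("<polyline3d: %d points, %.3f um>\n",
              nrow(x$points), polyline_length(x)))
  invisible(x)
}

#' Construct an axon trace
#'
#' An axon trace is a tree of `polyline3d` branches with a subtype and a
#' region label. Branch connectivity is recorded as each branch's parent
#' branch; a child branch shares its first point with the last point of its
#' parent (the bifurcation node). Root branches have parent `NA`.
#'
#' @param axon_id Character scalar identifier.
#' @param subtype One of [MYELO_SUBTYPES].
#' @param region One of [MYELO_REGIONS].
#' @param branches Named list of `polyline3d` objects.
#' @param parent Named character vector mapping branch id to parent branch
#'   id (`NA` for branches attached at the root). Defaults to a single
#'   unbranched trace when `branches` has length 1.
#' @return An object of class `axon_trace`.
#' @export
axon_trace <- function(axon_id, subtype, region = "other", branches,
                       parent = NULL) {
  check_subtype(subtype)
  check_region(region)
  stopifnot(is.list(branches), length(branches) >= 1L)
  if (is.null(names(branches)) || anyDuplicated(names(branches))) {
    stop_myelo("branches must be uniquely named", "myelo_structure_error")
  }
  for (b in branches) stopifnot(inherits(b, "polyline3d"))
  if (is.null(parent)) {
    parent <- stats::setNames(rep(NA_character_, length(branches)), names(branches))
  }
  if (!setequal(names(parent), names(branches))) {
    stop_myelo("parent map must cover exactly the branch ids", "myelo_structure_error")
  }
  parent <- parent[names(branches)]
  # cycle check: following parents must terminate at NA
  for (b in names(branches)) {
    seen <- character()
    cur <- b
    while (!is.na(parent[[cur]])) {
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (!cur %in% names(branches)) {
        stop_myelo("branch %s has unknown parent %s", "myelo_structure_error", b, cur)
      }
      if (cur %in% seen) {
        stop_myelo("branch connectivity contains a cycle at %s", "myelo_structure_error", cur)
      }
    }
  }
  total <- sum(vapply(branches, polyline_length, numeric(1)))
  if (total <= 0) stop_myelo("axon total length must be > 0", "myelo_degenerate_error")
  structure(list(axon_id = as.character(axon_id), subtype = as.character(subtype),
                 region = as.character(region), branches = branches,
                 parent = parent, total_length = total),
            class = "axon_trace")
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace %s: subtype %s, region %s, %d branch(es), %.2f um>\n",
              x$axon_id, x$subtype, x$region, length(x$branches), x$total_length))
  invisible(x)
}

#' Total length of an axon trace
#'
#' @param trace An `axon_trace`.
#' @return Sum of branch arc lengths in micrometres.
#' @export
axon_total_length <- function(trace) {
  stopifnot(inherits(trace, "axon_trace"))
  sum(vapply(trace$branches, polyline_length, numeric(1)))
}

#' Read an axon trace from an SWC file
#'
#' Parses the standard SWC neuromorphology format (whitespace-delimited
#' lines `id type x y z radius parent`, `#` comments, parent -1 for the
#' root) and splits the node tree into maximal unbranched branches at the
#' root, bifurcations and leaves. Coordinates are interpreted as
#' micrometres; the type and radius columns are ignored. A child branch's
#' polyline starts at the bifurcation node of its parent so geometry is
#' continuous across branch points.
#'
#' @param path Path to an SWC file.
#' @param axon_id Identifier for the resulting trace; defaults to the file
#'   name without extension.
#' @param subtype,region Labels attached to the trace (SWC carries neither).
#' @return An [axon_trace()].
#' @seealso [write_swc()] for the inverse operation.
#' @export
read_swc <- function(path, axon_id = NULL, subtype = "PV", region = "other") {
  if (!file.exists(path)) stop_myelo("file not found: %s", "myelo_io_error", path)
  if (is.null(axon_id)) axon_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L) {
    stop_myelo("%s: SWC has fewer than 2 nodes", "myelo_degenerate_error", path)
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n <- length(fields)
  rec <- matrix(NA_real_, nrow = n, ncol = 7L)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != 7L) {
      stop_myelo("%s: line %d: expected 7 fields, got %d", "myelo_parse_error",
                 path, idx[i], length(f))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) {
      stop_myelo("%s: line %d: non-numeric field", "myelo_parse_error", path, idx[i])
    }
    rec[i, ] <- v
  }
  id <- as.integer(rec[, 1]); parent <- as.integer(rec[, 7])
  xyz <- rec[, 3:5, drop = FALSE]
  if (anyDuplicated(id)) stop_myelo("%s: duplicate node ids", "myelo_structure_error", path)
  pos <- match(parent, id)
  orphan <- which(parent != -1L & is.na(pos))
  if (length(orphan) > 0L) {
    stop_myelo("%s: line %d: parent id %d not defined", "myelo_structure_error",
               path, idx[orphan[1]], parent[orphan[1]])
  }
  roots <- which(parent == -1L)
  if (length(roots) != 1L) {
    stop_myelo("%s: expected exactly one root (parent -1), found %d",
               "myelo_structure_error", path, length(roots))
  }
  n_children <- tabulate(pos[!is.na(pos)], nbins = n)
  root <- roots[1]
  # junction nodes start branches: the root and every bifurcation
  is_junction <- n_children >= 2L
  is_junction[root] <- TRUE
  children <- split(seq_len(n), factor(pos, levels = seq_len(n)))
  # every child of a junction node starts a chain; walk chains to the next
  # junction or leaf in breadth-first order so parents precede children
  branches <- list(); br_parent <- character(); end_node <- integer()
  queue <- children[[root]][order(id[children[[root]]])]
  bnum <- 0L
  while (length(queue) > 0L) {
    s <- queue[1L]; queue <- queue[-1L]
    chain <- c(pos[s], s)  # include the junction node for continuous geometry
    cur <- s
    while (n_children[cur] == 1L) {
      cur <- children[[cur]]
      chain <- c(chain, cur)
    }
    bnum <- bnum + 1L
    bid <- paste0("b", bnum)
    branches[[bid]] <- polyline3d(xyz[chain, , drop = FALSE])
    end_node[[bid]] <- cur
    jn <- pos[s]
    pb <- names(end_node)[end_node == jn]
    br_parent[[bid]] <- if (jn == root) NA_character_ else pb[1]
    if (n_children[cur] >= 2L) {
      queue <- c(queue, children[[cur]][order(id[children[[cur]]])])
    }
  }
  axon_trace(axon_id, subtype, region, branches, parent = br_parent)
}

#' Write an axon trace to an SWC file
#'
#' Serializes an [axon_trace()] back to SWC. Shared junction points are
#' emitted once; node ids are assigned in branch order. Radius is written
#' as 0.5 and type as 2 (axon) since neither is modelled.
#'
#' @param trace An `axon_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  stopifnot(inherits(trace, "axon_trace"))
  lines <- character()
  next_id <- 1L
  # node id of the last point of each written branch
  end_id <- stats::setNames(integer(0), character(0))
  root_id <- NA_integer_
  emit <- function(p, parent_id) {
    line <- sprintf("%d 2 %.17g %.17g %.17g 0.5 %d", next_id, p[1], p[2], p[3], parent_id)
    lines[[length(lines) + 1L]] <<- line
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  for (bid in names(trace$branches)) {
    pts <- trace$branches[[bid]]$points
    par <- trace$parent[[bid]]
    if (is.na(par)) {
      if (is.na(root_id)) {
        root_id <- emit(pts[1L, ], -1L)
      }
      prev <- root_id
    } else {
      if (!par %in% names(end_id)) {
        stop_myelo("branch %s written before its parent %s", "myelo_structure_error", bid, par)
      }
      prev <- end_id[[par]]
    }
    for (i in 2:nrow(pts)) prev <- emit(pts[i, ], prev)
    end_id[[bid]] <- prev
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Smooth a polyline with a centred moving average
#'
#' Coordinates are replaced by the mean over a centred window; near the
#' ends the window shrinks symmetrically so the first and last points are
#' preserved exactly. This is a contraction on jagged paths: each smoothed
#' segment is a convex combination of raw segments, so total arc length
#' never increases, and collinear traces are left geometrically unchanged.
#' `window = 1` is the identity.
#'
#' @param poly A [polyline3d()].
#' @param window Odd positive integer; number of points in the averaging
#'   window. Default 3.
#' @return A new `polyline3d` with recomputed arc length.
#' @export
smooth_trace <- function(poly, window = 3L) {
  stopifnot(inherits(poly, "polyline3d"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_myelo("smoothing window must be a positive odd integer", "myelo_argument_error")
  }
  if (window == 1L) return(poly)
  pts <- poly$points
  n <- nrow(pts)
  h <- (window - 1L) %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)  # symmetric shrink keeps endpoints fixed
    if (hi > 0L) out[i, ] <- colMeans(pts[(i - hi):(i + hi), , drop = FALSE])
  }
  polyline3d(out)
}

#' Smooth every branch of an axon trace
#'
#' Applies [smooth_trace()] identically to each branch, as done before any
#' length computation to reduce artifacts of jagged manual traces.
#'
#' @param trace An [axon_trace()].
#' @param window Odd positive integer window; default 3.
#' @return A new `axon_trace` with smoothed branches.
#' @export
smooth_axon <- function(trace, window = 3L) {
  stopifnot(inherits(trace, "axon_trace"))
  branches <- lapply(trace$branches, smooth_trace, window = window)
  axon_trace(trace$axon_id, trace$subtype, trace$region, branches, trace$parent)
}

#' Read myelin internode annotations
#'
#' Annotations are arc-length intervals `[s_start, s_end)` of myelin on a
#' named branch of a named axon, in a TSV with header
#' `axon_id  branch_id  s_start_um  s_end_um`.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `axon_id`, `branch_id`, `s_start_um`,
#'   `s_end_um`.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("axon_id", "branch_id", "s_start_um", "s_end_um"))
  df$axon_id <- as.character(df$axon_id)
  df$branch_id <- as.character(df$branch_id)
  df$s_start_um <- as.numeric(df$s_start_um)
  df$s_end_um <- as.numeric(df$s_end_um)
  bad <- which(!is.finite(df$s_start_um) | !is.finite(df$s_end_um) |
                 df$s_start_um < 0 | df$s_start_um >= df$s_end_um)
  if (length(bad) > 0L) {
    stop_myelo("%s: invalid interval on row %d (need 0 <= s_start < s_end)",
               "myelo_annotation_error", path, bad[1])
  }
  df
}

# Merge annotations on one branch: sort by s_start; overlaps up to
# `tol` um (rounding at shared node boundaries) are merged, larger
# overlaps are inconsistent input and raise. Returns sorted,
# non-overlapping intervals as a data frame (s_start_um, s_end_um).
merge_branch_annotations <- function(s_start, s_end, tol = 0.5) {
  o <- order(s_start, s_end)
  s_start <- s_start[o]; s_end <- s_end[o]
  ms <- s_start[1]; me <- s_end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(s_start)[-1]) {
    overlap <- me - s_start[i]
    if (overlap > tol) {
      stop_myelo("annotations overlap by %.3f um (> %.3f um tolerance)",
                 "myelo_annotation_error", overlap, tol)
    }
    if (overlap > 0) {
      me <- max(me, s_end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s_start[i]; me <- s_end[i]
    }
  }
  data.frame(s_start_um = c(out_s, ms), s_end_um = c(out_e, me))
}

#' Length of an annotated internode interval
#'
#' @param s_start_um,s_end_um Interval bounds in micrometres (vectorized).
#' @return `s_end_um - s_start_um`.
#' @export
arclength_interval_length <- function(s_start_um, s_end_um) {
  if (any(s_end_um <= s_start_um)) {
    stop_myelo("interval must satisfy s_start < s_end", "myelo_annotation_error")
  }
  s_end_um - s_start_um
}

#' Read a longitudinal PLM table
#'
#' TSV with header `axon_id subtype plm_baseline plm_recovery status`.
#' Status is one of `present`, `lost`, `excluded_always_unmyelinated`;
#' the last applies exactly when both PLM values are 0 (such axons are
#' dropped from linear models, not from proportion summaries). Lost axons
#' may carry `NA` recovery.
#'
#' @param path Path to the TSV.
#' @return A validated data frame.
#' @export
read_longitudinal <- function(path) {
  df <- read_tsv_checked(path, c("axon_id", "subtype", "plm_baseline",
                                 "plm_recovery", "status"))
  validate_longitudinal(df)
}

#' @rdname read_longitudinal
#' @param records A data frame shaped like the longitudinal TSV.
#' @export
validate_longitudinal <- function(records) {
  check_subtype(records$subtype)
  ok_status <- c("present", "lost", "excluded_always_unmyelinated")
  bad <- setdiff(unique(records$status), ok_status)
  if (length(bad) > 0L) {
    stop_myelo("unknown status value(s): %s", "myelo_record_error",
               paste(bad, collapse = ", "))
  }
  b <- records$plm_baseline; r <- records$plm_recovery
  live <- records$status != "lost"
  if (any(b < 0 | b > 99, na.rm = TRUE) ||
      any((r < 0 | r > 99) & live, na.rm = TRUE)) {
    stop_myelo("PLM values must lie in [0, 99] after the cap rule",
               "myelo_record_error")
  }
  both_zero <- live & !is.na(r) & b == 0 & r == 0
  flagged <- records$status == "excluded_always_unmyelinated"
  if (any(both_zero != flagged & live)) {
    stop_myelo(paste0("status 'excluded_always_unmyelinated' must be used ",
                      "exactly for records with baseline and recovery PLM both 0"),
               "myelo_record_error")
  }
  records
}

#' Read an ROI sheath-count table
#'
#' TSV with header `roi_id timepoint n_pv n_other`; `timepoint` is
#' `baseline` or `recovery`; counts are non-negative integers.
#'
#' @param path Path to the TSV.
#' @return A validated data frame.
#' @export
read_roi_sheaths <- function(path) {
  df <- read_tsv_checked(path, c("roi_id", "timepoint", "n_pv", "n_other"))
  bad <- setdiff(unique(df$timepoint), c("baseline", "recovery"))
  if (length(bad) > 0L) {
    stop_myelo("unknown timepoint(s): %s", "myelo_record_error",
               paste(bad, collapse = ", "))
  }
  if (any(df$n_pv < 0 | df$n_other < 0)) {
    stop_myelo("sheath counts must be non-negative", "myelo_record_error")
  }
  df
}
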