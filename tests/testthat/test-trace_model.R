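test_that("read_swc parses an unbranched trace with correct arc length", {
  tr <- read_swc(swc_unbranched(), axon_id = "a1", subtype = "PV")
  expect_s3_class(tr, "axon_trace")
  expect_length(tr$branches, 1L)
  expect_equal(tr$total_length, 20)
  expect_equal(unname(tr$parent), NA_character_)
})

test_that("read_swc splits at a bifurcation and records connectivity", {
  tr <- read_swc(swc_bifurcated(), axon_id = "a1")
  expect_length(tr$branches, 3L)
  # root chain is 20 um; each child is 10 um, starting at the branch point
  lens <- sort(vapply(tr$branches, polyline_length, numeric(1)))
  expect_equal(unname(lens), c(10, 10, 20))
  root_branch <- names(tr$parent)[is.na(tr$parent)]
  expect_length(root_branch, 1L)
  expect_true(all(tr$parent[setdiff(names(tr$parent), root_branch)] == root_branch))
  # children share their first point with the parent's last point
  junction <- tr$branches[[root_branch]]$points[3L, ]
  for (b in setdiff(names(tr$branches), root_branch)) {
    expect_equal(unname(tr$branches[[b]]$points[1L, ]), unname(junction))
  }
  expect_equal(tr$total_length, 40)
})

test_that("read_swc rejects malformed and structurally invalid input", {
  expect_error(read_swc(write_swc_lines(c("1 2 0 0 0 0.5 -1",
                                          "2 2 10 0 0 0.5"))),
               class = "myelo_parse_error")
  expect_error(read_swc(write_swc_lines(c("1 2 0 0 0 0.5 -1",
                                          "2 2 x 0 0 0.5 1"))),
               class = "myelo_parse_error")
  expect_error(read_swc(write_swc_lines(c("1 2 0 0 0 0.5 -1",
                                          "2 2 10 0 0 0.5 7"))),
               class = "myelo_structure_error")
  expect_error(read_swc(write_swc_lines("1 2 0 0 0 0.5 -1")),
               class = "myelo_degenerate_error")
})

test_that("write_swc / read_swc round-trips coordinates and topology", {
  for (fixture in list(swc_unbranched(), swc_bifurcated())) {
    tr <- read_swc(fixture, axon_id = "rt")
    out <- tempfile(fileext = ".swc")
    write_swc(tr, out)
    tr2 <- read_swc(out, axon_id = "rt")
    expect_equal(length(tr$branches), length(tr2$branches))
    expect_equal(tr$total_length, tr2$total_length)
    for (b in names(tr$branches)) {
      expect_equal(tr2$branches[[b]]$points, tr$branches[[b]]$points)
    }
    expect_equal(tr2$parent, tr$parent)
  }
})

test_that("smoothing is identity at window 1 and contracts jagged traces", {
  zig <- polyline3d(cbind(0:4, c(0, 1, 0, 1, 0), 0))
  expect_identical(smooth_trace(zig, 1L), zig)
  sm <- smooth_trace(zig, 3L)
  # endpoints preserved exactly
  expect_equal(sm$points[1, ], zig$points[1, ])
  expect_equal(sm$points[5, ], zig$points[5, ])
  expect_lt(polyline_length(sm), polyline_length(zig))
  # straight line: geometry (hence length) unchanged at any window
  straight <- polyline3d(cbind(seq(0, 50, by = 5), 0, 0))
  for (w in c(3L, 5L, 7L)) {
    expect_equal(polyline_length(smooth_trace(straight, w)), 50)
  }
  expect_error(smooth_trace(zig, 4L), class = "myelo_argument_error")
})

test_that("moving-average smoothing never increases length", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pts <- cbind(cumsum(runif(n, 0.1, 2)), rnorm(n), rnorm(n))
    poly <- polyline3d(pts)
    for (w in c(3L, 5L)) {
      expect_lte(polyline_length(smooth_trace(poly, w)),
                 polyline_length(poly) + 1e-12)
    }
  }
})

test_that("branch lengths are consistent with the cumulative arc length", {
  tr <- read_swc(swc_bifurcated())
  total <- sum(vapply(tr$branches, polyline_length, numeric(1)))
  expect_equal(tr$total_length, total, tolerance = 1e-12)
  p <- tr$branches[[1]]
  expect_equal(p$arclength[1], 0)
  expect_true(all(diff(p$arclength) >= 0))
})

test_that("interval lengths and annotation validation behave per contract", {
  expect_equal(arclength_interval_length(10, 60), 50)
  expect_equal(arclength_interval_length(c(0, 10), c(10, 20)), c(10, 10))
  expect_error(arclength_interval_length(10, 10), class = "myelo_annotation_error")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("axon_id\tbranch_id\ts_start_um\ts_end_um",
               "a1\tb1\t0\t10", "a1\tb1\t10\t20"), f)
  df <- read_annotations(f)
  expect_equal(nrow(df), 2L)
  writeLines(c("axon_id\tbranch_id\ts_start_um\ts_end_um",
               "a1\tb1\t15\t10"), f)
  expect_error(read_annotations(f), class = "myelo_annotation_error")
})

test_that("annotations overlapping within tolerance merge; larger overlaps fail", {
  merged <- myelotrace:::merge_branch_annotations(c(0, 9.7), c(10, 20), tol = 0.5)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$s_start_um, 0)
  expect_equal(merged$s_end_um, 20)
  expect_error(myelotrace:::merge_branch_annotations(c(0, 9), c(10, 20), tol = 0.5),
               class = "myelo_annotation_error")
  # abutting intervals stay separate
  two <- myelotrace:::merge_branch_annotations(c(0, 10), c(10, 20))
  expect_equal(nrow(two), 2L)
})

test_that("longitudinal validation enforces the always-unmyelinated status rule", {
  good <- data.frame(axon_id = c("a", "b"), subtype = "PV",
                     plm_baseline = c(0, 50), plm_recovery = c(0, 60),
                     status = c("excluded_always_unmyelinated", "present"))
  expect_silent(validate_longitudinal(good))
  bad <- good
  bad$status <- c("present", "present")
  expect_error(validate_longitudinal(bad), class = "myelo_record_error")
  over <- good
  over$plm_recovery[2] <- 100
  expect_error(validate_longitudinal(over), class = "myelo_record_error")
})

test_that("unknown subtype and region labels are rejected", {
  expect_error(axon_trace("a", "FOO", "SS",
                          list(b1 = polyline3d(cbind(c(0, 1), 0, 0)))),
               class = "myelo_subtype_error")
  expect_error(axon_trace("a", "PV", "nowhere",
                          list(b1 = polyline3d(cbind(c(0, 1), 0, 0)))),
               class = "myelo_region_error")
})
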