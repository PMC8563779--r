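# Relative-angle corner detection, GA placement, segment matrix assembly.

test_that("relative angle matches hand-computable cases and clamps safely", {
  tp <- structure(list(id = "t", points = rbind(c(0, 0), c(1, 0), c(2, 0)),
                       closed = FALSE, piece_length = 1, dimension = 2L),
                  class = "target_profile")
  expect_equal(relative_angle(tp, 2, 1), 0)
  tp$points <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(relative_angle(tp, 2, 1), 90)
  expect_error(relative_angle(tp, 1, 1), "out of range")
})

test_that("relative angle on a regular n-gon equals the exterior angle", {
  for (n in c(5L, 8L, 12L)) {
    th <- seq(0, 2 * pi, length.out = n + 1L)
    tp <- structure(list(id = "ngon", points = cbind(cos(th), sin(th)),
                         closed = TRUE, piece_length = 1, dimension = 2L),
                    class = "target_profile")
    for (i in c(1L, 3L, n))
      expect_equal(relative_angle(tp, i, 1), 360 / n, tolerance = 1e-9)
  }
})

test_that("relative angle is invariant to rigid motion and uniform scaling", {
  set.seed(21)
  pts <- cbind(cumsum(runif(30, 0.5, 1)), cumsum(rnorm(30, 0, 0.4)))
  tp <- structure(list(id = "w", points = pts, closed = FALSE,
                       piece_length = 1, dimension = 2L),
                  class = "target_profile")
  b0 <- relative_angle(tp, 5:25, 3)
  tp2 <- tp
  tp2$points <- random_rigid(pts * 3.7)
  b1 <- relative_angle(tp2, 5:25, 3)
  expect_lt(max(abs(b0 - b1)), 1e-8)
})

test_that("apex detection finds square corners and nothing on a circle", {
  sq <- square_target(10)
  expect_equal(detect_apices(sq, 1, 45), c(1L, 11L, 21L, 31L))
  circ <- resample_to_target(circle_design(10), 0.5)
  expect_length(detect_apices(circ, 1, 90), 0L)
  # every apex clears the threshold and no two share a run
  ap <- detect_apices(sq, 2, 30)
  expect_true(all(relative_angle(sq, ap, 2) >= 30))
  expect_equal(length(ap), 4L)
})

test_that("burred star: large intervals keep only the true lobe tips", {
  gen <- generate_leaflike(p = 1, lobes = 5, burr_amp = 0.03, burr_freq = 60,
                           seed = 4)
  tp <- resample_to_target(gen$profiles[[1]], 2)
  apices <- detect_apices(tp, 30, 60)
  expect_length(apices, 5L)
  # oracle: each apex maps to its nearest true tip angle, all tips hit
  truth <- attr(gen$profiles[[1]], "lobe_angles")
  th <- atan2(tp$points[apices, 2], tp$points[apices, 1]) %% (2 * pi)
  nearest <- vapply(th, function(a) {
    d <- abs(a - truth); which.min(pmin(d, 2 * pi - d))
  }, integer(1))
  expect_setequal(nearest, 1:5)
  d <- vapply(seq_along(th), function(i) {
    dd <- abs(th[i] - truth[nearest[i]]); min(dd, 2 * pi - dd)
  }, numeric(1))
  expect_lt(max(d), 2 * pi / 60)   # within one burr wavelength
})

test_that("apex count sweep stabilizes at the lobe count for large k", {
  sq <- square_target(10)
  expect_equal(apex_count_sweep(sq, 1:5, 45), rep(4L, 5L))
  circ <- resample_to_target(circle_design(10), 0.5)
  expect_equal(apex_count_sweep(circ, c(1, 5, 10), 90), rep(0L, 3L))
  gen <- generate_leaflike(p = 1, lobes = 5, burr_amp = 0.03, burr_freq = 60,
                           seed = 4)
  tp <- resample_to_target(gen$profiles[[1]], 2)
  expect_equal(apex_count_sweep(tp, c(15, 25, 35, 45), 60), rep(5L, 4L))
})

test_that("exact-divisibility placements reach fitness zero", {
  tp <- straight_target(12)
  r <- place_supplementary_points(tp, NULL, 3, seed = 1)
  expect_equal(r$boundaries, c(1L, 5L, 9L, 13L))
  expect_equal(r$fitness, 0)
  r2 <- place_supplementary_points(tp, c(5L, 9L), 3, seed = 1)
  expect_equal(r2$boundaries, c(1L, 5L, 9L, 13L))
  expect_true(all(r2$primary))
  expect_equal(r2$fitness, 0)
})

test_that("GA placement matches exhaustive search on small instances", {
  cases <- list(list(npieces = 10L, primary = 6L, q = 4L),
                list(npieces = 17L, primary = c(4L, 9L), q = 5L),
                list(npieces = 23L, primary = 7L, q = 6L))
  for (cs in cases) {
    tp <- straight_target(cs$npieces)
    got <- place_supplementary_points(tp, cs$primary, cs$q, seed = 2)
    want <- exhaustive_placement(cs$npieces, cs$primary, cs$q)
    expect_equal(got$fitness, want, tolerance = 1e-12)
    expect_true(all(cs$primary %in% got$boundaries))
    expect_equal(length(got$boundaries), cs$q + 1L)
    expect_true(all(diff(got$boundaries) >= 1L))
  }
})

test_that("unconstrained GA placement attains the analytic lower bound", {
  for (cs in list(c(100L, 7L), c(57L, 5L), c(40L, 8L))) {
    tp <- straight_target(cs[1])
    got <- place_supplementary_points(tp, NULL, cs[2], seed = 3)
    expect_equal(got$fitness, placement_fitness_bound(cs[1], cs[2]),
                 tolerance = 1e-12)
  }
})

test_that("GA never loses to the even-spacing heuristic and is deterministic", {
  gen <- generate_leaflike(p = 1, lobes = 5, burr_amp = 0.03, seed = 4)
  tp <- resample_to_target(gen$profiles[[1]], 2)
  apices <- detect_apices(tp, 30, 60)
  a <- place_supplementary_points(tp, apices, 12, seed = 9)
  b <- place_supplementary_points(tp, apices, 12, seed = 9)
  expect_identical(a$boundaries, b$boundaries)
  heur <- chainmorph:::.even_spacing_boundaries(
    sort(unique(c(1L, apices, nrow(tp$points)))), 12L)
  fh <- chainmorph:::.placement_fitness(heur, nrow(tp$points) - 1L, 12L)
  expect_lte(a$fitness, fh)
})

test_that("infeasible portion counts are rejected", {
  tp <- straight_target(5)
  expect_error(place_supplementary_points(tp, NULL, 9, seed = 1),
               "infeasible")
  expect_error(place_supplementary_points(tp, c(2L, 3L, 4L), 2, seed = 1),
               "sub-profiles")
})

test_that("segment matrix entries are boundary differences with exact row sums", {
  # worked-example bookkeeping: cumulative sums invert to the printed row
  b <- c(1L, 208L, 298L, 805L, 935L, 1033L, 1132L)
  sp <- segmentation_points(b, id = "j1")
  sp2 <- segmentation_points(c(1L, 208L, 323L, 536L, 666L, 793L, 1002L),
                             id = "j2")
  sm <- build_segment_matrix(list(sp, sp2), c("M", "C", "G", "M", "C", "G"))
  expect_equal(unname(sm$m[1, ]), c(207L, 90L, 507L, 130L, 98L, 99L))
  expect_equal(unname(rowSums(sm$m)), c(1131L, 1001L))
  expect_equal(unname(sm$m[, 1]), c(207L, 207L))

  single <- build_segment_matrix(list(segmentation_points(c(1L, 42L))), "G")
  expect_equal(unname(single$m[1, 1]), 41L)
})

test_that("unequal M columns are equalized by borrowing from resizable columns", {
  sp1 <- segmentation_points(c(1L, 13L, 50L, 62L), c(TRUE, TRUE, TRUE, TRUE))
  sp2 <- segmentation_points(c(1L, 13L, 48L, 61L), c(TRUE, TRUE, TRUE, TRUE),
                             id = "p2")
  sm <- build_segment_matrix(list(sp1, sp2), c("M", "G", "M"))
  expect_equal(length(unique(sm$m[, 1])), 1L)
  expect_equal(length(unique(sm$m[, 3])), 1L)
  expect_equal(unname(rowSums(sm$m)), c(61L, 60L))
  expect_true(all(sm$m >= 1L))
})
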