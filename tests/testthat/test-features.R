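# Feature extraction: orientation differences, length ratios, direction
# vectors, and variable counting.

# Small fitted 2D chain reused across tests.
make_chain_2d <- function(p = 6, seed = 51, joint_mean = c(40, -35),
                          groups = "A") {
  gen <- generate_chain_profiles(p = p, types = c("M", "G", "M"), m_m = 12,
                                 g_mean = 40, g_sd = 5,
                                 joint_mean = joint_mean, joint_sd = 1,
                                 groups = groups, noise_sd = 0, seed = seed)
  targets <- lapply(gen$profiles, resample_to_target, piece_length = 1)
  segs <- lapply(seq_along(targets), function(j)
    segmentation_points(c(1L, 1L + cumsum(gen$truth$sm[j, ])),
                        id = targets[[j]]$id))
  sm <- build_segment_matrix(segs, gen$truth$types)
  list(chain = build_chain(targets, segment_matrix = sm), gen = gen)
}

test_that("orientation differences recover the generator's joint angles", {
  mk <- make_chain_2d()
  ch <- mk$chain
  q <- ncol(ch$EM)
  expect_equal(q - 1L, 2L)
  for (j in seq_len(nrow(ch$EM))) {
    expect_equal(orientation_difference_2d(ch, j, 1),
                 mk$gen$truth$joints[j, 1], tolerance = 1.5)
    expect_equal(orientation_difference_2d(ch, j, 2),
                 mk$gen$truth$joints[j, 2], tolerance = 1.5)
  }
  expect_error(orientation_difference_2d(ch, 1, 3), "1..q-1")
})

test_that("collinear and perpendicular segments give 0 and +90 degrees", {
  fake <- list(dimension = 2L,
               EM = matrix(0, 1, 2),
               aligned = matrix(list(
                 list(points = cbind(0:3, rep(0, 4))),
                 list(points = cbind(rep(3, 4), 0:3))), 1, 2))
  class(fake) <- "chain_fit"
  expect_equal(orientation_difference_2d(fake, 1, 1), 90)
  fake$aligned[[1, 2]] <- list(points = cbind(3:6, rep(0, 4)))
  expect_equal(orientation_difference_2d(fake, 1, 1), 0)
})

test_that("length ratios divide by the column maximum and reject M columns", {
  sm <- structure(list(m = rbind(c(10L, 90L), c(10L, 115L)),
                       types = c("M", "C"), ids = c("a", "b"),
                       subprofile = c(1L, 1L)), class = "segment_matrix")
  expect_equal(length_ratio(sm, 2), c(90 / 115, 1), ignore_attr = TRUE)
  expect_error(length_ratio(sm, 1), "is M")
  sm$m[, 2] <- c(50L, 50L)
  expect_equal(length_ratio(sm, 2), c(1, 1), ignore_attr = TRUE)
})

test_that("3D direction vectors are unit, equivariant, and guarded", {
  sut <- generate_suturelike(p = 4, groups = "A", group_rot = 0,
                             noise_sd = 0, seed = 52)
  targets <- lapply(sut$profiles, resample_to_target, piece_length = 2)
  segs <- lapply(targets, function(tp)
    place_supplementary_points(tp, NULL, 2, seed = 1))
  sm <- build_segment_matrix(segs, c("G", "G"))
  ch <- build_chain(targets, segment_matrix = sm)
  u <- segment_direction_3d(ch, 1, 1)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-9)
  # equivariance: rotating all profiles rotates u accordingly
  a <- 0.8
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  targets_r <- lapply(targets, function(tp) {
    tp$points <- tp$points %*% rz
    tp
  })
  ch_r <- build_chain(targets_r, segment_matrix = sm)
  for (e in 1:2) {
    u0 <- segment_direction_3d(ch, 2, e)
    u1 <- segment_direction_3d(ch_r, 2, e)
    expect_equal(as.vector(u0 %*% rz), u1, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("feature tables assemble the selected blocks with stable names", {
  mk <- make_chain_2d(groups = c("A", "B"))
  f <- assemble_features(mk$chain, blocks = c("sigma", "lengths", "arclen"))
  expect_named(f, c("id", "group", "sigma_1", "sigma_2", "g_2", "arclen"))
  expect_true(all(f$g_2 > 0 & f$g_2 <= 1))
  expect_equal(max(f$g_2), 1)
  fa <- assemble_features(mk$chain, blocks = "sigma", sigma_abs = TRUE)
  expect_true(all(fa$sigma_1 >= 0))
  expect_error(assemble_features(mk$chain, blocks = "u"), "3D")
  expect_error(assemble_features(mk$chain, blocks = "nope"), "unknown")
})

test_that("variable counts reproduce the published schemes", {
  # 2D mandible scheme: 20 segments (12 M, 2 C, 6 G) -> 28 fitted variables
  mandible <- unlist(strsplit(
    "M G M M G M M G M M C G M M C G M M G M", " "))
  expect_length(mandible, 20L)
  expect_equal(count_chain_parameters(mandible, 2L), 28L)
  # and 19 orientation-difference variables from 20 segments
  expect_equal(length(mandible) - 1L, 19L)

  # 3D suture schemes
  expect_equal(count_chain_parameters(
    c("M", "G", "M", "H", "M", "G"), 3L), 21L)      # sagittal
  expect_equal(count_chain_parameters(
    c("M", "G", "H", "H", "G", "M"), 3L), 22L)      # coronal
  expect_equal(count_chain_parameters(
    c("G", "H", "H", "G"), 3L), 16L)                # lambdoid

  # leaf scheme: 35 G segments -> 34 sigma + apex/burr counts + arc length
  expect_equal((35L - 1L) + 3L, 37L)
})

test_that("lambdoid-style analysis blocks give 12 + 3 = 15 variables", {
  sut <- generate_suturelike(p = 6, groups = c("A", "B"), noise_sd = 0.005,
                             seed = 53)
  targets <- lapply(sut$profiles, resample_to_target, piece_length = 2)
  segs <- lapply(targets, function(tp)
    place_supplementary_points(tp, NULL, 4, seed = 1))
  sm <- build_segment_matrix(segs, c("G", "H", "H", "G"))
  ch <- build_chain(targets, segment_matrix = sm)
  f <- assemble_features(ch, blocks = c("u", "anchors"))
  u_cols <- grep("^u_", names(f))
  anchor_cols <- grep("^anchor_P2_", names(f))
  expect_length(u_cols, 12L)
  expect_length(anchor_cols, 3L)
})

test_that("sigma vanishes along a straight chain and ratios ignore additions", {
  gen <- generate_chain_profiles(p = 3, types = c("G", "G"), g_mean = c(30, 40),
                                 g_sd = 3, joint_mean = 0, joint_sd = 0,
                                 noise_sd = 0, seed = 54)
  targets <- lapply(gen$profiles, resample_to_target, piece_length = 1)
  segs <- lapply(seq_along(targets), function(j)
    segmentation_points(c(1L, 1L + cumsum(gen$truth$sm[j, ])),
                        id = targets[[j]]$id))
  sm <- build_segment_matrix(segs, c("G", "G"))
  ch <- build_chain(targets, segment_matrix = sm)
  f <- assemble_features(ch, blocks = "sigma")
  expect_lt(max(abs(f$sigma_1)), 0.5)
  # g ratios unchanged by dropping a below-max profile
  r_full <- length_ratio(sm, 1)
  keep <- which(sm$m[, 1] != min(sm$m[, 1]))[1]
  drop_j <- which(sm$m[, 1] == min(sm$m[, 1]))[1]
  sm2 <- sm
  sm2$m <- sm$m[-drop_j, , drop = FALSE]
  r_sub <- length_ratio(sm2, 1)
  expect_equal(r_sub, r_full[-drop_j], ignore_attr = TRUE)
})
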