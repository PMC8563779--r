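# Synthetic profile families with known ground truth, emulating the three
# kinds of study data the chain method targets: chain-generated open 2D
# profiles, serrated closed leaf-like outlines, and smooth open 3D
# suture-like curves.

#' Generate 2D profiles from a known shape-changing chain
#'
#' Builds each profile by concatenating ground-truth segment polylines:
#' M-segments use a fixed arc template, C-segments a fixed curvature, and
#' G-segments a fixed unit template, with per-profile piece counts drawn
#' around group means and consecutive segments joined at group-specific
#' inter-segment angles. Isotropic Gaussian coordinate noise is added last.
#' The true segment matrix and joint angles are returned for recovery tests.
#'
#' @param p number of profiles.
#' @param types segment type vector (any of `M`, `C`, `G`).
#' @param m_m pieces in every M-segment.
#' @param g_mean mean piece count of each resizable segment; a vector (one
#'   per resizable segment), or a matrix with one row per group.
#' @param g_sd standard deviation of resizable piece counts.
#' @param joint_mean mean inter-segment angles in degrees (`q - 1` values),
#'   or a matrix with one row per group.
#' @param joint_sd per-profile angular noise in degrees.
#' @param groups character vector of group names, recycled over profiles
#'   round-robin.
#' @param noise_sd coordinate noise, in units of `piece_length`.
#' @param piece_length piece length of the generated polylines.
#' @param kappa_c curvature of C-segments (in 1/length units).
#' @param seed integer RNG seed; identical seeds reproduce coordinates
#'   exactly.
#' @return list with `profiles` (list of open [design_profile]s) and `truth`
#'   (`sm` true piece-count matrix, `joints` true per-profile joint angles,
#'   `types`, `piece_length`).
#' @export
generate_chain_profiles <- function(p = 20L,
                                    types = c("M", "G", "M"),
                                    m_m = 15L,
                                    g_mean = 50,
                                    g_sd = 5,
                                    joint_mean = NULL,
                                    joint_sd = 1,
                                    groups = "A",
                                    noise_sd = 0.05,
                                    piece_length = 1,
                                    kappa_c = 0.05,
                                    seed = 1L) {
  types <- toupper(types)
  if (!all(types %in% c("M", "C", "G")))
    stop("2D chain generator supports M, C and G segments")
  q <- length(types)
  ngrp <- length(groups)
  resizable <- which(types != "M")
  if (is.null(joint_mean)) joint_mean <- rep(45, q - 1L)
  jm <- if (is.matrix(joint_mean)) joint_mean
        else matrix(joint_mean, ngrp, max(q - 1L, 1L), byrow = TRUE)
  gm <- if (is.matrix(g_mean)) g_mean
        else matrix(g_mean, ngrp, length(resizable), byrow = TRUE)
  h <- piece_length
  # fixed ground-truth shapes shared by all profiles
  m_template <- generate_segment_points(
    .segment_model("C", h, kappa = 0.03 / h), m_m)
  g_unit <- {
    t <- seq(0, 1, length.out = 200L)
    raw <- cbind(t, 0.15 * sin(pi * t))     # gentle arch
    raw / sum(.rownorms(diff(raw)))
  }
  .with_seed(seed, {
    sm_true <- matrix(NA_integer_, p, q)
    joints_true <- matrix(NA_real_, p, max(q - 1L, 1L))
    profiles <- vector("list", p)
    for (j in seq_len(p)) {
      gidx <- ((j - 1L) %% ngrp) + 1L
      m_j <- integer(q)
      m_j[types == "M"] <- m_m
      m_j[resizable] <- pmax(4L, round(stats::rnorm(length(resizable),
                                                    gm[gidx, ], g_sd)))
      ang <- if (q > 1L) stats::rnorm(q - 1L, jm[gidx, seq_len(q - 1L)],
                                      joint_sd) else numeric(0)
      pts <- NULL
      heading <- 0
      for (e in seq_len(q)) {
        seg <- switch(types[[e]],
          M = m_template,
          C = generate_segment_points(.segment_model("C", h,
                                                     kappa = kappa_c), m_j[e]),
          G = generate_segment_points(.segment_model("G", h,
                                                     template = g_unit), m_j[e]))
        seg <- sweep(seg, 2, seg[1L, ])
        start_dir <- .dir2(seg[2L, ] - seg[1L, ])
        if (is.null(pts)) {
          rot <- .rot2(-start_dir)
          pts <- seg %*% t(rot)
          heading <- 0
        } else {
          n0 <- nrow(pts)
          end_dir <- .dir2(pts[n0, ] - pts[n0 - 1L, ])
          target <- end_dir + ang[e - 1L]
          rot <- .rot2(target - start_dir)
          seg <- seg %*% t(rot)
          seg <- sweep(seg, 2, pts[n0, ] - seg[1L, ], `+`)
          pts <- rbind(pts, seg[-1L, , drop = FALSE])
        }
      }
      pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd * h),
                          nrow(pts))
      sm_true[j, ] <- m_j
      if (q > 1L) joints_true[j, ] <- ang
      profiles[[j]] <- design_profile(pts, id = sprintf("chain_%02d", j),
                                      group = groups[gidx], closed = FALSE)
    }
    list(profiles = profiles,
         truth = list(sm = sm_true, joints = joints_true, types = types,
                      piece_length = h))
  })
}

#' Generate closed serrated leaf-like outlines
#'
#' Radial model around a base ellipse: low-frequency lobes give the global
#' apices and a high-frequency sinusoid adds burrs (serration). The true
#' lobe-tip polar angles are returned so detection can be checked against
#' ground truth.
#'
#' @param p number of outlines.
#' @param lobes number of global lobes (>= 3).
#' @param lobe_amp relative lobe amplitude.
#' @param tip_sharpness exponent (> 1) narrowing the lobe tips so that the
#'   tips, not the valleys between them, are the sharpest corners.
#' @param burr_amp relative burr amplitude (0 for a smooth outline).
#' @param burr_freq burrs per revolution.
#' @param radius base radius in length units.
#' @param ellipticity y/x axis ratio of the base ellipse.
#' @param n_dense dense sampling of the generator curve.
#' @param noise_sd radial noise relative to `radius`.
#' @param groups group labels, recycled.
#' @param seed integer RNG seed.
#' @return list with `profiles` (closed [design_profile]s) and `truth`
#'   (`lobe_angles` in radians, generator settings).
#' @export
generate_leaflike <- function(p = 10L, lobes = 5L, lobe_amp = 0.4,
                              tip_sharpness = 4,
                              burr_amp = 0.02, burr_freq = 60L,
                              radius = 100, ellipticity = 1,
                              n_dense = 4000L, noise_sd = 0,
                              groups = "leaf", seed = 1L) {
  if (lobes < 3L) stop("need at least 3 lobes")
  .with_seed(seed, {
    profiles <- vector("list", p)
    for (j in seq_len(p)) {
      phase <- stats::runif(1, 0, 2 * pi / lobes)
      th <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
      lobe <- ((1 + cos(lobes * (th - phase))) / 2)^tip_sharpness
      r <- radius * (1 + lobe_amp * lobe + burr_amp * sin(burr_freq * th))
      if (noise_sd > 0)
        r <- r + stats::rnorm(length(th), 0, noise_sd * radius)
      pts <- cbind(r * cos(th), ellipticity * r * sin(th))
      profiles[[j]] <- design_profile(pts, id = sprintf("leaf_%02d", j),
                                      group = groups[((j - 1L) %% length(groups)) + 1L],
                                      closed = TRUE)
      attr(profiles[[j]], "lobe_angles") <- (phase +
        2 * pi * (seq_len(lobes) - 1L) / lobes) %% (2 * pi)
    }
    list(profiles = profiles,
         truth = list(lobes = lobes,
                      lobe_angles = lapply(profiles, attr, "lobe_angles"),
                      burr_freq = burr_freq, burr_amp = burr_amp))
  })
}

#' Generate smooth open 3D suture-like curves with anchor points
#'
#' Each group shares a base 3D arc; groups differ by a rigid offset
#' (rotation about the vertical axis plus translation) and a length scaling,
#' with small per-specimen shape noise on top. The curve endpoints are
#' labelled as anchor landmarks (`P1`, `P2`), mimicking suture intersection
#' points.
#'
#' @param p number of curves.
#' @param groups group labels, recycled.
#' @param group_rot per-group rotation offsets in degrees about z.
#' @param group_shift per-group translations (matrix, one row of 3 per
#'   group, or a single numeric recycled on x).
#' @param group_scale per-group length scalings.
#' @param radius base arc radius.
#' @param n_dense dense sampling of the generator curve.
#' @param noise_sd coordinate noise relative to `radius`.
#' @param seed integer RNG seed.
#' @return list with `profiles` (open 3D [design_profile]s carrying an
#'   `anchors` field) and `truth` (the group offsets).
#' @export
generate_suturelike <- function(p = 12L, groups = c("A", "B"),
                                group_rot = NULL, group_shift = NULL,
                                group_scale = NULL, radius = 50,
                                n_dense = 600L, noise_sd = 0.01,
                                seed = 1L) {
  ngrp <- length(groups)
  if (is.null(group_rot)) group_rot <- seq(0, 15, length.out = ngrp)
  if (is.null(group_scale)) group_scale <- rep(1, ngrp)
  shift <- if (is.null(group_shift)) matrix(0, ngrp, 3L)
           else if (is.matrix(group_shift)) group_shift
           else cbind(group_shift, 0, 0)
  .with_seed(seed, {
    t <- seq(0, pi, length.out = n_dense)
    base <- cbind(radius * cos(t), radius * sin(t),
                  0.3 * radius * sin(2 * t))
    profiles <- vector("list", p)
    for (j in seq_len(p)) {
      gidx <- ((j - 1L) %% ngrp) + 1L
      a <- group_rot[gidx] * pi / 180
      rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      pts <- (base * group_scale[gidx]) %*% t(rz)
      pts <- sweep(pts, 2, shift[gidx, ], `+`)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd * radius),
                          nrow(pts))
      pr <- design_profile(pts, id = sprintf("suture_%02d", j),
                           group = groups[gidx], closed = FALSE)
      pr$anchors <- list(P1 = pts[1L, ], P2 = pts[nrow(pts), ])
      profiles[[j]] <- pr
    }
    list(profiles = profiles,
         truth = list(rot = group_rot, shift = shift, scale = group_scale))
  })
}
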