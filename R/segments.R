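# The four segment types of the shape-changing chain: fitting them to
# corresponding portions, generating their polylines, and rigid alignment.
#
# M: rigid, fixed shape and size (mean form of equal-piece portions)
# C: planar circular arc of constant curvature, variable length
# H: circular helix of constant curvature and torsion, variable length (3D)
# G: fixed shape, variable size (unit-arc-length template, rescaled)

#' Extract a portion of a target profile
#' @param profile a `target_profile`.
#' @param boundaries integer pair `c(k, k2)` of point indices, `k < k2`.
#' @return matrix of the points `k..k2` inclusive (`k2 - k` pieces).
#' @export
extract_portion <- function(profile, boundaries) {
  n <- nrow(profile$points)
  k <- boundaries[[1L]]; k2 <- boundaries[[2L]]
  if (k < 1L || k2 > n || k >= k2)
    stop("portion boundaries out of range: ", k, "..", k2, " on ", n, " points")
  profile$points[k:k2, , drop = FALSE]
}

#' @noRd
.segment_model <- function(type, piece_length, template = NULL,
                           kappa = NULL, tau = NULL) {
  structure(list(type = type, piece_length = piece_length,
                 template = template, kappa = kappa, tau = tau),
            class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  extra <- switch(x$type,
    M = sprintf("%d pieces", nrow(x$template) - 1L),
    C = sprintf("kappa = %.6g", x$kappa),
    H = sprintf("kappa = %.6g, tau = %.6g", x$kappa, x$tau),
    G = sprintf("unit template, %d points", nrow(x$template)))
  cat(sprintf("segment_model %s (%s; piece_length %.6g)\n",
              x$type, extra, x$piece_length))
  invisible(x)
}

#' Fit a rigid M-segment
#'
#' The M-segment is the rigid-motion-only generalized Procrustes mean of the
#' corresponding portions (which must all contain the same number of pieces),
#' re-resampled so its pieces equal the common piece length. It represents
#' the average form, shape *and* size, of a low-variation region.
#'
#' @param portions list of point matrices with identical dimensions.
#' @param piece_length common piece length.
#' @return a `segment_model` of type `"M"`.
#' @export
fit_m_segment <- function(portions, piece_length) {
  npts <- vapply(portions, nrow, integer(1))
  if (length(unique(npts)) != 1L)
    stop("M-segment portions must have equal piece counts, got: ",
         paste(npts, collapse = ", "))
  mean_shape <- if (length(portions) == 1L) {
    sweep(portions[[1L]], 2, colMeans(portions[[1L]]))
  } else {
    .gpa(portions, scale = FALSE)$mean
  }
  rs <- .equal_chord_resample(mean_shape, npts[[1L]] - 1L)
  .segment_model("M", piece_length, template = rs$points)
}

# Taubin algebraic circle fit; returns curvature (0 for collinear points).
#' @noRd
.taubin_curvature <- function(pts) {
  ctr <- colMeans(pts)
  x <- pts[, 1L] - ctr[1L]
  y <- pts[, 2L] - ctr[2L]
  z <- x^2 + y^2
  zm <- mean(z)
  if (zm < 1e-300) return(0)
  z0 <- (z - zm) / (2 * sqrt(zm))
  sv <- svd(cbind(z0, x, y))
  v <- sv$v[, 3L]
  a <- v[1L] / (2 * sqrt(zm))
  b <- v[2L]; cc <- v[3L]
  d <- -zm * a
  disc <- b^2 + cc^2 - 4 * a * d
  if (disc <= 0) return(0)
  2 * abs(a) / sqrt(disc)
}

#' Fit a constant-curvature C-segment (2D)
#'
#' Each portion's curvature is estimated by a total-least-squares (Taubin
#' algebraic) circle fit; the segment curvature is the unweighted mean over
#' portions. Collinear portions yield curvature 0 (a straight segment).
#'
#' @param portions list of 2D point matrices, each with at least 3 points.
#' @param piece_length common piece length.
#' @return a `segment_model` of type `"C"`.
#' @export
fit_c_segment <- function(portions, piece_length) {
  for (p in portions) {
    if (ncol(p) != 2L) stop("C-segments are planar; use fit_h_segment in 3D")
    if (nrow(p) < 3L) stop("curvature fit needs at least 3 points")
  }
  kappa <- mean(vapply(portions, .taubin_curvature, numeric(1)))
  .segment_model("C", piece_length, kappa = kappa)
}

# Menger curvature of the circumcircle through three points (2D or 3D).
#' @noRd
.menger <- function(a, b, c) {
  if (length(a) == 2L) { a <- c(a, 0); b <- c(b, 0); c <- c(c, 0) }
  u <- b - a; v <- c - a
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  area2 <- sqrt(sum(cr^2))              # twice the triangle area
  den <- sqrt(sum(u^2)) * sqrt(sum(v^2)) * sqrt(sum((c - b)^2))
  if (den < 1e-300) return(0)
  2 * area2 / den
}

# Discrete curvature/torsion of a 3D polyline via consecutive triples
# (circumradius) and the signed dihedral angle between osculating planes.
#' @noRd
.frenet_estimates <- function(pts) {
  n <- nrow(pts)
  kap <- vapply(seq_len(n - 2L), function(i)
    .menger(pts[i, ], pts[i + 1L, ], pts[i + 2L, ]), numeric(1))
  tau <- NULL
  if (n >= 4L) {
    tau <- vapply(seq_len(n - 3L), function(i) {
      e1 <- pts[i + 1L, ] - pts[i, ]
      e2 <- pts[i + 2L, ] - pts[i + 1L, ]
      e3 <- pts[i + 3L, ] - pts[i + 2L, ]
      n1 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
              e1[3L] * e2[1L] - e1[1L] * e2[3L],
              e1[1L] * e2[2L] - e1[2L] * e2[1L])
      n2 <- c(e2[2L] * e3[3L] - e2[3L] * e3[2L],
              e2[3L] * e3[1L] - e2[1L] * e3[3L],
              e2[1L] * e3[2L] - e2[2L] * e3[1L])
      n1n <- sqrt(sum(n1^2)); n2n <- sqrt(sum(n2^2))
      if (n1n < 1e-300 || n2n < 1e-300) return(0)
      phi <- .safe_acos(sum(n1 * n2) / (n1n * n2n))
      sgn <- sign(sum((n1 / n1n) * e3))   # plane turn sense along the curve
      sgn * phi / sqrt(sum(e2^2))
    }, numeric(1))
  }
  list(kappa = mean(kap), tau = if (is.null(tau)) 0 else mean(tau))
}

#' Fit a constant-curvature, constant-torsion H-segment (3D)
#'
#' Curvature is estimated at each interior point as the Menger circumradius
#' curvature of consecutive triples; torsion as the signed dihedral angle
#' between consecutive osculating planes divided by the middle chord length.
#' Per-portion estimates are averaged along the portion, and the segment
#' parameters are the unweighted means over portions. Estimates converge to
#' the true helix parameters at rate O(piece_length^2).
#'
#' @param portions list of 3D point matrices, each with at least 4 points.
#' @param piece_length common piece length.
#' @return a `segment_model` of type `"H"` with fields `kappa` and `tau`.
#' @export
fit_h_segment <- function(portions, piece_length) {
  for (p in portions) {
    if (ncol(p) != 3L) stop("H-segments are spatial; use fit_c_segment in 2D")
    if (nrow(p) < 4L) stop("torsion fit needs at least 4 points")
  }
  est <- lapply(portions, .frenet_estimates)
  .segment_model("H", piece_length,
                 kappa = mean(vapply(est, `[[`, numeric(1), "kappa")),
                 tau = mean(vapply(est, `[[`, numeric(1), "tau")))
}

#' Fit a scalable G-segment
#'
#' Each portion is rescaled to unit arc length and resampled to a common
#' point count (the largest portion's, so no exemplar loses detail); the
#' template is their rigid-motion-only Procrustes mean, stored at unit arc
#' length. G-segments capture regions that keep their shape while growing.
#'
#' @param portions list of point matrices (piece counts may differ).
#' @param piece_length common piece length.
#' @return a `segment_model` of type `"G"` holding the unit template.
#' @export
fit_g_segment <- function(portions, piece_length) {
  if (!length(portions)) stop("need at least one portion")
  npts <- max(vapply(portions, nrow, integer(1)))
  unitized <- lapply(portions, function(p) {
    total <- sum(.rownorms(diff(p)))
    if (total < 1e-12) stop("degenerate portion: zero arc length")
    .arc_resample(p / total, npts - 1L)
  })
  mean_shape <- if (length(unitized) == 1L) {
    sweep(unitized[[1L]], 2, colMeans(unitized[[1L]]))
  } else {
    .gpa(unitized, scale = FALSE)$mean
  }
  mean_shape <- mean_shape / sum(.rownorms(diff(mean_shape)))
  .segment_model("G", piece_length, template = mean_shape)
}

# Solve the helix parameter step whose chord equals `target`
# (chord(d) = sqrt(4 r^2 sin^2(d/2) + c^2 d^2)); bisection to 1e-10.
#' @noRd
.helix_step <- function(r, c, target) {
  chord <- function(d) sqrt(4 * r^2 * sin(d / 2)^2 + c^2 * d^2)
  lo <- target / sqrt(r^2 + c^2)   # chord <= arc => root is at least this
  lo <- lo * 0.5
  hi <- lo
  while (chord(hi) < target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (chord(mid) >= target) hi <- mid else lo <- mid
    if (hi - lo < 1e-10 * hi) break
  }
  (lo + hi) / 2
}

#' Generate the polyline of a segment model
#'
#' Produces `m + 1` points whose consecutive distances all equal the model's
#' piece length: M returns its rigid template (`m` must match); C samples a
#' planar arc of the fitted curvature at chord steps; H samples a circular
#' helix, solving the arc step so chords stay uniform; G rescales its unit
#' template to arc length `m * piece_length` and resamples.
#'
#' @param model a `segment_model`.
#' @param m number of pieces.
#' @return matrix of `m + 1` points.
#' @export
generate_segment_points <- function(model, m) {
  h <- model$piece_length
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  switch(model$type,
    M = {
      if (m != nrow(model$template) - 1L)
        stop("M-segment has ", nrow(model$template) - 1L,
             " pieces; requested ", m)
      model$template
    },
    C = {
      k <- model$kappa
      if (k <= 1e-12) {
        cbind(x = (0:m) * h, y = rep(0, m + 1L))
      } else {
        if (h * k / 2 > 1)
          stop("piece_length exceeds the arc's diameter")
        theta <- 2 * asin(h * k / 2)
        i <- 0:m
        cbind(x = sin(i * theta) / k, y = (1 - cos(i * theta)) / k)
      }
    },
    H = {
      k <- model$kappa; t <- model$tau
      if (k <= 1e-12) {
        cbind(x = (0:m) * h, y = rep(0, m + 1L), z = rep(0, m + 1L))
      } else {
        r <- k / (k^2 + t^2)
        cc <- t / (k^2 + t^2)
        d <- .helix_step(r, cc, h)
        i <- 0:m
        pts <- cbind(x = r * cos(i * d) - r, y = r * sin(i * d),
                     z = cc * i * d)
        pts
      }
    },
    G = {
      scaled <- model$template * (m * h)
      .equal_chord_resample(scaled, m)$points
    },
    stop("unknown segment type ", model$type))
}

#' Rigidly align a segment polyline to its profile portion
#'
#' Finds the rotation (determinant +1, no reflection, no scaling) and
#' translation minimizing the sum of squared point-to-point distances, and
#' reports the maximum pointwise distance after alignment — the segment's
#' matching error entry in the error matrix.
#'
#' @param segment_points matrix of segment points.
#' @param portion_points matrix of the corresponding portion, same size.
#' @return object of class `aligned_segment`: `points` (aligned segment),
#'   `rotation`, `translation`, `error` (max pointwise distance),
#'   `pointwise` (all pointwise distances).
#' @export
align_segment_to_portion <- function(segment_points, portion_points) {
  if (!identical(dim(segment_points), dim(portion_points)))
    stop("segment and portion must have identical point counts")
  cs <- colMeans(segment_points)
  cp <- colMeans(portion_points)
  xs <- sweep(segment_points, 2, cs)
  xp <- sweep(portion_points, 2, cp)
  r <- .kabsch(xs, xp)
  aligned <- sweep(xs %*% r, 2, cp, `+`)
  dimnames(aligned) <- dimnames(portion_points)
  pw <- .rownorms(aligned - portion_points)
  structure(list(points = aligned, rotation = r,
                 translation = cp - as.vector(cs %*% r),
                 error = max(pw), pointwise = pw),
            class = "aligned_segment")
}
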