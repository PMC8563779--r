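# Internal geometry helpers shared across modules.

#' @noRd
.rownorms <- function(m) sqrt(rowSums(m^2))

#' Cumulative arc length along a polyline (first entry 0).
#' @noRd
.cumarc <- function(pts) {
  d <- .rownorms(diff(pts))
  c(0, cumsum(d))
}

#' Optimal rotation (det = +1) aligning centred X onto centred Y in the
#' least-squares sense (Kabsch). Returns the d x d rotation matrix R such
#' that X %*% R approximates Y.
#' @noRd
.kabsch <- function(x, y) {
  m <- crossprod(x, y)
  sv <- svd(m)
  d <- ncol(x)
  s <- diag(c(rep(1, d - 1), sign(det(sv$u %*% t(sv$v)))), d)
  sv$u %*% s %*% t(sv$v)
}

#' Rigid (+ optional scaling) generalized Procrustes analysis.
#'
#' Iteratively aligns a list of same-cardinality configurations to their
#' evolving mean until the mean shape stabilizes. Reflections are never
#' allowed. With `scale = TRUE` every configuration is normalized to unit
#' centroid size after each rotation.
#' @noRd
.gpa <- function(configs, scale = FALSE, tol = 1e-11, max_iter = 200L) {
  stopifnot(length(configs) >= 1L)
  dims <- vapply(configs, ncol, integer(1))
  npts <- vapply(configs, nrow, integer(1))
  if (length(unique(dims)) != 1L || length(unique(npts)) != 1L)
    stop("all configurations must share point count and dimension")
  centred <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12)
      stop("degenerate configuration: all points coincident")
    if (scale) m / cs else m
  })
  if (length(centred) == 1L)
    return(list(aligned = centred, mean = centred[[1L]], iterations = 0L))
  mean_shape <- centred[[1L]]
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(centred, function(m) {
      r <- .kabsch(m, mean_shape)
      out <- m %*% r
      if (scale) out / sqrt(sum(out^2)) else out
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    if (scale) new_mean <- new_mean / sqrt(sum(new_mean^2))
    rss_trace <- c(rss_trace,
                   sum(vapply(aligned, function(a) sum((a - new_mean)^2),
                              numeric(1))))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    centred <- aligned
    if (delta < tol) break
  }
  list(aligned = centred, mean = mean_shape, iterations = it, rss = rss_trace)
}

# Rotate a GPA solution into a canonical pose (principal axes of the mean
# shape, flips resolved by the first point's coordinates) so that aligned
# outputs do not depend on the inputs' common pre-rotation.
#' @noRd
.canonical_pose <- function(g) {
  d <- ncol(g$mean)
  v <- svd(g$mean)$v
  if (det(v) < 0) v[, d] <- -v[, d]
  flips <- if (d == 2L) list(diag(2), -diag(2))
           else list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                     diag(c(-1, -1, 1)))
  m0 <- g$mean %*% v
  score <- vapply(flips, function(f) {
    m <- m0 %*% f
    sum(m[1L, ] * 2^(ncol(m):1))
  }, numeric(1))
  r <- v %*% flips[[which.max(score)]]
  g$mean <- g$mean %*% r
  g$aligned <- lapply(g$aligned, function(a) a %*% r)
  g
}

#' Walk chords of fixed length `step` along a polyline, starting at its first
#' vertex. Returns the chord endpoints (nsteps + 1 points including the start)
#' and the arc-length position reached, or NULL if the walk runs off the end.
#' @noRd
.walk_chords <- function(pts, step, nsteps) {
  n <- nrow(pts)
  d <- ncol(pts)
  cum <- .cumarc(pts)
  out <- matrix(NA_real_, nsteps + 1L, d)
  out[1L, ] <- pts[1L, ]
  p <- pts[1L, ]
  seg <- 1L        # index of the polyline vertex at or behind p
  for (k in seq_len(nsteps)) {
    idx <- seg:n
    diffm <- pts[idx, , drop = FALSE]
    for (j in seq_len(d)) diffm[, j] <- diffm[, j] - p[j]
    dv <- sqrt(rowSums(diffm^2))
    dv[1L] <- 0      # measure the partial first segment from p itself
    cross <- which(dv[-length(dv)] <= step & dv[-1L] >= step)
    if (!length(cross)) return(NULL)
    j <- cross[1L]
    # crossing lies between q0 (p itself when j == 1) and vertex seg + j
    q0 <- if (j == 1L) p else pts[seg + j - 1L, ]
    b <- pts[seg + j, ]
    seglen <- sqrt(sum((b - q0)^2))
    u <- (b - q0) / seglen
    w <- q0 - p
    wu <- sum(w * u)
    disc <- wu^2 - (sum(w^2) - step^2)
    if (disc < 0) return(NULL)
    t <- min(max(-wu + sqrt(disc), 0), seglen)
    p <- q0 + t * u
    seg <- seg + j - 1L
    out[k + 1L, ] <- p
  }
  list(points = out,
       arc = cum[seg] + sqrt(sum((p - pts[seg, ])^2)))
}

# Solve for the common chord length at which `npieces` chord steps traverse
# the polyline's full arc length `total`. The traversed arc grows smoothly
# and monotonically with the chord until the walk runs off the end, so a
# secant iteration from the feasible side (bisection fallback, upper bracket
# shrunk on failures) converges in a few walk evaluations. Returns a step at
# which the walk is guaranteed to succeed.
#' @noRd
.solve_chord_step <- function(pts, npieces, total) {
  arcf <- function(c) {
    w <- .walk_chords(pts, c, npieces)
    if (is.null(w)) NA_real_ else w$arc
  }
  hi <- total / npieces * (1 + 1e-9)  # chords cover at least their own arc
  lo <- total / npieces * 0.9
  a_lo <- arcf(lo)
  while ((is.na(a_lo) || a_lo > total) && lo > 1e-12 * hi) {
    lo <- lo / 2
    a_lo <- arcf(lo)
  }
  if (is.na(a_lo)) stop("chord step search failed")
  tol <- 1e-14 * total / npieces
  lo2 <- NA_real_; a_lo2 <- NA_real_
  for (it in 1:100) {
    if (hi - lo < tol || total - a_lo < 1e-13 * total) break
    guess <- if (!is.na(lo2) && a_lo != a_lo2)
      lo + (total - a_lo) * (lo - lo2) / (a_lo - a_lo2)
    else (lo + hi) / 2
    if (!is.finite(guess) || guess <= lo || guess >= hi)
      guess <- (lo + hi) / 2
    a_g <- arcf(guess)
    if (is.na(a_g) || a_g > total) {
      # ran off, or jumped past the target (closed-loop corner cutting):
      # treat as the infeasible side of the bracket
      hi <- guess
    } else {
      lo2 <- lo; a_lo2 <- a_lo
      lo <- guess; a_lo <- a_g
    }
  }
  lo
}

#' Resample a polyline into exactly `npieces` chords of one common length,
#' chosen so that the walk lands exactly on the final vertex. Endpoints are
#' preserved exactly; every piece has identical length.
#' @noRd
.equal_chord_resample <- function(pts, npieces) {
  total <- sum(.rownorms(diff(pts)))
  if (npieces < 1L) stop("npieces must be >= 1")
  hi <- .solve_chord_step(pts, npieces, total)
  w <- .walk_chords(pts, hi, npieces)
  if (is.null(w)) {
    hi <- hi * (1 - 1e-12)
    w <- .walk_chords(pts, hi, npieces)
  }
  if (is.null(w)) stop("chord resampling failed to converge")
  res <- w$points
  res[npieces + 1L, ] <- pts[nrow(pts), ]   # pin the endpoint exactly
  list(points = res, step = hi)
}

#' Fast equal-arc-length resampling by linear interpolation (used when
#' portions are reduced to a common point count before averaging; generated
#' polylines use the exact equal-chord solver instead).
#' @noRd
.arc_resample <- function(pts, npieces) {
  cum <- .cumarc(pts)
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = npieces + 1L)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(pts) - 1L)
  w <- (s - cum[i]) / pmax(cum[i + 1L] - cum[i], 1e-300)
  pts[i, , drop = FALSE] * (1 - w) + pts[i + 1L, , drop = FALSE] * w
}

#' Clamp to [-1, 1] before acos.
#' @noRd
.safe_acos <- function(x) acos(pmin(1, pmax(-1, x)))

#' Wrap an angle in degrees to [-180, 180).
#' @noRd
.wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Run code with a temporarily seeded RNG, restoring the caller's state.
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' 2D rotation matrix for an angle in degrees.
#' @noRd
.rot2 <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
}
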