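# Shared fixtures and independent oracles for the test suite.

# A target profile straight along +x with unit pieces (npieces pieces).
straight_target <- function(npieces, id = "line") {
  structure(list(id = id, group = NA_character_,
                 points = cbind(0:npieces, rep(0, npieces + 1L)),
                 closed = FALSE, piece_length = 1, dimension = 2L),
            class = "target_profile")
}

# Closed unit-piece square of side `side` (piece length 1 divides the side).
square_target <- function(side = 10) {
  dp <- design_profile(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                       id = "square", closed = TRUE)
  resample_to_target(dp, 1)
}

# Dense circle design profile of radius r.
circle_design <- function(r = 10, n = 2000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  design_profile(cbind(r * cos(th), r * sin(th)), id = "circle", closed = TRUE)
}

# Exact planar arc portion: radius R, m pieces of chord h.
arc_portion <- function(R, m, h) {
  theta <- 2 * asin(h / (2 * R))
  i <- 0:m
  cbind(R * sin(i * theta), R * (1 - cos(i * theta)))
}

# Exact circular helix portion with curvature k, torsion t, m chords of h.
helix_portion <- function(k, t, m, h) {
  r <- k / (k^2 + t^2)
  cc <- t / (k^2 + t^2)
  chord <- function(d) sqrt(4 * r^2 * sin(d / 2)^2 + cc^2 * d^2)
  lo <- 0; hi <- h / sqrt(r^2 + cc^2) * 2
  while (chord(hi) < h) hi <- hi * 2
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (chord(mid) >= h) hi <- mid else lo <- mid
  }
  d <- (lo + hi) / 2
  i <- 0:m
  cbind(r * cos(i * d), r * sin(i * d), cc * i * d)
}

# Random rigid motion applied to a point matrix (seeded by the caller).
random_rigid <- function(pts) {
  d <- ncol(pts)
  if (d == 2L) {
    a <- runif(1, 0, 2 * pi)
    r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  } else {
    m <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(m)
    r <- qr.Q(qr_)
    if (det(r) < 0) r[, 1] <- -r[, 1]
  }
  sweep(pts %*% r, 2, rnorm(d, 0, 5), `+`)
}

# Brute-force 2D rigid alignment by rotation-grid scan (independent oracle
# for the SVD-based alignment): a 1e-4 rad grid refined locally, reporting
# the minimal max pointwise distance.
grid_align_error <- function(seg, portion, step = 1e-4) {
  cs <- colMeans(seg); cp <- colMeans(portion)
  xs <- sweep(seg, 2, cs); xp <- sweep(portion, 2, cp)
  scan <- function(angles) {
    ss <- vapply(angles, function(a) {
      r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      sum((xs %*% r - xp)^2)
    }, numeric(1))
    angles[which.min(ss)]
  }
  besta <- scan(seq(0, 2 * pi, by = step))
  for (s in c(step / 100, step / 1e4))
    besta <- scan(seq(besta - 100 * s, besta + 100 * s, by = s))
  r <- matrix(c(cos(besta), sin(besta), -sin(besta), cos(besta)), 2, 2)
  max(sqrt(rowSums((sweep(xs %*% r, 2, cp, `+`) - portion)^2)))
}

# Exhaustive search over supplementary placements (small instances only).
exhaustive_placement <- function(npieces, primary, q) {
  n <- npieces + 1L
  primary <- sort(unique(c(1L, primary, n)))
  nsupp <- q - (length(primary) - 1L)
  cands <- setdiff(2:(n - 1L), primary)
  if (nsupp == 0L)
    return(sum((diff(primary) - npieces / q)^2))
  combs <- utils::combn(cands, nsupp)
  best <- Inf
  for (i in seq_len(ncol(combs))) {
    b <- sort(c(primary, combs[, i]))
    f <- sum((diff(b) - npieces / q)^2)
    if (f < best) best <- f
  }
  best
}

# The error matrix printed for the two-profile worked example.
worked_example_em <- function() {
  rbind(c(0.5750, 0.5599, 1.1759, 0.8270, 0.2809, 0.1215),
        c(0.5750, 0.7843, 0.4901, 0.8270, 0.3837, 0.2854))
}
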