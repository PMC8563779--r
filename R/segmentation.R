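# Homologous segmentation: relative-angle apex detection, GA placement of
# supplementary segmentation points, and segment-matrix assembly.

# Index wrap for closed profiles: positions live on the N-1 unique points.
#' @noRd
.wrap_index <- function(i, n_unique) ((i - 1L) %% n_unique) + 1L

#' Relative angle at a profile point
#'
#' The turning angle at point `i` measured over a point interval `k`: the
#' angle between the forward chord (point `i` to point `i + k`) and the
#' backward chord (point `i - k` to point `i`). At `k = 1` this is the classic
#' exterior angle between two neighbouring pieces; larger `k` low-pass filters
#' the outline so that high-frequency serrations ("burrs") score low while
#' globally sharp corners keep a high angle.
#'
#' @param profile a `target_profile`.
#' @param i point index (1-based); vectorized.
#' @param k point interval, `>= 1`.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
relative_angle <- function(profile, i, k = 1L) {
  pts <- profile$points
  n <- nrow(pts)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (profile$closed) {
    nu <- n - 1L
    if (k >= nu) stop("k too large for profile length")
    idx <- .wrap_index(i, nu)
    fwd <- pts[.wrap_index(idx + k, nu), , drop = FALSE] -
           pts[idx, , drop = FALSE]
    bwd <- pts[idx, , drop = FALSE] -
           pts[.wrap_index(idx - k, nu), , drop = FALSE]
  } else {
    if (any(i - k < 1L) || any(i + k > n))
      stop("index out of range for open profile (need k < i <= N - k)")
    fwd <- pts[i + k, , drop = FALSE] - pts[i, , drop = FALSE]
    bwd <- pts[i, , drop = FALSE] - pts[i - k, , drop = FALSE]
  }
  cosv <- rowSums(fwd * bwd) / (.rownorms(fwd) * .rownorms(bwd))
  .safe_acos(cosv) * 180 / pi
}

# Relative angle at every admissible point; returns indices and angles.
#' @noRd
.relative_angle_profile <- function(profile, k) {
  n <- nrow(profile$points)
  idx <- if (profile$closed) seq_len(n - 1L) else seq.int(k + 1L, n - k)
  list(index = idx, beta = relative_angle(profile, idx, k))
}

#' Detect apices (globally sharp corners) on a profile
#'
#' Points whose relative angle at interval `k` reaches the threshold `T` are
#' grouped into maximal contiguous runs; each run contributes one apex, the
#' in-run point of largest relative angle (lowest index on ties). On closed
#' profiles, runs meeting across the seam are merged.
#'
#' @param profile a `target_profile`.
#' @param k point interval for [relative_angle].
#' @param T angle threshold in degrees, in `(0, 180)`.
#' @return integer vector of apex point indices (possibly empty), increasing.
#' @export
detect_apices <- function(profile, k = 1L, T = 45) {
  if (T <= 0 || T >= 180) stop("T must be in (0, 180) degrees")
  ra <- .relative_angle_profile(profile, k)
  hot <- ra$beta >= T
  if (!any(hot)) return(integer(0))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  if (profile$closed && length(runs) > 1L &&
      runs[[1L]][1L] == 1L &&
      runs[[length(runs)]][length(runs[[length(runs)]])] == length(hot)) {
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs <- runs[-length(runs)]
  }
  apices <- vapply(runs, function(run) {
    b <- ra$beta[run]
    ra$index[run][which.max(b)]   # which.max takes the first (lowest) on ties
  }, integer(1))
  sort(unique(apices))
}

#' Apex count as a function of the point interval
#'
#' Sweeps [detect_apices] over a range of intervals `k`. On serrated outlines
#' the count drops as `k` grows past the burr wavelength and plateaus at the
#' number of global apices, which guides the choice of `k`.
#'
#' @param profile a `target_profile`.
#' @param k_range integer vector of intervals.
#' @param T angle threshold in degrees.
#' @return integer vector of apex counts, one per entry of `k_range`.
#' @export
apex_count_sweep <- function(profile, k_range, T = 45) {
  vapply(k_range, function(k) length(detect_apices(profile, k, T)), integer(1))
}

#' Keep the strongest apices of a profile
#'
#' When noisy specimens yield more detected apices than the segmentation
#' scheme expects, the detected set is reduced to the `n` points with the
#' largest relative angle (lowest index on ties), so all profiles in a study
#' carry the same number of homologous primary points.
#'
#' @param profile a `target_profile`.
#' @param apices integer vector from [detect_apices].
#' @param n number of apices to keep.
#' @param k the point interval the apices were detected at.
#' @return sorted integer vector of at most `n` apex indices.
#' @export
select_apices <- function(profile, apices, n, k = 1L) {
  if (length(apices) <= n) return(apices)
  strength <- relative_angle(profile, apices, k)
  sort(apices[order(-strength, apices)[seq_len(n)]])
}

#' Segmentation points of one profile
#'
#' @param boundaries strictly increasing 1-based point indices; the first must
#'   be 1 and the last the profile's point count.
#' @param primary logical flags marking anatomical/apex boundaries (as opposed
#'   to supplementary, optimizer-placed ones).
#' @param id profile id.
#' @param fitness optional even-spacing fitness value of the placement.
#' @return object of class `segmentation_points`.
#' @export
segmentation_points <- function(boundaries, primary = NULL, id = "profile",
                                fitness = NA_real_) {
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  if (is.null(primary)) primary <- rep(TRUE, length(boundaries))
  if (length(primary) != length(boundaries))
    stop("primary flags must match boundaries")
  primary[c(1L, length(primary))] <- TRUE
  structure(list(id = id, boundaries = boundaries, primary = primary,
                 fitness = fitness),
            class = "segmentation_points")
}

# Fitness of a full boundary vector: sum over portions of the squared
# deviation of the portion piece count from the even share (N - 1)/q.
#' @noRd
.placement_fitness <- function(boundaries, npieces, q) {
  sum((diff(boundaries) - npieces / q)^2)
}

# Even-spacing heuristic: allocate portions to sub-profiles by largest
# remainder on their piece share, then cut each sub-profile evenly.
#' @noRd
.even_spacing_boundaries <- function(primary, q) {
  pieces <- diff(primary)
  npieces <- sum(pieces)
  nsub <- length(pieces)
  share <- pieces / npieces * q
  alloc <- pmax(1L, floor(share))
  while (sum(alloc) < q) {
    i <- which.max(share - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > q) {
    cand <- which(alloc > 1L)
    i <- cand[which.min((share - alloc)[cand])]
    alloc[i] <- alloc[i] - 1L
  }
  out <- integer(0)
  for (s in seq_len(nsub)) {
    cuts <- primary[s] + round(seq_len(alloc[s] - 1L) * pieces[s] / alloc[s])
    out <- c(out, primary[s], cuts)
  }
  sort(unique(c(out, primary[nsub + 1L])))
}

#' Place supplementary segmentation points with a genetic algorithm
#'
#' Given the primary (homologous) segmentation points of one profile, inserts
#' supplementary boundaries so that the profile is divided into exactly `q`
#' portions, minimizing the even-spacing fitness
#' `F = sum_e (k[e+1] - k[e] - (N - 1)/q)^2`. Integer genes are the
#' supplementary boundary indices; the initial population is seeded with an
#' even-spacing heuristic, so the returned fitness never exceeds the
#' heuristic's.
#'
#' @param profile a `target_profile`.
#' @param primary sorted point indices of the primary boundaries (the profile
#'   ends are added if missing).
#' @param q total number of portions wanted.
#' @param ga list of GA settings: `pop` (default 50), `generations` (100),
#'   `p_crossover` (0.8), `p_mutation` (0.05 per gene), `elitism` (1).
#' @param seed integer RNG seed (placement is deterministic given the seed).
#' @return a [segmentation_points] object with `q + 1` boundaries and the
#'   attained fitness.
#' @export
place_supplementary_points <- function(profile, primary = NULL, q,
                                       ga = list(), seed = 1L) {
  n <- nrow(profile$points)
  npieces <- n - 1L
  primary <- sort(unique(as.integer(c(1L, primary, n))))
  if (any(primary < 1L) || any(primary > n))
    stop("primary boundaries out of range")
  nsub <- length(primary) - 1L
  if (q < nsub)
    stop("q = ", q, " portions but ", nsub, " sub-profiles already defined")
  if (q > npieces)
    stop("infeasible: ", q, " portions need at least ", q, " pieces, have ",
         npieces)
  nsupp <- q - nsub
  heur <- .even_spacing_boundaries(primary, q)
  if (nsupp == 0L) {
    return(segmentation_points(primary,
                               primary = rep(TRUE, length(primary)),
                               id = profile$id,
                               fitness = .placement_fitness(primary, npieces, q)))
  }
  cfg <- utils::modifyList(list(pop = 50L, generations = 100L,
                                p_crossover = 0.8, p_mutation = 0.05,
                                elitism = 1L), ga)
  candidates <- setdiff(seq.int(2L, n - 1L), primary)
  if (length(candidates) < nsupp) stop("not enough interior points for q")
  fit_genome <- function(genes) {
    if (anyDuplicated(genes)) return(Inf)
    .placement_fitness(sort(c(primary, genes)), npieces, q)
  }
  heur_genes <- sort(setdiff(heur, primary))
  best <- .with_seed(seed, {
    pop <- c(list(heur_genes),
             replicate(cfg$pop - 1L,
                       sort(sample(candidates, nsupp)), simplify = FALSE))
    fitn <- vapply(pop, fit_genome, numeric(1))
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fitn)
      elite <- pop[ord[seq_len(cfg$elitism)]]
      newpop <- elite
      while (length(newpop) < cfg$pop) {
        pick <- function() {       # tournament of 2
          ij <- sample.int(cfg$pop, 2L)
          pop[[ij[which.min(fitn[ij])]]]
        }
        a <- pick(); b <- pick()
        if (nsupp > 1L && stats::runif(1) < cfg$p_crossover) {
          cut <- sample.int(nsupp - 1L, 1L)
          child <- sort(c(a[seq_len(cut)], b[seq.int(cut + 1L, nsupp)]))
        } else child <- a
        mut <- stats::runif(nsupp) < cfg$p_mutation
        if (any(mut))
          child[mut] <- sample(candidates, sum(mut))
        newpop[[length(newpop) + 1L]] <- sort(child)
      }
      pop <- newpop
      fitn <- vapply(pop, fit_genome, numeric(1))
    }
    pop[[which.min(fitn)]]
  })
  boundaries <- sort(c(primary, best))
  segmentation_points(boundaries,
                      primary = boundaries %in% primary,
                      id = profile$id,
                      fitness = .placement_fitness(boundaries, npieces, q))
}

#' Minimal even-spacing fitness attainable without primary constraints
#'
#' With `npieces = q * floor + s` leftover pieces, the best integer partition
#' puts `floor + 1` pieces in `s` portions and `floor` in the rest, giving
#' `F = s (1 - frac)^2 + (q - s) frac^2` with `frac` the fractional even share.
#'
#' @param npieces total pieces on the profile.
#' @param q portions.
#' @return the analytic minimum of the placement fitness.
#' @export
placement_fitness_bound <- function(npieces, q) {
  frac <- npieces / q - floor(npieces / q)
  s <- round(frac * q)
  s * (1 - frac)^2 + (q - s) * frac^2
}

#' Build the segment matrix from per-profile segmentation points
#'
#' Entry `m[j, e]` is the number of pieces allotted to segment `e` on profile
#' `j`, i.e. the difference of consecutive boundary indices; row sums equal
#' each profile's piece count. Columns typed `M` (rigid segments) must be
#' identical across profiles: unequal M-columns are equalized to the column
#' mode by donating the difference to an adjacent non-M column within the same
#' sub-profile (a homology error is raised when no such donor exists).
#'
#' @param all_points list of [segmentation_points], one per profile, all with
#'   the same number of boundaries and the same primary pattern.
#' @param type_vector character vector of segment types, one of
#'   `"M","C","H","G"`, length `q`.
#' @return object of class `segment_matrix`: fields `m` (p x q integer
#'   matrix), `types`, `ids`, `subprofile` (sub-profile index per column).
#' @export
build_segment_matrix <- function(all_points, type_vector) {
  type_vector <- toupper(type_vector)
  if (!all(type_vector %in% c("M", "C", "H", "G")))
    stop("segment types must be M, C, H or G")
  q <- length(type_vector)
  nb <- vapply(all_points, function(s) length(s$boundaries), integer(1))
  if (any(nb != q + 1L))
    stop("every profile needs q + 1 = ", q + 1L, " boundaries")
  m <- t(vapply(all_points, function(s) diff(s$boundaries), integer(q)))
  if (q == 1L) m <- matrix(m, ncol = 1L)
  ids <- vapply(all_points, `[[`, character(1), "id")
  rownames(m) <- ids
  # sub-profile index of each portion: count primary boundaries at or before
  # the portion's left boundary
  prim <- all_points[[1L]]$primary
  subprofile <- cumsum(prim[seq_len(q)])
  if (any(m < 1L))
    stop("empty portion (zero pieces) on profile(s): ",
         paste(ids[rowSums(m < 1L) > 0], collapse = ", "))
  for (e in which(type_vector == "M")) {
    col <- m[, e]
    if (length(unique(col)) == 1L) next
    tab <- table(col)
    target <- as.integer(names(tab)[which.max(tab)])
    bad <- character(0)
    for (j in which(col != target)) {
      delta <- m[j, e] - target
      # donate within the sub-profile when possible; a lone M column may
      # borrow across its primary boundary from the nearest resizable column
      donors <- which(type_vector != "M")
      donors <- donors[order(subprofile[donors] != subprofile[e],
                             abs(donors - e))]
      ok <- FALSE
      for (d in donors) {
        if (m[j, d] + delta >= 1L) {
          m[j, d] <- m[j, d] + delta
          m[j, e] <- target
          ok <- TRUE
          break
        }
      }
      if (!ok) bad <- c(bad, ids[j])
    }
    if (length(bad))
      stop("cannot equalize M-segment column ", e,
           " for profile(s): ", paste(bad, collapse = ", "))
  }
  structure(list(m = m, types = type_vector, ids = ids,
                 subprofile = subprofile),
            class = "segment_matrix")
}

#' Boundary indices implied by one row of a segment matrix
#'
#' The e-th segmentation point of profile `j` is `1 + sum of the first e - 1`
#' piece counts; the last is the profile's point count.
#'
#' @param sm a `segment_matrix`.
#' @param j profile row index.
#' @return integer vector of `q + 1` boundary point indices.
#' @export
segment_boundaries <- function(sm, j) {
  as.integer(c(1L, 1L + cumsum(sm$m[j, ])))
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf("segment_matrix: %d profiles x %d segments [%s]\n",
              nrow(x$m), ncol(x$m), paste(x$types, collapse = " ")))
  print(x$m)
  invisible(x)
}
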