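# Assembling the shape-changing chain over all profiles, error metrics, and
# the two segment-length optimizers.

#' Fit a shape-changing chain to a set of profiles
#'
#' For every segment (column of the segment matrix) the typed model is fitted
#' on the corresponding portions of all profiles; the segment polyline is then
#' generated at each profile's piece count and rigidly aligned to its portion.
#' The error matrix holds the maximum point-to-point distance of each aligned
#' segment, and the summary metrics are the matrix maximum, the matrix mean,
#' per-profile row means, and the per-profile mean pointwise error normalized
#' by the profile's point count.
#'
#' @param profiles list of `target_profile` objects (same dimension; pieces of
#'   a common length).
#' @param type_vector character vector of segment types (`M`, `C`, `H`, `G`);
#'   used when `segment_matrix` carries none, and checked against it otherwise.
#' @param segment_matrix a `segment_matrix` whose row sums match the profiles'
#'   piece counts.
#' @return object of class `chain_fit`: `models` (per-column segment models),
#'   `aligned` (p x q list matrix of `aligned_segment`s), `EM` (error matrix),
#'   `metrics` (list `E_max`, `E_mean`, `E_profile` (row means), `E_tilde`
#'   (per-profile normalized mean pointwise error)), plus the inputs.
#' @export
build_chain <- function(profiles, type_vector = NULL, segment_matrix) {
  sm <- segment_matrix
  if (is.null(type_vector)) type_vector <- sm$types
  if (!identical(toupper(type_vector), sm$types))
    stop("type_vector disagrees with the segment matrix")
  p <- nrow(sm$m); q <- ncol(sm$m)
  if (length(profiles) != p)
    stop("segment matrix has ", p, " rows but ", length(profiles), " profiles")
  npts <- vapply(profiles, function(pr) nrow(pr$points), integer(1))
  if (!all(rowSums(sm$m) == npts - 1L))
    stop("segment-matrix row sums must equal each profile's piece count; ",
         "offending profile(s): ",
         paste(sm$ids[rowSums(sm$m) != npts - 1L], collapse = ", "))
  dim <- profiles[[1L]]$dimension
  h <- mean(vapply(profiles, `[[`, numeric(1), "piece_length"))
  boundaries <- lapply(seq_len(p), function(j) segment_boundaries(sm, j))
  models <- vector("list", q)
  aligned <- matrix(vector("list", p * q), p, q)
  EM <- matrix(NA_real_, p, q, dimnames = list(sm$ids, NULL))
  for (e in seq_len(q)) {
    portions <- lapply(seq_len(p), function(j)
      extract_portion(profiles[[j]], boundaries[[j]][c(e, e + 1L)]))
    models[[e]] <- switch(sm$types[[e]],
      M = fit_m_segment(portions, h),
      C = fit_c_segment(portions, h),
      H = fit_h_segment(portions, h),
      G = fit_g_segment(portions, h))
    for (j in seq_len(p)) {
      seg <- generate_segment_points(models[[e]], sm$m[j, e])
      al <- align_segment_to_portion(seg, portions[[j]])
      aligned[[j, e]] <- al
      EM[j, e] <- al$error
    }
  }
  fit <- structure(list(profiles = profiles, sm = sm, models = models,
                        aligned = aligned, EM = EM, dimension = dim,
                        piece_length = h),
                   class = "chain_fit")
  fit$metrics <- error_metrics(fit)
  fit
}

#' Matching-error metrics of a fitted chain
#'
#' @param chain a `chain_fit`.
#' @return list with `E_max` (maximum entry of the error matrix), `E_mean`
#'   (mean entry), `E_profile` (per-profile mean of the row's maxima), and
#'   `E_tilde` (per-profile sum of all pointwise segment-to-portion distances
#'   divided by the profile's point count).
#' @export
error_metrics <- function(chain) {
  EM <- chain$EM
  p <- nrow(EM)
  e_tilde <- vapply(seq_len(p), function(j) {
    tot <- sum(vapply(seq_len(ncol(EM)), function(e)
      sum(chain$aligned[[j, e]]$pointwise), numeric(1)))
    tot / nrow(chain$profiles[[j]]$points)
  }, numeric(1))
  c(em_summary(EM), list(E_tilde = e_tilde))
}

#' Summary metrics of a bare error matrix
#'
#' @param EM numeric p x q matrix of segment matching errors.
#' @return list with `E_max`, `E_mean`, and `E_profile` (row means).
#' @export
em_summary <- function(EM) {
  list(E_max = max(EM), E_mean = mean(EM), E_profile = rowMeans(EM))
}

#' @export
print.chain_fit <- function(x, ...) {
  cat(sprintf(
    "chain_fit: %d profiles, %d segments [%s], %dD\n  E_max %.4f, E_mean %.4f\n",
    nrow(x$EM), ncol(x$EM), paste(x$sm$types, collapse = " "), x$dimension,
    x$metrics$E_max, x$metrics$E_mean))
  invisible(x)
}

# Rebuild a chain with a modified segment matrix.
#' @noRd
.rebuild <- function(chain, m_new) {
  sm <- chain$sm
  sm$m <- m_new
  build_chain(chain$profiles, sm$types, sm)
}

#' Piece-by-piece optimization of the segment matrix
#'
#' For each profile in turn, one piece is moved from its worst-matched
#' (highest-error) resizable segment to the best-matched (lowest-error)
#' resizable segment within the same sub-profile; the move is kept only if
#' that profile's normalized error decreases. Rigid M-segments and row sums
#' are never altered, so homologous boundaries stay put. Passes repeat until
#' a full pass accepts no move.
#'
#' @param chain a `chain_fit`.
#' @param max_iter maximum number of full passes.
#' @param tol minimum decrease in the profile's normalized error for a move
#'   to be accepted.
#' @return the optimized `chain_fit` (mean error never above the input's).
#' @export
optimize_piecewise <- function(chain, max_iter = 50L, tol = 0) {
  sm <- chain$sm
  movable <- sm$types != "M"
  if (sum(movable) < 2L) return(chain)
  p <- nrow(sm$m)
  for (pass in seq_len(max_iter)) {
    accepted <- FALSE
    for (j in seq_len(p)) {
      errs <- chain$EM[j, ]
      cand <- which(movable & chain$sm$m[j, ] > 1L)
      if (!length(cand)) next
      donor <- recip <- NULL
      for (d in cand[order(errs[cand], decreasing = TRUE)]) {
        rc <- setdiff(which(movable & sm$subprofile == sm$subprofile[d]), d)
        if (length(rc)) { donor <- d; recip <- rc[which.min(errs[rc])]; break }
      }
      if (is.null(donor)) next
      m_new <- chain$sm$m
      m_new[j, donor] <- m_new[j, donor] - 1L
      m_new[j, recip] <- m_new[j, recip] + 1L
      trial <- .rebuild(chain, m_new)
      if (trial$metrics$E_tilde[[j]] < chain$metrics$E_tilde[[j]] - tol) {
        chain <- trial
        accepted <- TRUE
      }
    }
    if (!accepted) break
  }
  chain
}

# Random composition of `total` pieces into `k` parts, each >= 1.
#' @noRd
.random_composition <- function(total, k) {
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, k - 1L))
  diff(c(0L, cuts, total))
}

# Normalized matching error of profile j under a proposed piece-count row,
# with the chain's segment models held fixed (the other profiles' matching
# scheme is unchanged while a proposal is scored).
#' @noRd
.profile_error_fixed_models <- function(chain, j, m_row) {
  bounds <- c(1L, 1L + cumsum(m_row))
  tot <- 0
  for (e in seq_along(m_row)) {
    portion <- extract_portion(chain$profiles[[j]], bounds[c(e, e + 1L)])
    seg <- generate_segment_points(chain$models[[e]], m_row[e])
    tot <- tot + sum(align_segment_to_portion(seg, portion)$pointwise)
  }
  tot / nrow(chain$profiles[[j]]$points)
}

#' Re-segmentation of the worst-matched profiles
#'
#' Profiles are ranked by their normalized matching error; for the worst
#' `fraction` of them, the lengths of the resizable (G/C/H) segments are
#' randomly regenerated within each sub-profile (M lengths untouched, row
#' sums conserved) and the new lengths are kept only when that profile's
#' error decreases. Rounds repeat until one passes with no acceptance.
#'
#' @param chain a `chain_fit`.
#' @param fraction share of profiles re-segmented per round, in `(0, 1]`.
#' @param restarts random proposals tried per profile per round.
#' @param seed integer RNG seed; the result is deterministic given it.
#' @param max_rounds cap on optimization rounds.
#' @return the optimized `chain_fit`.
#' @export
optimize_worst_profiles <- function(chain, fraction = 0.1, restarts = 10L,
                                    seed = 1L, max_rounds = 200L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  sm <- chain$sm
  movable <- sm$types != "M"
  if (!any(movable)) return(chain)
  p <- nrow(sm$m)
  nworst <- ceiling(fraction * p)
  .with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      accepted <- FALSE
      worst <- order(chain$metrics$E_tilde, decreasing = TRUE)[seq_len(nworst)]
      for (j in worst) {
        # score proposals against the current models; the other profiles'
        # matching scheme stays unchanged while candidates are compared
        best_row <- chain$sm$m[j, ]
        best_err <- .profile_error_fixed_models(chain, j, best_row)
        for (r in seq_len(restarts)) {
          row_new <- chain$sm$m[j, ]
          for (s in unique(sm$subprofile)) {
            cols <- which(sm$subprofile == s & movable)
            if (length(cols) < 1L) next
            total <- sum(row_new[cols])
            if (total < length(cols)) next
            row_new[cols] <- .random_composition(total, length(cols))
          }
          err <- .profile_error_fixed_models(chain, j, row_new)
          if (err < best_err) {
            best_err <- err
            best_row <- row_new
          }
        }
        if (!identical(best_row, chain$sm$m[j, ])) {
          m_new <- chain$sm$m
          m_new[j, ] <- best_row
          trial <- .rebuild(chain, m_new)
          if (trial$metrics$E_tilde[[j]] < chain$metrics$E_tilde[[j]]) {
            chain <- trial
            accepted <- TRUE
          }
        }
      }
      if (!accepted) break
    }
    chain
  })
}
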