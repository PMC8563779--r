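# Morphometric variables extracted from a fitted chain: inter-segment
# orientation differences, piece-count length ratios, 3D direction vectors,
# and the assembled feature table that feeds discriminant analysis.

# Planar direction angle (degrees) of a 2D vector.
#' @noRd
.dir2 <- function(v) atan2(v[2L], v[1L]) * 180 / pi

#' Orientation difference between neighbouring segments (2D)
#'
#' The signed angle (counter-clockwise positive, wrapped to `[-180, 180)`)
#' between the direction of the first piece of segment `e + 1` and the
#' direction of the last piece of segment `e`, both taken from the aligned
#' chain on profile `j`. This is the rotation of the virtual joint between
#' the two segments.
#'
#' @param chain a `chain_fit` in 2D.
#' @param j profile index.
#' @param e segment index, `1 <= e <= q - 1`.
#' @return signed angle in degrees.
#' @export
orientation_difference_2d <- function(chain, j, e) {
  if (chain$dimension != 2L)
    stop("orientation differences are planar; use segment_direction_3d in 3D")
  q <- ncol(chain$EM)
  if (e < 1L || e > q - 1L) stop("e must be in 1..q-1")
  za <- chain$aligned[[j, e]]$points
  zb <- chain$aligned[[j, e + 1L]]$points
  n <- nrow(za)
  .wrap180(.dir2(zb[2L, ] - zb[1L, ]) - .dir2(za[n, ] - za[n - 1L, ]))
}

#' Planar orientation of one segment (2D)
#'
#' Direction angle, in degrees, of the chord from the aligned segment's start
#' point to its endpoint.
#'
#' @inheritParams orientation_difference_2d
#' @return angle in degrees in `[-180, 180)`.
#' @export
segment_orientation_2d <- function(chain, j, e) {
  if (chain$dimension != 2L) stop("planar orientation needs a 2D chain")
  z <- chain$aligned[[j, e]]$points
  .wrap180(.dir2(z[nrow(z), ] - z[1L, ]))
}

#' Piece-count length ratio of a resizable segment
#'
#' For a G-, C- or H-typed column, each profile's piece count divided by the
#' largest count in the column; values lie in `(0, 1]` and the maximum 1 is
#' attained by the longest profile.
#'
#' @param sm a `segment_matrix`.
#' @param e column index (must not be typed `M`).
#' @return numeric vector, one ratio per profile.
#' @export
length_ratio <- function(sm, e) {
  if (sm$types[[e]] == "M")
    stop("length ratios are defined for G/C/H segments, column ", e, " is M")
  sm$m[, e] / max(sm$m[, e])
}

#' Unit direction vector of one segment (3D)
#'
#' The normalized chord from the aligned segment's start point to its
#' endpoint on profile `j`.
#'
#' @param chain a `chain_fit` in 3D.
#' @param j profile index.
#' @param e segment index.
#' @return unit numeric vector of length 3.
#' @export
segment_direction_3d <- function(chain, j, e) {
  if (chain$dimension != 3L) stop("direction vectors need a 3D chain")
  z <- chain$aligned[[j, e]]$points
  v <- z[nrow(z), ] - z[1L, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate segment: coincident endpoints")
  v / nv
}

#' Assemble the morphometric feature table of a fitted chain
#'
#' Builds one row per profile from the selected blocks:
#' \describe{
#'   \item{`sigma`}{the `q - 1` signed orientation differences between
#'     neighbouring segments (2D; absolute values with `sigma_abs = TRUE`).}
#'   \item{`orientation`}{the `q` planar segment orientations (2D).}
#'   \item{`lengths`}{one piece-count ratio per G/C/H column.}
#'   \item{`u`}{the `3 q` components of the segment direction vectors (3D).}
#'   \item{`arclen`}{each profile's total arc length.}
#'   \item{`n_apex`}{apex count at `apex_k`, `apex_T`.}
#'   \item{`n_burr`}{apex count at the small-interval burr settings
#'     `burr_k`, `burr_T`.}
#'   \item{`anchors`}{coordinates of any named anchor points stored on the
#'     profiles (e.g. suture intersection landmarks).}
#' }
#'
#' @param chain a `chain_fit`.
#' @param blocks character vector naming the blocks to include.
#' @param sigma_abs use absolute orientation differences.
#' @param apex_k,apex_T,burr_k,burr_T relative-angle settings for the count
#'   blocks.
#' @return a `data.frame` with columns `id`, `group`, then the feature
#'   columns named `sigma_e`, `orient_e`, `g_e`, `u_e_x|y|z`, `arclen`,
#'   `n_apex`, `n_burr`, `anchor_<name>_<x|y|z>`.
#' @export
assemble_features <- function(chain,
                              blocks = if (chain$dimension == 2L) "sigma"
                                       else "u",
                              sigma_abs = FALSE,
                              apex_k = 1L, apex_T = 45,
                              burr_k = 1L, burr_T = 30) {
  p <- nrow(chain$EM); q <- ncol(chain$EM)
  known <- c("sigma", "orientation", "lengths", "u", "arclen",
             "n_apex", "n_burr", "anchors")
  bad <- setdiff(blocks, known)
  if (length(bad)) stop("unknown feature block(s): ", paste(bad, collapse = ", "))
  if (chain$dimension == 2L && "u" %in% blocks)
    stop("direction-vector block needs a 3D chain")
  if (chain$dimension == 3L && any(c("sigma", "orientation") %in% blocks))
    stop("planar angle blocks need a 2D chain")
  out <- data.frame(
    id = vapply(chain$profiles, `[[`, character(1), "id"),
    group = vapply(chain$profiles, function(p) as.character(p$group),
                   character(1)),
    stringsAsFactors = FALSE)
  if ("sigma" %in% blocks && q >= 2L) {
    for (e in seq_len(q - 1L)) {
      v <- vapply(seq_len(p), function(j)
        orientation_difference_2d(chain, j, e), numeric(1))
      out[[paste0("sigma_", e)]] <- if (sigma_abs) abs(v) else v
    }
  }
  if ("orientation" %in% blocks) {
    for (e in seq_len(q))
      out[[paste0("orient_", e)]] <- vapply(seq_len(p), function(j)
        segment_orientation_2d(chain, j, e), numeric(1))
  }
  if ("lengths" %in% blocks) {
    for (e in which(chain$sm$types != "M"))
      out[[paste0("g_", e)]] <- length_ratio(chain$sm, e)
  }
  if ("u" %in% blocks) {
    for (e in seq_len(q)) {
      u <- t(vapply(seq_len(p), function(j)
        segment_direction_3d(chain, j, e), numeric(3)))
      out[[paste0("u_", e, "_x")]] <- u[, 1L]
      out[[paste0("u_", e, "_y")]] <- u[, 2L]
      out[[paste0("u_", e, "_z")]] <- u[, 3L]
    }
  }
  if ("arclen" %in% blocks)
    out$arclen <- vapply(chain$profiles, arc_length, numeric(1))
  if ("n_apex" %in% blocks)
    out$n_apex <- vapply(chain$profiles, function(pr)
      length(detect_apices(pr, apex_k, apex_T)), numeric(1))
  if ("n_burr" %in% blocks)
    out$n_burr <- vapply(chain$profiles, function(pr)
      length(detect_apices(pr, burr_k, burr_T)), numeric(1))
  if ("anchors" %in% blocks) {
    anames <- names(chain$profiles[[1L]]$anchors)
    for (a in anames) {
      coords <- t(vapply(chain$profiles, function(pr) pr$anchors[[a]],
                         numeric(chain$dimension)))
      ax <- c("x", "y", "z")[seq_len(chain$dimension)]
      for (d in seq_along(ax))
        out[[paste0("anchor_", a, "_", ax[d])]] <- coords[, d]
    }
  }
  out
}

#' Fitted-parameter count of a chain scheme
#'
#' How many parameters a chain fit contributes for statistics: in 2D, one
#' orientation per segment plus one length ratio per resizable (G/C/H)
#' segment; in 3D, three orientation components per segment plus one length
#' parameter per G/H segment.
#'
#' @param type_vector character vector of segment types.
#' @param dimension 2 or 3.
#' @return integer parameter count.
#' @export
count_chain_parameters <- function(type_vector, dimension) {
  type_vector <- toupper(type_vector)
  q <- length(type_vector)
  resizable <- sum(type_vector != "M")
  if (dimension == 2L) q + resizable
  else 3L * q + resizable
}
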