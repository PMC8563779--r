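# Outline profile containers, file I/O, resampling, and superimposition.

#' Create a design profile
#'
#' A design profile is the raw ordered outline of one specimen: an open or
#' closed polyline in 2 or 3 dimensions, in arbitrary length units. Closed
#' profiles are stored with the first point duplicated at the end, so open- and
#' closed-curve bookkeeping (piece counts, boundary indices) is identical.
#'
#' @param points numeric matrix, one point per row, 2 or 3 columns.
#' @param id character identifier.
#' @param group character group label (may be `NA`).
#' @param closed logical; if `TRUE` and the terminal point does not repeat the
#'   first, the duplicate is appended.
#' @return an object of class `design_profile`.
#' @export
design_profile <- function(points, id = "profile", group = NA_character_,
                           closed = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!ncol(points) %in% c(2L, 3L))
    stop("points must have 2 or 3 columns")
  if (nrow(points) < 3L)
    stop("a profile needs at least 3 points")
  if (closed && sqrt(sum((points[1L, ] - points[nrow(points), ])^2)) > 1e-12)
    points <- rbind(points, points[1L, , drop = FALSE])
  seglen <- .rownorms(diff(points))
  if (any(seglen <= 1e-12))
    stop("consecutive points coincide at row(s): ",
         paste(which(seglen <= 1e-12), collapse = ", "))
  structure(list(id = id, group = group, points = points, closed = closed,
                 dimension = ncol(points)),
            class = "design_profile")
}

#' @export
print.design_profile <- function(x, ...) {
  cat(sprintf("design_profile '%s' (%s, %dD, %d points, group %s)\n",
              x$id, if (x$closed) "closed" else "open", x$dimension,
              nrow(x$points), x$group))
  invisible(x)
}

#' Read an outline profile from disk
#'
#' Supported formats: CSV with a `x,y[,z]` header and one point per row, and
#' TPS landmark files (`LM=`/`LM3=` blocks; the `ID=` field, when present,
#' names the profile).
#'
#' @param path file path.
#' @param fmt `"csv"` or `"tps"`.
#' @param closed logical; closed outlines get the duplicated terminal point.
#' @param id profile id; defaults to the file name (or the TPS `ID=` field).
#' @param group group label.
#' @return a [design_profile].
#' @export
read_profile <- function(path, fmt = c("csv", "tps"), closed = FALSE,
                         id = NULL, group = NA_character_) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("file ", path, " has no coordinate rows")
    header <- tolower(gsub('"', "", trimws(strsplit(lines[[1L]], ",")[[1L]])))
    if (!identical(header[seq_len(min(2L, length(header)))], c("x", "y")))
      stop("CSV header must be x,y[,z], got: ", lines[[1L]])
    dim <- length(header)
    if (!dim %in% c(2L, 3L)) stop("CSV header must have 2 or 3 columns")
    rows <- lapply(seq_along(lines)[-1L], function(i) {
      fields <- trimws(strsplit(lines[[i]], ",")[[1L]])
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != dim || anyNA(vals))
        stop("malformed row at line ", i, " of ", path, ": ", lines[[i]])
      vals
    })
    pts <- do.call(rbind, rows)
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    lines <- readLines(path, warn = FALSE)
    lm_line <- grep("^LM3?=", lines)
    if (!length(lm_line)) stop("no LM=/LM3= block in TPS file ", path)
    lm_line <- lm_line[[1L]]
    dim <- if (grepl("^LM3=", lines[lm_line])) 3L else 2L
    n <- as.integer(sub("^LM3?=", "", lines[lm_line]))
    coord_lines <- lines[(lm_line + 1L):(lm_line + n)]
    pts <- t(vapply(seq_along(coord_lines), function(i) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(coord_lines[[i]]),
                                                   "[ \t]+")[[1L]]))
      if (length(vals) != dim || anyNA(vals))
        stop("malformed TPS coordinate at line ", lm_line + i, " of ", path)
      vals
    }, numeric(dim)))
    if (is.null(id)) {
      id_line <- grep("^ID=", lines, value = TRUE)
      id <- if (length(id_line)) sub("^ID=", "", id_line[[1L]])
            else sub("\\.[^.]*$", "", basename(path))
    }
  }
  design_profile(pts, id = id, group = group, closed = closed)
}

#' Write a profile's coordinates to CSV (header x,y[,z], one point per row)
#' @param profile a [design_profile] or [target_profile].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  pts <- profile$points
  colnames(pts) <- c("x", "y", "z")[seq_len(ncol(pts))]
  utils::write.csv(as.data.frame(pts), path, row.names = FALSE)
  invisible(path)
}

#' Resample a design profile into a target profile of equal-length pieces
#'
#' The outline is converted into a piecewise-linear curve whose consecutive
#' points all lie the same chord distance apart: the unit "piece" of the
#' chain-fitting machinery. The piece count is `round(arc length /
#' piece_length)` and the exact common chord is then solved by bisection so
#' that the walk from the first point lands exactly on the last; endpoints of
#' open profiles are therefore preserved exactly, and closed profiles keep
#' their duplicated start point.
#'
#' @param profile a [design_profile] (a `target_profile` is accepted and
#'   treated as its own design polyline).
#' @param piece_length requested piece length, in the profile's units; must be
#'   positive and small enough that at least 3 pieces result.
#' @return an object of class `target_profile` with fields `points`,
#'   `piece_length` (the achieved common chord), `id`, `group`, `closed`,
#'   `dimension`.
#' @export
resample_to_target <- function(profile, piece_length) {
  pts <- profile$points
  total <- sum(.rownorms(diff(pts)))
  if (piece_length <= 0) stop("piece_length must be positive")
  if (piece_length >= total / 2)
    stop("piece_length too large for profile '", profile$id,
         "' (arc length ", signif(total, 6), ")")
  npieces <- round(total / piece_length)
  if (npieces < 3L)
    stop("piece_length too large: fewer than 3 pieces on '", profile$id, "'")
  if (isTRUE(profile$closed)) {
    # walk on the loop traversed twice so the final chord may cross the seam
    ext <- rbind(pts, pts[-1L, , drop = FALSE])
    rs <- .equal_chord_resample_arc(ext, npieces, total)
    out <- rs$points
    out[npieces + 1L, ] <- out[1L, ]
  } else {
    rs <- .equal_chord_resample(pts, npieces)
    out <- rs$points
  }
  structure(list(id = profile$id, group = profile$group, points = out,
                 closed = isTRUE(profile$closed), piece_length = rs$step,
                 dimension = ncol(out), anchors = profile$anchors),
            class = "target_profile")
}

# Equal-chord resample against a target arc length (closed-profile case:
# `pts` is the loop laid out twice, `total` one perimeter).
#' @noRd
.equal_chord_resample_arc <- function(pts, npieces, total) {
  hi <- .solve_chord_step(pts, npieces, total)
  w <- .walk_chords(pts, hi, npieces)
  if (is.null(w)) {
    hi <- hi * (1 - 1e-12)
    w <- .walk_chords(pts, hi, npieces)
  }
  if (is.null(w)) stop("chord resampling failed to converge")
  list(points = w$points, step = hi)
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf(
    "target_profile '%s' (%s, %dD, %d points = %d pieces of %.6g)\n",
    x$id, if (x$closed) "closed" else "open", x$dimension, nrow(x$points),
    nrow(x$points) - 1L, x$piece_length))
  invisible(x)
}

#' Relocate the cyclic start point of a closed target profile
#'
#' Closed outlines have an arbitrary starting point; relocating it to a
#' detected apex makes portions start at homologous positions across
#' specimens. The duplicated-start storage convention is preserved.
#'
#' @param profile a closed `target_profile`.
#' @param start point index (into the current ordering) that becomes point 1.
#' @return the rotated `target_profile`.
#' @export
rotate_closed_profile <- function(profile, start) {
  if (!isTRUE(profile$closed)) stop("profile is not closed")
  n <- nrow(profile$points)
  nu <- n - 1L
  start <- ((start - 1L) %% nu) + 1L
  if (start == 1L) return(profile)
  idx <- c(start:nu, seq_len(start - 1L))
  profile$points <- profile$points[c(idx, start), , drop = FALSE]
  profile
}

#' Total arc length of a profile's polyline
#' @param profile a design or target profile.
#' @return scalar arc length in the profile's units.
#' @export
arc_length <- function(profile) sum(.rownorms(diff(profile$points)))

#' Generalized Procrustes superimposition
#'
#' Aligns a set of same-cardinality point configurations by translation,
#' rotation (reflections excluded) and, optionally, scaling to unit centroid
#' size, iterating against the evolving mean shape until it stabilizes
#' (change below `1e-9`).
#'
#' @param configurations list of numeric matrices with identical dimensions.
#' @param scale logical; scale each configuration to centroid size 1.
#' @return list with `aligned` (list of aligned configurations, centroids at
#'   the origin), `mean` (the consensus shape), `iterations`, and `rss` (the
#'   per-iteration residual sum of squares, a non-increasing sequence).
#' @export
procrustes_superimpose <- function(configurations, scale = TRUE) {
  if (length(configurations) < 2L)
    stop("need at least 2 configurations")
  .canonical_pose(.gpa(lapply(configurations, as.matrix), scale = scale,
                       tol = 1e-10))
}
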