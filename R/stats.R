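# Stepwise linear discriminant analysis on chain features, with canonical
# components, confusion matrices, and leave-one-out cross-validation.
#
# Variable selection is forward-with-removal on the partial F derived from
# Wilks' lambda; classification uses MASS::lda with pooled covariance and
# equal priors.

# Wilks' lambda det(W)/det(T) for a column subset.
#' @noRd
.wilks <- function(x, groups, cols) {
  if (!length(cols)) return(1)
  xs <- as.matrix(x[, cols, drop = FALSE])
  n <- nrow(xs)
  tot <- crossprod(sweep(xs, 2, colMeans(xs)))
  within <- matrix(0, length(cols), length(cols))
  for (g in levels(groups)) {
    xg <- xs[groups == g, , drop = FALSE]
    within <- within + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  dt <- det(tot)
  if (dt <= 0) return(NA_real_)
  det(within) / dt
}

# Partial F for entering `v` given the selected set (p = |selected|):
# F = ((n - g - p) / (g - 1)) (lambda_p / lambda_{p+1} - 1).
#' @noRd
.f_to_enter <- function(x, groups, selected, v) {
  n <- nrow(x); g <- nlevels(groups); p <- length(selected)
  l0 <- .wilks(x, groups, selected)
  l1 <- .wilks(x, groups, c(selected, v))
  if (is.na(l0) || is.na(l1) || l1 <= 0) return(NA_real_)
  (n - g - p) / (g - 1) * (l0 / l1 - 1)
}

#' @noRd
.f_to_remove <- function(x, groups, selected, v) {
  n <- nrow(x); g <- nlevels(groups); p <- length(selected)
  l0 <- .wilks(x, groups, setdiff(selected, v))
  l1 <- .wilks(x, groups, selected)
  if (is.na(l0) || is.na(l1) || l1 <= 0) return(NA_real_)
  (n - g - p + 1) / (g - 1) * (l0 / l1 - 1)
}

# Numeric feature columns of a feature table (id/group dropped).
#' @noRd
.feature_columns <- function(features) {
  x <- features[, setdiff(colnames(features), c("id", "group")), drop = FALSE]
  keep <- vapply(x, is.numeric, logical(1))
  x[, keep, drop = FALSE]
}

#' Stepwise linear discriminant analysis
#'
#' Forward selection with removal on the Wilks'-lambda partial F: at each
#' step the variable with the largest F-to-enter joins if `F >= f_enter`
#' (ties broken by the smaller column index), then any included variable with
#' `F-to-remove < f_remove` is dropped. The classifier on the selected
#' variables is linear DA with pooled covariance and equal priors, yielding
#' `min(g - 1, #selected)` canonical components. If no variable passes
#' `f_enter` an explicit empty-model result is returned.
#'
#' @param features a feature `data.frame` (the `id`/`group` columns are
#'   ignored as predictors) or numeric matrix.
#' @param groups factor (or coercible) of group labels; taken from
#'   `features$group` when missing.
#' @param f_enter,f_remove partial-F thresholds (defaults 3.84 / 2.71).
#' @return object of class `chain_da`: `selected` (variable names in entry
#'   order), `steps` (per-step action, variable, Wilks' lambda, F),
#'   `empty` flag, and for non-empty models `fit` (the `MASS::lda` object),
#'   `scores` (canonical scores), `loadings`, `confusion`, `accuracy` (%),
#'   `loocv_confusion`, `loocv_accuracy` (%), `loocv_skipped`.
#' @export
stepwise_da <- function(features, groups = NULL, f_enter = 3.84,
                        f_remove = 2.71) {
  if (is.null(groups)) {
    if (!"group" %in% colnames(features))
      stop("no groups given and no 'group' column present")
    groups <- features$group
  }
  groups <- droplevels(as.factor(groups))
  x <- as.data.frame(.feature_columns(as.data.frame(features)))
  n <- nrow(x); g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  vars <- colnames(x)
  selected <- character(0)
  steps <- data.frame(action = character(0), variable = character(0),
                      lambda = numeric(0), F = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    changed <- FALSE
    remaining <- setdiff(vars, selected)
    if (length(remaining) && n - g - length(selected) > length(selected) + 1L) {
      fs <- vapply(remaining, function(v)
        .f_to_enter(x, groups, selected, v), numeric(1))
      if (any(!is.na(fs)) && max(fs, na.rm = TRUE) >= f_enter) {
        v <- remaining[which.max(fs)]   # first max = smallest index on ties
        selected <- c(selected, v)
        steps <- rbind(steps, data.frame(
          action = "enter", variable = v,
          lambda = .wilks(x, groups, selected),
          F = max(fs, na.rm = TRUE), stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      frm <- vapply(selected, function(v)
        .f_to_remove(x, groups, selected, v), numeric(1))
      worst <- which.min(frm)
      if (!is.na(frm[worst]) && frm[worst] < f_remove &&
          selected[worst] != utils::tail(selected, 1L)) {
        v <- selected[worst]
        selected <- setdiff(selected, v)
        steps <- rbind(steps, data.frame(
          action = "remove", variable = v,
          lambda = .wilks(x, groups, selected),
          F = frm[worst], stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected)) {
    return(structure(list(selected = character(0), steps = steps,
                          empty = TRUE, groups = groups),
                     class = "chain_da"))
  }
  xs <- x[, selected, drop = FALSE]
  fit <- tryCatch(
    MASS::lda(xs, grouping = groups, prior = rep(1 / g, g)),
    error = function(e)
      stop("singular pooled covariance over variables: ",
           paste(selected, collapse = ", "), " (", conditionMessage(e), ")"))
  pred <- stats::predict(fit, xs)
  confusion <- table(truth = groups, predicted = pred$class)
  accuracy <- 100 * sum(diag(confusion)) / n
  cv <- loocv(cbind(xs, group = groups), groups, selected)
  structure(list(selected = selected, steps = steps, empty = FALSE,
                 fit = fit, groups = groups,
                 scores = pred$x, loadings = fit$scaling,
                 confusion = confusion, accuracy = accuracy,
                 loocv_confusion = cv$confusion,
                 loocv_accuracy = cv$accuracy,
                 loocv_skipped = cv$skipped),
            class = "chain_da")
}

#' @export
print.chain_da <- function(x, ...) {
  if (x$empty) {
    cat("chain_da: empty model (no variable passed the entry threshold)\n")
  } else {
    cat(sprintf(
      "chain_da: %d variables [%s]\n  accuracy %.1f%%, LOOCV %.1f%%\n",
      length(x$selected), paste(x$selected, collapse = ", "),
      x$accuracy, x$loocv_accuracy))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of a linear DA classifier
#'
#' With the variable set fixed, the equal-prior pooled-covariance LDA
#' classifier is refitted on every n - 1 subset and the held-out sample
#' classified. Folds in which a group would drop below 2 training samples
#' are skipped with a warning.
#'
#' @param features feature table containing the selected variables.
#' @param groups factor of group labels.
#' @param selected character vector of variable names to use.
#' @return list with `confusion` (rows sum to the classified group sizes),
#'   `accuracy` (% correct of classified samples), and `skipped` (indices of
#'   skipped folds).
#' @export
loocv <- function(features, groups, selected) {
  groups <- droplevels(as.factor(groups))
  x <- as.data.frame(features)[, selected, drop = FALSE]
  n <- nrow(x); g <- nlevels(groups)
  pred <- factor(rep(NA_character_, n), levels = levels(groups))
  skipped <- integer(0)
  for (i in seq_len(n)) {
    tr_groups <- groups[-i]
    if (any(table(tr_groups) < 2L)) {
      skipped <- c(skipped, i)
      next
    }
    fit <- MASS::lda(x[-i, , drop = FALSE], grouping = tr_groups,
                     prior = rep(1 / g, g))
    pred[i] <- stats::predict(fit, x[i, , drop = FALSE])$class
  }
  if (length(skipped))
    warning(length(skipped), " LOOCV fold(s) skipped (group below 2 samples)")
  keep <- setdiff(seq_len(n), skipped)
  confusion <- table(truth = groups[keep], predicted = pred[keep])
  list(confusion = confusion,
       accuracy = 100 * sum(pred[keep] == groups[keep]) / length(keep),
       skipped = skipped)
}
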