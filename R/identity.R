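#' Cross-validated nearest-centroid decoding of object identity
#'
#' Leave-one-run-out decoding accuracy for the recurring objects: per fold, a
#' DLDA subspace and class centroids are fitted on the training runs only,
#' every held-out recurring trial is projected and assigned to the nearest
#' centroid (Euclidean distance in the standardized subspace; ties broken by
#' the lowest object id), and the overall fraction of correct assignments is
#' returned. Folds whose training runs miss a class are skipped with a
#' warning.
#'
#' @param X Responses, trials x Ndim.
#' @param labels Object ids, length `nrow(X)` (recurring trials only).
#' @param runs Run id per trial, length `nrow(X)`; defines the folds.
#' @param ... Passed to [fit_dlda()].
#' @return Decoding accuracy in \[0, 1\], with attributes `n_classified` and
#'   `per_fold` (data frame of per-fold accuracies).
#' @export
classify_accuracy <- function(X, labels, runs, ...) {
  X <- as.matrix(X)
  stopifnot(length(labels) == nrow(X), length(runs) == nrow(X))
  fold_ids <- unique(runs)
  if (length(fold_ids) < 2L) stop("need at least 2 runs for cross-validation",
    call. = FALSE
  )
  classes <- sort(unique(labels))
  correct <- 0L
  total <- 0L
  per_fold <- list()
  for (f in fold_ids) {
    test <- runs == f
    train_labels <- labels[!test]
    if (!all(classes %in% train_labels)) {
      warning(sprintf("fold %s skipped: class missing from training runs", f))
      next
    }
    sub <- fit_dlda(X[!test, , drop = FALSE], train_labels,
      fitted_on = sprintf("runs != %s", f), ...
    )
    Yt <- project_subspace(sub, X[test, , drop = FALSE])
    # squared distance to every centroid; ties -> lowest object id (first hit)
    d2 <- outer(rowSums(Yt^2), rowSums(sub$class_means^2), "+") -
      2 * Yt %*% t(sub$class_means)
    pred <- sub$classes[apply(d2, 1, which.min)]
    hits <- sum(pred == labels[test])
    correct <- correct + hits
    total <- total + sum(test)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, n = sum(test), accuracy = hits / sum(test))
  }
  if (total == 0L) stop("all folds skipped; no class-complete training split",
    call. = FALSE
  )
  structure(correct / total,
    n_classified = total,
    per_fold = do.call(rbind, per_fold)
  )
}

#' Group-level identity inference via the minimum statistic
#'
#' Tests the global null hypothesis that no observer carries identity
#' information, using the *minimum* cross-validated accuracy over observers
#' as the test statistic: the observed `alpha_min` is compared with its
#' permutation null distribution, obtained by re-running the full
#' cross-validated decoding with object labels permuted within run (the same
#' permutation scheme applied to every observer in each iteration, preserving
#' per-run class counts exactly). `p_min = (1 + #{null >= observed}) /
#' (B + 1)`.
#'
#' @param observers A list with one element per observer, each a list with
#'   `X` (trials x Ndim), `labels` and `runs` as in [classify_accuracy()].
#' @param B Number of permutations, at least 100 (fewer gives an unstable
#'   p-value and is refused).
#' @param seed Integer seed.
#' @param ... Passed to [classify_accuracy()].
#' @return A list: `alpha_min`, `accuracies` (per observer), `p_min`, `null`
#'   (the B null minima).
#' @export
min_statistic_test <- function(observers, B = 1000L, seed = 1L, ...) {
  if (length(observers) < 2L) stop("need at least 2 observers", call. = FALSE)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  acc <- vapply(
    observers,
    function(o) as.numeric(classify_accuracy(o$X, o$labels, o$runs, ...)),
    numeric(1)
  )
  alpha_min <- min(acc)
  null_min <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      min(vapply(observers, function(o) {
        perm <- permute_within_run(o$labels, o$runs)
        as.numeric(classify_accuracy(o$X, perm, o$runs, ...))
      }, numeric(1)))
    }, numeric(1))
  })
  list(
    alpha_min = alpha_min, accuracies = acc,
    p_min = (1 + sum(null_min >= alpha_min)) / (B + 1),
    null = null_min
  )
}

permute_within_run <- function(labels, runs) {
  out <- labels
  for (r in unique(runs)) {
    idx <- which(runs == r)
    out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}
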