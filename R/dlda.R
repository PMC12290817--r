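#' Fit a direct-LDA discriminative subspace
#'
#' Identifies the (kappa - 1)-dimensional subspace that optimally
#' discriminates the kappa response classes (one per recurring object), by
#' direct linear discriminant analysis (DLDA) — the variant of multi-class
#' Fisher LDA that remains tractable when the dimensionality far exceeds the
#' trial count:
#'
#' 1. eigendecompose the between-class scatter and keep the at most
#'    `kappa - 1` eigenvectors with eigenvalue above `tol` times the leading
#'    one, scaled to whiten the between-class scatter;
#' 2. in that space, eigendecompose the within-class scatter and whiten it,
#'    regularizing eigenvalues by `eps` times their mean;
#' 3. standardize every retained dimension to unit variance on the training
#'    data.
#'
#' Dimensions are ordered by decreasing discriminability (between/within
#' variance ratio) and each basis vector's largest-magnitude component is made
#' positive, so the fit is deterministic. The final standardization makes the
#' projected coordinates the "standardized Euclidean (Mahalanobis)" metric in
#' which all distances are measured: projected training responses have unit
#' variance per dimension, so normalized amplitudes sit near 1 and normalized
#' distances between unrelated responses near 1.40.
#'
#' @param X Numeric matrix, trials x Ndim.
#' @param labels Class labels (object ids), length `nrow(X)`; every class
#'   needs at least 2 trials.
#' @param kappa Number of classes; defaults to the number of distinct labels.
#' @param tol Relative rank tolerance for the between-class eigenvalues.
#' @param eps Relative regularization of the within-class eigenvalues.
#' @param fitted_on Free-form identifier of the training data, kept for
#'   leakage audits.
#' @return An object of class `discriminant_subspace`: `basis`
#'   (Ndim x d), `center` (Ndim), `scale` (d), `classes`, `class_means`
#'   (kappa x d, in standardized subspace coordinates), `kappa`, `ndim`,
#'   `fitted_on`.
#' @export
fit_dlda <- function(X, labels, kappa = NULL, tol = 1e-10, eps = 1e-6,
                     fitted_on = NA_character_) {
  X <- as.matrix(X)
  labels <- as.vector(labels)
  if (length(labels) != nrow(X)) stop("labels must match rows of X", call. = FALSE)
  classes <- sort(unique(labels))
  if (is.null(kappa)) kappa <- length(classes)
  if (length(classes) != kappa) {
    stop(sprintf("expected %d classes, found %d", kappa, length(classes)),
      call. = FALSE
    )
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop("every class needs at least 2 trials (underdetermined class)",
      call. = FALSE
    )
  }
  ndim <- ncol(X)
  if (ndim < kappa - 1L) stop("Ndim must be at least kappa - 1", call. = FALSE)
  K <- nrow(X)
  center <- colMeans(X)
  M <- rowsum(X, group = factor(labels, levels = classes), reorder = TRUE)
  M <- M / as.vector(counts) # class means, kappa x Ndim
  A <- (M - matrix(center, kappa, ndim, byrow = TRUE)) *
    sqrt(as.vector(counts) / K) # Sb = t(A) %*% A
  # eigen via the small kappa x kappa Gram matrix
  eg <- eigen(tcrossprod(A), symmetric = TRUE)
  total_scatter <- sum(sweep(X, 2, center)^2) / K
  if (eg$values[1] <= 1e-12 * total_scatter) {
    stop("between-class scatter is degenerate (all class means identical)",
      call. = FALSE
    )
  }
  keep <- which(eg$values > tol * eg$values[1] & eg$values > 0)
  keep <- keep[seq_len(min(length(keep), kappa - 1L))]
  V <- crossprod(A, eg$vectors[, keep, drop = FALSE]) # Ndim x d
  V <- sweep(V, 2, sqrt(eg$values[keep]), "/") # orthonormal eigenvectors
  B1 <- sweep(V, 2, sqrt(eg$values[keep]), "/") # whitens Sb
  # within-class scatter in the whitened between space
  Xw <- X - M[match(labels, classes), , drop = FALSE]
  Zw <- Xw %*% B1
  Sw <- crossprod(Zw) / K
  ew <- eigen(Sw, symmetric = TRUE)
  gam <- ew$values + eps * mean(ew$values)
  B2 <- sweep(ew$vectors, 2, sqrt(gam), "/")
  # discriminability per dimension: between is diag(1/gam) after whitening
  ord <- order(gam) # ascending within-eigenvalue = descending Fisher ratio
  basis <- (B1 %*% B2)[, ord, drop = FALSE]
  # deterministic sign convention
  flip <- apply(basis, 2, function(b) sign(b[which.max(abs(b))]))
  basis <- sweep(basis, 2, flip, "*")
  Y <- (X - matrix(center, K, ndim, byrow = TRUE)) %*% basis
  scale <- apply(Y, 2, stats::sd)
  scale[scale == 0] <- 1
  Ys <- sweep(Y, 2, scale, "/")
  cm <- rowsum(Ys, group = factor(labels, levels = classes)) / as.vector(counts)
  structure(
    list(
      basis = basis, center = center, scale = scale, classes = classes,
      class_means = cm, kappa = kappa, ndim = ndim, fitted_on = fitted_on
    ),
    class = "discriminant_subspace"
  )
}

#' @export
print.discriminant_subspace <- function(x, ...) {
  cat(sprintf(
    "discriminant_subspace: %d classes, Ndim = %d -> %d dimensions (fitted_on: %s)\n",
    x$kappa, x$ndim, ncol(x$basis), x$fitted_on
  ))
  invisible(x)
}

#' Project responses into a fitted discriminative subspace
#'
#' Applies the stored centering, basis and standardization. Works for any
#' trials, including singular-object and held-out trials: the subspace is
#' generic and captures response variance well beyond the classes it was
#' optimized for.
#'
#' @param subspace A [fit_dlda()] result.
#' @param X Numeric matrix, trials x Ndim (Ndim as at fit time).
#' @return Numeric matrix, trials x d, standardized subspace coordinates.
#' @export
project_subspace <- function(subspace, X) {
  if (!inherits(subspace, "discriminant_subspace")) {
    stop("`subspace` must be a discriminant_subspace", call. = FALSE)
  }
  X <- as.matrix(X)
  if (ncol(X) != subspace$ndim) {
    stop(sprintf(
      "X has %d columns but the subspace was fitted on Ndim = %d",
      ncol(X), subspace$ndim
    ), call. = FALSE)
  }
  Y <- (X - matrix(subspace$center, nrow(X), subspace$ndim, byrow = TRUE)) %*%
    subspace$basis
  sweep(Y, 2, subspace$scale, "/")
}

#' Compare the discriminative subspace with principal components
#'
#' Quantifies how the DLDA subspace relates to a plain PCA of the same data:
#' the fraction of total variance captured by the 14 (generally
#' `ncol(basis)`) leading principal components, the fraction of the subspace
#' variance lying within the span of those components, and the distribution
#' of subspace variance over its dimensions.
#'
#' @param subspace A [fit_dlda()] result.
#' @param X Numeric matrix, trials x Ndim.
#' @param n_pc Number of leading principal components to compare against
#'   (default: the subspace dimensionality).
#' @return A list with `pca_frac` (variance fraction in the leading PCs),
#'   `subspace_overlap` (fraction of subspace variance within their span) and
#'   `per_dim_frac` (variance fraction per subspace dimension, sums to 1).
#' @export
variance_report <- function(subspace, X, n_pc = NULL) {
  X <- as.matrix(X)
  d <- ncol(subspace$basis)
  if (is.null(n_pc)) n_pc <- d
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = n_pc)
  total_var <- sum(sv$d^2)
  pca_frac <- sum(sv$d[seq_len(n_pc)]^2) / total_var
  # orthonormalize the (generally oblique) subspace basis
  Q <- qr.Q(qr(subspace$basis))
  S <- Xc %*% Q # subspace content of every trial
  sub_var <- sum(S^2)
  P <- sv$v # Ndim x n_pc orthonormal
  # component of the subspace signal lying in the PC span:
  recon <- S %*% t(Q) # back in original space
  overlap <- sum((recon %*% P)^2) / sub_var
  Yv <- apply(Xc %*% subspace$basis, 2, stats::var)
  list(
    pca_frac = pca_frac,
    subspace_overlap = overlap,
    per_dim_frac = Yv / sum(Yv)
  )
}
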