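#' Normalized amplitude and distance of subspace patterns
#'
#' In the standardized discriminative subspace with `kappa - 1` dimensions,
#' the normalized amplitude of a pattern is the root mean square of its
#' coordinates, `a_k = sqrt(sum(y_k^2) / (kappa - 1))`, and the normalized
#' distance between two patterns is
#' `d_kl = sqrt(sum((y_k - y_l)^2) / (kappa - 1))`. With unit-variance
#' coordinates the mean amplitude sits near 1 and the mean distance between
#' unrelated patterns near 1.40, the value expected between random points
#' (see [expected_random_distance()]).
#'
#' @param y,y_k,y_l Numeric vector of subspace coordinates, or a matrix with
#'   one pattern per row.
#' @param kappa Class count; coordinates must have `kappa - 1` entries.
#' @return Numeric scalar (or vector, for matrix input).
#' @export
normalized_amplitude <- function(y, kappa = NULL) {
  if (is.matrix(y)) {
    check_kappa(ncol(y), kappa)
    return(sqrt(rowMeans(y^2)))
  }
  check_kappa(length(y), kappa)
  sqrt(mean(y^2))
}

#' @rdname normalized_amplitude
#' @export
normalized_distance <- function(y_k, y_l, kappa = NULL) {
  if (length(y_k) != length(y_l)) {
    stop("patterns must have equal length", call. = FALSE)
  }
  check_kappa(length(y_k), kappa)
  sqrt(mean((y_k - y_l)^2))
}

check_kappa <- function(len, kappa) {
  if (!is.null(kappa) && len != kappa - 1L) {
    stop(sprintf("expected kappa - 1 = %d coordinates, got %d", kappa - 1L, len),
      call. = FALSE
    )
  }
  invisible(len)
}

#' Expected distance between random points on a hypersphere
#'
#' Mean Euclidean distance between two independent uniformly random points on
#' the n-dimensional unit-radius hypersphere (the sphere S^n embedded in
#' (n+1)-dimensional space):
#' `d_ave(n) = 2^n * Gamma((n+1)/2)^2 / (sqrt(pi) * Gamma(n + 1/2))`.
#' The circle is `n = 1` (`4/pi`), the ordinary sphere `n = 2` (`4/3`), and
#' `d_ave(14) = 1.4017`, the baseline for normalized distances in the
#' 14-dimensional discriminative subspace. The value increases monotonically
#' towards `sqrt(2)` as n grows.
#'
#' @param n Sphere dimension, positive integer.
#' @return Numeric scalar.
#' @examples
#' expected_random_distance(14)
#' @export
expected_random_distance <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  exp(n * log(2) + 2 * lgamma((n + 1) / 2) - 0.5 * log(pi) - lgamma(n + 1 / 2))
}

#' Pairwise within-run distances between projected trials
#'
#' Computes, for every within-run pair of recurring trials, the normalized
#' distance between projected responses together with the object pair and the
#' latency (difference of trial indices, in trials; singular trials occupy
#' index positions but contribute no pairs). Cross-run pairs are never formed.
#'
#' @param Y Projected responses, trials x (kappa - 1), row-aligned with
#'   `meta`.
#' @param meta Trial metadata data frame with columns `run_id`,
#'   `trial_index`, `object_id`, `is_recurring` (e.g.
#'   `parcel_response_set$trial_meta`).
#' @param observer_id Observer label stored with every record.
#' @param parcel_id Parcel label stored with every record.
#' @return A `pairwise_distance_set` data frame: `observer_id`, `parcel_id`,
#'   `run_id`, `k`, `l` (trial indices, `k < l`), `i`, `j` (object pair,
#'   `i <= j`), `delay` (`l - k`), `d_raw`, and `d_corr` (NA until
#'   [residual_correct()]).
#' @export
compute_pairwise <- function(Y, meta, observer_id = 1L, parcel_id = "parcel1") {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(meta)) {
    stop("meta must be row-aligned with Y", call. = FALSE)
  }
  need <- c("run_id", "trial_index", "object_id", "is_recurring")
  if (!all(need %in% names(meta))) {
    stop("meta must have columns run_id, trial_index, object_id, is_recurring",
      call. = FALSE
    )
  }
  d <- ncol(Y)
  out <- vector("list", length(unique(meta$run_id)))
  n <- 0L
  for (r in unique(meta$run_id)) {
    rows <- which(meta$run_id == r & meta$is_recurring)
    if (length(rows) < 2L) next
    Dr <- as.matrix(stats::dist(Y[rows, , drop = FALSE])) / sqrt(d)
    idx <- which(upper.tri(Dr), arr.ind = TRUE)
    ki <- meta$trial_index[rows[idx[, 1]]]
    li <- meta$trial_index[rows[idx[, 2]]]
    oi <- meta$object_id[rows[idx[, 1]]]
    oj <- meta$object_id[rows[idx[, 2]]]
    n <- n + 1L
    out[[n]] <- data.frame(
      observer_id = observer_id, parcel_id = parcel_id, run_id = r,
      k = ki, l = li,
      i = pmin(oi, oj), j = pmax(oi, oj),
      delay = li - ki,
      d_raw = Dr[idx], d_corr = NA_real_
    )
  }
  if (n == 0L) stop("no run contains 2 or more recurring trials", call. = FALSE)
  res <- do.call(rbind, out[seq_len(n)])
  class(res) <- c("pairwise_distance_set", "data.frame")
  res
}

#' Delay-dependent average distance profile
#'
#' The average distance `T(delay)` over all trial pairs at each latency,
#' pooled over observers and runs (for one parcel). Adjacent trials in the
#' overlapping-window regime are measured against partially shared signal, so
#' raw distances dip at short delays; this profile is the estimate of that
#' temporal-autocorrelation footprint that [residual_correct()] removes.
#'
#' @param dset A [compute_pairwise()] result (one parcel, any number of
#'   observers/runs).
#' @param include_same_object Include pairs of trials showing the same object
#'   (default TRUE; the profile describes temporal correlation of responses,
#'   not object structure).
#' @return A `delay_profile` data frame with columns `delay`, `t_mean`,
#'   `n_pairs`, and attribute `grand_mean` — the unweighted mean of `t_mean`
#'   over defined delays.
#' @export
delay_profile <- function(dset, include_same_object = TRUE) {
  if (nrow(dset) == 0L) stop("dset is empty", call. = FALSE)
  d <- dset
  if (!include_same_object) d <- d[d$i != d$j, , drop = FALSE]
  agg <- stats::aggregate(d$d_raw, by = list(delay = d$delay), FUN = mean)
  cnt <- stats::aggregate(d$d_raw, by = list(delay = d$delay), FUN = length)
  prof <- data.frame(delay = agg$delay, t_mean = agg$x, n_pairs = cnt$x)
  prof <- prof[order(prof$delay), ]
  rownames(prof) <- NULL
  attr(prof, "grand_mean") <- mean(prof$t_mean)
  class(prof) <- c("delay_profile", "data.frame")
  prof
}

#' Residualize distances against the delay profile
#'
#' Subtracts the average effect of temporal correlation from every pairwise
#' distance: `d_corr = d_raw - T(delay) + mean(T)`, where `mean(T)` is the
#' unweighted average of the profile over delays. When the profile was
#' computed from the same data, the delay-conditional means of the corrected
#' distances are all equal to `mean(T)`; correcting twice changes nothing.
#'
#' @param dset A [compute_pairwise()] result.
#' @param profile A [delay_profile()] covering every delay present in `dset`;
#'   a missing delay is an error (no silent fallback).
#' @return `dset` with `d_corr` filled.
#' @export
residual_correct <- function(dset, profile) {
  pos <- match(dset$delay, profile$delay)
  if (anyNA(pos)) {
    missing <- sort(unique(dset$delay[is.na(pos)]))
    stop(sprintf(
      "profile does not cover delay(s): %s",
      paste(utils::head(missing, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  dset$d_corr <- dset$d_raw - profile$t_mean[pos] + attr(profile, "grand_mean")
  dset
}
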