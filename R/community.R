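#' Community sensitivity of a parcel
#'
#' Splits corrected pairwise distances between *distinct* recurring objects
#' into within-community and between-community groups and computes the mean
#' of each, the signed difference `delta_bw = D_B - D_W` ("community
#' sensitivity"; positive means responses to objects of the same community are
#' relatively closer), and a two-sample t-statistic with its p-value. Only
#' pairs with latency at or above `tau_lb` enter.
#'
#' @param dset A corrected [pairwise_distance_set][compute_pairwise] (one
#'   parcel; observers and runs pooled).
#' @param pair_types A [classify_pairs()] table for the graph in force.
#' @param tau_lb Lower latency bound (trials), default 1.
#' @param var_equal Use the pooled-variance Student t-test (default TRUE);
#'   Welch when FALSE.
#' @param use Distance column to test, `"d_corr"` (default) or `"d_raw"`.
#' @return A list: `d_w`, `d_b`, `delta_bw`, `t_bw`, `p`, `n_w`, `n_b`,
#'   `tau_lb`.
#' @export
community_sensitivity <- function(dset, pair_types, tau_lb = 1L,
                                  var_equal = TRUE, use = c("d_corr", "d_raw")) {
  use <- match.arg(use)
  g <- community_groups(dset, pair_types, tau_lb, use)
  if (length(g$within) < 2L || length(g$between) < 2L) {
    stop("insufficient data: a community group has fewer than 2 distances",
      call. = FALSE
    )
  }
  tt <- stats::t.test(g$between, g$within, var.equal = var_equal)
  list(
    d_w = mean(g$within), d_b = mean(g$between),
    delta_bw = mean(g$between) - mean(g$within),
    t_bw = unname(tt$statistic), p = tt$p.value,
    n_w = length(g$within), n_b = length(g$between), tau_lb = tau_lb
  )
}

# distances of distinct-object pairs at latency >= tau_lb, split by community
community_groups <- function(dset, pair_types, tau_lb, use) {
  if (anyNA(dset[[use]])) {
    stop(sprintf("column %s contains NA; run residual_correct() first?", use),
      call. = FALSE
    )
  }
  tm <- pair_type_matrix(pair_types)
  keep <- dset$i != dset$j & dset$delay >= tau_lb &
    dset$i <= nrow(tm) & dset$j <= nrow(tm)
  d <- dset[keep, , drop = FALSE]
  type <- tm[cbind(d$i, d$j)]
  within <- type %in% c("SA", "SN")
  list(within = d[[use]][within], between = d[[use]][!within])
}

#' Latency sweep and the consistency criterion for community sensitivity
#'
#' Recomputes the community-sensitivity t-statistic for every lower latency
#' bound `tau_lb` in `1..tau_max`, adjusting p-values for false discovery
#' across parcels within each bound (Benjamini-Hochberg, level `q`). The
#' consistency measure `tau_sig` of a parcel is the largest bound up to which
#' the test is significant at *every* bound (0 if not significant at bound
#' 1); a parcel is *community sensitive* only if `tau_sig >= tau_max`, which
#' rules out effects driven by temporal proximity alone. A bound with an
#' empty group is treated as non-significant for that parcel.
#'
#' @param dsets A named list of corrected
#'   [pairwise_distance_set][compute_pairwise]s, one per parcel (a single set
#'   is accepted).
#' @inheritParams community_sensitivity
#' @param tau_max Largest lower bound in the sweep (default 30).
#' @param q FDR level (default 0.05).
#' @return A `sensitivity_report` data frame, one row per parcel:
#'   `parcel_id`, `d_w`, `d_b`, `delta_bw`, `t_bw`, `p`, `p_adj` (at bound
#'   1), `tau_sig`, `sensitive`, `sign`. Attributes `sweep_t`, `sweep_p` and
#'   `sweep_p_adj` hold parcel x bound matrices.
#' @export
latency_sweep <- function(dsets, pair_types, tau_max = 30L, q = 0.05,
                          var_equal = TRUE, use = c("d_corr", "d_raw")) {
  use <- match.arg(use)
  if (is.data.frame(dsets)) dsets <- list(dsets)
  np <- length(dsets)
  ids <- names(dsets)
  if (is.null(ids)) {
    ids <- vapply(dsets, function(d) as.character(d$parcel_id[1]), character(1))
  }
  t_mat <- p_mat <- matrix(NA_real_, np, tau_max, dimnames = list(ids, NULL))
  base <- vector("list", np)
  for (w in seq_len(np)) {
    for (tau in seq_len(tau_max)) {
      res <- tryCatch(
        community_sensitivity(dsets[[w]], pair_types, tau,
          var_equal = var_equal, use = use
        ),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        t_mat[w, tau] <- res$t_bw
        p_mat[w, tau] <- res$p
        if (tau == 1L) base[[w]] <- res
      }
    }
  }
  p_adj <- apply(p_mat, 2, fdr_adjust_na)
  if (np == 1L) p_adj <- matrix(p_adj, nrow = 1L)
  sig <- !is.na(p_adj) & p_adj < q
  tau_sig <- apply(sig, 1, function(s) {
    runlen <- which(!s)
    if (length(runlen) == 0L) length(s) else runlen[1] - 1L
  })
  report <- data.frame(
    parcel_id = ids,
    d_w = vapply(base, function(b) if (is.null(b)) NA_real_ else b$d_w, 0),
    d_b = vapply(base, function(b) if (is.null(b)) NA_real_ else b$d_b, 0),
    delta_bw = vapply(base, function(b) if (is.null(b)) NA_real_ else b$delta_bw, 0),
    t_bw = vapply(base, function(b) if (is.null(b)) NA_real_ else b$t_bw, 0),
    p = vapply(base, function(b) if (is.null(b)) NA_real_ else b$p, 0),
    p_adj = p_adj[, 1],
    tau_sig = as.integer(tau_sig),
    sensitive = tau_sig >= tau_max,
    sign = ifelse(tau_sig >= tau_max, sign(t_mat[, 1]), 0)
  )
  rownames(report) <- NULL
  attr(report, "sweep_t") <- t_mat
  attr(report, "sweep_p") <- p_mat
  attr(report, "sweep_p_adj") <- p_adj
  attr(report, "q") <- q
  attr(report, "tau_max") <- tau_max
  class(report) <- c("sensitivity_report", "data.frame")
  report
}

fdr_adjust_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- fdr_adjust(p[ok])
  out
}

#' Pair-type distance statistics
#'
#' For each of the four object-pair types (SA, DA, SN, DN) on the structured
#' graph, compares that type's corrected distances against the pooled
#' distances of all four types (which include the tested type's own members)
#' with a two-sample t-test. Negative `t` means the type's pairs are closer
#' than average.
#'
#' @inheritParams community_sensitivity
#' @return A data frame with one row per type: `type`, `mean_d`, `n`, `t`,
#'   `p` (`NA` with a warning for an absent type).
#' @export
pair_type_stats <- function(dset, pair_types, tau_lb = 1L, var_equal = TRUE,
                            use = c("d_corr", "d_raw")) {
  use <- match.arg(use)
  tm <- pair_type_matrix(pair_types)
  keep <- dset$i != dset$j & dset$delay >= tau_lb
  d <- dset[keep, , drop = FALSE]
  type <- tm[cbind(d$i, d$j)]
  pool <- d[[use]]
  out <- lapply(c("SA", "DA", "SN", "DN"), function(tp) {
    x <- pool[type == tp]
    if (length(x) < 2L) {
      warning(sprintf("pair type %s has fewer than 2 distances", tp))
      return(data.frame(
        type = tp, mean_d = NA_real_, n = length(x),
        t = NA_real_, p = NA_real_
      ))
    }
    tt <- stats::t.test(x, pool, var.equal = var_equal)
    data.frame(
      type = tp, mean_d = mean(x), n = length(x),
      t = unname(tt$statistic), p = tt$p.value
    )
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of p-values across parcels (wrapper around
#' [stats::p.adjust()] with domain validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, monotone and bounded by 1.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
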