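#' Object-by-object distance matrix from corrected pairwise distances
#'
#' Averages corrected distances per object pair within each run, then
#' averages the run matrices (per observer). A pair never co-occurring in a
#' run contributes nothing to that run; a pair co-occurring in no run is `NA`
#' in the result. The matrix is symmetric with a zero diagonal by convention
#' (the same-object entries measure response reliability, not identity, and
#' are excluded from the geometric summaries).
#'
#' @param dset A corrected [pairwise_distance_set][compute_pairwise] for one
#'   (parcel, observer).
#' @param n_objects Number of recurring objects (default 15).
#' @param use Distance column, `"d_corr"` (default) or `"d_raw"`.
#' @return A symmetric `n_objects` x `n_objects` matrix.
#' @export
object_distance_matrix <- function(dset, n_objects = 15L, use = c("d_corr", "d_raw")) {
  use <- match.arg(use)
  if (anyNA(dset[[use]])) {
    stop(sprintf("column %s contains NA; run residual_correct() first?", use),
      call. = FALSE
    )
  }
  d <- dset[dset$i != dset$j & dset$i <= n_objects & dset$j <= n_objects, ,
    drop = FALSE
  ]
  sum_m <- matrix(0, n_objects, n_objects)
  cnt_m <- matrix(0L, n_objects, n_objects)
  for (r in unique(d$run_id)) {
    dr <- d[d$run_id == r, , drop = FALSE]
    agg <- stats::aggregate(dr[[use]], by = list(i = dr$i, j = dr$j), FUN = mean)
    idx <- cbind(agg$i, agg$j)
    sum_m[idx] <- sum_m[idx] + agg$x
    cnt_m[idx] <- cnt_m[idx] + 1L
  }
  M <- ifelse(cnt_m > 0L, sum_m / pmax(cnt_m, 1L), NA_real_)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 0
  M
}

#' Automorphisms of the modular community graph
#'
#' Enumerates every node permutation that preserves both adjacency and
#' community membership. The group is constructed from the 6 symmetries of
#' the community triangle combined with the `3! = 6` permutations of the
#' internal objects within each community (boundary objects are forced by the
#' triangle symmetry, since each one is identified by the neighbouring
#' community it links to), giving `6 * 6^3 = 1296` permutations; every
#' permutation is verified to preserve adjacency before it is returned.
#'
#' @param graph The modular [community_graph][build_modular_graph].
#' @return A list of integer permutation vectors `p` (node `v` maps to
#'   `p[v]`); the identity comes first.
#' @export
graph_automorphisms <- function(graph) {
  stopifnot_graph(graph)
  if (graph$type != "modular") {
    stop("automorphism enumeration supports the modular graph only", call. = FALSE)
  }
  adj <- graph$adjacency
  comms <- sort(unique(graph$community))
  members <- lapply(comms, function(cm) which(graph$community == cm))
  internal <- lapply(members, function(m) m[graph$role[m] == "internal"])
  boundary <- lapply(members, function(m) m[graph$role[m] == "boundary"])
  perms3 <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  out <- list()
  for (sigma in perms3) {
    # boundary mapping forced: the boundary node of community c linking to
    # community t must map to the boundary node of sigma[c] linking to sigma[t]
    bmap <- integer(15L)
    ok <- TRUE
    for (cm in comms) {
      for (b in boundary[[cm]]) {
        target_comm <- sigma[cm]
        target_link <- sigma[graph$boundary_partner[b]]
        cand <- boundary[[target_comm]][
          graph$boundary_partner[boundary[[target_comm]]] == target_link
        ]
        if (length(cand) != 1L) {
          ok <- FALSE
          break
        }
        bmap[b] <- cand
      }
      if (!ok) break
    }
    if (!ok) next
    for (i1 in perms3) {
      for (i2 in perms3) {
        for (i3 in perms3) {
          p <- bmap
          p[internal[[1]]] <- internal[[sigma[1]]][i1]
          p[internal[[2]]] <- internal[[sigma[2]]][i2]
          p[internal[[3]]] <- internal[[sigma[3]]][i3]
          if (all(adj[p, p] == adj)) out[[length(out) + 1L]] <- p
        }
      }
    }
  }
  is_id <- vapply(out, function(p) all(p == seq_len(15L)), logical(1))
  c(out[is_id], out[!is_id])
}

#' Average a distance matrix over graph automorphisms
#'
#' Distance matrices of different observers cannot be averaged entry-wise —
#' observers need not share activity patterns, and object identities are
#' arbitrary with respect to graph structure. Averaging each matrix over all
#' structure-preserving permutations first makes the result depend only on
#' the graph-structural relation of each pair, after which observer averaging
#' is meaningful. The exact group average over the 1296 automorphisms is used
#' by default; a Monte-Carlo mode drawing `n_samples` random group elements
#' reproduces the sampled-permutation estimator and converges to the exact
#' average.
#'
#' @param M A symmetric 15 x 15 matrix.
#' @param perms Automorphism list from [graph_automorphisms()] (computed from
#'   the canonical modular graph when omitted).
#' @param n_samples If given, average over this many uniformly sampled group
#'   elements instead of the exact group.
#' @param seed Seed for the sampled mode.
#' @return The averaged matrix; exact averaging is idempotent and leaves the
#'   off-diagonal grand mean unchanged.
#' @export
permutation_average <- function(M, perms = NULL, n_samples = NULL, seed = 1L) {
  if (!isTRUE(all.equal(M, t(M)))) stop("M must be symmetric", call. = FALSE)
  if (is.null(perms)) perms <- graph_automorphisms(build_modular_graph())
  if (!is.null(n_samples)) {
    perms <- withr::with_seed(
      seed,
      perms[sample.int(length(perms), n_samples, replace = TRUE)]
    )
  }
  acc <- matrix(0, nrow(M), ncol(M))
  for (p in perms) {
    ip <- integer(length(p))
    ip[p] <- seq_along(p) # M entry for (u, v) read from (p^-1 u, p^-1 v)
    acc <- acc + M[ip, ip]
  }
  acc / length(perms)
}

#' Two-dimensional embedding of an object distance matrix
#'
#' Nonmetric multidimensional scaling (stress-1 criterion, [MASS::isoMDS()])
#' of a 15 x 15 distance matrix into the plane, taking the best of
#' `n_restarts` random initializations plus the classical-scaling start.
#' After automorphism averaging the embedded maps inherit the three-fold
#' rotational symmetry of the community triangle.
#'
#' @param M Symmetric non-negative matrix (zero diagonal).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of random initializations (default 20).
#' @param k Embedding dimension (default 2).
#' @param metric Use classical (metric) scaling instead (default FALSE).
#' @param graph Optional [community_graph][build_modular_graph] supplying
#'   community and role annotation for the output.
#' @return An `embedding_map` list: `points` (n x k), `stress` (percent, 0
#'   for metric scaling), `community`, `role`.
#' @export
mds_embed <- function(M, seed = 1L, n_restarts = 20L, k = 2L, metric = FALSE,
                      graph = NULL) {
  n <- nrow(M)
  D <- stats::as.dist(M)
  if (all(abs(M[upper.tri(M)] - mean(M[upper.tri(M)])) < 1e-12)) {
    warning("all off-diagonal distances equal; embedding is degenerate")
  }
  if (metric) {
    pts <- stats::cmdscale(D, k = k)
    stress <- 0
  } else {
    fits <- withr::with_seed(seed, {
      inits <- c(
        list(stats::cmdscale(D, k = k)),
        lapply(seq_len(n_restarts), function(r) matrix(stats::rnorm(n * k), n, k))
      )
      lapply(inits, function(y0) {
        tryCatch(
          suppressMessages(MASS::isoMDS(D, y = y0, k = k, trace = FALSE)),
          error = function(e) NULL
        )
      })
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) stop("MDS failed for every initialization", call. = FALSE)
    best <- fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
    pts <- best$points
    stress <- best$stress
  }
  structure(
    list(
      points = pts, stress = stress,
      community = if (!is.null(graph)) graph$community else NULL,
      role = if (!is.null(graph)) graph$role else NULL
    ),
    class = "embedding_map"
  )
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf(
    "embedding_map: %d points in %d dimensions, stress = %.3f\n",
    nrow(x$points), ncol(x$points), x$stress
  ))
  invisible(x)
}

#' Internal vs linking object distance summary
#'
#' Cross-tabulates the off-diagonal entries of object distance matrices by
#' the role pair (internal-internal, internal-linking, linking-linking) and
#' community relation (within, between) of each object pair, returning the
#' mean and standard error per cell. With a list of matrices (one per parcel)
#' the standard error is over parcels; with a single matrix it is over pair
#' entries.
#'
#' @param M A 15 x 15 matrix or a list of them.
#' @param graph The modular [community_graph][build_modular_graph].
#' @return A data frame with columns `role_pair`, `relation`, `mean`, `se`,
#'   `n_pairs`.
#' @export
internal_linking_summary <- function(M, graph) {
  stopifnot_graph(graph)
  mats <- if (is.list(M)) M else list(M)
  idx <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  role_i <- graph$role[idx[, 1]]
  role_j <- graph$role[idx[, 2]]
  role_pair <- ifelse(role_i == "internal" & role_j == "internal",
    "internal-internal",
    ifelse(role_i == "boundary" & role_j == "boundary",
      "linking-linking", "internal-linking"
    )
  )
  relation <- ifelse(graph$community[idx[, 1]] == graph$community[idx[, 2]],
    "within", "between"
  )
  cells <- expand.grid(
    role_pair = c("internal-internal", "internal-linking", "linking-linking"),
    relation = c("within", "between"), stringsAsFactors = FALSE
  )
  per_parcel <- vapply(mats, function(m) {
    vals <- m[idx]
    vapply(seq_len(nrow(cells)), function(cc) {
      sel <- role_pair == cells$role_pair[cc] & relation == cells$relation[cc]
      if (any(sel)) mean(vals[sel], na.rm = TRUE) else NA_real_
    }, numeric(1))
  }, numeric(nrow(cells)))
  per_parcel <- matrix(per_parcel, nrow = nrow(cells))
  if (length(mats) > 1L) {
    cells$mean <- rowMeans(per_parcel, na.rm = TRUE)
    cells$se <- apply(per_parcel, 1, stats::sd, na.rm = TRUE) / sqrt(length(mats))
  } else {
    vals <- mats[[1]][idx]
    cells$mean <- per_parcel[, 1]
    cells$se <- vapply(seq_len(nrow(cells)), function(cc) {
      sel <- role_pair == cells$role_pair[cc] & relation == cells$relation[cc]
      x <- vals[sel]
      if (length(x) > 1L) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
    }, numeric(1))
  }
  cells$n_pairs <- vapply(seq_len(nrow(cells)), function(cc) {
    sum(role_pair == cells$role_pair[cc] & relation == cells$relation[cc])
  }, integer(1))
  cells
}
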