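#' Corrected pairwise distances for every parcel of a study
#'
#' Runs the distance stage of the pipeline on a simulated (or ingested)
#' study bundle: per (parcel, observer), fit a DLDA subspace on the recurring
#' trials, project all trials, and collect within-run pairwise distances;
#' then, per parcel, estimate the delay profile pooled over observers and
#' runs and residualize the distances against it.
#'
#' @param study A [simulate_study()] bundle.
#' @param subspace_fit `"cross-run"` (default) fits, for every run, the
#'   subspace on the *other* runs and projects only the held-out run before
#'   measuring its distances; `"all"` fits once per (observer, parcel) on all
#'   recurring trials. Cross-run fitting keeps the subspace independent of
#'   the responses whose distances it measures: fitting on the same data lets
#'   temporally clustered drift leak into the apparent class structure, which
#'   biases within-community distances downward at *every* latency and
#'   survives both the residual correction and the latency sweep.
#' @param include_same_object Passed to [delay_profile()].
#' @param ... Passed to [fit_dlda()].
#' @return A named list, one element per parcel, each a list with `dset`
#'   (corrected [pairwise_distance_set][compute_pairwise], observers pooled),
#'   `profile` (the parcel's [delay_profile()]), and `subspaces` (per
#'   observer; per run fold for cross-run fitting).
#' @export
parcel_distances <- function(study, subspace_fit = c("cross-run", "all"),
                             include_same_object = TRUE, ...) {
  subspace_fit <- match.arg(subspace_fit)
  specs <- study$specs
  out <- vector("list", length(specs))
  names(out) <- vapply(specs, function(s) s$parcel_id, character(1))
  for (p in names(out)) {
    sets <- vector("list", length(study$observers))
    subs <- vector("list", length(study$observers))
    for (u in seq_along(study$observers)) {
      obs <- study$observers[[u]]
      prs <- obs$parcels[[p]]
      meta <- prs$trial_meta
      rec <- meta$is_recurring
      if (subspace_fit == "all") {
        sub <- fit_dlda(prs$responses[rec, , drop = FALSE],
          meta$object_id[rec],
          fitted_on = sprintf("observer %d, parcel %s, all runs", u, p), ...
        )
        Y <- project_subspace(sub, prs$responses)
        sets[[u]] <- compute_pairwise(Y, meta,
          observer_id = obs$observer_id, parcel_id = p
        )
        subs[[u]] <- sub
      } else {
        run_ids <- unique(meta$run_id)
        if (length(run_ids) < 2L) {
          stop("cross-run subspace fitting needs at least 2 runs", call. = FALSE)
        }
        fold_sets <- vector("list", length(run_ids))
        fold_subs <- vector("list", length(run_ids))
        for (f in seq_along(run_ids)) {
          train <- rec & meta$run_id != run_ids[f]
          sub <- fit_dlda(prs$responses[train, , drop = FALSE],
            meta$object_id[train],
            fitted_on = sprintf(
              "observer %d, parcel %s, runs != %s", u, p, run_ids[f]
            ), ...
          )
          rows <- meta$run_id == run_ids[f]
          Y <- project_subspace(sub, prs$responses[rows, , drop = FALSE])
          fold_sets[[f]] <- compute_pairwise(Y, meta[rows, , drop = FALSE],
            observer_id = obs$observer_id, parcel_id = p
          )
          fold_subs[[f]] <- sub
        }
        sets[[u]] <- do.call(rbind, fold_sets)
        subs[[u]] <- fold_subs
      }
    }
    dset <- do.call(rbind, sets)
    class(dset) <- c("pairwise_distance_set", "data.frame")
    profile <- delay_profile(dset, include_same_object = include_same_object)
    dset <- residual_correct(dset, profile)
    out[[p]] <- list(dset = dset, profile = profile, subspaces = subs)
  }
  out
}

#' Community-structure analysis of a study
#'
#' Applies the latency sweep with FDR control across parcels to the corrected
#' distances of every parcel, and appends per-parcel pair-type statistics.
#'
#' @param distances A [parcel_distances()] result (or a study bundle, which
#'   is passed through [parcel_distances()] first).
#' @param graph The community graph in force (defaults to the study's graph
#'   when a bundle is given, else the canonical modular graph).
#' @inheritParams latency_sweep
#' @return A [sensitivity_report][latency_sweep] with extra columns `t_SA`,
#'   `t_DA`, `t_SN`, `t_DN`.
#' @export
analyze_community <- function(distances, graph = NULL, tau_max = 30L, q = 0.05,
                              var_equal = TRUE, use = "d_corr") {
  if (inherits(distances, "study_bundle")) {
    if (is.null(graph)) graph <- distances$graph
    distances <- parcel_distances(distances)
  }
  if (is.null(graph)) graph <- build_modular_graph()
  pt <- classify_pairs(graph)
  dsets <- lapply(distances, `[[`, "dset")
  report <- latency_sweep(dsets, pt,
    tau_max = tau_max, q = q,
    var_equal = var_equal, use = use
  )
  tt <- lapply(dsets, function(d) {
    suppressWarnings(pair_type_stats(d, pt, var_equal = var_equal, use = use))
  })
  for (tp in c("SA", "DA", "SN", "DN")) {
    report[[paste0("t_", tp)]] <-
      vapply(tt, function(x) x$t[x$type == tp], numeric(1))
  }
  report
}

#' Identity-selectivity analysis of a study
#'
#' Per parcel: cross-validated nearest-centroid decoding accuracy for every
#' observer (leave-one-run-out, recurring trials), the minimum accuracy
#' across observers, and its permutation p-value ([min_statistic_test()]).
#'
#' @param study A [simulate_study()] bundle.
#' @param B Permutations for the minimum-statistic test (default 200).
#' @param seed Integer seed.
#' @param alpha Significance level for the `selective` flag.
#' @param ... Passed to [classify_accuracy()].
#' @return A data frame, one row per parcel: `parcel_id`, `alpha_min`,
#'   `p_min`, `selective`, plus one accuracy column per observer. The per-
#'   parcel test results are attached as attribute `tests`.
#' @export
analyze_identity <- function(study, B = 200L, seed = 1L, alpha = 0.05, ...) {
  ids <- vapply(study$specs, function(s) s$parcel_id, character(1))
  tests <- vector("list", length(ids))
  names(tests) <- ids
  rows <- vector("list", length(ids))
  for (p in seq_along(ids)) {
    observers <- lapply(study$observers, function(obs) {
      prs <- obs$parcels[[ids[p]]]
      rec <- prs$trial_meta$is_recurring
      list(
        X = prs$responses[rec, , drop = FALSE],
        labels = prs$trial_meta$object_id[rec],
        runs = prs$trial_meta$run_id[rec]
      )
    })
    res <- min_statistic_test(observers, B = B, seed = seed + p, ...)
    tests[[p]] <- res
    acc <- as.list(res$accuracies)
    names(acc) <- paste0("acc_obs", seq_along(acc))
    rows[[p]] <- data.frame(
      parcel_id = ids[p], alpha_min = res$alpha_min, p_min = res$p_min,
      selective = res$p_min < alpha, acc
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}

#' Automorphism-averaged geometry of a study
#'
#' Per parcel: per-observer object distance matrices, their automorphism
#' averages, the across-observer average, its two-dimensional embedding, and
#' the internal-vs-linking summary.
#'
#' @param distances A [parcel_distances()] result.
#' @param graph The modular [community_graph][build_modular_graph].
#' @param seed Seed for the MDS restarts.
#' @param ... Passed to [mds_embed()].
#' @return A named list per parcel: `observer_matrices`, `averaged` (group-
#'   then observer-averaged matrix), `embedding`, `summary`.
#' @export
analyze_geometry <- function(distances, graph = build_modular_graph(),
                             seed = 1L, ...) {
  perms <- graph_automorphisms(graph)
  out <- vector("list", length(distances))
  names(out) <- names(distances)
  for (p in names(distances)) {
    dset <- distances[[p]]$dset
    obs_ids <- unique(dset$observer_id)
    mats <- lapply(obs_ids, function(u) {
      object_distance_matrix(dset[dset$observer_id == u, , drop = FALSE])
    })
    averaged <- Reduce(`+`, lapply(mats, permutation_average, perms = perms)) /
      length(mats)
    out[[p]] <- list(
      observer_matrices = mats,
      averaged = averaged,
      embedding = mds_embed(averaged, seed = seed, graph = graph, ...),
      summary = internal_linking_summary(averaged, graph)
    )
  }
  out
}
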