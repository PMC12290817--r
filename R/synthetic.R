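#' Specification of a surrogate parcel
#'
#' Describes one simulated functional parcel: its dimensionality and the
#' strengths of the signal components that the downstream analysis is meant to
#' recover. A trial response is generated in `n_t * n_vox` dimensions as
#'
#'   x_k = mu_obj(k) + community_beta * (c_comm(k) - mu_bar) + drift_k + eps_k
#'
#' where the class means `mu_o` are fixed random directions with per-dimension
#' SD `identity_snr * noise_sd`, `c_comm` is the centroid of the class means
#' in the trial object's community and `mu_bar` their grand mean (so
#' `community_beta > 0` pushes communities apart from each other, increasing
#' between-community response distances: within-community attraction in
#' relative terms; `community_beta < 0` has the opposite sign), `drift_k` is a
#' shared additive AR(1) vector across trials (reset between runs) and
#' `eps_k` is isotropic Gaussian noise. Singular trials receive a fresh random
#' mean each and no community term.
#'
#' The default drift parameters are calibrated so that the delay-conditional
#' mean distance profile of projected responses shows an approximately 5%
#' dip at delays below 4 trials, the empirical temporal-autocorrelation regime
#' the residualization stage must remove.
#'
#' @param parcel_id Parcel label (opaque).
#' @param n_vox Voxels per parcel, 45..462 (default 200).
#' @param n_t Time points per trial (default 9).
#' @param identity_snr Ratio of class-mean dispersion to noise SD.
#' @param community_beta Signed community-effect strength.
#' @param drift_rho AR(1) coefficient of the shared drift, in \[0, 1).
#' @param drift_sd Stationary SD of the drift per dimension.
#' @param noise_sd Isotropic noise SD.
#' @return A `parcel_spec` object (validated list).
#' @export
parcel_spec <- function(parcel_id = "parcel1", n_vox = 200L, n_t = 9L,
                        identity_snr = 0.1, community_beta = 0,
                        drift_rho = 0.8, drift_sd = 0.43, noise_sd = 1) {
  spec <- list(
    parcel_id = as.character(parcel_id), n_vox = as.integer(n_vox),
    n_t = as.integer(n_t), identity_snr = identity_snr,
    community_beta = community_beta, drift_rho = drift_rho,
    drift_sd = drift_sd, noise_sd = noise_sd
  )
  num <- unlist(spec[-1])
  if (any(!is.finite(num))) stop("parcel_spec values must be finite", call. = FALSE)
  if (spec$n_vox < 45L || spec$n_vox > 462L) {
    stop("n_vox must be within 45..462 (range of parcel sizes)", call. = FALSE)
  }
  if (spec$n_t < 1L) stop("n_t must be >= 1", call. = FALSE)
  if (spec$drift_rho < 0 || spec$drift_rho >= 1) {
    stop("drift_rho must be in [0, 1)", call. = FALSE)
  }
  if (spec$identity_snr < 0 || spec$drift_sd < 0 || spec$noise_sd < 0) {
    stop("identity_snr, drift_sd and noise_sd must be >= 0", call. = FALSE)
  }
  class(spec) <- "parcel_spec"
  spec
}

#' @export
print.parcel_spec <- function(x, ...) {
  cat(sprintf(
    "parcel_spec '%s': Ndim = %d (%d t x %d vox), identity_snr = %g, beta = %g, drift (rho = %g, sd = %g), noise_sd = %g\n",
    x$parcel_id, x$n_t * x$n_vox, x$n_t, x$n_vox, x$identity_snr,
    x$community_beta, x$drift_rho, x$drift_sd, x$noise_sd
  ))
  invisible(x)
}

# stationary AR(1) drift matrix for one run: n_trials x ndim
ar1_drift <- function(n_trials, ndim, rho, sd) {
  d <- matrix(0, n_trials, ndim)
  if (sd <= 0 || n_trials == 0L) return(d)
  d[1L, ] <- stats::rnorm(ndim, sd = sd)
  if (n_trials > 1L) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (k in 2:n_trials) {
      d[k, ] <- rho * d[k - 1L, ] + stats::rnorm(ndim, sd = innov_sd)
    }
  }
  d
}

#' Simulate multivariate responses for one parcel
#'
#' Generates a trials x Ndim response matrix for the given trial sequences,
#' following the generative model documented in [parcel_spec()]. All trials
#' (recurring and singular) receive responses; community analyses downstream
#' exclude singular trials themselves.
#'
#' @param spec A [parcel_spec()].
#' @param sequences List of `trial_sequence` data frames (one per run).
#' @param graph The [community_graph][build_modular_graph] whose community
#'   labels define the community effect.
#' @param seed Integer seed.
#' @return A list of class `parcel_response_set`: `responses` (K x Ndim
#'   matrix), `trial_meta` (row-aligned data frame: `run_id`, `trial_index`,
#'   `object_id`, `is_recurring`), `parcel_id`, `ground_truth` (class means,
#'   community centroids, drift realizations, the spec and seed).
#' @export
simulate_parcel <- function(spec, sequences, graph, seed) {
  if (!inherits(spec, "parcel_spec")) spec <- do.call(parcel_spec, spec)
  stopifnot_graph(graph)
  if (is.data.frame(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0L) stop("sequences must be non-empty", call. = FALSE)
  ndim <- spec$n_t * spec$n_vox
  n_obj <- length(graph$node_ids)
  meta <- do.call(rbind, lapply(sequences, function(s) {
    s[c("run_id", "trial_index", "object_id", "is_recurring")]
  }))
  rownames(meta) <- NULL
  withr::with_seed(seed, {
    mu <- matrix(stats::rnorm(n_obj * ndim, sd = spec$identity_snr * spec$noise_sd),
      n_obj, ndim
    )
    mu_bar <- colMeans(mu)
    centroids <- t(vapply(
      sort(unique(graph$community)),
      function(cm) colMeans(mu[graph$community == cm, , drop = FALSE]),
      numeric(ndim)
    ))
    eff_means <- mu + spec$community_beta *
      (centroids[graph$community, , drop = FALSE] -
        matrix(mu_bar, n_obj, ndim, byrow = TRUE))
    K <- nrow(meta)
    X <- matrix(0, K, ndim)
    rec <- meta$is_recurring
    X[rec, ] <- eff_means[meta$object_id[rec], , drop = FALSE]
    n_sing <- sum(!rec)
    if (n_sing > 0L) {
      X[!rec, ] <- matrix(
        stats::rnorm(n_sing * ndim, sd = spec$identity_snr * spec$noise_sd),
        n_sing, ndim
      )
    }
    drift <- matrix(0, K, ndim)
    for (r in unique(meta$run_id)) {
      rows <- which(meta$run_id == r)
      drift[rows, ] <- ar1_drift(length(rows), ndim, spec$drift_rho, spec$drift_sd)
    }
    X <- X + drift + matrix(stats::rnorm(K * ndim, sd = spec$noise_sd), K, ndim)
  })
  structure(
    list(
      responses = X, trial_meta = meta, parcel_id = spec$parcel_id,
      ground_truth = list(
        spec = spec, seed = seed, class_means = mu, community_centroids = centroids,
        grand_mean = mu_bar, drift = drift
      )
    ),
    class = "parcel_response_set"
  )
}

#' Simulate a multi-observer study
#'
#' Builds the full study bundle: per observer, independent counterbalanced
#' presentation sequences for the chosen condition, and one response set per
#' parcel spec. Observers receive independent class means — the analysis never
#' assumes shared activity patterns across observers — and independent noise.
#' Fully reproducible from `seed`.
#'
#' @param n_observers Number of observers (the study design uses 8).
#' @param parcel_specs List of [parcel_spec()]s (a single spec is accepted).
#' @param condition `"structured"` (modular graph) or `"unstructured"`
#'   (complete graph with counterfactual community labels).
#' @param runs Runs per observer (the study design uses 18).
#' @param seed Integer seed.
#' @param n_recurring,n_singular Recurring/singular trials per run
#'   (defaults 180/20).
#' @param n_candidates Candidate walks for counterbalancing post-selection.
#' @return A list of class `study_bundle`: `condition`, `graph`, `specs`, and
#'   `observers` — per observer a list with `sequences` (per run) and
#'   `parcels` (named list of `parcel_response_set`s).
#' @export
simulate_study <- function(n_observers, parcel_specs,
                           condition = c("structured", "unstructured"),
                           runs = 18L, seed = 1L,
                           n_recurring = 180L, n_singular = 20L,
                           n_candidates = 200L) {
  condition <- match.arg(condition)
  if (n_observers < 1L) stop("n_observers must be >= 1", call. = FALSE)
  if (inherits(parcel_specs, "parcel_spec")) parcel_specs <- list(parcel_specs)
  graph <- if (condition == "structured") build_modular_graph() else build_complete_graph()
  n_par <- length(parcel_specs)
  seeds <- withr::with_seed(
    seed,
    matrix(
      sample.int(.Machine$integer.max, n_observers * (runs + runs + n_par)),
      nrow = n_observers
    )
  )
  singular_counter <- 1001L
  observers <- vector("list", n_observers)
  for (u in seq_len(n_observers)) {
    sequences <- vector("list", runs)
    for (r in seq_len(runs)) {
      walk <- counterbalance_select(graph, n_candidates, n_recurring,
        seed = seeds[u, r]
      )
      sequences[[r]] <- insert_singulars(walk, n_singular,
        seed = seeds[u, runs + r],
        run_id = r, first_singular_id = singular_counter
      )
      singular_counter <- singular_counter + n_singular
    }
    parcels <- vector("list", n_par)
    for (p in seq_len(n_par)) {
      parcels[[p]] <- simulate_parcel(parcel_specs[[p]], sequences, graph,
        seed = seeds[u, 2L * runs + p]
      )
    }
    names(parcels) <- vapply(parcel_specs, function(s) s$parcel_id, character(1))
    observers[[u]] <- list(observer_id = u, sequences = sequences, parcels = parcels)
  }
  structure(
    list(
      condition = condition, graph = graph, specs = parcel_specs,
      observers = observers, seed = seed
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "study_bundle: %s condition, %d observer(s), %d run(s)/observer, %d parcel(s)\n",
    x$condition, length(x$observers), length(x$observers[[1]]$sequences),
    length(x$specs)
  ))
  invisible(x)
}
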