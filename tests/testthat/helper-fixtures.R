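# Shared fixtures: everything is generated in code at test time.

the_graph <- build_modular_graph()
the_pairs <- classify_pairs(the_graph)

# counterbalanced sequences for `runs` runs (small candidate pool for speed)
make_sequences <- function(runs, seed, graph = the_graph, n_recurring = 180L,
                           n_singular = 20L, n_candidates = 20L) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2L * runs))
  lapply(seq_len(runs), function(r) {
    walk <- counterbalance_select(graph, n_candidates, n_recurring,
      seed = seeds[r]
    )
    insert_singulars(walk, n_singular,
      seed = seeds[runs + r], run_id = r,
      first_singular_id = 1001L + (r - 1L) * n_singular
    )
  })
}

# minimal single-observer study bundle around one simulated parcel
make_study <- function(spec, runs = 6L, seed = 1L, graph = the_graph,
                       n_candidates = 20L) {
  seqs <- make_sequences(runs, seed, graph = graph, n_candidates = n_candidates)
  prs <- simulate_parcel(spec, seqs, graph, seed = seed + 7L)
  structure(
    list(
      condition = if (graph$type == "modular") "structured" else "unstructured",
      graph = graph, specs = list(spec),
      observers = list(list(observer_id = 1L, sequences = seqs,
        parcels = stats::setNames(list(prs), spec$parcel_id)
      ))
    ),
    class = "study_bundle"
  )
}

# corrected distance set for one simulated parcel (cross-run subspace fit)
sim_corrected_dset <- function(seed, identity_snr = 0, community_beta = 0,
                               drift_sd = 0, drift_rho = 0.8, runs = 6L,
                               n_vox = 45L, n_t = 2L, graph = the_graph) {
  spec <- parcel_spec("p1",
    n_vox = n_vox, n_t = n_t, identity_snr = identity_snr,
    community_beta = community_beta, drift_rho = drift_rho, drift_sd = drift_sd
  )
  study <- make_study(spec, runs = runs, seed = seed, graph = graph)
  parcel_distances(study)[["p1"]]
}

# hand-built pairwise distance set with full control over groups
fake_dset <- function(i, j, delay, d, run_id = 1L) {
  out <- data.frame(
    observer_id = 1L, parcel_id = "p1", run_id = run_id,
    k = seq_along(i), l = seq_along(i) + delay,
    i = pmin(i, j), j = pmax(i, j), delay = delay,
    d_raw = d, d_corr = d
  )
  class(out) <- c("pairwise_distance_set", "data.frame")
  out
}
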