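#' Pipeline configuration
#'
#' Collects every knob of the simulate -> project -> distances -> statistics
#' -> geometry pipeline in one validated list. A configuration can also be
#' read from a YAML document with [read_config()].
#'
#' @param condition `"structured"` or `"unstructured"`.
#' @param n_observers,runs Study size (defaults 2 observers x 2 runs: the
#'   demo scale; the full design is 8 x 18).
#' @param parcel_specs List of [parcel_spec()]s.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param alpha Significance level for the identity flag.
#' @param tau_max Largest latency bound of the sweep (default 30).
#' @param q FDR level across parcels (default 0.05).
#' @param identity_B Permutations for the minimum-statistic test.
#' @param run_identity,run_geometry Stage switches.
#' @param n_recurring,n_singular,n_candidates Sequence-generation sizes.
#' @param out_dir Output directory (created by [run_pipeline()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(condition = "structured", n_observers = 2L,
                            runs = 2L, parcel_specs = list(parcel_spec()),
                            seed = 1L, alpha = 0.05, tau_max = 30L, q = 0.05,
                            identity_B = 200L, run_identity = TRUE,
                            run_geometry = TRUE, n_recurring = 180L,
                            n_singular = 20L, n_candidates = 200L,
                            out_dir = tempfile("tcrsa_out")) {
  cfg <- list(
    condition = condition, n_observers = as.integer(n_observers),
    runs = as.integer(runs), parcel_specs = parcel_specs,
    seed = as.integer(seed), alpha = alpha, tau_max = as.integer(tau_max),
    q = q, identity_B = as.integer(identity_B),
    run_identity = isTRUE(run_identity), run_geometry = isTRUE(run_geometry),
    n_recurring = as.integer(n_recurring), n_singular = as.integer(n_singular),
    n_candidates = as.integer(n_candidates), out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  errs <- validate_config(cfg)
  if (!isTRUE(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks ranges and invariants without touching any data.
#'
#' @param config A [pipeline_config()] (or plain list with the same fields).
#' @return `TRUE` if valid, otherwise a character vector of error messages.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(config$condition %in% c("structured", "unstructured"),
    "condition must be 'structured' or 'unstructured'"
  )
  chk(is.numeric(config$n_observers) && config$n_observers >= 1,
    "n_observers must be >= 1"
  )
  chk(is.numeric(config$runs) && config$runs >= 1, "runs must be >= 1")
  chk(length(config$parcel_specs) >= 1, "at least one parcel spec required")
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
    "alpha must be in (0, 1)"
  )
  chk(is.numeric(config$q) && config$q > 0 && config$q < 1,
    "q must be in (0, 1)"
  )
  chk(is.numeric(config$tau_max) && config$tau_max >= 1, "tau_max must be >= 1")
  chk(is.numeric(config$seed) && is.finite(config$seed), "seed must be finite")
  chk(is.character(config$out_dir) && nzchar(config$out_dir),
    "out_dir must be a non-empty path"
  )
  spec_errs <- unlist(lapply(seq_along(config$parcel_specs), function(p) {
    tryCatch(
      {
        do.call(parcel_spec, unclass(config$parcel_specs[[p]]))
        character(0)
      },
      error = function(e) sprintf("parcel_specs[[%d]]: %s", p, conditionMessage(e))
    )
  }))
  errs <- c(errs, spec_errs)
  if (length(errs) == 0L) TRUE else errs
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments, with
#'   `parcel_specs` a list of [parcel_spec()] field maps.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$parcel_specs)) {
    raw$parcel_specs <- lapply(raw$parcel_specs, function(s) do.call(parcel_spec, s))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulation, projection, distance computation, residual
#' correction, community and identity statistics, and geometry in dependency
#' order, writing every stage's outputs as TSV under `config$out_dir` and
#' returning a manifest of output checksums. Re-running with the same
#' configuration and seed reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `run_manifest`: `config`, `files` (data frame of
#'   path, md5), `timings` (seconds per stage), and in-memory `results`
#'   (`study`, `distances`, `community`, `identity`, `geometry`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  errs <- validate_config(config)
  if (!isTRUE(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  say("stage 1/5: simulating %s study (%d observers x %d runs, %d parcels)",
    config$condition, config$n_observers, config$runs,
    length(config$parcel_specs)
  )
  study <- simulate_study(config$n_observers, config$parcel_specs,
    condition = config$condition, runs = config$runs, seed = config$seed,
    n_recurring = config$n_recurring, n_singular = config$n_singular,
    n_candidates = config$n_candidates
  )
  for (u in seq_along(study$observers)) {
    write_sequences(study$observers[[u]]$sequences,
      file.path(config$out_dir, sprintf("sequences_obs%02d.tsv", u)),
      observer_id = u
    )
    for (p in names(study$observers[[u]]$parcels)) {
      utils::write.table(
        round(study$observers[[u]]$parcels[[p]]$responses, 6),
        file.path(config$out_dir, sprintf("responses_obs%02d_%s.tsv", u, p)),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
    }
  }
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  say("stage 2/5: DLDA projection and pairwise distances")
  distances <- parcel_distances(study)
  for (p in names(distances)) {
    utils::write.table(distances[[p]]$dset,
      file.path(config$out_dir, sprintf("distances_%s.tsv", p)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(distances[[p]]$profile,
      file.path(config$out_dir, sprintf("delay_profile_%s.tsv", p)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  timings["distances"] <- tic() - t0

  t0 <- tic()
  say("stage 3/5: community statistics (tau_max = %d, q = %g)",
    config$tau_max, config$q
  )
  community <- analyze_community(distances,
    graph = study$graph,
    tau_max = config$tau_max, q = config$q
  )
  utils::write.table(community, file.path(config$out_dir, "community_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  timings["community"] <- tic() - t0

  identity <- NULL
  if (config$run_identity) {
    t0 <- tic()
    say("stage 4/5: identity decoding (B = %d permutations)", config$identity_B)
    identity <- analyze_identity(study,
      B = config$identity_B,
      seed = config$seed, alpha = config$alpha
    )
    utils::write.table(identity, file.path(config$out_dir, "identity_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    timings["identity"] <- tic() - t0
  }

  geometry <- NULL
  if (config$run_geometry && study$condition == "structured") {
    t0 <- tic()
    say("stage 5/5: automorphism-averaged geometry and MDS")
    geometry <- analyze_geometry(distances,
      graph = study$graph,
      seed = config$seed
    )
    for (p in names(geometry)) {
      utils::write.table(round(geometry[[p]]$averaged, 6),
        file.path(config$out_dir, sprintf("distance_matrix_%s.tsv", p)),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
      emb <- geometry[[p]]$embedding
      utils::write.table(
        data.frame(
          object = seq_len(nrow(emb$points)),
          x = round(emb$points[, 1], 6), y = round(emb$points[, 2], 6),
          community = emb$community, role = emb$role
        ),
        file.path(config$out_dir, sprintf("embedding_%s.tsv", p)),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    timings["geometry"] <- tic() - t0
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    config = config,
    files = data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    ),
    timings = timings,
    results = list(
      study = study, distances = distances, community = community,
      identity = identity, geometry = geometry
    )
  )
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "run_manifest: %d output files in %s (total %.1f s)\n",
    nrow(x$files), x$config$out_dir, sum(x$timings)
  ))
  invisible(x)
}
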