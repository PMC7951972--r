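# Orchestration: single-snapshot profiling, overlap, null model and
# clonotype runs with tabular outputs and a reproducibility manifest.

#' Structurally profile one repertoire snapshot
#'
#' Runs the full per-snapshot pipeline: modellability filtering of VH and
#' VL reads, 90%-identity reduction to cluster centres, combinatorial
#' VH-VL pairing with interface-modellability prediction, and greedy
#' clustering of the predicted modellable Fvs into distinct structures.
#'
#' @param snapshot A [repertoire_snapshot()].
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @return List of class `profile_result`: `row` (one summary row: read
#'   counts, modellable sequence-identity-clustered counts, predicted
#'   modellable Fvs, distinct structures), `fvs`, `clustering`,
#'   `vh_centres`, `vl_centres`, `drops`, `manifest`.
#' @export
run_profile <- function(snapshot, library, config = profiler_config()) {
  t0 <- Sys.time()
  vh_mod <- modellability_filter(snapshot$vh, library)
  vl_mod <- modellability_filter(snapshot$vl, library)
  vh_centres <- greedy_identity_cluster(vh_mod, config$identity_threshold)
  vl_centres <- greedy_identity_cluster(vl_mod, config$identity_threshold)
  fvs <- predict_modellable_fvs(vh_centres, vl_centres, library,
                                config$pairing_threshold)
  fvs <- lapply(fvs, function(f) {
    f$repertoire_id <- snapshot$snapshot_id
    f
  })
  clustering <- cluster_distinct_structures(fvs, library, config)
  row <- data.frame(
    snapshot_id = snapshot$snapshot_id,
    n_vh = length(snapshot$vh), n_vl = length(snapshot$vl),
    mod_vh_sic = length(vh_centres), mod_vl_sic = length(vl_centres),
    fvs = length(fvs),
    distinct_structures = length(clustering$structures),
    stringsAsFactors = FALSE
  )
  structure(
    list(row = row, fvs = fvs, clustering = clustering,
         vh_centres = vh_centres, vl_centres = vl_centres,
         drops = rbind(attr(vh_mod, "drops"), attr(vl_mod, "drops")),
         manifest = run_manifest("profile", config,
                                 inputs = snapshot$snapshot_id, t0 = t0)),
    class = "profile_result"
  )
}

#' @export
print.profile_result <- function(x, ...) {
  print(x$row)
  invisible(x)
}

#' Sequential overlap over profiled repertoires
#'
#' @param profiles Named list of `profile_result` (or of raw Fv lists).
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @param order_by_diversity Most internally diverse repertoire first
#'   (default TRUE).
#' @return An `overlap_result` (see [chain_overlap()]).
#' @export
run_overlap <- function(profiles, library, config = profiler_config(),
                        order_by_diversity = TRUE) {
  fv_lists <- lapply(profiles, function(p) {
    if (inherits(p, "profile_result")) p$fvs else p
  })
  chain_overlap(fv_lists, library, config, order_by_diversity)
}

#' Random-Repertoire null model over profiled repertoires
#'
#' Draws a shared Modellable-Repertoire-Structures sample, restricts it to
#' each repertoire's observed CDR length combinations (LARS), draws one
#' size-matched Random Repertoire per genuine repertoire (without
#' replacement), clusters it, subsamples its distinct structures down to
#' the genuine count, and chains the subsampled sets (in the supplied
#' repertoire order) to obtain expected public-structure counts.
#'
#' @param profiles Named, ordered list of `profile_result`.
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @param n_mrs Size of the shared MRS draw; defaults to 25x the largest
#'   repertoire's Fv count (LARS sets are then typically 10-20x larger
#'   than the Fv counts they are resampled to).
#' @param seed Master seed; per-stage sub-seeds are derived from it.
#' @return List of class `null_model_result`: `rr_rows` (per-repertoire
#'   data frame: Fv count, RR distinct structures, Fvs per distinct
#'   structure), `expected` (an `overlap_result`), `mrs_size`.
#' @export
run_null_model <- function(profiles, library, config = profiler_config(),
                           n_mrs = NULL, seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  n_fvs <- vapply(profiles, function(p) length(p$fvs), 1L)
  if (is.null(n_mrs)) n_mrs <- 25L * max(n_fvs)
  mrs <- sample_mrs(library, n_mrs, seed = substream_seed(seed, 1L))
  rr_rows <- list()
  rr_sets <- list()
  rr_samples <- list()
  for (k in seq_along(profiles)) {
    id <- names(profiles)[k]
    p <- profiles[[k]]
    lars <- build_lars(mrs, observed_length_vectors(p$fvs))
    rr <- sample_random_repertoire(lars, n_fvs[k],
                                   seed = substream_seed(seed, 10L + k),
                                   repertoire_id = id)
    rr_clust <- cluster_distinct_structures(rr, library, config)
    n_genuine <- length(p$clustering$structures)
    rr_sets[[id]] <- subsample_distinct(rr_clust$structures,
                                        min(n_genuine,
                                            length(rr_clust$structures)),
                                        seed = substream_seed(seed, 100L + k))
    rr_samples[[id]] <- rr
    rr_rows[[k]] <- data.frame(
      repertoire = id, n_fvs = n_fvs[k], lars_size = length(lars),
      rr_distinct = length(rr_clust$structures),
      rr_fvs_per_distinct = n_fvs[k] / length(rr_clust$structures),
      genuine_distinct = n_genuine,
      genuine_fvs_per_distinct = n_fvs[k] / n_genuine,
      stringsAsFactors = FALSE
    )
  }
  expected <- if (length(profiles) >= 2L) {
    expected_overlap_chain(rr_sets, rr_samples, library, config)
  } else NULL
  structure(
    list(rr_rows = do.call(rbind, rr_rows), expected = expected,
         mrs_size = n_mrs),
    class = "null_model_result"
  )
}

#' @export
print.null_model_result <- function(x, ...) {
  print(x$rr_rows)
  if (!is.null(x$expected)) print(x$expected$steps)
  invisible(x)
}

#' Clonotype the VH reads of several repertoires
#'
#' @param snapshots Named, ordered list of [repertoire_snapshot()].
#' @param mode Clonotype definition (see [cluster_clonotypes()]).
#' @return Output of [public_clonotype_counts()].
#' @export
run_clonotype <- function(snapshots, mode = c("briney_exact", "soto_80")) {
  mode <- match.arg(mode)
  public_clonotype_counts(lapply(snapshots, `[[`, "vh"), mode)
}

#' Reproducibility manifest for a run
#'
#' Snapshot of the effective configuration, inputs and timing, sufficient
#' to reproduce the run given the same inputs.
#'
#' @param stage Stage label.
#' @param config A [profiler_config()].
#' @param inputs Character description of inputs.
#' @param t0 Start time.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(stage, config, inputs = character(),
                         t0 = Sys.time()) {
  structure(
    list(stage = stage, config = unclass(config), inputs = inputs,
         started = format(t0),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         r_version = as.character(getRversion())),
    class = "run_manifest"
  )
}
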