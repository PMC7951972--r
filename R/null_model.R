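# Random Repertoires: MRS -> LARS -> RR construction and expected
# public-structure overlap under random structural sampling.

# Derive a bounded per-stage sub-seed from a master seed.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629) + 1L
}

# Pools behind MRS sampling: orientation references, CDR3 templates per
# chain, and CDR1/CDR2 template pairs linked by source structure
# (mirroring V-gene-encoded co-selection of the two first loops).
.mrs_pools <- function(library) {
  tpls <- library$cdr_templates
  region_of <- vapply(tpls, `[[`, "", "region")
  by_region <- split(names(tpls), region_of)
  linked <- function(r1, r2) {
    src1 <- split(by_region[[r1]],
                  vapply(tpls[by_region[[r1]]], `[[`, "", "source_structure"))
    src2 <- split(by_region[[r2]],
                  vapply(tpls[by_region[[r2]]], `[[`, "", "source_structure"))
    shared <- sort(intersect(names(src1), names(src2)))
    pairs <- list()
    for (s in shared) {
      for (a in sort(src1[[s]])) for (b in sort(src2[[s]])) {
        pairs[[length(pairs) + 1L]] <- c(a, b)
      }
    }
    pairs
  }
  list(
    orientation = sort(names(library$reference_fvs)),
    h3 = sort(by_region[["H3"]] %||% character()),
    l3 = sort(by_region[["L3"]] %||% character()),
    h12 = linked("H1", "H2"),
    l12 = linked("L1", "L2")
  )
}

#' Sample Modellable Repertoire Structures
#'
#' Draws `n` random structure keys, each assembled from one uniform draw
#' (with replacement) per pool: an orientation reference, a CDRH3
#' template, a CDRL3 template, a linked CDRH1/H2 template pair sharing a
#' source structure, and a linked CDRL1/L2 pair. The key's length vector
#' derives from the drawn templates.
#'
#' @param library A [template_library()].
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return List of `structure_sample` objects (`fv_id`, `key`,
#'   `draw_index`, `repertoire_id = NA`).
#' @export
sample_mrs <- function(library, n, seed = 1L) {
  pools <- .mrs_pools(library)
  if (any(vapply(pools, length, 1L) == 0L)) {
    stop("empty MRS pool(s): ",
         paste(names(pools)[vapply(pools, length, 1L) == 0L],
               collapse = ", "))
  }
  if (n == 0L) return(list())
  tpls <- library$cdr_templates
  with_rng(seed, {
    i_or <- sample.int(length(pools$orientation), n, replace = TRUE)
    i_h3 <- sample.int(length(pools$h3), n, replace = TRUE)
    i_l3 <- sample.int(length(pools$l3), n, replace = TRUE)
    i_h12 <- sample.int(length(pools$h12), n, replace = TRUE)
    i_l12 <- sample.int(length(pools$l12), n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      h12 <- pools$h12[[i_h12[i]]]
      l12 <- pools$l12[[i_l12[i]]]
      ids <- c(H1 = h12[1], H2 = h12[2], H3 = pools$h3[i_h3[i]],
               L1 = l12[1], L2 = l12[2], L3 = pools$l3[i_l3[i]])
      lens <- vapply(ids, function(id) tpls[[id]]$length, 1L)
      structure(
        list(fv_id = sprintf("MRS%06d", i),
             repertoire_id = NA_character_,
             key = structure_key(pools$orientation[i_or[i]], ids, lens),
             draw_index = i),
        class = c("structure_sample", "paired_fv")
      )
    })
  })
}

#' Restrict samples to observed CDR length combinations
#'
#' The Length-Accessible Repertoire Structures: the subset of sampled
#' structures whose length vector was observed in a genuine repertoire
#' snapshot.
#'
#' @param mrs_samples List from [sample_mrs()].
#' @param observed_length_vectors Character vector of observed length
#'   vectors (`"13-10-12-11-8-9"` form), e.g. from
#'   [observed_length_vectors()].
#' @return Filtered list.
#' @export
build_lars <- function(mrs_samples, observed_length_vectors) {
  Filter(function(s) lv_string(s$key) %in% observed_length_vectors,
         mrs_samples)
}

#' Length vectors observed in a set of Fvs
#'
#' @param fvs List of key-bearing Fvs.
#' @return Sorted unique character vector of length-vector strings.
#' @export
observed_length_vectors <- function(fvs) {
  sort(unique(vapply(fvs, function(f) lv_string(f$key), "")))
}

#' Draw a Random Repertoire from a LARS set
#'
#' Uniform sampling without replacement, the same number of times as the
#' genuine snapshot's predicted modellable Fv count.
#'
#' @param lars List from [build_lars()].
#' @param n_fvs Sample size (must not exceed `length(lars)`).
#' @param seed RNG seed.
#' @param repertoire_id Label stamped on the drawn samples.
#' @return List of `structure_sample`.
#' @export
sample_random_repertoire <- function(lars, n_fvs, seed = 1L,
                                     repertoire_id = "RR") {
  if (n_fvs > length(lars)) {
    stop("cannot draw ", n_fvs, " structures without replacement from a ",
         "LARS of size ", length(lars))
  }
  idx <- with_rng(seed, sort(sample.int(length(lars), n_fvs)))
  lapply(lars[idx], function(s) {
    s$repertoire_id <- repertoire_id
    s
  })
}

#' Subsample distinct structures
#'
#' Reduces a Random Repertoire's distinct structures to the number
#' observed in the matching genuine snapshot (uniformly, without
#' replacement), keeping each centre's members for seeding
#' expected-overlap chains.
#'
#' @param structures List of `distinct_structure`.
#' @param n_target Number to retain (<= length).
#' @param seed RNG seed.
#' @return Subset of `structures` in original order.
#' @export
subsample_distinct <- function(structures, n_target, seed = 1L) {
  if (n_target > length(structures)) {
    stop("cannot subsample ", n_target, " from ", length(structures),
         " structures")
  }
  idx <- with_rng(seed, sort(sample.int(length(structures), n_target)))
  structures[idx]
}

#' Expected overlap across chained Random Repertoires
#'
#' Runs the sequential overlap comparison on subsampled Random-Repertoire
#' structure sets, in the genuine repertoires' order: step 1 lists the
#' first RR's retained distinct structures, later steps feed the sampled
#' pairings belonging to each subsequent RR's retained structures. The
#' result is the statistically expected public-structure count under
#' random structural sampling.
#'
#' @param rr_structsets Named list: repertoire id -> list of (subsampled)
#'   `distinct_structure` whose members are `structure_sample`s.
#' @param rr_samples Named list: repertoire id -> the full RR sample list
#'   (member lookup).
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @return An `overlap_result` (see [chain_overlap()]).
#' @export
expected_overlap_chain <- function(rr_structsets, rr_samples, library,
                                   config = profiler_config()) {
  stopifnot(length(rr_structsets) >= 2L,
            identical(names(rr_structsets), names(rr_samples)))
  member_fvs <- lapply(names(rr_structsets), function(id) {
    keep <- unique(unlist(lapply(rr_structsets[[id]],
                                 function(s) s$members$fv_id)))
    sel <- Filter(function(s) s$fv_id %in% keep, rr_samples[[id]])
    lapply(sel, function(s) {
      s$repertoire_id <- id
      s
    })
  })
  names(member_fvs) <- names(rr_structsets)
  chain_overlap(member_fvs, library, config, order_by_diversity = FALSE)
}
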