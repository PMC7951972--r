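# The core algorithm: 8-parameter structure keys, greedy geometric
# clustering into distinct structures, cross-repertoire overlap chaining,
# baseline subtraction, and summaries.

REGIONS <- c("H1", "H2", "H3", "L1", "L2", "L3")

#' Profiling configuration
#'
#' Thresholds governing the pipeline: the orientation gate (1.5 angstrom)
#' and length-weighted CDR RMSD gate (1 angstrom) for distinct-structure
#' clustering, the 90% chain identity threshold, the 85% interface
#' pairing threshold, and the seed controlling the (only) stochastic step,
#' the choice of representative among identically-keyed pairings.
#'
#' @param orientation_threshold Orientation RMSD gate in angstroms.
#' @param cdr_threshold Combined CDR RMSD gate in angstroms.
#' @param identity_threshold Chain sequence-identity clustering threshold.
#' @param pairing_threshold Interface identity threshold.
#' @param seed Integer RNG seed.
#' @param sqrt_combined Apply the square root in the combined CDR measure
#'   (the default); `FALSE` exposes the no-root variant for sensitivity
#'   analysis.
#' @return Object of class `profiler_config`.
#' @export
profiler_config <- function(orientation_threshold = 1.5,
                            cdr_threshold = 1.0,
                            identity_threshold = 0.90,
                            pairing_threshold = 0.85,
                            seed = 1L,
                            sqrt_combined = TRUE) {
  stopifnot(orientation_threshold > 0, cdr_threshold > 0,
            identity_threshold > 0, pairing_threshold > 0)
  structure(
    list(orientation_threshold = orientation_threshold,
         cdr_threshold = cdr_threshold,
         identity_threshold = identity_threshold,
         pairing_threshold = pairing_threshold,
         seed = as.integer(seed),
         sqrt_combined = isTRUE(sqrt_combined)),
    class = "profiler_config"
  )
}

#' The 8-parameter binding-site descriptor
#'
#' An Fv's predicted binding site is summarised by its orientation
#' template, its six CDR loop templates, and the vector of North CDR
#' lengths.
#'
#' @param orientation_ref Reference Fv id.
#' @param templates Named character vector of template ids for
#'   `H1`,`H2`,`H3`,`L1`,`L2`,`L3`.
#' @param lengths Named integer vector of CDR lengths, same regions.
#' @return Object of class `structure_key`.
#' @export
structure_key <- function(orientation_ref, templates, lengths) {
  templates <- templates[REGIONS]
  lengths <- as.integer(lengths[REGIONS])
  if (anyNA(templates) || anyNA(lengths)) {
    stop("structure key requires all six CDR templates and lengths")
  }
  names(templates) <- names(lengths) <- REGIONS
  structure(
    list(orientation_ref = orientation_ref, templates = templates,
         lengths = lengths),
    class = "structure_key"
  )
}

#' @export
format.structure_key <- function(x, ...) {
  paste(c(x$orientation_ref, unname(x$templates),
          paste(x$lengths, collapse = "-")), collapse = "|")
}

#' @export
print.structure_key <- function(x, ...) {
  cat("<structure_key ", format(x), ">\n", sep = "")
  invisible(x)
}

lv_string <- function(key) paste(key$lengths, collapse = "-")

#' Length-weighted combined CDR RMSD between two structure keys
#'
#' `sqrt( sum_X L_X * D_X^2 / sum_X L_X )` over the six CDRs, where `L_X`
#' is the North CDR length and `D_X` the precomputed anchor-frame Calpha
#' RMSD between the two keys' region-X templates. Defined only for
#' identical length vectors (callers pre-partition by length combination).
#' Symmetric, zero when all six template ids coincide, and bounded between
#' the smallest and largest per-region `D_X`.
#'
#' @param key_a,key_b [structure_key()] objects with identical length
#'   vectors.
#' @param library A [template_library()] holding the per-(region, length)
#'   RMSD matrices.
#' @param sqrt_combined `FALSE` returns the no-root variant.
#' @return RMSD in angstroms.
#' @export
combined_cdr_rmsd <- function(key_a, key_b, library, sqrt_combined = TRUE) {
  if (!identical(key_a$lengths, key_b$lengths)) {
    stop("combined CDR RMSD requires identical length vectors")
  }
  L <- key_a$lengths
  d2 <- vapply(REGIONS, function(r) {
    D <- library$cdr_rmsd[[cdr_key(r, L[[r]])]]
    if (is.null(D)) stop("library lacks RMSD matrix for ",
                         cdr_key(r, L[[r]]))
    D[key_a$templates[[r]], key_b$templates[[r]]]^2
  }, 1)
  val <- sum(L * d2) / sum(L)
  if (sqrt_combined) sqrt(val) else val
}

# Columnar view of a list of key-bearing Fvs (paired_fv or key surrogates).
.fv_frame <- function(fvs) {
  if (length(fvs) == 0L) {
    return(data.frame(fv_id = character(), rep_id = character(),
                      or_ref = character(), lv = character(),
                      key_string = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    fv_id = vapply(fvs, `[[`, "", "fv_id"),
    rep_id = vapply(fvs, function(f)
      f$repertoire_id %||% NA_character_, ""),
    or_ref = vapply(fvs, function(f) f$key$orientation_ref, ""),
    lv = vapply(fvs, function(f) lv_string(f$key), ""),
    key_string = vapply(fvs, function(f) format(f$key), ""),
    stringsAsFactors = FALSE
  )
  for (r in REGIONS) {
    df[[paste0("t_", r)]] <- vapply(fvs, function(f)
      f$key$templates[[r]], "")
  }
  df
}

# Run expr with a private RNG stream, restoring global state after.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Collapse identically-keyed pairings to one representative
#'
#' One representative survives per identical 8-parameter key. When seed
#' centres are supplied (overlap mode) and a group's key matches a seed
#' centre, the seed is the representative and the group members are
#' recorded as shared with it; otherwise the representative is chosen
#' uniformly at random under the configured seed. Multiplicity is
#' recorded.
#'
#' @param fvs List of key-bearing Fvs.
#' @param seed_centres Optional list of `distinct_structure` seeds.
#' @param seed RNG seed for representative choice.
#' @return List with `representatives` (subset of `fvs`), `dup_members`
#'   (data frame `fv_id`, `rep_id`, `attached_to`, `seed_centre`), and
#'   `multiplicity` (named integer by representative fv id).
#' @export
dedupe_identical_keys <- function(fvs, seed_centres = NULL, seed = 1L) {
  df <- .fv_frame(fvs)
  seed_keys <- character()
  if (length(seed_centres)) {
    seed_keys <- stats::setNames(
      vapply(seed_centres, `[[`, "", "centre_id"),
      vapply(seed_centres, function(s) format(s$key), ""))
  }
  groups <- split(seq_along(fvs), df$key_string)
  # preserve first-appearance order of groups
  groups <- groups[order(vapply(groups, min, 1L))]
  reps <- integer()
  dup <- list()
  mult <- integer()
  with_rng(seed, {
    for (ks in names(groups)) {
      idx <- groups[[ks]]
      if (ks %in% names(seed_keys)) {
        # every member of the group is shared with the seed centre
        for (i in idx) {
          dup[[length(dup) + 1L]] <- data.frame(
            fv_id = df$fv_id[i], rep_id = df$rep_id[i],
            attached_to = seed_keys[[ks]], seed_centre = TRUE,
            stringsAsFactors = FALSE)
        }
        next
      }
      pick <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
      reps <- c(reps, pick)
      mult[df$fv_id[pick]] <- length(idx)
      for (i in setdiff(idx, pick)) {
        dup[[length(dup) + 1L]] <- data.frame(
          fv_id = df$fv_id[i], rep_id = df$rep_id[i],
          attached_to = df$fv_id[pick], seed_centre = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  })
  list(
    representatives = fvs[sort(reps)],
    dup_members = if (length(dup)) do.call(rbind, dup) else
      data.frame(fv_id = character(), rep_id = character(),
                 attached_to = character(), seed_centre = logical(),
                 stringsAsFactors = FALSE),
    multiplicity = mult
  )
}

new_distinct_structure <- function(centre_id, key, origin_repertoire,
                                   is_seed = FALSE) {
  structure(
    list(centre_id = centre_id, key = key,
         origin_repertoire = origin_repertoire,
         presence = if (is.na(origin_repertoire)) character()
                    else origin_repertoire,
         members = data.frame(repertoire_id = origin_repertoire,
                              fv_id = centre_id,
                              stringsAsFactors = FALSE),
         is_seed = is_seed),
    class = "distinct_structure"
  )
}

#' @export
print.distinct_structure <- function(x, ...) {
  cat(sprintf("<distinct_structure %s: %d member(s), present in {%s}>\n",
              x$centre_id, nrow(x$members),
              paste(x$presence, collapse = ",")))
  invisible(x)
}

#' Greedy clustering of Fvs into distinct structures
#'
#' Implements the four-step identification of distinct binding-site
#' structures: (1) identically-keyed pairings are collapsed
#' ([dedupe_identical_keys()]); (2) keys whose CDR length vector occurs
#' exactly once become distinct structures immediately (no RMSD comparison
#' across differing loop lengths); (3) the rest are partitioned by length
#' vector and processed greedily in input order — a pairing founds a new
#' cluster centre when its orientation RMSD to every existing same-length
#' centre exceeds the orientation gate, or when its combined CDR RMSD
#' (length-weighted, [combined_cdr_rmsd()]) exceeds the CDR gate to every
#' existing centre; (4) otherwise it is stripped and recorded as a member
#' of the first centre (in centre-creation order) within both gates.
#' When seed centres are supplied they are listed before the data, are
#' never merged or deleted, and accumulate members and repertoire
#' presence.
#'
#' @param fvs List of key-bearing Fvs (class `paired_fv` or any object
#'   with `fv_id`, `repertoire_id`, `key`).
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @param seed_centres Optional list of `distinct_structure` objects from
#'   a previous run.
#' @return List of class `structure_clustering`: `structures` (list of
#'   `distinct_structure`), `assignments` (data frame `fv_id`,
#'   `repertoire_id`, `centre_id`, `role`).
#' @export
cluster_distinct_structures <- function(fvs, library,
                                        config = profiler_config(),
                                        seed_centres = NULL) {
  o_thr <- config$orientation_threshold
  c_thr <- config$cdr_threshold
  or_mat <- library$orientation_rmsd

  structures <- list()
  assignments <- list()
  note <- function(fv_id, rep_id, centre_id, role) {
    assignments[[length(assignments) + 1L]] <<- data.frame(
      fv_id = fv_id, repertoire_id = rep_id, centre_id = centre_id,
      role = role, stringsAsFactors = FALSE)
  }
  add_member <- function(k, rep_id, fv_id) {
    s <- structures[[k]]
    s$members <- rbind(s$members, data.frame(
      repertoire_id = rep_id, fv_id = fv_id, stringsAsFactors = FALSE))
    if (!is.na(rep_id) && !(rep_id %in% s$presence)) {
      s$presence <- c(s$presence, rep_id)
    }
    structures[[k]] <<- s
  }

  # seeds enter first and stay centres
  seed_index <- character()
  if (length(seed_centres)) {
    for (s in seed_centres) {
      s$is_seed <- TRUE
      structures[[length(structures) + 1L]] <- s
      seed_index[s$centre_id] <- length(structures)
    }
  }

  ded <- dedupe_identical_keys(fvs, seed_centres, seed = config$seed)
  for (i in seq_len(nrow(ded$dup_members))) {
    d <- ded$dup_members[i, ]
    if (d$seed_centre) {
      add_member(as.integer(seed_index[[d$attached_to]]), d$rep_id, d$fv_id)
      note(d$fv_id, d$rep_id, d$attached_to, "duplicate")
    }
  }
  reps <- ded$representatives

  # length-vector occupancy over all unique keys (seeds included)
  rep_lv <- vapply(reps, function(f) lv_string(f$key), "")
  seed_lv <- vapply(structures[vapply(structures, `[[`, TRUE, "is_seed")],
                    function(s) lv_string(s$key), "")
  lv_count <- table(c(rep_lv, seed_lv))

  # per-LV running centre bookkeeping (indices into `structures`)
  lv_centres <- list()
  register_centre <- function(fv, singleton) {
    st <- new_distinct_structure(fv$fv_id, fv$key,
                                 fv$repertoire_id %||% NA_character_)
    structures[[length(structures) + 1L]] <<- st
    k <- length(structures)
    if (!singleton) {
      lv <- lv_string(fv$key)
      lv_centres[[lv]] <<- c(lv_centres[[lv]], k)
    }
    note(fv$fv_id, fv$repertoire_id %||% NA_character_, fv$fv_id,
         if (singleton) "singleton" else "centre")
    k
  }
  # seeds participate in their LV partitions
  for (k in seq_along(structures)) {
    lv <- lv_string(structures[[k]]$key)
    if (lv_count[[lv]] >= 2L) lv_centres[[lv]] <- c(lv_centres[[lv]], k)
  }

  for (fv in reps) {
    lv <- lv_string(fv$key)
    if (lv_count[[lv]] == 1L) {
      register_centre(fv, singleton = TRUE)
      next
    }
    cand <- lv_centres[[lv]]
    if (is.null(cand) || length(cand) == 0L) {
      register_centre(fv, singleton = FALSE)
      next
    }
    or_d <- or_mat[fv$key$orientation_ref,
                   vapply(structures[cand], function(s)
                     s$key$orientation_ref, "")]
    if (all(or_d > o_thr)) {
      register_centre(fv, singleton = FALSE)
      next
    }
    cdr_d <- vapply(cand, function(k) {
      combined_cdr_rmsd(fv$key, structures[[k]]$key, library,
                        config$sqrt_combined)
    }, 1)
    if (all(cdr_d > c_thr)) {
      register_centre(fv, singleton = FALSE)
      next
    }
    hit <- which(or_d <= o_thr & cdr_d <= c_thr)
    # the orientation-close and CDR-close centres are almost always the
    # same object; if not, fall back to the first CDR-close centre
    target <- if (length(hit)) cand[hit[1]] else cand[which(cdr_d <= c_thr)[1]]
    add_member(target, fv$repertoire_id %||% NA_character_, fv$fv_id)
    note(fv$fv_id, fv$repertoire_id %||% NA_character_,
         structures[[target]]$centre_id, "member")
    # identically-keyed duplicates follow their representative
    dups <- ded$dup_members
    dups <- dups[!dups$seed_centre & dups$attached_to == fv$fv_id, ]
    for (i in seq_len(nrow(dups))) {
      add_member(target, dups$rep_id[i], dups$fv_id[i])
      note(dups$fv_id[i], dups$rep_id[i], structures[[target]]$centre_id,
           "duplicate")
    }
  }

  # duplicates of representatives that became centres
  dups <- ded$dup_members
  if (nrow(dups)) {
    centre_ids <- vapply(structures, `[[`, "", "centre_id")
    for (i in seq_len(nrow(dups))) {
      d <- dups[i, ]
      if (d$seed_centre) next
      k <- match(d$attached_to, centre_ids)
      if (!is.na(k)) {  # representative is a centre; members already
                        # handled otherwise
        add_member(k, d$rep_id, d$fv_id)
        note(d$fv_id, d$rep_id, d$attached_to, "duplicate")
      }
    }
  }

  structure(
    list(
      structures = structures,
      assignments = if (length(assignments)) do.call(rbind, assignments)
        else data.frame(fv_id = character(), repertoire_id = character(),
                        centre_id = character(), role = character(),
                        stringsAsFactors = FALSE)
    ),
    class = "structure_clustering"
  )
}

#' @export
print.structure_clustering <- function(x, ...) {
  cat(sprintf("<structure_clustering: %d distinct structures, %d assignments>\n",
              length(x$structures), nrow(x$assignments)))
  invisible(x)
}

#' Sequential public-structure overlap across repertoires
#'
#' Lists the distinct structures of the first repertoire, then clusters
#' each subsequent repertoire's Fvs against all accumulated centres
#' (seeded greedy clustering, so earlier centres always persist). After
#' step k, a structure is public when its presence set covers all k
#' repertoires so far. By default repertoires are ordered by their solo
#' internal structural diversity, most diverse first.
#'
#' @param repertoire_fvs Named list: repertoire id -> list of key-bearing
#'   Fvs; each Fv is stamped with its list's repertoire id before
#'   clustering.
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @param order_by_diversity Reorder repertoires by descending solo
#'   distinct-structure count (ties keep input order).
#' @return List of class `overlap_result`: `steps` (data frame `step`,
#'   `repertoire`, `fvs_added`, `cumulative_distinct`, `public`,
#'   `public_pct`), `structures`, `order`.
#' @export
chain_overlap <- function(repertoire_fvs, library,
                          config = profiler_config(),
                          order_by_diversity = TRUE) {
  stopifnot(length(repertoire_fvs) >= 1L)
  ids <- names(repertoire_fvs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("repertoire_fvs must be a named list")
  }
  repertoire_fvs <- lapply(ids, function(id) {
    lapply(repertoire_fvs[[id]], function(f) {
      f$repertoire_id <- id
      f
    })
  })
  names(repertoire_fvs) <- ids
  if (order_by_diversity && length(ids) > 1L) {
    solo <- vapply(ids, function(id) {
      length(cluster_distinct_structures(repertoire_fvs[[id]], library,
                                         config)$structures)
    }, 1L)
    ids <- ids[order(-solo)]
  }
  centres <- NULL
  steps <- list()
  for (k in seq_along(ids)) {
    res <- cluster_distinct_structures(repertoire_fvs[[ids[k]]], library,
                                       config, seed_centres = centres)
    centres <- res$structures
    seen <- ids[seq_len(k)]
    public <- sum(vapply(centres, function(s)
      all(seen %in% s$presence), TRUE))
    steps[[k]] <- data.frame(
      step = k, repertoire = ids[k],
      fvs_added = length(repertoire_fvs[[ids[k]]]),
      cumulative_distinct = length(centres),
      public = public,
      public_pct = 100 * public / length(centres),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(steps = do.call(rbind, steps), structures = centres, order = ids),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  print(x$steps)
  invisible(x)
}

#' Remove structures already present in a baseline
#'
#' Clusters the later ('after') Fvs with the baseline ('before') distinct
#' structures as immovable seeds, and keeps only the Fvs that did not fall
#' into any baseline cluster (i.e. those founding or joining new centres):
#' the pure post-exposure structural repertoire.
#'
#' @param after_fvs List of key-bearing Fvs.
#' @param before_centres List of `distinct_structure` seeds from the same
#'   individual's baseline.
#' @param library A [template_library()].
#' @param config A [profiler_config()].
#' @return Subset of `after_fvs`.
#' @export
subtract_baseline <- function(after_fvs, before_centres, library,
                              config = profiler_config()) {
  if (length(after_fvs) == 0L) return(list())
  res <- cluster_distinct_structures(after_fvs, library, config,
                                     seed_centres = before_centres)
  seed_ids <- vapply(before_centres, `[[`, "", "centre_id")
  a <- res$assignments
  kept_ids <- a$fv_id[!(a$centre_id %in% seed_ids)]
  Filter(function(f) f$fv_id %in% kept_ids, after_fvs)
}

#' Fraction of structures proximal to another structure set
#'
#' The fraction of centres in `structures_a` having at least one centre in
#' `structures_b` with an identical CDR length vector, orientation RMSD
#' within the configured orientation gate, and combined CDR RMSD within
#' `radius`.
#'
#' @param structures_a,structures_b Lists of `distinct_structure`.
#' @param library A [template_library()].
#' @param radius Combined CDR RMSD radius in angstroms (> 0).
#' @param config A [profiler_config()] (orientation gate).
#' @return Fraction in `[0, 1]`.
#' @export
proximity_fraction <- function(structures_a, structures_b, library,
                               radius = 1.0, config = profiler_config()) {
  stopifnot(radius > 0)
  if (length(structures_a) == 0L) return(NaN)
  b_lv <- vapply(structures_b, function(s) lv_string(s$key), "")
  or_mat <- library$orientation_rmsd
  hits <- vapply(structures_a, function(a) {
    cand <- structures_b[b_lv == lv_string(a$key)]
    if (length(cand) == 0L) return(FALSE)
    for (b in cand) {
      if (or_mat[a$key$orientation_ref, b$key$orientation_ref] <=
            config$orientation_threshold &&
          combined_cdr_rmsd(a$key, b$key, library,
                            config$sqrt_combined) <= radius) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  mean(hits)
}

#' Summaries of a distinct-structure profile
#'
#' Per-CDR counts of unique member loop templates per structure (with
#' medians across structures), and CDR3 length usage split by
#' public/private status.
#'
#' @param structures List of `distinct_structure`.
#' @param fvs The Fvs that were clustered (for member key lookup).
#' @param n_repertoires Number of repertoires compared (defines public).
#' @return List with `templates_per_structure` (data frame: centre id plus
#'   one column per region), `region_medians` (named numeric), and
#'   `length_usage` (data frame `centre_id`, `public`, `h3`, `l3`,
#'   `h3_l3`).
#' @export
summarize_distinct_structures <- function(structures, fvs,
                                          n_repertoires = 1L) {
  key_by_id <- stats::setNames(lapply(fvs, `[[`, "key"),
                               vapply(fvs, `[[`, "", "fv_id"))
  per <- lapply(structures, function(s) {
    ids <- unique(s$members$fv_id)
    keys <- c(list(s$key), key_by_id[intersect(ids, names(key_by_id))])
    counts <- vapply(REGIONS, function(r) {
      length(unique(vapply(keys, function(k) k$templates[[r]], "")))
    }, 1L)
    c(list(centre_id = s$centre_id), as.list(counts))
  })
  tps <- do.call(rbind, lapply(per, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  medians <- vapply(REGIONS, function(r) stats::median(tps[[r]]), 1)
  lu <- do.call(rbind, lapply(structures, function(s) {
    data.frame(
      centre_id = s$centre_id,
      public = length(s$presence) == n_repertoires,
      h3 = s$key$lengths[["H3"]],
      l3 = s$key$lengths[["L3"]],
      h3_l3 = s$key$lengths[["H3"]] + s$key$lengths[["L3"]],
      stringsAsFactors = FALSE
    )
  }))
  list(templates_per_structure = tps, region_medians = medians,
       length_usage = lu)
}
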