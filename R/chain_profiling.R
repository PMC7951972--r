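# Per-chain modellability and 90%-identity reduction to cluster centres.

#' Filter chains to those with fully modellable CDRs
#'
#' A chain survives when its North CDRs are extractable, a framework can be
#' assigned, and every CDR of the chain receives an admissible loop
#' template. Survivors carry their framework and per-region template
#' assignments; drops are logged with per-region failure reasons.
#'
#' @param chains List of [numbered_chain()].
#' @param library A [template_library()].
#' @return List of `modellable_chain` objects (`chain`, `framework_id`,
#'   `assignments`, `cluster_size`), with attribute `"drops"`: data frame
#'   of `read_id`, `reason`.
#' @export
modellability_filter <- function(chains, library) {
  out <- list()
  drops <- list()
  drop <- function(id, why) {
    drops[[length(drops) + 1L]] <<- data.frame(
      read_id = id, reason = why, stringsAsFactors = FALSE)
  }
  for (ch in chains) {
    cdrs <- extract_north_cdrs(ch)
    if (!cdr_extractable(cdrs)) {
      drop(ch$read_id, paste0("cdr_extraction: ", attr(cdrs, "reason")))
      next
    }
    fw <- assign_framework(ch, library)
    if (is.null(fw)) {
      drop(ch$read_id, "framework: no framework shares positions")
      next
    }
    assignments <- list()
    failed <- NULL
    for (region in names(cdrs)) {
      a <- assign_cdr_template(cdrs[[region]], fw, library)
      if (is.null(a)) {
        failed <- region
        break
      }
      assignments[[region]] <- a
    }
    if (!is.null(failed)) {
      drop(ch$read_id, paste0("template: no admissible template for ", failed))
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(chain = ch, cdrs = cdrs, framework_id = fw$framework_id,
           assignments = assignments, cluster_size = 1L,
           members = data.frame(read_id = ch$read_id, identity = 1,
                                stringsAsFactors = FALSE)),
      class = "modellable_chain"
    )
  }
  attr(out, "drops") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(read_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Aligned sequence identity between two numbered chains
#'
#' Matching residues at shared occupied IMGT positions divided by the
#' length of the longer sequence (the global-identity convention); 1.0 iff
#' the chains are identical over occupied positions and equal length.
#'
#' @param a,b [numbered_chain()] objects.
#' @return Identity fraction in `[0, 1]`.
#' @export
chain_identity <- function(a, b) {
  sa <- chain_sequence(a)
  sb <- chain_sequence(b)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] == sb[shared]) / max(length(sa), length(sb))
}

#' Greedy sequence-identity clustering of modellable chains
#'
#' Deterministic greedy longest-first clustering over IMGT-aligned
#' identity: chains are sorted by sequence length descending (ties keep
#' input order); each chain joins the first existing centre (in centre
#' creation order) with identity at or above the threshold, otherwise it
#' founds a new centre. Centres record the reads they represent.
#'
#' @param chains List of `modellable_chain` (from
#'   [modellability_filter()]).
#' @param threshold Identity threshold in `(0, 1]` (default 0.9).
#' @return List of centre `modellable_chain`s with `cluster_size` and
#'   `members` (read id + identity to centre) filled in.
#' @export
greedy_identity_cluster <- function(chains, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(chains) == 0L) return(list())
  lens <- vapply(chains, function(m) length(m$chain$residues), 1L)
  ord <- order(-lens)  # stable: ties keep input order
  centres <- list()
  for (i in ord) {
    m <- chains[[i]]
    placed <- FALSE
    for (k in seq_along(centres)) {
      ident <- chain_identity(m$chain, centres[[k]]$chain)
      if (ident >= threshold - 1e-12) {
        centres[[k]]$cluster_size <- centres[[k]]$cluster_size + 1L
        centres[[k]]$members <- rbind(
          centres[[k]]$members,
          data.frame(read_id = m$chain$read_id, identity = ident,
                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) centres[[length(centres) + 1L]] <- m
  }
  centres
}

#' Cluster-membership table
#'
#' @param centres Output of [greedy_identity_cluster()].
#' @return Data frame `centre_id`, `read_id`, `identity`.
#' @export
identity_cluster_table <- function(centres) {
  do.call(rbind, c(lapply(centres, function(m) {
    cbind(data.frame(centre_id = m$chain$read_id,
                     stringsAsFactors = FALSE), m$members)
  }), list(data.frame(centre_id = character(), read_id = character(),
                      identity = numeric(), stringsAsFactors = FALSE))))
}
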