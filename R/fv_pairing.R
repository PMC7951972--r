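# Combinatorial VH-VL pairing with interface-modellability prediction.

#' Interface signature of a VH-VL pair
#'
#' Concatenates the residues at the library's 20 key VH-VL interface
#' positions, in the configured row order; positions absent from a chain
#' emit the gap symbol `-`, which never matches anything.
#'
#' @param vh,vl [numbered_chain()] objects.
#' @param positions Data frame with columns `chain` and `position`
#'   (20 rows), as held in a library's `interface_positions`.
#' @return A length-20 character string.
#' @export
interface_signature <- function(vh, vl, positions) {
  sh <- chain_sequence(vh)
  sl <- chain_sequence(vl)
  res <- vapply(seq_len(nrow(positions)), function(i) {
    src <- if (positions$chain[i] == "H") sh else sl
    r <- src[positions$position[i]]
    if (is.na(r)) "-" else unname(r)
  }, "")
  paste(res, collapse = "")
}

# Per-chain signature halves and match-count matrices against references.
.signature_matches <- function(chains, positions, refs_mat, which_chain) {
  rows <- which(positions$chain == which_chain)
  sig <- t(vapply(chains, function(m) {
    s <- chain_sequence(m$chain)
    r <- s[positions$position[rows]]
    ifelse(is.na(r), "-", r)
  }, character(length(rows))))
  if (length(rows) == 1L) sig <- matrix(sig, ncol = 1L)
  # matches[i, ref] = count of identical non-gap residues
  M <- matrix(0L, nrow(sig), nrow(refs_mat))
  for (p in seq_along(rows)) {
    eq <- outer(sig[, p], refs_mat[, rows[p]], "==")
    eq[sig[, p] == "-", ] <- FALSE
    M <- M + eq
  }
  M
}

#' Predict modellable Fv pairings
#'
#' Evaluates every VH centre x VL centre pair: its 20-residue interface
#' signature is compared to every reference Fv (identity = matches / 20;
#' gaps never match). A pair is kept iff its best reference identity
#' reaches the threshold, and it inherits the orientation of the
#' highest-identity reference (ties broken by lexicographic reference id).
#'
#' @param vh_centres,vl_centres Lists of `modellable_chain` centres (from
#'   [greedy_identity_cluster()]).
#' @param library A [template_library()] (non-empty reference set
#'   required).
#' @param threshold Interface identity threshold in `(0, 1]`
#'   (default 0.85).
#' @return List of `paired_fv` objects: `fv_id` (`"<vh>|<vl>"`), `vh_id`,
#'   `vl_id`, `orientation_ref`, `interface_identity`, and the derived
#'   8-parameter `key` (see [structure_key()]).
#' @export
predict_modellable_fvs <- function(vh_centres, vl_centres, library,
                                   threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(library$reference_fvs) == 0L) {
    stop("library carries no reference Fvs; pairing is not configured")
  }
  if (length(vh_centres) == 0L || length(vl_centres) == 0L) return(list())
  pos <- library$interface_positions
  ref_ids <- sort(names(library$reference_fvs))
  refs_mat <- t(vapply(ref_ids, function(id) {
    strsplit(library$reference_fvs[[id]]$interface_residues, "")[[1]]
  }, character(20L)))
  MH <- .signature_matches(vh_centres, pos, refs_mat, "H")
  ML <- .signature_matches(vl_centres, pos, refs_mat, "L")
  out <- list()
  min_matches <- threshold * 20 - 1e-9
  for (i in seq_along(vh_centres)) {
    tot <- sweep(ML, 2, MH[i, ], "+")  # |VL| x |refs| total matches
    best <- apply(tot, 1, max)
    best_ref <- apply(tot, 1, which.max)  # first max = lexicographic tie-break
    keep <- which(best >= min_matches)
    for (j in keep) {
      vh_id <- vh_centres[[i]]$chain$read_id
      vl_id <- vl_centres[[j]]$chain$read_id
      out[[length(out) + 1L]] <- paired_fv(
        vh = vh_centres[[i]], vl = vl_centres[[j]],
        orientation_ref = ref_ids[best_ref[j]],
        interface_identity = unname(best[j]) / 20
      )
    }
  }
  out
}

#' Construct a paired Fv
#'
#' @param vh,vl `modellable_chain` centres.
#' @param orientation_ref Inherited reference Fv id.
#' @param interface_identity Best interface identity achieved.
#' @param repertoire_id Optional repertoire label.
#' @return Object of class `paired_fv` carrying its [structure_key()].
#' @export
paired_fv <- function(vh, vl, orientation_ref, interface_identity,
                      repertoire_id = NA_character_) {
  templates <- c(
    vapply(vh$assignments, `[[`, "", "template_id"),
    vapply(vl$assignments, `[[`, "", "template_id")
  )
  vh_cdrs <- vh$cdrs %||% extract_north_cdrs(vh$chain)
  vl_cdrs <- vl$cdrs %||% extract_north_cdrs(vl$chain)
  lh <- vapply(vh_cdrs, `[[`, 1L, "length")
  ll <- vapply(vl_cdrs, `[[`, 1L, "length")
  structure(
    list(
      fv_id = paste(vh$chain$read_id, vl$chain$read_id, sep = "|"),
      vh_id = vh$chain$read_id, vl_id = vl$chain$read_id,
      orientation_ref = orientation_ref,
      interface_identity = interface_identity,
      repertoire_id = repertoire_id,
      key = structure_key(orientation_ref, templates, c(lh, ll))
    ),
    class = "paired_fv"
  )
}
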