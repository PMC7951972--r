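# IMGT position handling and North CDR definitions.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' North CDR windows in IMGT numbering
#'
#' Returns the inclusive IMGT residue-number windows delimiting the North
#' CDR definitions for a heavy or light chain: CDR1 24-40, CDR2 55-66 (H)
#' or 55-69 (L), CDR3 105-117.
#'
#' @param chain_type `"H"` or `"L"`.
#' @return Named list of length-2 integer vectors (`lo`, `hi`) keyed by
#'   region label (`H1`..`H3` or `L1`..`L3`).
#' @export
north_cdr_windows <- function(chain_type) {
  chain_type <- match.arg(chain_type, c("H", "L"))
  if (chain_type == "H") {
    list(H1 = c(24L, 40L), H2 = c(55L, 66L), H3 = c(105L, 117L))
  } else {
    list(L1 = c(24L, 40L), L2 = c(55L, 69L), L3 = c(105L, 117L))
  }
}

# Parse IMGT position labels ("24", "111A") into number + insertion code.
parse_imgt_positions <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)([A-Z]?)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed IMGT position label(s): ",
         paste(labels[bad], collapse = ", "))
  }
  data.frame(
    label = labels,
    num = vapply(m, function(x) as.integer(x[2]), 1L),
    ins = vapply(m, function(x) x[3], ""),
    stringsAsFactors = FALSE
  )
}

# Sort key implementing the IMGT insertion convention: insertions ascend
# after their base position (111, 111A, 111B, ...) except at 112, where
# they descend and precede the base (112B, 112A, 112).
imgt_sort_key <- function(labels) {
  p <- parse_imgt_positions(labels)
  ins_rank <- ifelse(p$ins == "", 0L, match(p$ins, LETTERS))
  key <- ifelse(
    p$num == 112L,
    ifelse(p$ins == "", 60, 60 - ins_rank),
    ins_rank
  )
  p$num * 100 + key
}

#' Order IMGT position labels
#'
#' @param labels Character vector of IMGT position labels (e.g. `"24"`,
#'   `"111A"`).
#' @return Integer permutation ordering `labels` by IMGT convention.
#' @export
imgt_order <- function(labels) {
  order(imgt_sort_key(labels))
}

#' Construct an IMGT-numbered chain
#'
#' A `numbered_chain` is one IMGT-numbered VH or VL read: an ordered mapping
#' from IMGT positions (number plus optional insertion code) to amino-acid
#' letters, with germline V/J gene calls.
#'
#' @param read_id Opaque read identifier.
#' @param chain_type `"H"` or `"L"`.
#' @param positions Character vector of IMGT position labels.
#' @param residues Character vector of one-letter amino-acid codes, parallel
#'   to `positions`.
#' @param v_call,j_call Germline gene calls (may be `NA`).
#' @param isotype Optional isotype label.
#' @return Object of class `numbered_chain`.
#' @export
numbered_chain <- function(read_id, chain_type, positions, residues,
                           v_call = NA_character_, j_call = NA_character_,
                           isotype = NA_character_) {
  chain_type <- match.arg(chain_type, c("H", "L"))
  positions <- as.character(positions)
  residues <- toupper(as.character(residues))
  if (length(positions) != length(residues)) {
    stop("positions and residues must be parallel vectors")
  }
  if (anyDuplicated(positions)) {
    stop("duplicated IMGT positions in read ", read_id)
  }
  bad <- !(residues %in% AA_ALPHABET)
  if (any(bad)) {
    stop("read ", read_id, ": non-standard residue(s) ",
         paste(unique(residues[bad]), collapse = ","))
  }
  if (!is.na(v_call) && nzchar(v_call)) {
    locus <- substr(v_call, 1, 3)
    if (locus %in% c("IGH", "IGK", "IGL")) {
      implied <- if (locus == "IGH") "H" else "L"
      if (implied != chain_type) {
        stop("read ", read_id, ": chain_type ", chain_type,
             " inconsistent with v_call ", v_call)
      }
    }
  }
  ord <- imgt_order(positions)
  structure(
    list(
      read_id = as.character(read_id),
      chain_type = chain_type,
      positions = positions[ord],
      residues = residues[ord],
      v_call = v_call,
      j_call = j_call,
      isotype = isotype
    ),
    class = "numbered_chain"
  )
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("<numbered_chain %s [%s] %d residues, v=%s j=%s>\n",
              x$read_id, x$chain_type, length(x$residues),
              x$v_call, x$j_call))
  invisible(x)
}

#' Full aligned sequence of a chain
#'
#' @param chain A [numbered_chain()].
#' @return Named character vector, residue letters named by IMGT position,
#'   in IMGT order.
#' @export
chain_sequence <- function(chain) {
  stats::setNames(chain$residues, chain$positions)
}

# One CDR loop slice.
cdr_slice <- function(region, sequence) {
  structure(
    list(region = region, sequence = sequence, length = nchar(sequence)),
    class = "cdr_slice"
  )
}

#' Extract the North CDR loops of a chain
#'
#' Slices the residues falling inside each North CDR window (including any
#' insertion codes) for the chain's type. A chain is un-extractable when a
#' CDR window is empty or when either framework position immediately
#' flanking a window is missing; such chains are excluded downstream.
#'
#' @param chain A [numbered_chain()].
#' @return Named list of CDR slices (regions `H1`..`H3` or `L1`..`L3`),
#'   each with `region`, `sequence` and `length`; or a zero-length list
#'   with a `"reason"` attribute when un-extractable (see
#'   [cdr_extractable()]).
#' @export
extract_north_cdrs <- function(chain) {
  stopifnot(inherits(chain, "numbered_chain"))
  wins <- north_cdr_windows(chain$chain_type)
  p <- parse_imgt_positions(chain$positions)
  out <- list()
  for (region in names(wins)) {
    w <- wins[[region]]
    inside <- p$num >= w[1] & p$num <= w[2]
    if (!any(inside)) {
      return(structure(list(),
                       reason = paste0(region, ": empty CDR window")))
    }
    # flanking framework residues must be present to anchor the loop
    if (!any(p$num == w[1] - 1L) || !any(p$num == w[2] + 1L)) {
      return(structure(
        list(),
        reason = paste0(region, ": missing flanking framework position")
      ))
    }
    out[[region]] <- cdr_slice(region,
                               paste(chain$residues[inside], collapse = ""))
  }
  out
}

#' Did CDR extraction succeed?
#'
#' @param cdrs Result of [extract_north_cdrs()].
#' @return `TRUE` for a full slice set, `FALSE` for a flagged failure.
#' @export
cdr_extractable <- function(cdrs) length(cdrs) > 0L

#' IMGT position labels realising a CDR of a given length
#'
#' Places `length` residues inside the region's North window using the
#' IMGT centre-out gapping convention; lengths exceeding the window width
#' use insertion codes around positions 111/112 (CDR3) or the window
#' midpoint (CDR1/2).
#'
#' @param region One of `H1`,`H2`,`H3`,`L1`,`L2`,`L3`.
#' @param length Number of loop residues (>= 1).
#' @return Character vector of `length` IMGT position labels in order.
#' @export
imgt_cdr_positions <- function(region, length) {
  stopifnot(length >= 1)
  chain_type <- substr(region, 1, 1)
  w <- north_cdr_windows(chain_type)[[region]]
  width <- w[2] - w[1] + 1L
  if (length <= width) {
    n_left <- ceiling(length / 2)
    n_right <- length - n_left
    left <- seq(w[1], length.out = n_left)
    right <- if (n_right > 0) seq(w[2] - n_right + 1L, w[2]) else integer()
    return(as.character(c(left, right)))
  }
  # insertions at the loop apex: for CDR3 the convention is ascending
  # letters after 111 then descending letters before 112; elsewhere all
  # insertions ascend after the left-centre position
  extra <- length - width
  mid_left <- w[1] + ceiling(width / 2) - 1L   # 111 for CDR3
  if (mid_left == 111L) {
    n_asc <- ceiling(extra / 2)
    n_desc <- extra - n_asc
    return(c(
      as.character(seq(w[1], mid_left)),
      paste0(mid_left, LETTERS[seq_len(n_asc)]),
      if (n_desc > 0) paste0(mid_left + 1L, rev(LETTERS[seq_len(n_desc)])),
      as.character(seq(mid_left + 1L, w[2]))
    ))
  }
  c(
    as.character(seq(w[1], mid_left)),
    paste0(mid_left, LETTERS[seq_len(extra)]),
    as.character(seq(mid_left + 1L, w[2]))
  )
}
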