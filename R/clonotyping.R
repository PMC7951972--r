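# Sequence-based comparator: clonotype assignment (exact-CDRH3 or
# 80%-identity definitions), public clonotypes, germline proximity.

# IGHV5-51*01 -> IGHV5-51 (gene level).
strip_allele <- function(gene) sub("\\*.*$", "", gene)

# IGHV5-51 -> V5-51 (display form used in clonotype keys).
.display_gene <- function(gene) sub("^IG[HKL]", "", strip_allele(gene))

#' Clonotype key string
#'
#' Renders the `"V+CDRH3+J"` display form, e.g.
#' `"V5-51+ARPYGSGSYSDY+J4"`.
#'
#' @param v_gene,j_gene Gene calls (allele suffixes tolerated).
#' @param cdrh3 Representative CDRH3 sequence.
#' @return Character key.
#' @export
clonotype_key <- function(v_gene, j_gene, cdrh3) {
  paste(.display_gene(v_gene), cdrh3, .display_gene(j_gene), sep = "+")
}

.hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va == vb) / length(va)
}

#' Cluster heavy chains into clonotypes
#'
#' Chains are first partitioned by gene-level closest V gene, J gene and
#' CDRH3 length; within a partition, `briney_exact` groups identical
#' CDRH3 sequences while `soto_80` greedily clusters CDRH3s at >= 80%
#' identity to a representative (same greedy-representative engine as the
#' chain clustering; first chain of a group is its representative).
#' Chains without both gene calls are excluded with a warning.
#'
#' @param chains List of VH [numbered_chain()], or list of lists
#'   `(repertoire_id, chain)`.
#' @param mode `"briney_exact"` or `"soto_80"`.
#' @param identity Identity threshold for `soto_80` (default 0.80).
#' @return List of `clonotype` objects: `v_gene`, `j_gene`,
#'   `cdrh3_representative`, `key_string`, `members` (data frame
#'   `repertoire_id`, `read_id`, `cdrh3`, `identity`).
#' @export
cluster_clonotypes <- function(chains, mode = c("briney_exact", "soto_80"),
                               identity = 0.80) {
  mode <- match.arg(mode)
  recs <- list()
  skipped <- 0L
  for (entry in chains) {
    if (inherits(entry, "numbered_chain")) {
      ch <- entry; rep_id <- NA_character_
    } else {
      ch <- entry$chain; rep_id <- entry$repertoire_id
    }
    if (is.na(ch$v_call) || is.na(ch$j_call)) {
      skipped <- skipped + 1L
      next
    }
    cdrs <- extract_north_cdrs(ch)
    if (!cdr_extractable(cdrs) || is.null(cdrs$H3)) {
      skipped <- skipped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      repertoire_id = rep_id, read_id = ch$read_id,
      v_gene = strip_allele(ch$v_call), j_gene = strip_allele(ch$j_call),
      cdrh3 = cdrs$H3$sequence, stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " chain(s) excluded from clonotyping ",
            "(missing gene call or CDRH3)")
  }
  if (length(recs) == 0L) return(list())
  df <- do.call(rbind, recs)
  part_key <- paste(df$v_gene, df$j_gene, nchar(df$cdrh3), sep = "/")
  parts <- split(seq_len(nrow(df)), part_key)
  parts <- parts[order(vapply(parts, min, 1L))]
  out <- list()
  emit <- function(rows, rep_cdrh3, idents) {
    sub <- df[rows, c("repertoire_id", "read_id", "cdrh3")]
    sub$identity <- idents
    out[[length(out) + 1L]] <<- structure(
      list(v_gene = df$v_gene[rows[1]], j_gene = df$j_gene[rows[1]],
           cdrh3_representative = rep_cdrh3,
           key_string = clonotype_key(df$v_gene[rows[1]],
                                      df$j_gene[rows[1]], rep_cdrh3),
           members = sub),
      class = "clonotype")
  }
  for (rows in parts) {
    if (mode == "briney_exact") {
      by_seq <- split(rows, df$cdrh3[rows])
      by_seq <- by_seq[order(vapply(by_seq, min, 1L))]
      for (g in by_seq) emit(g, df$cdrh3[g[1]], rep(1, length(g)))
    } else {
      reps_rows <- list()
      for (i in rows) {
        placed <- FALSE
        for (k in seq_along(reps_rows)) {
          ident <- .hamming_identity(df$cdrh3[i],
                                     df$cdrh3[reps_rows[[k]]$rep[1]])
          if (ident >= identity - 1e-12) {
            reps_rows[[k]]$rows <- c(reps_rows[[k]]$rows, i)
            reps_rows[[k]]$idents <- c(reps_rows[[k]]$idents, ident)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          reps_rows[[length(reps_rows) + 1L]] <-
            list(rep = i, rows = i, idents = 1)
        }
      }
      for (g in reps_rows) emit(g$rows, df$cdrh3[g$rep], g$idents)
    }
  }
  out
}

#' @export
print.clonotype <- function(x, ...) {
  cat(sprintf("<clonotype %s: %d member(s)>\n", x$key_string,
              nrow(x$members)))
  invisible(x)
}

#' Public clonotype counts across chained repertoires
#'
#' Pools the VH chains of the ordered repertoires, clusters clonotypes
#' once, then counts — for each step k — the clonotypes with members from
#' every one of the first k repertoires.
#'
#' @param repertoires Named (ordered) list: repertoire id -> list of VH
#'   [numbered_chain()].
#' @param mode Clonotype definition (see [cluster_clonotypes()]).
#' @return List with `steps` (data frame `step`, `repertoire`,
#'   `cumulative_clonotypes`, `public`, `public_pct`) and `clonotypes`.
#' @export
public_clonotype_counts <- function(repertoires,
                                    mode = c("briney_exact", "soto_80")) {
  mode <- match.arg(mode)
  stopifnot(length(repertoires) >= 1L)
  pooled <- list()
  for (id in names(repertoires)) {
    for (ch in repertoires[[id]]) {
      pooled[[length(pooled) + 1L]] <- list(repertoire_id = id, chain = ch)
    }
  }
  clons <- cluster_clonotypes(pooled, mode)
  ids <- names(repertoires)
  steps <- lapply(seq_along(ids), function(k) {
    seen <- ids[seq_len(k)]
    # clonotypes observed within the first k repertoires
    in_scope <- Filter(function(cl)
      any(cl$members$repertoire_id %in% seen), clons)
    public <- sum(vapply(in_scope, function(cl)
      all(seen %in% cl$members$repertoire_id), TRUE))
    data.frame(step = k, repertoire = ids[k],
               cumulative_clonotypes = length(in_scope),
               public = public,
               public_pct = 100 * public / max(1L, length(in_scope)),
               stringsAsFactors = FALSE)
  })
  list(steps = do.call(rbind, steps), clonotypes = clons)
}

#' Closest germline V gene and identity
#'
#' Maximal sequence identity over shared occupied V-region positions
#' (IMGT numbers <= 104) between the chain and each IMGT-aligned germline
#' sequence; identity = matches / shared positions. Ties break to the
#' lexicographically first gene name; an empty overlap with every gene
#' yields identity 0 with the `no_overlap` flag set.
#'
#' @param chain A [numbered_chain()].
#' @param germline_set Named list: gene name -> named character vector of
#'   residues by IMGT position.
#' @return List `gene`, `identity`, `no_overlap`.
#' @export
closest_germline_identity <- function(chain, germline_set) {
  stopifnot(length(germline_set) > 0L)
  seq <- chain_sequence(chain)
  vnum <- parse_imgt_positions(names(seq))$num
  vseq <- seq[vnum <= 104L]
  best <- list(gene = NA_character_, identity = -1)
  for (gene in sort(names(germline_set))) {
    g <- germline_set[[gene]]
    gnum <- parse_imgt_positions(names(g))$num
    g <- g[gnum <= 104L]
    shared <- intersect(names(vseq), names(g))
    if (length(shared) == 0L) next
    ident <- sum(vseq[shared] == g[shared]) / length(shared)
    if (ident > best$identity + 1e-12) {
      best <- list(gene = gene, identity = ident)
    }
  }
  if (best$identity < 0) {
    return(list(gene = NA_character_, identity = 0, no_overlap = TRUE))
  }
  c(best, list(no_overlap = FALSE))
}
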