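# Reading, writing and partitioning numbered repertoire snapshots.

#' Construct a repertoire snapshot
#'
#' @param snapshot_id Snapshot label.
#' @param vh,vl Lists of [numbered_chain()] objects (`H` and `L`
#'   respectively).
#' @param metadata Named character list (e.g. `individual`, `timepoint`).
#' @return Object of class `repertoire_snapshot`.
#' @export
repertoire_snapshot <- function(snapshot_id, vh = list(), vl = list(),
                                metadata = list()) {
  stopifnot(all(vapply(vh, function(c) c$chain_type == "H", TRUE)),
            all(vapply(vl, function(c) c$chain_type == "L", TRUE)))
  structure(
    list(snapshot_id = snapshot_id, vh = vh, vl = vl, metadata = metadata),
    class = "repertoire_snapshot"
  )
}

#' @export
print.repertoire_snapshot <- function(x, ...) {
  cat(sprintf("<repertoire_snapshot %s: %d VH, %d VL>\n",
              x$snapshot_id, length(x$vh), length(x$vl)))
  invisible(x)
}

# Build a chain from one parsed record, or return a reason string.
.record_to_chain <- function(read_id, chain_type, positions, residues,
                             v_call, j_call, isotype) {
  tryCatch(
    numbered_chain(read_id, chain_type, positions, residues,
                   v_call, j_call, isotype),
    error = function(e) conditionMessage(e)
  )
}

#' Read an IMGT-numbered repertoire snapshot
#'
#' Supported dialects:
#' \describe{
#'   \item{`oas_csv`}{CSV with columns `read_id`, `chain_type`,
#'     `imgt_positions` (space-separated IMGT labels), `sequence`
#'     (amino-acid string parallel to the positions), `v_call`, `j_call`
#'     and optionally `isotype`.}
#'   \item{`fasta_numbering`}{A FASTA file of amino-acid sequences plus a
#'     sidecar TSV (`<path>.numbering.tsv`, or given via `numbering_path`)
#'     with columns `read_id`, `chain_type`, `position`, `residue`,
#'     `v_call`, `j_call`, one row per residue in sequence order.}
#' }
#' Malformed individual records (non-standard residues, inconsistent
#' numbering) are skipped with a warning and logged in the `"drops"`
#' attribute; an unreadable file is fatal.
#'
#' @param path Input file path.
#' @param format `"oas_csv"` or `"fasta_numbering"`.
#' @param snapshot_id Snapshot label (defaults to the file name).
#' @param metadata Named list of snapshot metadata.
#' @param numbering_path Sidecar numbering table for `fasta_numbering`.
#' @return A [repertoire_snapshot()] with attribute `"drops"`: a data frame
#'   of dropped read ids and reason codes.
#' @export
read_numbered_repertoire <- function(path,
                                     format = c("oas_csv", "fasta_numbering"),
                                     snapshot_id = basename(path),
                                     metadata = list(),
                                     numbering_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "oas_csv") {
    recs <- .parse_oas_csv(path)
  } else {
    recs <- .parse_fasta_numbering(path, numbering_path)
  }
  vh <- list(); vl <- list()
  drops <- list()
  for (r in recs) {
    res <- .record_to_chain(r$read_id, r$chain_type, r$positions, r$residues,
                            r$v_call, r$j_call, r$isotype)
    if (is.character(res)) {
      drops[[length(drops) + 1L]] <- data.frame(
        read_id = r$read_id, reason = res, stringsAsFactors = FALSE)
      next
    }
    if (res$chain_type == "H") vh[[length(vh) + 1L]] <- res
    else vl[[length(vl) + 1L]] <- res
  }
  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(read_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (nrow(drops) > 0) {
    warning(nrow(drops), " record(s) dropped while reading ", path)
  }
  snap <- repertoire_snapshot(snapshot_id, vh, vl, metadata)
  attr(snap, "drops") <- drops
  snap
}

.parse_oas_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("unreadable CSV ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0) return(list())
  needed <- c("read_id", "chain_type", "imgt_positions", "sequence",
              "v_call", "j_call")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("OAS-style CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"isotype" %in% names(df)) df$isotype <- NA_character_
  lapply(seq_len(nrow(df)), function(i) {
    list(
      read_id = df$read_id[i],
      chain_type = df$chain_type[i],
      positions = strsplit(df$imgt_positions[i], " ", fixed = TRUE)[[1]],
      residues = strsplit(df$sequence[i], "")[[1]],
      v_call = df$v_call[i],
      j_call = df$j_call[i],
      isotype = df$isotype[i]
    )
  })
}

.parse_fasta_numbering <- function(path, numbering_path) {
  if (is.null(numbering_path)) {
    numbering_path <- paste0(path, ".numbering.tsv")
  }
  if (!file.exists(numbering_path)) {
    stop("numbering sidecar not found: ", numbering_path)
  }
  lines <- readLines(path)
  heads <- grep("^>", lines)
  seqs <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    seqs[[id]] <- paste(lines[(heads[i] + 1L):to], collapse = "")
  }
  num <- utils::read.delim(numbering_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  split_num <- split(num, num$read_id)
  lapply(names(seqs), function(id) {
    tab <- split_num[[id]]
    if (is.null(tab)) {
      return(list(read_id = id, chain_type = "?", positions = character(),
                  residues = strsplit(seqs[[id]], "")[[1]],
                  v_call = NA_character_, j_call = NA_character_,
                  isotype = NA_character_))
    }
    list(
      read_id = id,
      chain_type = tab$chain_type[1],
      positions = tab$position,
      residues = tab$residue,
      v_call = tab$v_call[1],
      j_call = tab$j_call[1],
      isotype = NA_character_
    )
  })
}

#' Write a snapshot as an OAS-style CSV
#'
#' Inverse of [read_numbered_repertoire()] for the `oas_csv` dialect:
#' reading the written file yields an identical snapshot.
#'
#' @param snapshot A [repertoire_snapshot()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  chains <- c(snapshot$vh, snapshot$vl)
  df <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(
      read_id = ch$read_id,
      chain_type = ch$chain_type,
      imgt_positions = paste(ch$positions, collapse = " "),
      sequence = paste(ch$residues, collapse = ""),
      v_call = ch$v_call,
      j_call = ch$j_call,
      isotype = ch$isotype,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(df)) {
    df <- data.frame(read_id = character(), chain_type = character(),
                     imgt_positions = character(), sequence = character(),
                     v_call = character(), j_call = character(),
                     isotype = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Retain only deeply sequenced snapshots
#'
#' Keeps snapshots whose VH count is strictly greater than `min_vh` and
#' whose VL count is strictly greater than `min_vl`. Counts may be supplied
#' externally (for manifest-level filtering without loading reads).
#'
#' @param snapshots List of [repertoire_snapshot()], or a data frame with
#'   columns `snapshot_id`, `n_vh`, `n_vl`.
#' @param min_vh,min_vl Strict lower bounds on read counts (default
#'   100,000 each, the depth rule used for naive baseline cohorts).
#' @return The filtered list (or data frame rows), same order.
#' @export
select_deep_datasets <- function(snapshots, min_vh = 1e5, min_vl = 1e5) {
  if (is.data.frame(snapshots)) {
    return(snapshots[snapshots$n_vh > min_vh & snapshots$n_vl > min_vl, ,
                     drop = FALSE])
  }
  keep <- vapply(snapshots, function(s) {
    length(s$vh) > min_vh && length(s$vl) > min_vl
  }, TRUE)
  snapshots[keep]
}

# Default mapping from timepoint labels to classes for a vaccination
# time course: samples taken 8 days, 2 days and 1 hour before vaccination
# form the "before" pool; 1 hour and 1 day after are discarded as
# ambiguous; weeks 1-4 after form the "after" pool.
.default_timepoint_map <- function() {
  c("-8d" = "before", "-2d" = "before", "-1h" = "before",
    "+1h" = "discard", "+1d" = "discard",
    "+1w" = "after", "+2w" = "after", "+3w" = "after", "+4w" = "after")
}

#' Normalise a signed timepoint label to seconds
#'
#' Labels are `<sign><n><unit>` with unit `h` (hours), `d` (days) or
#' `w` (weeks), e.g. `"-8d"`, `"+2w"`.
#'
#' @param labels Character vector of timepoint labels.
#' @return Numeric vector of signed offsets in seconds.
#' @export
timepoint_seconds <- function(labels) {
  m <- regmatches(labels, regexec("^([+-])([0-9]+)([hdw])$", labels))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable timepoint label(s): ",
                     paste(labels[bad], collapse = ", "))
  sign <- vapply(m, function(x) if (x[2] == "-") -1 else 1, 1)
  n <- vapply(m, function(x) as.numeric(x[3]), 1)
  unit <- vapply(m, function(x) x[4], "")
  mult <- unname(c(h = 3600, d = 86400, w = 604800)[unit])
  sign * n * mult
}

#' Partition vaccination-course snapshots into before/after/discarded
#'
#' Applies a timepoint-label mapping (default: before = -8d/-2d/-1h,
#' discarded = +1h/+1d, after = +1w..+4w) to each snapshot's
#' `metadata$timepoint`; unknown labels are fatal unless `mapping`
#' covers them. The partition depends only on labels, not input order.
#'
#' @param snapshots List of [repertoire_snapshot()] with `timepoint`
#'   metadata.
#' @param mapping Named character vector label -> one of
#'   `"before"`, `"after"`, `"discard"`.
#' @return List with elements `before`, `after`, `discarded`, each a list
#'   of snapshots (original order preserved within each class).
#' @export
partition_vaccination_timepoints <- function(snapshots,
                                             mapping = .default_timepoint_map()) {
  labels <- vapply(snapshots, function(s) {
    tp <- s$metadata$timepoint
    if (is.null(tp)) NA_character_ else as.character(tp)
  }, "")
  unknown <- !is.na(labels) & !(labels %in% names(mapping))
  if (any(is.na(labels)) || any(unknown)) {
    stop("snapshot(s) with missing/unknown timepoint label: ",
         paste(unique(labels[is.na(labels) | unknown]), collapse = ", "))
  }
  cls <- mapping[labels]
  list(
    before = snapshots[cls == "before"],
    after = snapshots[cls == "after"],
    discarded = snapshots[cls == "discard"]
  )
}

#' Pool snapshots into one
#'
#' Concatenates the VH and VL reads of several snapshots (e.g. all
#' "before vaccination" timepoints of one individual).
#'
#' @param snapshots List of [repertoire_snapshot()].
#' @param snapshot_id Label for the pooled snapshot.
#' @return A [repertoire_snapshot()].
#' @export
pool_snapshots <- function(snapshots, snapshot_id = "pooled") {
  repertoire_snapshot(
    snapshot_id,
    vh = do.call(c, c(lapply(snapshots, `[[`, "vh"), list(list()))),
    vl = do.call(c, c(lapply(snapshots, `[[`, "vl"), list(list()))),
    metadata = list(pooled_from = vapply(snapshots, `[[`, "", "snapshot_id"))
  )
}
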