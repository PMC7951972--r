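# Versioned JSON archive for template libraries.

.LIBRARY_FORMAT <- "repstruct-library/1"

# Cheap content checksum (corruption detection, not cryptographic).
.text_checksum <- function(s) {
  v <- utf8ToInt(s)
  mix <- sum((v %% 251) * (seq_along(v) %% 997)) %% 2147483647
  sprintf("%d:%d", nchar(s), mix)
}

.mat_ser <- function(m) {
  list(dim = dim(m), dimnames = dimnames(m), data = as.numeric(m))
}

.mat_deser <- function(x) {
  m <- array(as.numeric(unlist(x$data)), dim = as.integer(unlist(x$dim)))
  if (!is.null(x$dimnames) && length(x$dimnames)) {
    dimnames(m) <- lapply(x$dimnames, function(d)
      as.character(unlist(d)))
  }
  m
}

.serialize_library <- function(library) {
  list(
    cdr_templates = lapply(unname(library$cdr_templates), function(t) {
      list(template_id = t$template_id, region = t$region,
           loop_ca = .mat_ser(t$loop_ca), anchor_ca = .mat_ser(t$anchor_ca),
           loop_seq = t$loop_seq, env_classes = t$env_classes,
           source_structure = t$source_structure,
           release_date = format(t$release_date),
           organism_human = t$organism_human)
    }),
    frameworks = lapply(unname(library$frameworks), function(f) {
      list(framework_id = f$framework_id, chain_type = f$chain_type,
           positions = names(f$framework_seq),
           residues = unname(f$framework_seq),
           anchors = lapply(f$anchors, .mat_ser),
           release_date = format(f$release_date))
    }),
    reference_fvs = lapply(unname(library$reference_fvs), function(r) {
      list(fv_id = r$fv_id, interface_residues = r$interface_residues,
           orientation_coords = .mat_ser(r$orientation_coords),
           release_date = format(r$release_date))
    }),
    substitution_table = .mat_ser(library$substitution_table),
    ess_thresholds = list(
      cdr3_bands = library$ess_thresholds$cdr3_bands,
      default = library$ess_thresholds$default
    ),
    interface_positions = library$interface_positions,
    cdr_rmsd = lapply(library$cdr_rmsd, .mat_ser),
    orientation_rmsd = .mat_ser(library$orientation_rmsd)
  )
}

#' Save a template library to a versioned JSON archive
#'
#' Lossless (full numeric precision) serialization of all library fields
#' including the precomputed RMSD matrices, with a format-version tag and
#' a content checksum verified on load.
#'
#' @param library A [template_library()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "template_library"))
  payload <- jsonlite::toJSON(.serialize_library(library),
                              digits = NA, auto_unbox = TRUE, null = "null")
  doc <- sprintf('{"format":"%s","checksum":"%s","payload":%s}',
                 .LIBRARY_FORMAT, .text_checksum(payload), payload)
  writeLines(doc, path)
  invisible(path)
}

#' Load a template library from a JSON archive
#'
#' Fatal on unreadable/truncated files, unknown format versions, or
#' checksum mismatches.
#'
#' @param path Archive path written by [save_library()].
#' @return A [template_library()].
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library archive not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                       simplifyVector = FALSE),
    error = function(e) stop("corrupt library archive ", path, ": ",
                             conditionMessage(e))
  )
  if (!identical(doc$format, .LIBRARY_FORMAT)) {
    stop("library archive ", path, " has unsupported format version: ",
         doc$format %||% "<missing>")
  }
  payload_json <- jsonlite::toJSON(doc$payload, digits = NA,
                                   auto_unbox = TRUE, null = "null")
  # re-serialized payload must hash identically; guards truncation and edits
  if (!identical(.text_checksum(payload_json), doc$checksum)) {
    stop("library archive ", path, " failed checksum verification")
  }
  p <- doc$payload
  tpls <- lapply(p$cdr_templates, function(t) {
    cdr_template(t$template_id, t$region, .mat_deser(t$loop_ca),
                 .mat_deser(t$anchor_ca), t$loop_seq,
                 as.character(unlist(t$env_classes)),
                 t$source_structure, t$release_date, t$organism_human)
  })
  fws <- lapply(p$frameworks, function(f) {
    framework_template(
      f$framework_id, f$chain_type,
      stats::setNames(as.character(unlist(f$residues)),
                      as.character(unlist(f$positions))),
      lapply(f$anchors, .mat_deser), f$release_date)
  })
  refs <- lapply(p$reference_fvs, function(r) {
    reference_fv(r$fv_id, r$interface_residues,
                 .mat_deser(r$orientation_coords), r$release_date)
  })
  bands <- p$ess_thresholds$cdr3_bands
  th <- list(
    cdr3_bands = data.frame(
      min_len = vapply(bands, function(b) as.integer(b$min_len), 1L),
      max_len = vapply(bands, function(b) as.integer(b$max_len), 1L),
      score = vapply(bands, function(b) as.numeric(b$score), 1)
    ),
    default = as.numeric(p$ess_thresholds$default)
  )
  ip <- data.frame(
    chain = vapply(p$interface_positions, function(r) r$chain, ""),
    position = vapply(p$interface_positions,
                      function(r) as.character(r$position), ""),
    stringsAsFactors = FALSE
  )
  lib <- template_library(tpls, fws, refs,
                          substitution_table = .mat_deser(p$substitution_table),
                          ess_thresholds = th,
                          interface_positions = ip,
                          precompute = FALSE)
  lib$cdr_rmsd <- lapply(p$cdr_rmsd, .mat_deser)
  lib$orientation_rmsd <- .mat_deser(p$orientation_rmsd)
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a
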