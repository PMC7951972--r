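# The structural knowledge base: CDR loop templates, framework templates,
# reference Fvs with orientation coordinates, the environment-specific
# substitution (ESS) scorer, and FREAD-like template assignment.

cdr_key <- function(region, length) paste0(region, ":", length)

#' Construct a CDR loop template
#'
#' A template carries the Calpha trace of a solved loop of a given North
#' CDR region and length, plus the 5 N-terminal and 5 C-terminal anchor
#' residues used to graft it onto a framework.
#'
#' @param template_id Unique template identifier.
#' @param region One of `H1`,`H2`,`H3`,`L1`,`L2`,`L3`.
#' @param loop_ca length x 3 matrix of loop Calpha coordinates (angstroms).
#' @param anchor_ca 10 x 3 matrix of anchor Calpha coordinates
#'   (5 N-terminal then 5 C-terminal).
#' @param loop_seq One-letter amino-acid sequence of the loop.
#' @param env_classes Per-position environment labels (e.g. `"buried"` /
#'   `"exposed"`); recycled if length 1.
#' @param source_structure Identifier of the source structure (templates
#'   for CDR1 and CDR2 of the same chain share this when they derive from
#'   one structure).
#' @param release_date Release date (`Date` or ISO string) used for
#'   date-blinded reruns.
#' @param organism_human Source-organism label (kept but never used to
#'   filter templates).
#' @return Object of class `cdr_template`.
#' @export
cdr_template <- function(template_id, region, loop_ca, anchor_ca, loop_seq,
                         env_classes = "exposed",
                         source_structure = template_id,
                         release_date = as.Date("2000-01-01"),
                         organism_human = TRUE) {
  region <- match.arg(region, c("H1", "H2", "H3", "L1", "L2", "L3"))
  loop_ca <- as.matrix(loop_ca)
  anchor_ca <- as.matrix(anchor_ca)
  len <- nchar(loop_seq)
  if (nrow(loop_ca) != len || ncol(loop_ca) != 3L) {
    stop("loop_ca must be length x 3 for template ", template_id)
  }
  if (nrow(anchor_ca) != 10L || ncol(anchor_ca) != 3L) {
    stop("anchor_ca must be 10 x 3 for template ", template_id)
  }
  if (!all(is.finite(loop_ca)) || !all(is.finite(anchor_ca))) {
    stop("non-finite coordinates in template ", template_id)
  }
  if (length(env_classes) == 1L) env_classes <- rep(env_classes, len)
  stopifnot(length(env_classes) == len)
  structure(
    list(template_id = template_id, region = region, length = len,
         loop_ca = loop_ca, anchor_ca = anchor_ca, loop_seq = loop_seq,
         env_classes = env_classes, source_structure = source_structure,
         release_date = as.Date(release_date),
         organism_human = organism_human),
    class = "cdr_template"
  )
}

#' Construct a framework template
#'
#' A variable domain with the North CDRs excised: the remaining IMGT
#' position -> residue mapping plus, for each CDR of the chain type, the
#' 10 anchor Calpha coordinates onto which loop templates are grafted.
#'
#' @param framework_id Unique identifier.
#' @param chain_type `"H"` or `"L"`.
#' @param framework_seq Named character vector, residues named by IMGT
#'   position (CDR windows excluded).
#' @param anchors Named list of 10 x 3 matrices, one per CDR region of the
#'   chain type.
#' @param release_date Release date for date-blinded reruns.
#' @return Object of class `framework_template`.
#' @export
framework_template <- function(framework_id, chain_type, framework_seq,
                               anchors,
                               release_date = as.Date("2000-01-01")) {
  chain_type <- match.arg(chain_type, c("H", "L"))
  regions <- names(north_cdr_windows(chain_type))
  if (!all(regions %in% names(anchors))) {
    stop("framework ", framework_id, " lacks anchors for all CDRs")
  }
  for (r in regions) {
    a <- as.matrix(anchors[[r]])
    if (nrow(a) != 10L || ncol(a) != 3L) {
      stop("framework ", framework_id, ": anchor set ", r, " must be 10 x 3")
    }
    anchors[[r]] <- a
  }
  structure(
    list(framework_id = framework_id, chain_type = chain_type,
         framework_seq = framework_seq, anchors = anchors[regions],
         release_date = as.Date(release_date)),
    class = "framework_template"
  )
}

#' Construct a reference Fv
#'
#' A solved VH-VL pairing used for orientation prediction: its residues at
#' the library's 20 key interface positions, and pseudo-atom coordinates
#' describing its VH-VL packing, expressed in a common heavy-chain frame
#' shared library-wide (so orientation dissimilarity is a plain coordinate
#' RMSD).
#'
#' @param fv_id Unique identifier.
#' @param interface_residues Length-20 string of residues at the key
#'   interface positions (gap symbol `-` allowed).
#' @param orientation_coords K x 3 matrix of pseudo-atom coordinates in the
#'   common heavy-chain frame.
#' @param release_date Release date for date-blinded reruns.
#' @return Object of class `reference_fv`.
#' @export
reference_fv <- function(fv_id, interface_residues, orientation_coords,
                         release_date = as.Date("2000-01-01")) {
  if (nchar(interface_residues) != 20L) {
    stop("reference Fv ", fv_id, " must carry exactly 20 interface residues")
  }
  orientation_coords <- as.matrix(orientation_coords)
  stopifnot(ncol(orientation_coords) == 3L,
            all(is.finite(orientation_coords)))
  structure(
    list(fv_id = fv_id, interface_residues = interface_residues,
         orientation_coords = orientation_coords,
         release_date = as.Date(release_date)),
    class = "reference_fv"
  )
}

# Physicochemical groups behind the default substitution table.
.aa_groups <- list(
  c("I", "L", "V", "M"), c("F", "W", "Y"), c("K", "R", "H"),
  c("D", "E"), c("N", "Q"), c("S", "T"), c("A", "G"), c("C"), c("P")
)

#' Default environment-specific substitution table
#'
#' A 3-D array `[env_class, template_aa, query_aa]` with two environment
#' classes (`buried`, `exposed`). Scaled so an exact match scores 5 per
#' position (making the published CDR3 admission bands of 25/35/40
#' attainable by a self-match at every length), a same-group conservative
#' substitution 4, and any other substitution 0; row maxima therefore sit
#' on the diagonal. Fully replaceable by an imported table.
#'
#' @return Numeric array with dimnames.
#' @export
default_substitution_table <- function() {
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (g in .aa_groups) S[g, g] <- 4
  diag(S) <- 5
  arr <- array(0, dim = c(2, 20, 20),
               dimnames = list(c("buried", "exposed"),
                               AA_ALPHABET, AA_ALPHABET))
  arr["buried", , ] <- S
  arr["exposed", , ] <- S
  arr
}

#' Default ESS admission thresholds
#'
#' CDR3 loops (H3 and L3) are admitted by length band: lengths up to 8
#' require ESS >= 25, lengths 9-10 require >= 35, lengths 11 and above
#' require >= 40. All other regions use the conventional default of 25.
#'
#' @return List with `cdr3_bands` (data frame `min_len`, `max_len`,
#'   `score`) and `default`.
#' @export
default_ess_thresholds <- function() {
  list(
    cdr3_bands = data.frame(
      min_len = c(0L, 9L, 11L),
      max_len = c(8L, 10L, .Machine$integer.max),
      score = c(25, 35, 40)
    ),
    default = 25
  )
}

#' ESS admission threshold for one region and loop length
#'
#' @param library A [template_library()] (or a thresholds list).
#' @param region CDR region label.
#' @param length Loop length.
#' @return Minimum admissible ESS score.
#' @export
ess_threshold <- function(library, region, length) {
  th <- if (inherits(library, "template_library")) library$ess_thresholds
        else library
  if (region %in% c("H3", "L3")) {
    b <- th$cdr3_bands
    hit <- which(length >= b$min_len & length <= b$max_len)[1]
    if (is.na(hit)) stop("no ESS band covers CDR3 length ", length)
    return(b$score[hit])
  }
  th$default
}

#' Environment-specific substitution score of a query loop vs a template
#'
#' Position-wise sum of `table[env_class(pos), template_aa(pos),
#' query_aa(pos)]` over the loop. Deterministic; equal lengths required;
#' a missing table entry is an error (tables must be total).
#'
#' @param query_cdr A CDR slice (from [extract_north_cdrs()]) or a plain
#'   amino-acid string.
#' @param template A [cdr_template()].
#' @param table Substitution array as from [default_substitution_table()].
#' @return Numeric score.
#' @export
ess_score <- function(query_cdr, template, table) {
  q <- if (is.character(query_cdr)) query_cdr else query_cdr$sequence
  if (nchar(q) != template$length) {
    stop("query length ", nchar(q), " != template length ", template$length)
  }
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(template$loop_seq, "")[[1]]
  idx <- cbind(match(template$env_classes, dimnames(table)[[1]]),
               match(ta, dimnames(table)[[2]]),
               match(qa, dimnames(table)[[3]]))
  if (anyNA(idx)) stop("substitution table lacks entries for this loop")
  sum(table[idx])
}

#' Assemble a template library
#'
#' Indexes CDR templates by (region, length) and precomputes the pairwise
#' loop RMSD matrix for every (region, length) bin (templates superposed on
#' their 10 anchor Calpha, RMSD over loop Calpha) and the pairwise
#' orientation RMSD matrix over reference Fvs.
#'
#' @param cdr_templates List of [cdr_template()].
#' @param frameworks List of [framework_template()].
#' @param reference_fvs List of [reference_fv()].
#' @param substitution_table Array as [default_substitution_table()].
#' @param ess_thresholds As [default_ess_thresholds()].
#' @param interface_positions Data frame with columns `chain` (`H`/`L`) and
#'   `position` (IMGT labels), exactly 20 rows; row order defines signature
#'   order.
#' @param precompute Recompute RMSD matrices (default TRUE); set FALSE when
#'   restoring matrices from an archive.
#' @return Object of class `template_library`.
#' @export
template_library <- function(cdr_templates, frameworks, reference_fvs,
                             substitution_table = default_substitution_table(),
                             ess_thresholds = default_ess_thresholds(),
                             interface_positions,
                             precompute = TRUE) {
  if (nrow(interface_positions) != 20L) {
    stop("interface_positions must list exactly 20 key positions")
  }
  names(cdr_templates) <- vapply(cdr_templates, `[[`, "", "template_id")
  names(frameworks) <- vapply(frameworks, `[[`, "", "framework_id")
  names(reference_fvs) <- vapply(reference_fvs, `[[`, "", "fv_id")
  keys <- vapply(cdr_templates, function(t) cdr_key(t$region, t$length), "")
  index <- split(names(cdr_templates), keys)
  lib <- structure(
    list(
      version = "repstruct-library/1",
      cdr_templates = cdr_templates,
      cdr_index = index,
      frameworks = frameworks,
      reference_fvs = reference_fvs,
      substitution_table = substitution_table,
      ess_thresholds = ess_thresholds,
      interface_positions = interface_positions,
      cdr_rmsd = list(),
      orientation_rmsd = NULL
    ),
    class = "template_library"
  )
  if (precompute) {
    lib$cdr_rmsd <- stats::setNames(lapply(names(index), function(k) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      precompute_cdr_rmsd_matrix(lib, parts[1], as.integer(parts[2]))
    }), names(index))
    lib$orientation_rmsd <- .orientation_matrix(reference_fvs)
  }
  lib
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf(paste0("<template_library: %d CDR templates in %d ",
                     "(region,length) bins, %d frameworks, %d reference Fvs>\n"),
              length(x$cdr_templates), length(x$cdr_index),
              length(x$frameworks), length(x$reference_fvs)))
  invisible(x)
}

#' Template ids available for one (region, length) bin
#'
#' @param library A [template_library()].
#' @param region CDR region label.
#' @param length Loop length.
#' @return Character vector of template ids (possibly empty).
#' @export
library_templates <- function(library, region, length) {
  ids <- library$cdr_index[[cdr_key(region, length)]]
  if (is.null(ids)) character() else ids
}

#' Pairwise loop RMSD matrix for one (region, length) bin
#'
#' For each template pair, the second template is rigidly superposed onto
#' the first over the 10 anchor Calpha (the graft frame), and the RMSD is
#' taken over the loop Calpha. Symmetric with zero diagonal.
#'
#' @param library A [template_library()].
#' @param region CDR region label.
#' @param length Loop length.
#' @return Symmetric numeric matrix with template-id dimnames.
#' @export
precompute_cdr_rmsd_matrix <- function(library, region, length) {
  ids <- sort(library_templates(library, region, length))
  n <- length(ids)
  if (n == 0L) stop("no templates at ", cdr_key(region, length))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(D)
  tpls <- library$cdr_templates[ids]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- anchor_frame_loop_rmsd(tpls[[i]], tpls[[j]])
    }
  }
  D
}

#' Anchor-frame loop RMSD between two CDR templates
#'
#' Superposes template B onto template A over the 10 anchor Calpha (the
#' graft frame), then takes the Calpha RMSD over the loops. Symmetric.
#'
#' @param tpl_a,tpl_b Same-region, same-length [cdr_template()] objects.
#' @return RMSD in angstroms.
#' @export
anchor_frame_loop_rmsd <- function(tpl_a, tpl_b) {
  fit <- superpose_rmsd(tpl_a$anchor_ca, tpl_b$anchor_ca)
  moved <- tpl_b$loop_ca %*% t(fit$rotation) +
    matrix(fit$translation, nrow(tpl_b$loop_ca), 3, byrow = TRUE)
  coord_rmsd(tpl_a$loop_ca, moved)
}

.orientation_matrix <- function(reference_fvs) {
  ids <- sort(names(reference_fvs))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- coord_rmsd(
        reference_fvs[[ids[i]]]$orientation_coords,
        reference_fvs[[ids[j]]]$orientation_coords)
    }
  }
  M
}

#' Orientation RMSD between two reference Fvs
#'
#' Plain coordinate RMSD between the orientation pseudo-atoms, which are
#' pre-expressed in the library's common heavy-chain frame (no
#' re-superposition). Symmetric; zero iff the coordinates are identical.
#'
#' @param ref_a,ref_b [reference_fv()] objects.
#' @return RMSD in angstroms.
#' @export
orientation_rmsd <- function(ref_a, ref_b) {
  coord_rmsd(ref_a$orientation_coords, ref_b$orientation_coords)
}

#' Assign the closest framework to a chain
#'
#' Maximal sequence identity over the IMGT positions shared between the
#' chain and each same-chain-type framework (identity = matches / shared
#' occupied positions); ties broken by lexicographic framework id.
#'
#' @param chain A [numbered_chain()].
#' @param library A [template_library()].
#' @return The winning [framework_template()], or `NULL` when no framework
#'   shares any position with the chain (chain unmodellable).
#' @export
assign_framework <- function(chain, library) {
  fws <- Filter(function(f) f$chain_type == chain$chain_type,
                library$frameworks)
  if (length(fws) == 0L) return(NULL)
  seq <- chain_sequence(chain)
  ids <- sort(names(fws))
  best_id <- NULL
  best_ident <- -1
  for (id in ids) {
    fseq <- fws[[id]]$framework_seq
    shared <- intersect(names(seq), names(fseq))
    if (length(shared) == 0L) next
    ident <- sum(seq[shared] == fseq[shared]) / length(shared)
    if (ident > best_ident + 1e-12) {
      best_ident <- ident
      best_id <- id
    }
  }
  if (is.null(best_id)) return(NULL)
  fws[[best_id]]
}

#' FREAD-like template assignment for one CDR loop
#'
#' Candidates are the library templates of the query's region and length
#' whose ESS score against the query meets the admission threshold; each
#' candidate's anchor RMSD is the minimised Calpha RMSD between its 10
#' anchor residues and the framework's anchors for that region. The
#' admissible candidate with the lowest anchor RMSD wins (ties broken by
#' lexicographically lower template id).
#'
#' @param query A CDR slice (with `region` and `sequence`).
#' @param framework A [framework_template()] carrying anchors for the
#'   query's region.
#' @param library A [template_library()].
#' @return List with `region`, `template_id`, `ess`, `anchor_rmsd`; or
#'   `NULL` when no admissible template exists (loop unmodellable).
#' @export
assign_cdr_template <- function(query, framework, library) {
  region <- query$region
  len <- nchar(query$sequence)
  ids <- sort(library_templates(library, region, len))
  if (length(ids) == 0L) return(NULL)
  thr <- ess_threshold(library, region, len)
  fw_anchors <- framework$anchors[[region]]
  if (is.null(fw_anchors)) {
    stop("framework ", framework$framework_id, " lacks anchors for ", region)
  }
  ess <- vapply(ids, function(id) {
    ess_score(query$sequence, library$cdr_templates[[id]],
              library$substitution_table)
  }, 1)
  admissible <- ids[ess >= thr - 1e-9]
  if (length(admissible) == 0L) return(NULL)
  rmsd <- vapply(admissible, function(id) {
    superpose_rmsd(fw_anchors, library$cdr_templates[[id]]$anchor_ca)$rmsd
  }, 1)
  pick <- admissible[order(rmsd, admissible)][1]
  list(region = region, template_id = pick,
       ess = unname(ess[match(pick, ids)]),
       anchor_rmsd = unname(rmsd[match(pick, admissible)]))
}

#' Restrict a library to templates released before a cutoff date
#'
#' Removes CDR templates, frameworks and reference Fvs whose release date
#' is on or after `cutoff`, and re-derives the RMSD matrices for the
#' surviving entries. Used to rerun profiling blinded to recent template
#' structures.
#'
#' @param library A [template_library()].
#' @param cutoff A `Date` (or ISO string).
#' @return A new [template_library()].
#' @export
filter_library_by_date <- function(library, cutoff) {
  cutoff <- as.Date(cutoff)
  keep_t <- Filter(function(t) t$release_date < cutoff, library$cdr_templates)
  keep_f <- Filter(function(f) f$release_date < cutoff, library$frameworks)
  keep_r <- Filter(function(r) r$release_date < cutoff, library$reference_fvs)
  template_library(keep_t, keep_f, keep_r,
                   substitution_table = library$substitution_table,
                   ess_thresholds = library$ess_thresholds,
                   interface_positions = library$interface_positions)
}
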