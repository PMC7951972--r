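# Synthetic fixtures: template libraries with planted geometric clusters
# and multi-individual cohorts with known modellability, pairing,
# distinct-structure and public/private ground truth.

#' Cohort specification for synthetic data generation
#'
#' Defines the study conditions emulated by the generator: a small cohort
#' of unrelated individuals whose repertoires realise a set of planted
#' binding-site structures, a fraction of which are public (present in
#' every individual). Geometric scales are margin-enforced — within-cluster
#' template RMSD below half the clustering gate, between-cluster RMSD
#' above twice it — so that greedy order-dependence can never flip the
#' planted ground truth.
#'
#' @param n_individuals Number of individuals (default 3).
#' @param n_structures Number of planted distinct structures (default 50).
#' @param public_fraction Fraction of planted structures present in every
#'   individual (default 0.4).
#' @param members_per_cluster Loop templates per planted geometric cluster
#'   (default 2); each yields one read variant per structure.
#' @param n_decoys Unmodellable decoy reads per chain per individual
#'   (default 4).
#' @param within_rmsd Target within-cluster template RMSD scale in
#'   angstroms (must stay below `cdr_threshold / 2`).
#' @param between_rmsd Minimum between-cluster template RMSD (must exceed
#'   `2 * cdr_threshold`).
#' @param orientation_within,orientation_between Same scales for the
#'   orientation pseudo-atom clusters, against the orientation gate.
#' @param h3_lengths,l3_lengths CDR3 length menus the planted length
#'   vectors are drawn from.
#' @param late_date_fraction Fraction of loop templates stamped with a
#'   recent release date (for date-blinded reruns).
#' @param orientation_threshold,cdr_threshold The clustering gates the
#'   margins are enforced against (profiler defaults).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 3L,
                        n_structures = 50L,
                        public_fraction = 0.4,
                        members_per_cluster = 2L,
                        n_decoys = 4L,
                        within_rmsd = 0.3,
                        between_rmsd = 2.5,
                        orientation_within = 0.4,
                        orientation_between = 4.0,
                        h3_lengths = 10:14,
                        l3_lengths = 9:11,
                        late_date_fraction = 0.15,
                        orientation_threshold = 1.5,
                        cdr_threshold = 1.0) {
  stopifnot(public_fraction >= 0, public_fraction <= 1,
            n_individuals >= 1, n_structures >= 1,
            members_per_cluster >= 1)
  if (!(within_rmsd < cdr_threshold / 2 && between_rmsd > 2 * cdr_threshold)) {
    stop("CDR margins violated: need within < threshold/2 < 2*threshold < between")
  }
  if (!(orientation_within < orientation_threshold / 2 &&
        orientation_between > 2 * orientation_threshold)) {
    stop("orientation margins violated")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_structures = as.integer(n_structures),
         public_fraction = public_fraction,
         members_per_cluster = as.integer(members_per_cluster),
         n_decoys = as.integer(n_decoys),
         within_rmsd = within_rmsd, between_rmsd = between_rmsd,
         orientation_within = orientation_within,
         orientation_between = orientation_between,
         h3_lengths = as.integer(h3_lengths),
         l3_lengths = as.integer(l3_lengths),
         late_date_fraction = late_date_fraction,
         orientation_threshold = orientation_threshold,
         cdr_threshold = cdr_threshold),
    class = "cohort_spec"
  )
}

# Fixed planted lengths for the non-CDR3 loops and framework layouts.
.FIXED_LENGTHS <- c(H1 = 13L, H2 = 10L, L1 = 11L, L2 = 8L)
.BG_BINS <- data.frame(
  region = c("H1", "H2", "L1", "L2", "H3", "H3", "L3"),
  length = c(15L, 9L, 12L, 9L, 9L, 15L, 8L),
  stringsAsFactors = FALSE
)
.H_FW_NUMS <- c(1:23, 41:54, 67:104, 118:128)
.L_FW_NUMS <- c(1:23, 41:54, 70:104, 118:128)
.H_IFACE <- c(41, 43, 45, 47, 50, 68, 70, 85, 89, 103)
.L_IFACE <- c(42, 44, 46, 49, 52, 71, 87, 96, 98, 100)
# framework positions carrying a per-structure identity barcode, standing
# in for FW1/junctional sequence diversity (outside the interface set)
.H_BARCODE <- c(2, 6, 9, 12, 16, 19, 21, 78)
.L_BARCODE <- c(2, 6, 9, 12, 16, 19, 21, 78)

.rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                              collapse = "")

# Structure plan: length-vector combo, plus per-chain cluster ranks.
# heavy_rank indexes a structure within its CDRH3-length group and selects
# its H1/H2/H3 template clusters; light_rank likewise for the light chain.
# Two structures sharing a CDR3 length on a chain therefore never share
# any loop cluster on that chain (keeping their reads well below the 90%
# identity threshold), and same-length-vector structures differ in all six
# CDR clusters (keeping their combined CDR RMSD above the gate).
.structure_plan <- function(spec) {
  grid <- expand.grid(h3 = spec$h3_lengths, l3 = spec$l3_lengths)
  n_combos <- nrow(grid)
  i <- seq_len(spec$n_structures)
  combo <- ((i - 1L) %% n_combos) + 1L
  plan <- data.frame(
    structure_id = sprintf("PS%03d", i),
    h3_len = grid$h3[combo], l3_len = grid$l3[combo],
    stringsAsFactors = FALSE
  )
  plan$heavy_rank <- stats::ave(i, plan$h3_len, FUN = seq_along)
  plan$light_rank <- stats::ave(i, plan$l3_len, FUN = seq_along)
  plan
}

# Generate one (region, length) bin of clustered loop templates.
# Returns list(templates, table rows). Linked source ids are supplied by
# the caller so CDR1/CDR2 partners share a source structure.
.generate_bin <- function(region, length, n_clusters, spec, anchors_canon,
                          thresholds, sub_table, source_fmt) {
  m <- spec$members_per_cluster
  thr <- ess_threshold(thresholds, region, length)
  for (attempt in 1:50) {
    bases <- list()
    guard <- 0L
    while (length(bases) < n_clusters) {
      cand <- matrix(stats::runif(length * 3, 0, 8), length, 3)
      ok <- all(vapply(bases, function(b)
        coord_rmsd(b, cand) > spec$between_rmsd + 0.6, TRUE))
      if (ok) bases[[length(bases) + 1L]] <- cand
      guard <- guard + 1L
      if (guard > 500L) break
    }
    if (length(bases) < n_clusters) next
    tpls <- list()
    rows <- list()
    seqs <- character()
    for (cl in seq_len(n_clusters)) {
      for (mem in seq_len(m)) {
        # sequence unique enough that no other template admits it
        seq_ok <- FALSE
        for (s_try in 1:100) {
          sq <- .rand_aa(length)
          cross <- vapply(seqs, function(other)
            .ess_seq(sq, other, sub_table), 1)
          self_cross <- vapply(seqs, function(other)
            .ess_seq(other, sq, sub_table), 1)
          if (all(c(cross, self_cross) < thr)) {
            seq_ok <- TRUE
            break
          }
        }
        if (!seq_ok) break
        seqs <- c(seqs, sq)
        id <- sprintf("T%s%02d_c%d_m%d", region, length, cl, mem)
        late <- stats::runif(1) < spec$late_date_fraction
        tpls[[id]] <- cdr_template(
          id, region,
          loop_ca = bases[[cl]] +
            matrix(stats::rnorm(length * 3,
                                sd = spec$within_rmsd / sqrt(6)),
                   length, 3),
          anchor_ca = anchors_canon +
            matrix(stats::rnorm(30, sd = 0.02), 10, 3),
          loop_seq = sq,
          env_classes = rep(c("buried", "exposed"), length.out = length),
          source_structure = sprintf(source_fmt, cl, mem),
          release_date = if (late) as.Date("2020-06-01")
                         else as.Date("2015-01-01"))
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, length = length, cluster = cl, member = mem,
          template_id = id, late = late, stringsAsFactors = FALSE)
      }
    }
    if (length(tpls) < n_clusters * m) next
    # verify achieved margins in the anchor graft frame
    ok <- TRUE
    ids <- names(tpls)
    cl_of <- rep(seq_len(n_clusters), each = m)
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1L)) {
        d <- anchor_frame_loop_rmsd(tpls[[i]], tpls[[j]])
        lim_ok <- if (cl_of[i] == cl_of[j]) d < spec$cdr_threshold / 2
                  else d > 2 * spec$cdr_threshold
        if (!lim_ok) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      return(list(templates = tpls, rows = do.call(rbind, rows)))
    }
  }
  stop("failed to plant separated clusters at ", cdr_key(region, length),
       "; loosen the within/between scales")
}

# ESS between two raw sequences under a table (template side = second).
.ess_seq <- function(query, tpl_seq, table) {
  qa <- strsplit(query, "")[[1]]
  ta <- strsplit(tpl_seq, "")[[1]]
  env <- rep(c("buried", "exposed"), length.out = length(qa))
  sum(table[cbind(env, ta, qa)])
}

#' Generate a synthetic template library with planted clusters
#'
#' Builds, under one seed, a [template_library()] whose loop templates
#' form geometric clusters with margin-verified separation (within-cluster
#' anchor-frame RMSD below half the CDR gate, between-cluster above twice
#' it), orientation references likewise clustered against the orientation
#' gate, frameworks, a substitution table, 20 key interface positions and
#' per-template release dates. Template sequences are mutually exclusive
#' under the ESS admission thresholds, so every synthetic read is
#' admitted by exactly its own planted template. Ground-truth labels for
#' every planted entity are returned alongside.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; generation is a pure function of
#'   `(spec, seed)`.
#' @return List with `library` (a [template_library()]) and `truth`
#'   (structure plan, template/cluster table, per-structure signatures
#'   and reference ids, framework layouts).
#' @export
generate_template_library <- function(spec = cohort_spec(), seed = 1L) {
  sub_table <- default_substitution_table()
  thresholds <- default_ess_thresholds()
  plan <- .structure_plan(spec)
  max_heavy <- max(plan$heavy_rank)
  max_light <- max(plan$light_rank)
  with_rng(seed, {
    anchors_canon <- lapply(
      stats::setNames(nm = REGIONS),
      function(r) matrix(stats::runif(30, 0, 3), 10, 3))
    # planted bins: fixed-length loops plus every planted CDR3 length.
    # The source-structure tag links CDR1/CDR2 partner templates: planted
    # H1 and H2 (and L1/L2) bins share a tag so cluster-c member-m of each
    # derive from one synthetic source structure; CDR3 tags are per-bin.
    bins <- rbind(
      data.frame(region = names(.FIXED_LENGTHS),
                 length = unname(.FIXED_LENGTHS),
                 n_clusters = c(max_heavy, max_heavy, max_light, max_light),
                 tag = c("SH", "SH", "SL", "SL"),
                 stringsAsFactors = FALSE),
      data.frame(region = "H3", length = sort(unique(plan$h3_len)),
                 n_clusters = max_heavy,
                 tag = paste0("SH3L", sort(unique(plan$h3_len))),
                 stringsAsFactors = FALSE),
      data.frame(region = "L3", length = sort(unique(plan$l3_len)),
                 n_clusters = max_light,
                 tag = paste0("SL3L", sort(unique(plan$l3_len))),
                 stringsAsFactors = FALSE),
      cbind(.BG_BINS,
            n_clusters = 1L,
            tag = c("SHbg", "SHbg", "SLbg", "SLbg",
                    "SH3bg9", "SH3bg15", "SL3bg8"))
    )
    tpls <- list()
    rows <- list()
    for (b in seq_len(nrow(bins))) {
      r <- bins$region[b]
      fmt <- paste0(bins$tag[b], "_c%d_m%d")
      bin <- .generate_bin(r, bins$length[b], bins$n_clusters[b], spec,
                           anchors_canon[[r]], thresholds, sub_table, fmt)
      tpls <- c(tpls, bin$templates)
      rows[[length(rows) + 1L]] <- bin$rows
    }
    template_table <- do.call(rbind, rows)
    template_table$release_date <- as.Date(vapply(
      tpls[template_table$template_id],
      function(t) format(t$release_date), ""))

    # per-structure interface signatures, pairwise dissimilar (<= 6/10),
    # and framework barcodes, pairwise dissimilar (<= 2/8)
    make_strings <- function(len, max_shared) {
      out <- character()
      while (length(out) < spec$n_structures) {
        cand <- .rand_aa(len)
        ok <- all(vapply(out, function(s)
          sum(strsplit(cand, "")[[1]] == strsplit(s, "")[[1]]) <= max_shared,
          TRUE))
        if (ok) out <- c(out, cand)
      }
      out
    }
    hsig <- make_strings(10, 6)
    lsig <- make_strings(10, 6)
    hbar <- make_strings(8, 2)
    lbar <- make_strings(8, 2)

    # orientation clusters: bases separated, member refs tightly placed
    k_or <- max(1L, ceiling(0.6 * spec$n_structures))
    or_bases <- list()
    while (length(or_bases) < k_or) {
      cand <- matrix(stats::runif(15, 0, 12), 5, 3)
      if (all(vapply(or_bases, function(b)
        coord_rmsd(b, cand) > spec$orientation_between, TRUE))) {
        or_bases[[length(or_bases) + 1L]] <- cand
      }
    }
    or_cluster <- ((seq_len(spec$n_structures) - 1L) %% k_or) + 1L
    ref_ids <- sprintf("REF%03d", seq_len(spec$n_structures))
    repeat {
      coords <- lapply(seq_len(spec$n_structures), function(s) {
        or_bases[[or_cluster[s]]] +
          matrix(stats::rnorm(15, sd = spec$orientation_within / sqrt(6)),
                 5, 3)
      })
      ok <- TRUE
      for (i in seq_along(coords)) {
        for (j in seq_len(i - 1L)) {
          d <- coord_rmsd(coords[[i]], coords[[j]])
          lim_ok <- if (or_cluster[i] == or_cluster[j])
            d < spec$orientation_threshold / 2
          else d > 2 * spec$orientation_threshold
          if (!lim_ok) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) break
    }
    refs <- lapply(seq_len(spec$n_structures), function(s) {
      reference_fv(ref_ids[s], paste0(hsig[s], lsig[s]), coords[[s]],
                   release_date = as.Date("2015-01-01"))
    })

    # frameworks: the base layout each synthetic read is built on, plus a
    # dissimilar decoy so framework assignment is non-trivial
    h_pos <- as.character(.H_FW_NUMS)
    l_pos <- as.character(.L_FW_NUMS)
    fw_h_seq <- stats::setNames(sample(AA_ALPHABET, length(h_pos), TRUE),
                                h_pos)
    fw_l_seq <- stats::setNames(sample(AA_ALPHABET, length(l_pos), TRUE),
                                l_pos)
    anchor_sets <- function(chain) {
      regs <- names(north_cdr_windows(chain))
      stats::setNames(lapply(regs, function(r) anchors_canon[[r]]), regs)
    }
    fws <- list(
      framework_template("FWH1", "H", fw_h_seq, anchor_sets("H"),
                         as.Date("2015-01-01")),
      framework_template("FWH2", "H",
                         stats::setNames(sample(AA_ALPHABET,
                                                length(h_pos), TRUE), h_pos),
                         anchor_sets("H"), as.Date("2015-01-01")),
      framework_template("FWL1", "L", fw_l_seq, anchor_sets("L"),
                         as.Date("2015-01-01")),
      framework_template("FWL2", "L",
                         stats::setNames(sample(AA_ALPHABET,
                                                length(l_pos), TRUE), l_pos),
                         anchor_sets("L"), as.Date("2015-01-01"))
    )

    iface <- data.frame(
      chain = rep(c("H", "L"), each = 10),
      position = as.character(c(.H_IFACE, .L_IFACE)),
      stringsAsFactors = FALSE
    )
    lib <- template_library(tpls, fws, refs,
                            substitution_table = sub_table,
                            ess_thresholds = thresholds,
                            interface_positions = iface)
    plan$orientation_cluster <- or_cluster
    plan$ref_id <- ref_ids
    plan$lv <- paste(.FIXED_LENGTHS["H1"], .FIXED_LENGTHS["H2"],
                     plan$h3_len, .FIXED_LENGTHS["L1"],
                     .FIXED_LENGTHS["L2"], plan$l3_len, sep = "-")
    list(
      library = lib,
      truth = list(
        structures = plan,
        templates = template_table,
        hsig = hsig, lsig = lsig, hbar = hbar, lbar = lbar,
        fw_h_seq = fw_h_seq, fw_l_seq = fw_l_seq,
        spec = spec
      )
    )
  })
}

# Template id for (structure, region, member) under the planted plan.
.planted_template <- function(plan_row, region, member) {
  len <- switch(region,
                H3 = plan_row$h3_len, L3 = plan_row$l3_len,
                .FIXED_LENGTHS[[region]])
  rank <- if (substr(region, 1, 1) == "H") plan_row$heavy_rank
          else plan_row$light_rank
  sprintf("T%s%02d_c%d_m%d", region, len, rank, member)
}

# Build one synthetic read realising a structure variant.
.realize_chain <- function(read_id, chain_type, plan_row, member, gen,
                           lib, v_call, j_call, fw_mutation = FALSE) {
  truth <- gen$truth
  regions <- names(north_cdr_windows(chain_type))
  fw_seq <- if (chain_type == "H") truth$fw_h_seq else truth$fw_l_seq
  sig <- if (chain_type == "H") truth$hsig else truth$lsig
  bar <- if (chain_type == "H") truth$hbar else truth$lbar
  iface <- if (chain_type == "H") .H_IFACE else .L_IFACE
  barcode <- if (chain_type == "H") .H_BARCODE else .L_BARCODE
  s_idx <- match(plan_row$structure_id, truth$structures$structure_id)
  fw_seq[as.character(iface)] <- strsplit(sig[s_idx], "")[[1]]
  fw_seq[as.character(barcode)] <- strsplit(bar[s_idx], "")[[1]]
  if (fw_mutation) {
    # one framework substitution at a fixed non-interface position
    mut_pos <- "5"
    cur <- fw_seq[[mut_pos]]
    fw_seq[[mut_pos]] <- AA_ALPHABET[(match(cur, AA_ALPHABET) %% 20) + 1L]
  }
  positions <- names(fw_seq)
  residues <- unname(fw_seq)
  tids <- character()
  for (r in regions) {
    tid <- .planted_template(plan_row, r, member)
    tids[r] <- tid
    tpl <- lib$cdr_templates[[tid]]
    pos <- imgt_cdr_positions(r, tpl$length)
    positions <- c(positions, pos)
    residues <- c(residues, strsplit(tpl$loop_seq, "")[[1]])
  }
  list(
    chain = numbered_chain(read_id, chain_type, positions, residues,
                           v_call, j_call),
    template_ids = tids
  )
}

.decoy_chain <- function(read_id, chain_type, gen) {
  truth <- gen$truth
  fw_seq <- if (chain_type == "H") truth$fw_h_seq else truth$fw_l_seq
  regions <- names(north_cdr_windows(chain_type))
  positions <- names(fw_seq)
  residues <- unname(fw_seq)
  plan_row <- truth$structures[1, ]
  for (r in regions[1:2]) {
    tid <- .planted_template(plan_row, r, 1L)
    tpl <- gen$library$cdr_templates[[tid]]
    pos <- imgt_cdr_positions(r, tpl$length)
    positions <- c(positions, pos)
    residues <- c(residues, strsplit(tpl$loop_seq, "")[[1]])
  }
  # a 4-residue CDR3: no template of that length exists, and the
  # admission band cannot be met, so the read is never modellable
  cdr3 <- regions[3]
  pos <- imgt_cdr_positions(cdr3, 4L)
  positions <- c(positions, pos)
  residues <- c(residues, sample(AA_ALPHABET, 4, replace = TRUE))
  numbered_chain(read_id, chain_type,
                 positions, residues,
                 if (chain_type == "H") "IGHV1-69*01" else "IGKV1-39*01",
                 if (chain_type == "H") "IGHJ4*01" else "IGKJ2*01")
}

.H_VGENES <- c("IGHV1-69*01", "IGHV3-23*01", "IGHV5-51*01",
               "IGHV4-34*01", "IGHV3-30*01")
.H_JGENES <- c("IGHJ4*01", "IGHJ6*01")
.L_VGENES <- c("IGKV1-39*01", "IGKV3-20*01", "IGLV1-44*01", "IGLV2-14*01")
.L_JGENES <- c("IGKJ2*01", "IGLJ3*01")

#' Generate a synthetic multi-individual cohort
#'
#' Realises the planted structures of a generated library as OAS-style
#' numbered repertoire snapshots: the first
#' `ceiling(public_fraction * n_structures)` structures appear in every
#' individual, the remainder are distributed privately round-robin. Each
#' structure contributes, per chain and individual, one read per template
#' variant plus one framework-mutant read (which must merge with variant 1
#' at the 90% identity stage), and each individual additionally receives
#' unmodellable decoy reads. Truth tables map every read to its planted
#' structure and templates (or decoy status).
#'
#' @param gen Output of [generate_template_library()].
#' @param seed Integer seed (decoy loop residues only; the realisation is
#'   otherwise deterministic given `gen`).
#' @return List with `snapshots` (named list of [repertoire_snapshot()]),
#'   `reads` (truth data frame), `structures` (planted-structure truth
#'   with `public` flag and per-individual presence).
#' @export
generate_cohort <- function(gen, seed = 1L) {
  spec <- gen$truth$spec
  plan <- gen$truth$structures
  n_public <- ceiling(spec$public_fraction * spec$n_structures)
  if (n_public > spec$n_structures) {
    stop("infeasible public_fraction for n_structures")
  }
  individuals <- sprintf("I%d", seq_len(spec$n_individuals))
  plan$public <- seq_len(nrow(plan)) <= n_public
  priv <- which(!plan$public)
  owner <- individuals[((seq_along(priv) - 1L) %% spec$n_individuals) + 1L]
  plan$individuals <- ifelse(plan$public,
                             paste(individuals, collapse = ","),
                             NA_character_)
  plan$individuals[priv] <- owner
  with_rng(seed, {
    snapshots <- list()
    reads <- list()
    for (ind in individuals) {
      vh <- list(); vl <- list()
      mine <- plan[vapply(strsplit(plan$individuals, ","),
                          function(x) ind %in% x, TRUE), ]
      for (k in seq_len(nrow(mine))) {
        row <- mine[k, ]
        s_num <- match(row$structure_id, plan$structure_id)
        vgh <- .H_VGENES[((s_num - 1L) %% length(.H_VGENES)) + 1L]
        jgh <- .H_JGENES[((s_num - 1L) %% length(.H_JGENES)) + 1L]
        vgl <- .L_VGENES[((s_num - 1L) %% length(.L_VGENES)) + 1L]
        jgl <- .L_JGENES[((s_num - 1L) %% length(.L_JGENES)) + 1L]
        variants <- c(seq_len(spec$members_per_cluster), 1L)
        mutant <- c(rep(FALSE, spec$members_per_cluster), TRUE)
        for (v in seq_along(variants)) {
          idh <- sprintf("%s_%s_H%d", ind, row$structure_id, v)
          rh <- .realize_chain(idh, "H", row, variants[v], gen,
                               gen$library, vgh, jgh, mutant[v])
          vh[[length(vh) + 1L]] <- rh$chain
          idl <- sprintf("%s_%s_L%d", ind, row$structure_id, v)
          rl <- .realize_chain(idl, "L", row, variants[v], gen,
                               gen$library, vgl, jgl, mutant[v])
          vl[[length(vl) + 1L]] <- rl$chain
          reads[[length(reads) + 1L]] <- data.frame(
            individual = ind, read_id = idh, chain_type = "H",
            structure_id = row$structure_id, variant = variants[v],
            mutant = mutant[v], decoy = FALSE,
            t1 = rh$template_ids[[1]], t2 = rh$template_ids[[2]],
            t3 = rh$template_ids[[3]], stringsAsFactors = FALSE)
          reads[[length(reads) + 1L]] <- data.frame(
            individual = ind, read_id = idl, chain_type = "L",
            structure_id = row$structure_id, variant = variants[v],
            mutant = mutant[v], decoy = FALSE,
            t1 = rl$template_ids[[1]], t2 = rl$template_ids[[2]],
            t3 = rl$template_ids[[3]], stringsAsFactors = FALSE)
        }
      }
      for (d in seq_len(spec$n_decoys)) {
        idh <- sprintf("%s_DECOY_H%d", ind, d)
        idl <- sprintf("%s_DECOY_L%d", ind, d)
        vh[[length(vh) + 1L]] <- .decoy_chain(idh, "H", gen)
        vl[[length(vl) + 1L]] <- .decoy_chain(idl, "L", gen)
        for (id in c(idh, idl)) {
          reads[[length(reads) + 1L]] <- data.frame(
            individual = ind, read_id = id,
            chain_type = if (id == idh) "H" else "L",
            structure_id = NA_character_, variant = NA_integer_,
            mutant = FALSE, decoy = TRUE,
            t1 = NA_character_, t2 = NA_character_, t3 = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
      snapshots[[ind]] <- repertoire_snapshot(ind, vh, vl,
                                              metadata = list(individual = ind))
    }
    list(snapshots = snapshots,
         reads = do.call(rbind, reads),
         structures = plan)
  })
}
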