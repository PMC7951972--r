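test_that("interface signatures concatenate the 20 key positions", {
  gen <- shared_gen()
  lib <- gen$library
  coh <- shared_cohort()
  vh <- coh$snapshots$I1$vh[[1]]
  vl <- coh$snapshots$I1$vl[[1]]
  sig <- interface_signature(vh, vl, lib$interface_positions)
  expect_equal(nchar(sig), 20L)
  # a chain missing 3 of its key positions emits gap symbols there
  drop_pos <- lib$interface_positions$position[
    lib$interface_positions$chain == "H"][1:3]
  keep <- !(vh$positions %in% drop_pos)
  vh2 <- numbered_chain("gappy", "H", vh$positions[keep],
                        vh$residues[keep], vh$v_call, vh$j_call)
  sig2 <- interface_signature(vh2, vl, lib$interface_positions)
  expect_equal(lengths(regmatches(sig2, gregexpr("-", sig2))), 3L)
})

test_that("reference self-consistency: realised chains reproduce their
           reference's stored interface residues", {
  gen <- shared_gen()
  coh <- shared_cohort()
  truth <- gen$truth
  # variant-1 reads of each I1 structure must spell out the reference
  # interface string of their planted structure
  plan <- truth$structures
  i1 <- coh$reads[coh$reads$individual == "I1" & !coh$reads$decoy &
                    coh$reads$variant == 1 & !coh$reads$mutant, ]
  by_struct <- split(i1, i1$structure_id)
  snap <- coh$snapshots$I1
  all_chains <- c(snap$vh, snap$vl)
  names(all_chains) <- vapply(all_chains, `[[`, "", "read_id")
  for (sid in names(by_struct)[1:10]) {
    rows <- by_struct[[sid]]
    vh <- all_chains[[rows$read_id[rows$chain_type == "H"]]]
    vl <- all_chains[[rows$read_id[rows$chain_type == "L"]]]
    sig <- interface_signature(vh, vl, gen$library$interface_positions)
    ref_id <- plan$ref_id[plan$structure_id == sid]
    expect_equal(sig,
                 gen$library$reference_fvs[[ref_id]]$interface_residues)
  }
})

test_that("the 85% pairing gate keeps 17/20 and discards 16/20", {
  lib <- toy_library()
  # build chains spelling given residues at the key positions
  spell <- function(id, chain, letters20) {
    pos <- lib$interface_positions
    mine <- pos[pos$chain == chain, ]
    fw_nums <- if (chain == "H") c(1:23, 41:54, 67:104, 118:128)
               else c(1:23, 41:54, 70:104, 118:128)
    positions <- as.character(fw_nums)
    residues <- rep("G", length(positions))
    idx <- match(mine$position, positions)
    residues[idx] <- letters20
    wins <- north_cdr_windows(chain)
    for (r in names(wins)) {
      p <- imgt_cdr_positions(r, 9)
      positions <- c(positions, p)
      residues <- c(residues, rep("S", 9))
    }
    ch <- numbered_chain(id, chain, positions, residues)
    cdrs <- extract_north_cdrs(ch)
    structure(list(chain = ch, cdrs = cdrs, framework_id = "FW",
                   assignments = setNames(lapply(names(wins), function(r)
                     list(region = r, template_id = paste0("T", r))),
                     names(wins)),
                   cluster_size = 1L),
              class = "modellable_chain")
  }
  # reference R1 is 10 A's (H side) + 10 W's (L side)
  vh17 <- spell("vh17", "H", rep("A", 10))              # 10 H matches
  vl7 <- spell("vl7", "L", c(rep("W", 7), rep("G", 3))) # 7 L matches
  vl6 <- spell("vl6", "L", c(rep("W", 6), rep("G", 4))) # 6 L matches
  kept <- predict_modellable_fvs(list(vh17), list(vl7), lib, 0.85)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$interface_identity, 17 / 20)
  expect_equal(kept[[1]]$orientation_ref, "R1")
  none <- predict_modellable_fvs(list(vh17), list(vl6), lib, 0.85)
  expect_length(none, 0)
  # monotonicity: lowering the threshold never removes a kept pair
  low <- predict_modellable_fvs(list(vh17), list(vl7, vl6), lib, 0.80)
  expect_gte(length(low), length(kept))
  expect_true(kept[[1]]$fv_id %in% vapply(low, `[[`, "", "fv_id"))
})

test_that("pairing equals a brute-force scan with inherited references", {
  gen <- shared_gen()
  lib <- gen$library
  coh <- shared_cohort()
  prof <- shared_profiles()$I2
  vh_c <- prof$vh_centres[1:10]
  vl_c <- prof$vl_centres[1:10]
  got <- predict_modellable_fvs(vh_c, vl_c, lib, 0.85)
  # brute force over all pairs and references
  ref_ids <- sort(names(lib$reference_fvs))
  brute <- list()
  for (vh in vh_c) {
    for (vl in vl_c) {
      sig <- strsplit(interface_signature(vh$chain, vl$chain,
                                          lib$interface_positions),
                      "")[[1]]
      ident <- vapply(ref_ids, function(r) {
        ref <- strsplit(lib$reference_fvs[[r]]$interface_residues,
                        "")[[1]]
        sum(sig == ref & sig != "-") / 20
      }, 1)
      if (max(ident) >= 0.85 - 1e-12) {
        brute[[length(brute) + 1L]] <- list(
          fv_id = paste(vh$chain$read_id, vl$chain$read_id, sep = "|"),
          ref = ref_ids[which.max(ident)], ident = max(ident))
      }
    }
  }
  expect_equal(vapply(got, `[[`, "", "fv_id"),
               vapply(brute, `[[`, "", "fv_id"))
  expect_equal(vapply(got, `[[`, "", "orientation_ref"),
               vapply(brute, `[[`, "", "ref"))
  expect_equal(vapply(got, `[[`, 1, "interface_identity"),
               vapply(brute, `[[`, 1, "ident"))
  # output never exceeds |VH| x |VL|, and identities recompute
  expect_lte(length(got), length(vh_c) * length(vl_c))
})

test_that("pairing with an empty reference set is a configuration error", {
  lib <- toy_library()
  lib$reference_fvs <- list()
  prof <- shared_profiles()$I1
  expect_error(predict_modellable_fvs(prof$vh_centres[1],
                                      prof$vl_centres[1], lib),
               "reference")
})
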