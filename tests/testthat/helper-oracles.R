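# Independent oracles used to validate the geometric and clustering code,
# plus invariant assertions shared across test files.

# Horn's quaternion method: closed-form minimum RMSD between two point
# sets via the largest eigenvalue of the 4x4 key matrix. Independent of
# the SVD-based Kabsch implementation in the package.
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)  # 3x3 correlation
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Hand transcription of the length-weighted combined CDR measure.
hand_combined_rmsd <- function(lengths, d) {
  sqrt(sum(lengths * d^2) / sum(lengths))
}

# Straight-line transcription of the four distinct-structure steps:
# (1) collapse identical 8-parameter keys (seed preferred, else uniform
#     random under the seed, groups in first-appearance order);
# (2) keys with a unique CDR length vector become distinct structures;
# (3) remaining keys, split by length vector, processed greedily: a new
#     centre if orientation RMSD > gate to every centre, else if the
#     hand-computed combined CDR RMSD > gate to every centre;
# (4) otherwise stripped: attached to the first centre within both gates
#     (or, failing that, the first within the CDR gate).
# Returns a named vector: fv_id -> centre fv_id (seed ids included).
oracle_distinct_structures <- function(fvs, lib, config,
                                       seed_centres = NULL) {
  o_thr <- config$orientation_threshold
  c_thr <- config$cdr_threshold
  or_mat <- lib$orientation_rmsd
  key_str <- function(k) paste(c(k$orientation_ref, unname(k$templates),
                                 paste(k$lengths, collapse = "-")),
                               collapse = "|")
  comb <- function(ka, kb) {
    L <- ka$lengths
    d <- vapply(names(L), function(r) {
      lib$cdr_rmsd[[paste0(r, ":", L[[r]])]][ka$templates[[r]],
                                             kb$templates[[r]]]
    }, 1)
    hand_combined_rmsd(L, d)
  }
  seed_key <- vapply(seed_centres, function(s) key_str(s$key), "")
  keys <- vapply(fvs, function(f) key_str(f$key), "")
  groups <- split(seq_along(fvs), keys)
  groups <- groups[order(vapply(groups, min, 1L))]
  assign_to <- character()
  chosen <- integer()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  for (ks in names(groups)) {
    idx <- groups[[ks]]
    hit <- match(ks, seed_key)
    if (!is.na(hit)) {
      for (i in idx) assign_to[fvs[[i]]$fv_id] <-
          seed_centres[[hit]]$centre_id
      next
    }
    pick <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    chosen <- c(chosen, pick)
    for (i in setdiff(idx, pick)) assign_to[fvs[[i]]$fv_id] <-
        fvs[[pick]]$fv_id   # follows its representative (patched below)
  }
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  reps <- fvs[sort(chosen)]
  rep_lvs <- vapply(reps, function(f) paste(f$key$lengths, collapse = "-"), "")
  seed_lvs <- vapply(seed_centres, function(s)
    paste(s$key$lengths, collapse = "-"), "")
  lv_tab <- table(c(rep_lvs, seed_lvs))
  # centres per LV: list of (id, key); seeds enter first
  centres <- list()
  for (s in seed_centres) {
    lv <- paste(s$key$lengths, collapse = "-")
    centres[[lv]] <- c(centres[[lv]], list(list(id = s$centre_id,
                                                key = s$key)))
  }
  for (i in seq_along(reps)) {
    f <- reps[[i]]
    lv <- rep_lvs[i]
    if (lv_tab[[lv]] == 1L) {
      assign_to[f$fv_id] <- f$fv_id
      next
    }
    cs <- centres[[lv]]
    new_centre <- FALSE
    if (is.null(cs) || length(cs) == 0L) {
      new_centre <- TRUE
    } else {
      ors <- vapply(cs, function(c) or_mat[f$key$orientation_ref,
                                           c$key$orientation_ref], 1)
      if (all(ors > o_thr)) {
        new_centre <- TRUE
      } else {
        ds <- vapply(cs, function(c) comb(f$key, c$key), 1)
        if (all(ds > c_thr)) {
          new_centre <- TRUE
        } else {
          both <- which(ors <= o_thr & ds <= c_thr)
          tgt <- if (length(both)) both[1] else which(ds <= c_thr)[1]
          assign_to[f$fv_id] <- cs[[tgt]]$id
        }
      }
    }
    if (new_centre) {
      centres[[lv]] <- c(centres[[lv]], list(list(id = f$fv_id,
                                                  key = f$key)))
      assign_to[f$fv_id] <- f$fv_id
    }
  }
  # duplicates resolve to their representative's final centre
  for (id in names(assign_to)) {
    tgt <- assign_to[[id]]
    while (tgt %in% names(assign_to) && assign_to[[tgt]] != tgt) {
      tgt <- assign_to[[tgt]]
    }
    assign_to[id] <- tgt
  }
  assign_to
}

# fv_id -> centre_id mapping from a package clustering result
clustering_assignment_map <- function(res) {
  stats::setNames(res$assignments$centre_id, res$assignments$fv_id)
}

# Centre-separation and membership invariants for any clustering output.
assert_clustering_invariants <- function(res, lib, config) {
  o_thr <- config$orientation_threshold
  c_thr <- config$cdr_threshold
  or_mat <- lib$orientation_rmsd
  sts <- res$structures
  lvs <- vapply(sts, function(s) paste(s$key$lengths, collapse = "-"), "")
  ids <- vapply(sts, `[[`, "", "centre_id")
  # no two same-length-vector centres lie within both gates
  for (lv in unique(lvs)) {
    grp <- which(lvs == lv)
    if (length(grp) < 2) next
    for (a in seq_along(grp)) {
      for (b in seq_len(a - 1)) {
        sa <- sts[[grp[a]]]; sb <- sts[[grp[b]]]
        od <- or_mat[sa$key$orientation_ref, sb$key$orientation_ref]
        cd <- combined_cdr_rmsd(sa$key, sb$key, lib, config$sqrt_combined)
        testthat::expect_false(od <= o_thr && cd <= c_thr,
          label = sprintf("centres %s / %s separated", ids[grp[a]],
                          ids[grp[b]]))
      }
    }
  }
  invisible(TRUE)
}

# Full membership check needs the clustered fvs for key lookup.
assert_membership_invariant <- function(res, fvs, lib, config) {
  key_by_id <- stats::setNames(lapply(fvs, `[[`, "key"),
                               vapply(fvs, `[[`, "", "fv_id"))
  centre_key <- stats::setNames(lapply(res$structures, `[[`, "key"),
                                vapply(res$structures, `[[`, "",
                                       "centre_id"))
  or_mat <- lib$orientation_rmsd
  a <- res$assignments
  mem <- a[a$role == "member", ]
  for (i in seq_len(nrow(mem))) {
    kf <- key_by_id[[mem$fv_id[i]]]
    kc <- centre_key[[mem$centre_id[i]]]
    testthat::expect_identical(kf$lengths, kc$lengths)
    od <- or_mat[kf$orientation_ref, kc$orientation_ref]
    cd <- combined_cdr_rmsd(kf, kc, lib, config$sqrt_combined)
    testthat::expect_true(cd <= config$cdr_threshold,
                          label = paste("member", mem$fv_id[i],
                                        "within CDR gate of its centre"))
  }
  invisible(TRUE)
}
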