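key_from <- function(or, tpls, lens) {
  structure_key(or, setNames(tpls, c("H1", "H2", "H3", "L1", "L2", "L3")),
                setNames(as.integer(lens),
                         c("H1", "H2", "H3", "L1", "L2", "L3")))
}

fake_fv <- function(id, rep_id, key) {
  structure(list(fv_id = id, repertoire_id = rep_id, key = key),
            class = "paired_fv")
}

test_that("combined CDR RMSD is the length-weighted quadratic mean", {
  gen <- shared_gen()
  lib <- gen$library
  # identical template sets sit at distance zero
  fvs <- shared_profiles()$I1$fvs
  k <- fvs[[1]]$key
  expect_equal(combined_cdr_rmsd(k, k, lib), 0)
  # all per-CDR distances equal d: the combined value is d, any lengths.
  # Use a mock library whose D matrices are constant off-diagonal.
  d <- 0.73
  lens <- c(H1 = 13L, H2 = 10L, H3 = 15L, L1 = 11L, L2 = 8L, L3 = 9L)
  mock <- list(cdr_rmsd = setNames(lapply(names(lens), function(r) {
    matrix(c(0, d, d, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  }), paste0(names(lens), ":", lens)))
  ka <- key_from("o", rep("a", 6), lens)
  kb <- key_from("o", rep("b", 6), lens)
  expect_equal(combined_cdr_rmsd(ka, kb, mock), d, tolerance = 1e-12)
  # hand-computed weighted-RMS oracle, planted per-region D values
  ds <- c(0.2, 1.4, 0.9, 0.05, 2.2, 0.6)
  mock2 <- list(cdr_rmsd = setNames(lapply(seq_along(lens), function(i) {
    matrix(c(0, ds[i], ds[i], 0), 2, 2,
           dimnames = list(c("a", "b"), c("a", "b")))
  }), paste0(names(lens), ":", lens)))
  expect_equal(combined_cdr_rmsd(ka, kb, mock2),
               hand_combined_rmsd(lens, ds), tolerance = 1e-12)
  # no-root variant
  expect_equal(combined_cdr_rmsd(ka, kb, mock2, sqrt_combined = FALSE),
               hand_combined_rmsd(lens, ds)^2, tolerance = 1e-12)
  # bounded between the smallest and largest per-region distance
  got <- combined_cdr_rmsd(ka, kb, mock2)
  expect_gte(got, min(ds))
  expect_lte(got, max(ds))
  # mismatched length vectors refuse to compare
  kc <- key_from("o", rep("a", 6), lens + c(0, 0, 1, 0, 0, 0))
  expect_error(combined_cdr_rmsd(ka, kc, mock), "length vectors")
})

test_that("combined CDR RMSD matches the oracle on random tuples", {
  set.seed(61)
  for (i in 1:100) {
    lens <- setNames(sample(5:18, 6, TRUE),
                     c("H1", "H2", "H3", "L1", "L2", "L3"))
    ds <- runif(6, 0, 3)
    mock <- list(cdr_rmsd = setNames(lapply(1:6, function(j) {
      matrix(c(0, ds[j], ds[j], 0), 2, 2,
             dimnames = list(c("a", "b"), c("a", "b")))
    }), paste0(names(lens), ":", lens)))
    ka <- key_from("o", rep("a", 6), lens)
    kb <- key_from("o", rep("b", 6), lens)
    expect_equal(combined_cdr_rmsd(ka, kb, mock),
                 hand_combined_rmsd(lens, ds), tolerance = 1e-12)
  }
})

test_that("identical-key dedupe is deterministic and seed-centre aware", {
  fvs <- random_key_fvs(30, seed = 301)
  dup <- fvs[c(1, 1, 2, 3, 3, 3)]
  for (i in seq_along(dup)) dup[[i]]$fv_id <- sprintf("d%02d", i)
  a <- dedupe_identical_keys(dup, seed = 5)
  b <- dedupe_identical_keys(dup, seed = 5)
  expect_identical(vapply(a$representatives, `[[`, "", "fv_id"),
                   vapply(b$representatives, `[[`, "", "fv_id"))
  expect_length(a$representatives, 3)
  expect_equal(sum(a$multiplicity), 6)
  # a seed centre with a matching key absorbs the whole group
  seed_centre <- structure(
    list(centre_id = "SEED", key = dup[[1]]$key,
         origin_repertoire = "R0", presence = "R0",
         members = data.frame(repertoire_id = "R0", fv_id = "SEED"),
         is_seed = TRUE),
    class = "distinct_structure")
  s <- dedupe_identical_keys(dup, list(seed_centre), seed = 5)
  expect_true(all(s$dup_members$attached_to[s$dup_members$seed_centre]
                  == "SEED"))
  expect_length(s$representatives, 2)  # groups 2 and 3 remain
})

test_that("trivial clusterings behave as specified", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  fvs <- random_key_fvs(12, seed = 302)
  # one Fv: one distinct structure
  one <- cluster_distinct_structures(fvs[1], lib, cfg)
  expect_length(one$structures, 1)
  expect_equal(one$structures[[1]]$centre_id, fvs[[1]]$fv_id)
  # two same-length-vector Fvs whose orientation references sit farther
  # apart than the gate form two centres
  or_ids <- rownames(lib$orientation_rmsd)
  far <- which(lib$orientation_rmsd > 2.0, arr.ind = TRUE)[1, ]
  ka <- fvs[[1]]$key
  ka$orientation_ref <- or_ids[far[1]]
  kb <- ka
  kb$orientation_ref <- or_ids[far[2]]
  two <- cluster_distinct_structures(
    list(fake_fv("a", "R1", ka), fake_fv("b", "R1", kb)), lib, cfg)
  expect_length(two$structures, 2)
})

test_that("greedy clustering equals the four-step oracle transcription", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config(seed = 17)
  for (seed in 303:310) {
    n <- sample(40:120, 1)
    fvs <- random_key_fvs(n, seed = seed)
    res <- cluster_distinct_structures(fvs, lib, cfg)
    want <- oracle_distinct_structures(fvs, lib, cfg)
    got <- clustering_assignment_map(res)
    expect_identical(got[names(want)], want)
    # seeded mode: feed the first half's centres as seeds for the rest
    half <- cluster_distinct_structures(fvs[1:20], lib, cfg)
    res2 <- cluster_distinct_structures(fvs[21:n], lib, cfg,
                                        seed_centres = half$structures)
    want2 <- oracle_distinct_structures(fvs[21:n], lib, cfg,
                                        seed_centres = half$structures)
    got2 <- clustering_assignment_map(res2)
    expect_identical(got2[names(want2)], want2)
    # seeds are never deleted or merged
    expect_true(all(vapply(half$structures, `[[`, "", "centre_id") %in%
                      vapply(res2$structures, `[[`, "", "centre_id")))
  }
})

test_that("centre separation and membership hold on random clusterings", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  for (seed in 311:314) {
    fvs <- random_key_fvs(80, seed = seed)
    res <- cluster_distinct_structures(fvs, lib, cfg)
    assert_clustering_invariants(res, lib, cfg)
    assert_membership_invariant(res, fvs, lib, cfg)
  }
})

test_that("overlap bookkeeping: self-overlap and disjoint length vectors", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  fvs <- random_key_fvs(40, seed = 320, rep_ids = "A")
  fvs_b <- lapply(fvs, function(f) {
    f$repertoire_id <- "B"
    f$fv_id <- paste0("B_", f$fv_id)
    f
  })
  # the same repertoire twice: 100% public at step 2
  ov <- chain_overlap(list(A = fvs, B = fvs_b), lib, cfg,
                      order_by_diversity = FALSE)
  expect_equal(ov$steps$public_pct[2], 100)
  expect_equal(ov$steps$public[1], ov$steps$cumulative_distinct[1])
  # disjoint length vectors: zero public at step 2
  lv_a <- observed_length_vectors(fvs)
  pool <- random_key_fvs(300, seed = 321, rep_ids = "C")
  disjoint <- Filter(function(f)
    !(paste(f$key$lengths, collapse = "-") %in% lv_a), pool)[1:20]
  disjoint <- lapply(disjoint, function(f) {
    f$repertoire_id <- "C"
    f
  })
  ov2 <- chain_overlap(list(A = fvs, C = disjoint), lib, cfg,
                       order_by_diversity = FALSE)
  expect_equal(ov2$steps$public[2], 0)
})

test_that("public counts never increase along a randomized chain", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  for (seed in 330:332) {
    reps <- lapply(1:4, function(k) {
      lapply(random_key_fvs(30, seed = seed * 10 + k), function(f) {
        f$repertoire_id <- paste0("R", k)
        f$fv_id <- paste0("R", k, "_", f$fv_id)
        f
      })
    })
    names(reps) <- paste0("R", 1:4)
    ov <- chain_overlap(reps, lib, cfg, order_by_diversity = TRUE)
    expect_true(all(diff(ov$steps$public) <= 0))
    expect_equal(ov$steps$public_pct[1], 100)
    expect_true(all(diff(ov$steps$cumulative_distinct) >= 0))
  }
})

test_that("baseline subtraction keeps exactly the novel structures", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  before <- random_key_fvs(50, seed = 340, rep_ids = "before")
  bc <- cluster_distinct_structures(before, lib, cfg)$structures
  # after == before: nothing survives
  after_same <- lapply(before, function(f) {
    f$repertoire_id <- "after"
    f$fv_id <- paste0("after_", f$fv_id)
    f
  })
  expect_length(subtract_baseline(after_same, bc, lib, cfg), 0)
  # after with length vectors absent from before: all retained
  pool <- random_key_fvs(300, seed = 341, rep_ids = "after")
  lv_b <- vapply(bc, function(s) paste(s$key$lengths, collapse = "-"), "")
  novel <- Filter(function(f)
    !(paste(f$key$lengths, collapse = "-") %in% lv_b), pool)[1:15]
  expect_length(subtract_baseline(novel, bc, lib, cfg), 15)
  # planted mixture recovers the planted response labels
  mix <- c(after_same[1:10], novel)
  kept <- subtract_baseline(mix, bc, lib, cfg)
  expect_setequal(vapply(kept, `[[`, "", "fv_id"),
                  vapply(novel, `[[`, "", "fv_id"))
})

test_that("proximity fractions: identity, disjoint and planted geometry", {
  gen <- shared_gen()
  lib <- gen$library
  cfg <- profiler_config()
  a <- cluster_distinct_structures(random_key_fvs(40, seed = 350),
                                   lib, cfg)$structures
  expect_equal(proximity_fraction(a, a, lib, 1.0, cfg), 1.0)
  pool <- random_key_fvs(300, seed = 351)
  lv_a <- vapply(a, function(s) paste(s$key$lengths, collapse = "-"), "")
  b <- cluster_distinct_structures(
    Filter(function(f) !(paste(f$key$lengths, collapse = "-") %in% lv_a),
           pool)[1:15], lib, cfg)$structures
  expect_equal(proximity_fraction(a, b, lib, 1.0, cfg), 0.0)
  # brute-force all-pairs scan on mixed sets
  c_ <- cluster_distinct_structures(random_key_fvs(40, seed = 352),
                                    lib, cfg)$structures
  got <- proximity_fraction(a, c_, lib, 1.0, cfg)
  brute <- mean(vapply(a, function(sa) {
    any(vapply(c_, function(sb) {
      identical(sa$key$lengths, sb$key$lengths) &&
        lib$orientation_rmsd[sa$key$orientation_ref,
                             sb$key$orientation_ref] <= 1.5 &&
        combined_cdr_rmsd(sa$key, sb$key, lib) <= 1.0
    }, TRUE))
  }, TRUE))
  expect_equal(got, brute)
})

test_that("structure summaries count member templates and lengths", {
  gen <- shared_gen()
  prof <- shared_profiles()$I1
  res <- prof$clustering
  summ <- summarize_distinct_structures(res$structures, prof$fvs,
                                        n_repertoires = 1L)
  # every member variant of a planted structure contributes its template:
  # two variants per cluster gives counts of at most 2 per region
  expect_true(all(summ$templates_per_structure$H3 %in% 1:2))
  expect_true(all(summ$region_medians >= 1))
  expect_equal(nrow(summ$length_usage), length(res$structures))
  # solo profile: every structure is trivially public
  expect_true(all(summ$length_usage$public))
  expect_equal(summ$length_usage$h3_l3,
               summ$length_usage$h3 + summ$length_usage$l3)
  # single centre with three distinct member templates counts 3
  ks <- lapply(1:3, function(i) {
    key_from("o", c(paste0("h1_", i), "h2", "h3", "l1", "l2", "l3"),
             c(13, 10, 12, 11, 8, 9))
  })
  st <- structure(list(centre_id = "c1", key = ks[[1]],
                       origin_repertoire = "X", presence = "X",
                       members = data.frame(repertoire_id = "X",
                                            fv_id = c("c1", "f2", "f3")),
                       is_seed = FALSE),
                  class = "distinct_structure")
  fvs2 <- list(fake_fv("f2", "X", ks[[2]]), fake_fv("f3", "X", ks[[3]]))
  s2 <- summarize_distinct_structures(list(st), fvs2, 1L)
  expect_equal(s2$templates_per_structure$H1, 3L)
  expect_equal(s2$templates_per_structure$H2, 1L)
})
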