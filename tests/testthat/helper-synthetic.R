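# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# default-spec generated library + truth (one seed, reused widely)
shared_gen <- function() {
  cached("gen", function() generate_template_library(cohort_spec(),
                                                     seed = 101L))
}

shared_cohort <- function() {
  cached("cohort", function() generate_cohort(shared_gen(), seed = 101L))
}

shared_profiles <- function() {
  cached("profiles", function() {
    lapply(shared_cohort()$snapshots, run_profile,
           library = shared_gen()$library)
  })
}

# small hand-built library with exactly controllable geometry, used by the
# template-assignment and formula unit tests
toy_library <- function() {
  cached("toy", function() {
    set.seed(7)
    anchors <- matrix(runif(30, 0, 3), 10, 3)
    mk <- function(id, region, seq, shift = 0, date = "2015-01-01",
                   source = id, anchor_noise = 0) {
      len <- nchar(seq)
      base <- matrix(seq_len(len * 3) / 2, len, 3) + shift
      cdr_template(id, region, base,
                   anchors + matrix(rnorm(30, sd = anchor_noise), 10, 3),
                   seq, source_structure = source, release_date = date)
    }
    tpls <- list(
      mk("H3A", "H3", "ARDYWGQGT", date = "2016-05-01"),
      mk("H3B", "H3", "ARDFWGQGT", shift = 5, date = "2019-07-01"),
      mk("H3C", "H3", "GSSGSYYYM", shift = 10, date = "2016-05-01"),
      mk("H1A", "H1", "GFTFSSYAMSWVR", date = "2016-05-01"),
      mk("H2A", "H2", "AISGSGGSTY", date = "2016-05-01",
         source = "H1A"),
      mk("L1A", "L1", "RASQSVSSYLA", date = "2016-05-01"),
      mk("L2A", "L2", "DASNRATG", date = "2016-05-01", source = "L1A"),
      mk("L3A", "L3", "QQRSNWPLT", date = "2016-05-01")
    )
    h_fw <- as.character(c(1:23, 41:54, 67:104, 118:128))
    l_fw <- as.character(c(1:23, 41:54, 70:104, 118:128))
    set.seed(8)
    fws <- list(
      framework_template("FW_H", "H",
        setNames(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        length(h_fw), TRUE), h_fw),
        list(H1 = anchors, H2 = anchors, H3 = anchors)),
      framework_template("FW_L", "L",
        setNames(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        length(l_fw), TRUE), l_fw),
        list(L1 = anchors, L2 = anchors, L3 = anchors))
    )
    refs <- list(
      reference_fv("R1", "AAAAAAAAAAWWWWWWWWWW",
                   matrix(0, 5, 3), "2016-05-01"),
      reference_fv("R2", "CCCCCCCCCCYYYYYYYYYY",
                   matrix(1, 5, 3), "2016-05-01")
    )
    iface <- data.frame(chain = rep(c("H", "L"), each = 10),
                        position = as.character(c(41, 43, 45, 47, 50, 68,
                                                  70, 85, 89, 103,
                                                  42, 44, 46, 49, 52, 71,
                                                  87, 96, 98, 100)),
                        stringsAsFactors = FALSE)
    template_library(tpls, fws, refs, interface_positions = iface)
  })
}

# a bag of random structure keys drawn from the shared library, stamped
# with repertoire ids; the raw material for randomized clustering tests
random_key_fvs <- function(n, seed, rep_ids = "R1") {
  mrs <- sample_mrs(shared_gen()$library, n, seed = seed)
  ids <- rep_len(rep_ids, n)
  lapply(seq_len(n), function(i) {
    s <- mrs[[i]]
    s$fv_id <- sprintf("fv_%d_%03d", seed, i)
    s$repertoire_id <- ids[i]
    s
  })
}

# quick numbered-chain builder for IO / clonotype tests
make_chain <- function(read_id, chain_type = "H",
                       v_call = "IGHV5-51*01", j_call = "IGHJ4*01",
                       cdr3 = "ARPYGSGSYSDY",
                       fw_fill = "Q", cdr1 = "GFTFSSYAMSWVR",
                       cdr2 = NULL) {
  wins <- north_cdr_windows(chain_type)
  fw_nums <- if (chain_type == "H") c(1:23, 41:54, 67:104, 118:128)
             else c(1:23, 41:54, 70:104, 118:128)
  if (is.null(cdr2)) {
    cdr2 <- if (chain_type == "H") "AISGSGGSTY" else "DASNRATG"
  }
  positions <- as.character(fw_nums)
  residues <- rep(fw_fill, length(fw_nums))
  r3 <- names(wins)[3]
  for (spec in list(list(names(wins)[1], cdr1),
                    list(names(wins)[2], cdr2),
                    list(r3, cdr3))) {
    pos <- imgt_cdr_positions(spec[[1]], nchar(spec[[2]]))
    positions <- c(positions, pos)
    residues <- c(residues, strsplit(spec[[2]], "")[[1]])
  }
  numbered_chain(read_id, chain_type, positions, residues, v_call, j_call)
}
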