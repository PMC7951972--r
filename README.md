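# repstruct

Structural profiling of antibody repertoires in R.

Sequence-based repertoire analysis (clonotyping) finds almost no overlap
between the baseline antibody repertoires of unrelated individuals, yet
antibodies only need a similar binding-site *geometry* to engage the same
epitope. `repstruct` re-frames repertoire comparison in structure space:
from unpaired, IMGT-numbered VH and VL reads it

1. keeps only chains whose North CDR loops (IMGT windows 24–40,
   55–66 H / 55–69 L, 105–117) can all be assigned a loop template —
   admission by environment-specific substitution score (CDR3 bands:
   length ≤ 8 needs ESS ≥ 25, 9–10 ≥ 35, ≥ 11 ≥ 40), selection by
   lowest anchor-Cα RMSD to the assigned framework;
2. reduces chains to 90%-identity cluster centres and pairs all VH × VL
   centres, keeping pairs whose 20-residue interface signature matches a
   reference Fv at ≥ 85% (the pair inherits that reference's VH–VL
   orientation);
3. summarises each predicted Fv by an 8-parameter key — orientation
   template, six CDR templates, CDR length vector — and greedily
   clusters same-length-vector keys into **distinct structures** under a
   1.5 Å orientation gate and a 1 Å combined CDR gate, where the
   combined measure is the length-weighted root-mean-square
   `sqrt( Σ_X L_X D_X² / Σ_X L_X )` over the six CDRs;
4. chains repertoires (most structurally diverse first) to count
   **public** structures — those with member Fvs from every individual —
   and contrasts both diversity and sharing against **Random
   Repertoires**: size-matched draws (without replacement) from the
   length-accessible portion of random template-combination space;
5. provides V/J/CDRH3 clonotyping (exact or 80%-identity definitions) as
   the sequence-space comparator, plus germline-proximity summaries.

A synthetic-data module generates template libraries with planted,
margin-verified geometric clusters and multi-individual cohorts with full
read-level ground truth, so every stage of the pipeline is validated by
exact recovery rather than by eyeballing.

## Worked example

Generate a default synthetic cohort (3 individuals, 50 planted
structures of which 40% are public) and profile it:

```r
library(repstruct)

gen <- generate_template_library(cohort_spec(), seed = 1)
coh <- generate_cohort(gen, seed = 1)
profiles <- lapply(coh$snapshots, run_profile, library = gen$library)
do.call(rbind, lapply(profiles, `[[`, "row"))
#>    snapshot_id n_vh n_vl mod_vh_sic mod_vl_sic fvs distinct_structures
#> I1          I1   94   94         60         60 120                  30
#> I2          I2   94   94         60         60 120                  30
#> I3          I3   94   94         60         60 120                  30
```

Each individual's 94 + 94 reads lose their 4 + 4 unmodellable decoys,
collapse to 60 + 60 sequence-identity centres (the planted framework
mutants merge into their parent variant), pair into exactly 120
predicted-modellable Fvs, and cluster into 30 distinct structures — the
20 public plus 10 private structures planted in that individual.

```r
overlap <- run_overlap(profiles, gen$library)
overlap$steps
#>   step repertoire fvs_added cumulative_distinct public public_pct
#> 1    1         I1       120                  30     30        100
#> 2    2         I2       120                  40     20         50
#> 3    3         I3       120                  50     20         40
```

Chaining the three individuals recovers all 50 planted structures, 20 of
them public across everyone — exactly the generator's ground truth. The
null model shows what random structural sampling would have produced at
the same depth:

```r
nm <- run_null_model(profiles, gen$library, seed = 1)
nm$rr_rows[, c("repertoire", "n_fvs", "rr_distinct", "genuine_distinct")]
#>    repertoire n_fvs rr_distinct genuine_distinct
#> I1         I1   120         120               30
#> I2         I2   120         120               30
#> I3         I3   120         120               30
nm$expected$steps$public
#> [1] 30  0  0
```

Size-matched Random Repertoires are maximally diffuse (one distinct
structure per sampled Fv, versus four Fvs per structure in the genuine
cohorts) and share nothing across individuals, while the genuine cohorts
keep 40% of their structures public — the focused-sampling contrast the
method is built to expose. Clonotyping the same cohort
(`run_clonotype(coh$snapshots, "briney_exact")`) tracks the planted
public clones in sequence space for side-by-side comparison.

A thin command-line wrapper over the same functions ships at
`inst/cli/repstruct.R` (`simulate`, `profile`, `overlap`, `null-model`,
`clonotype`).

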