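# fibersense

Is an individual's gut microbiota **sensitive** or **resistant** to soluble
dietary fiber? When a fecal community is cultured in a continuous-flow
minibioreactor array (MBRA; 15 mL anaerobic chambers, 1.875 mL/h feed, 8 h
retention time) and exposed to inulin or psyllium alongside a cellulose
control, some donors' communities recompose dramatically while others barely
move. `fibersense` implements the multi-readout procedure for making that
call reproducibly, together with a fully synthetic MBRA study generator so
that every stage can be verified by parameter recovery — no sequencing data
required.

## The method

Each chamber at 48 h post-treatment (120 h) is summarized by six
parameters: relative bacterial load (qPCR), Bray–Curtis and unweighted
UniFrac distance of the chamber to its own 72 h pre-treatment composition,
Pielou evenness, and bioactive lipopolysaccharide and flagellin levels
(back-calculated from TLR4/TLR5 reporter-cell dilution series through
four-parameter logistic standard curves). After control- and
baseline-normalization and within-donor min–max scaling, a composite
Bray–Curtis distance over the 9 chambers of each donor (3 treatments × 3
replicates) yields three distance sets:

- `d_cc` — within-cellulose pairwise distances (the null spread),
- `d_ci`, `d_cp` — cellulose×inulin and cellulose×psyllium distances.

A donor is called **sensitive** when either fiber's mean contrast
`mean(d_cf) − mean(d_cc)` is a significant increase at α = 0.05 after
Bonferroni correction for the two fibers — by a one-sided permutation test
over the donor's nine chamber treatment labels (default; 9,999
permutations) or by one-way ANOVA + Tukey HSD (always reported). A PCoA of
the composite distances with feature-correlation vectors visualizes which
parameters drive the separation.

The simulator plants known effect sizes: logistic-growth-with-dilution
community dynamics (explicit Euler), fiber treatment as multiplicative
growth modifiers on a taxon subset from 72 h, Dirichlet-multinomial 16S
counts, lognormal qPCR noise, and noisy 4PL assay readouts. See the methods
vignette (`vignettes/fiber-sensitivity-methods.Rmd`) for the model,
parameter meanings, and design choices.

## Worked example

```r
library(fibersense)

profiles <- random_donor_profiles(3, sensitive = c(TRUE, FALSE, FALSE), seed = 1)
study    <- make_study(profiles, mbra_config(), seed = 1)
study
#> MBRA study: 3 donor(s), 3 treatment arm(s), 297 samples, 24 taxa
#>   sampling: 0-240 h; treatment from 72 h; seed 1

result <- run_sensitivity(study, seed = 1)
result$calls[, c("donor", "status", "d_cc", "d_ci", "d_cp",
                 "p_perm_inulin", "p_perm_psyllium")]
#>   donor    status  d_cc  d_ci  d_cp p_perm_inulin p_perm_psyllium
#> 1    D1 sensitive 0.259 0.697 0.815        0.0838           0.025
#> 2    D2 resistant 0.423 0.418 0.408        0.9810           1.000
#> 3    D3 resistant 0.390 0.450 0.420        0.5352           0.760

result$pcoa
#> PCoA: 27 objects, 13 positive axes
#>   axis 1-2 explain 41.0% + 18.3%
#>   13 negative eigenvalue(s), min -0.176
```

Donor D1 carries the planted fiber response (`sensitivity_delta = 3`:
responding taxa grow 4× faster under fiber): its cellulose–fiber composite
distances (0.70, 0.82) clearly exceed the within-control spread (0.26), and
the psyllium contrast clears the Bonferroni-corrected permutation threshold.
D2 and D3 were simulated resistant and are called resistant — their
cellulose–fiber distances match the control spread. The negative PCoA
eigenvalues are expected for Bray–Curtis dissimilarities and are reported
rather than silently corrected (`correction = "cailliez"` is available).

`write_study(study, dir)` emits the full TSV/Newick file set
(`counts.tsv`, `metadata.tsv`, `loads.tsv`, `assay_readouts.tsv`,
`standards.tsv`, `tree.nwk`, `truth.tsv`); `run_sensitivity(..., outdir =
dir)` adds `features.tsv`, `distances.tsv`, `pcoa.tsv`, `vectors.tsv`,
`calls.tsv`; `build_report(dir)` assembles a checksummed summary with a
calls-vs-truth confusion table for synthetic runs.

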