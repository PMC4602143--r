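# lipofam

De novo protein-family discovery and lipase candidate screening for
metagenomic protein datasets, with the enzyme-kinetics calculations used
to characterise a discovered biocatalyst.

## The problem

Metagenomic surveys produce millions of predicted proteins, most of which
no domain database can annotate — and homology-based enzyme discovery
systematically misses exactly those unannotatable families. `lipofam`
implements the complementary strategy for people hunting biocatalysts
(lipases and esterases in particular) in such data:

1. **Subtract** every sequence a known domain profile can explain
   (HMMER tblout hits with E ≤ 10⁻⁵);
2. **Reduce redundancy** by greedy incremental identity clustering in
   three steps (90, 75, 60% identity), discarding sequences that never
   co-cluster with anything;
3. **Cluster de novo**: all-vs-all Smith–Waterman bit scores (BLOSUM62,
   gap 11/1) form a similarity graph, partitioned by Markov clustering
   (MCL) at inflation *i* = 1.4; families with more than 10 members are
   kept;
4. **Represent** each family by the member with the smallest total
   distance Σⱼ d(i, j) to all other members (shared-6-mer distances, the
   guide-tree statistic);
5. **Screen** representatives with the three oxyanion-hole superfamily
   regular expressions (GX, GGGX, Y) for the Ser–Asp/Glu–His catalytic
   triad around the G-x-S-x-G catalytic elbow;
6. **Confirm** motif hits in a hydrolase-like profile context: external
   HMMER results or a built-in PSSM scorer with empirically calibrated
   Gumbel E-values (candidate iff best E ≤ 10⁻⁵).

For characterising a hit, the kinetics module provides the
Lineweaver–Burk fit (1/v = Km/Vmax · 1/[S] + 1/Vmax, so Km =
slope/intercept, Vmax = 1/intercept), kcat = Vmax/(60·[E]) and the
specificity constant kcat/Km, relative chain-length activity, Gaussian
optimum interpolation y = a·exp(−(x−μ)²/2σ²), and the enantiomeric ratio
of a kinetic resolution, E = ln[1 − c(1+eeP)] / ln[1 − c(1−eeP)].

A synthetic-metagenome generator with ground truth (planted families,
background decoys, motif carriers) makes the whole pipeline testable end
to end.

## Worked example

```r
library(lipofam)

specs <- tibble::tibble(
  n_members       = c(14, 13, 12),
  length          = c(120, 150, 100),
  within_identity = c(0.85, 0.90, 0.82),
  motif           = c("GX", NA, NA)       # plant one lipase-like family
)
mg <- generate_metagenome(specs, n_background = 30,
                          bg_length_range = c(80, 160), seed = 7)
mg
#> <synthetic_metagenome> 69 sequences, 3 planted families, 30 background decoys

res <- run_discovery(mg$records, config = pipeline_config())
res
#> <discovery_result>
#> # A tibble: 7 × 2
#>   stage                         n
#>   <chr>                     <int>
#> 1 input                        69
#> 2 unknown                      69
#> 3 retained                     39
#> 4 family_members               39
#> 5 representatives               3
#> 6 motif_hit_representatives     1
#> 7 confirmed                     1
```

The funnel reads: 69 input sequences (no domain hits were supplied, so
none are subtracted), 39 survive redundancy reduction — the 30 decoys
never co-cluster and are discarded — MCL finds 3 families of ≥ 11
members, one representative each, and exactly one representative (from
the family that carries the planted motif) matches a superfamily pattern:

```r
res$motif_hits
#> # A tibble: 2 × 7
#>   seq_id    superfamily match_start match_end anchor_nucleophile anchor_acid ...
#> 1 fam01_002 GX                    1        42                 18          31
#> 2 fam01_002 GGGX                  1        42                 18          31

evaluate_recovery(mg$truth, res$families,
                  representatives = res$representatives[, c("family", "id")])
#> <recovery_metrics> ARI = 1 over 39 ids; representative label rate = 1
```

Kinetics, using the published pNP-butyrate constants as generators:

```r
d <- mm_rates(km = 66.68, vmax = 400, conc = c(5, 10, 25, 50, 100, 200, 333))
fit_lineweaver_burk(d, enzyme_conc = 0.065)   # 65 nM enzyme
#> <mm_fit> (lineweaver_burk)
#>   Km   = 66.68 uM
#>   Vmax = 400 uM/min
#>   kcat = 102.5641 1/s
#>   kcat/Km = 1538154 1/(M s)

signif(specificity_constant(228, 66.68), 2)   # from the published kcat
#> [1] 3.4e+06

enantiomeric_ratio(conversion = 0.50, eeP = 0.43)
#> <enantio_result> E = 3.742  (conversion 0.5 , eeP 0.43 )
```

The double-reciprocal fit returns the generating Km and Vmax exactly on
noiseless data; with the published turnover number of 228 s⁻¹ the
butyrate specificity constant reproduces 3.4 × 10⁶ M⁻¹s⁻¹, and 50%
conversion at 43% product ee gives a moderate selectivity of E ≈ 3.7.
Fitted objects support `tidy()`, `glance()` and `autoplot()`.

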