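# apneahub

Hub-gene nomination from breath-hold blood transcriptome time courses.

Marine mammals tolerate the ischemia and hypoxia of long breath holds, and
blood cells are plausible first responders to a falling oxygen supply.
Given gene-level RNA-Seq counts from a few individuals sampled at a few
points during a breath hold (the archetype: 3 dolphins at baseline, 3 min
and 4.5 min), `apneahub` answers the screening question: *which genes rise
at every sampling step, and which of those sits at the centre of the
co-expression network?*  A gene that is both consistently induced and
highly connected — a hub — is a candidate driver of the response rather
than a passenger.

## The method in brief

1. **Filter** genes with fewer than 10 reads in every library.
2. **Normalize** by median-of-ratios size factors
   (s_j ∝ median over all-positive genes of count/geometric mean,
   rescaled to geometric mean 1).
3. **Select** genes whose mean normalized expression increases at every
   consecutive timepoint (strictly, by default).  Under exchangeable
   timepoint means a null gene passes with probability 1/3! = 1/6.
4. **Network**: connect selected genes whose |Pearson r| of
   log2(normalized + 1) expression reaches a threshold (default 0.98), or
   ingest an external edge list; drop named unwanted genes (default the
   ncRNA families RF00016, RF00026); trim all nodes with 0 or 1 connection
   in a single pass.
5. **Score**: compute six centralities per node — degree, clustering
   coefficient, closeness, betweenness, neighbourhood connectivity,
   stress — rank nodes on each (descending, fractional ties) and sum the
   six ranks into a **sum rank score**; the lowest score nominates the
   hub.  Reports order by score with fold change as tie-break.

Companion modules provide a running-sum gene-set enrichment engine
(weighted ES, gene-set permutation null with +1-smoothed p-values,
Benjamini–Hochberg q-values, GMT input), one-way ANOVA with Tukey HSD
post hocs for replicate enzyme assays, cohort descriptive statistics, and
a fully seeded negative-binomial simulator with planted ground truth
(monotone genes, a hub module, assay trends) so the entire pipeline is
testable without any data download.

## Worked example

Simulate the study design and screen it end to end:

```r
library(apneahub)

sim <- generate_counts(synthetic_config(seed = 42))
fit <- hub_screen(sim$counts, sim$metadata)
print(fit)
#> Breath-hold hub screen
#>   genes: 2000 input, 1981 after low-count filter, 317 step-wise increasing
#>   network: 317 nodes / 55 edges; 11 nodes / 45 edges after trim
#>   top hub: g1098 (sum rank score 34.0, fold change 5.70)
#>
#> Leading genes:
#>  gene_id sum_rank_score fold_change
#>    g1098             34    5.699783
#>    g0024             34    4.791817
#>    g1541             34    4.019711
#>    g0622             34    3.763287
#>    g0601             34    3.585294

sim$truth$hub_gene_id
#> [1] "g0622"
```

Reading this: of 2,000 simulated genes, 317 pass the step-wise filter
(~30 planted risers plus the expected ~1/6 of null genes).  At the strict
correlation threshold the planted 10-gene module survives trimming as a
near-clique of 11 nodes, whose members tie at the minimal sum rank score
of 34; the planted hub `g0622` is in that tied leading group, which is
exactly what the score can resolve — clique members with identical
connectivity are mathematically indistinguishable on all six metrics.
Fold changes near 4 are the planted 2^2 induction over the two steps.

The simulated enzyme assay, analysed as in the screen's wet-lab companion
(one-way ANOVA across timepoints, Tukey HSD post hocs on triplicates):

```r
assay <- generate_assay_data(synthetic_config(seed = 42))
one_way_anova(assay)
#> One-way ANOVA: F(2, 24) = 18.95, p = 1.153e-05
tukey_hsd(assay)
#>   group_i group_j diff    q    p_adj    lwr  upr
#> 1       0       3 2.39 5.35 2.52e-03  0.814 3.98
#> 2       0     4.5 3.86 8.62 7.80e-06  2.279 5.44
#> 3       3     4.5 1.46 3.27 7.30e-02 -0.116 3.05
```

Cohort descriptives in the conventional format:

```r
format_descriptives(descriptive_stats(c(24, 35, 21, 11)))
#> [1] "22.8 ± 9.9 (range = 11.0–35.0)"
```

Every stage is exported on its own (`filter_low_counts()`,
`estimate_size_factors()`, `select_stepwise_increasing()`,
`build_coexpression_graph()`, `trim_graph()`, `compute_centralities()`,
`sum_rank_scores()`, `gsea()`, …), and a thin command-line wrapper with
`simulate`/`filter`/`select`/`rank`/`network`/`gsea`/`assay` subcommands
ships in `inst/cli/apneahub`.  The methods vignette
(`vignettes/hub-nomination-methods.Rmd`) documents the models, the
simulator's planted structure and the design decisions.

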