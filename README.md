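# paddydiv

Tools for studying the diversification of Southeast Asian rice paddy
snakes (*Hypsiscopus*): coalescent demographic model selection and
divergence dating by rejection approximate Bayesian computation (ABC),
quantification of environmental niche overlap and niche shift between
species, and morphospace discrimination of a priori groups. The package is
written for the three-population system (murphyi, (plumbeus,
matannensis)), but every stage is driven by plain data structures —
phased FASTA alignments plus a population map, occurrence coordinates plus
raster layers, a trait table — and a synthetic-data module generates all
of them, so the full pipeline runs and is tested without any downloads.

## What it computes

**Demographic inference.** A C++ structured-coalescent engine simulates
multilocus datasets under six scenarios on the fixed topology — isolation
(`Is`), isolation with migration (`Im`), with population-size change
(`Isd`, `Imd`), and with founder-event bottlenecks (`Ifd`, `Ifmd`) — using
Wright–Fisher coalescence and infinite-sites mutation. Each dataset is
reduced to a fixed 76-entry summary vector (segregating sites, private
polymorphism, π, Watterson's θ, Tajima's D, Hudson's
F<sub>ST</sub> = 1 − H<sub>w</sub>/H<sub>b</sub>, shared and fixed sites;
mtDNA directly, nuclear loci as across-locus mean and variance). Rejection
ABC accepts the tolerance fraction of simulations nearest the observed
vector after MAD standardization; model support is the proportion of
accepted simulations per model, cross-validated by holding simulated
datasets out as pseudo-observations, and parameters are summarized over
the accepted draws.

**Niche quantification.** Occurrences and background are projected onto
the first two axes of a standardized environmental PCA; kernel-density
occupancy grids corrected by availability give Schoener's
D = 1 − ½ Σ|p₁ − p₂|, permutation niche-equivalency and
background-similarity tests, COUE indices (expansion, stability,
unfilling, centroid shift), Pearson-correlation layer pruning at
|r| > 0.80, and climate envelopes.

**Morphospace.** Trait-table preprocessing (juvenile exclusion below
300 mm, categorical encoding, log transform), standardized PCA, and LDA
with proportional priors, reporting per-axis group separation, the
in-sample confusion matrix, and a Clopper–Pearson exact interval with a
one-sided exact test against the no-information rate.

## Worked example

Simulate a seven-locus dataset (the empirical locus structure) under
isolation with a known root divergence of 2.5 Myr, read it back from
FASTA, and ask the ABC machinery which scenario produced it:

```r
library(paddydiv)
set.seed(42)

truth <- draw_parameters(demographic_model("Is"), 1)
truth$t_root <- 2.5e6; truth$t_pt <- 1.2e6
cfg <- synthetic_sequence_config("Is", true_params = truth, seed = 42)
gen <- gen_sequences(cfg, "demo_seqs")

alns <- lapply(gen$fasta, read_fasta_alignment)
names(alns) <- names(gen$fasta)
count_parsimony_informative(alns$cytb)
#> [1] 174
obs <- observed_sumstats(alns, read_popmap(gen$popmap), mtdna = "cytb")
round(obs[c("mt_S_total", "mt_pi_total", "mt_tajD_total", "mt_fst_PT")], 4)
#>    mt_S_total   mt_pi_total mt_tajD_total     mt_fst_PT
#>      234.0000        0.0407        0.1250        0.7074

tab <- simulate_reference_table(c("Is", "Im"), 1000, default_locus_specs())
rejection_abc(tab, obs, tolerance = 0.01)
#> <abc_result> 20 accepted simulations (tolerance 0.01 )
#> model posterior:
#>   Is   Im
#> 0.65 0.35

ps <- posterior_summary(tab, obs, model = "Is", tolerance = 0.05)
ps[ps$parameter %in% c("t_root", "t_pt"), ]
#>  parameter    mean  median    q2.5   q97.5
#>     t_root 3840954 3947452 1816929 5613022
#>       t_pt 2454260 2522503 1029000 4575460
```

The isolation model is preferred and the 95% interval on the root
divergence covers the generating value of 2.5 Myr; at this toy scale
(1,000 simulations per model) the posterior is deliberately coarse —
precision comes from raising `nsims` and lowering the tolerance. The
niche and morphology stages read analogous inputs (`env_stack()` +
occurrence CSV into `niche_compare()`; trait CSV into
`preprocess_morphology()`, `morph_pca()`, `morph_lda()`), and
`gen_env_occurrences()` / `gen_morphology()` generate matching synthetic
inputs.

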