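---
title: "Models and methods behind paddydiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paddydiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddydiv)
```

paddydiv studies the diversification of Southeast Asian rice paddy snakes
(*Hypsiscopus*) with three largely independent analyses that share one
pipeline: coalescent demographic model selection with rejection ABC,
environmental niche quantification between the two widespread species, and
morphospace discrimination of a priori groups. This vignette explains the
models, the tunable parameters, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## The coalescent model

Three populations sit on the fixed topology
(murphyi, (plumbeus, matannensis)). Backward in time, matannensis merges
into plumbeus at `t_pt` and their common ancestor merges into murphyi at
`t_root`, with `t_pt < t_root` enforced by joint rejection-resampling of
the pair (keeping both marginals uniform over the prior box conditional on
the ordering, rather than sorting, which would distort them). Within a
population of diploid effective size $N_e$, lineage pairs coalesce at rate
$1/(2 N_e)$ per generation; the mtDNA locus uses $0.25\,N_e$ (maternal,
haploid inheritance) and one sequence per individual, nuclear loci use
$N_e$ and two phased sequences per individual. Mutations follow the
infinite-sites model: the number of segregating sites on a genealogy is
Poisson with mean (total branch length $\times \mu \times$ locus length),
and every mutation creates one unique biallelic column.

Units: everything is simulated in generations with one generation per
year, so year-denominated priors map 1:1 onto generations and mutation
rates are per site per generation. This is the simplest coherent reading
of priors stated in years alongside unitless rates; any other generation
time would only rescale `t` and `Ne` jointly without changing the model
comparison.

The six scenarios toggle three event classes:

* **Migration** (`Im`, `Imd`, `Ifmd`): symmetric island-style migration
  between every pair of coexisting populations, with scaled rate
  $4Nm \sim U(0, 2)$ per pair. The backward per-lineage rate is
  $M / (4 N_e^{(i)}(t))$ with the population's current *diploid* size, so
  the per-generation migrant fraction is a demographic quantity shared by
  all loci.
* **Size change** (`Isd`, `Imd`): one instantaneous $N_e$ step per
  population at a time $\sim U(10^4, 5 \times 10^5)$ years, to an
  ancestral size redrawn from that population's $N_e$ prior. A step (not
  exponential growth) keeps the model in the piecewise-constant family of
  classic simulators.
* **Founder events** (`Ifd`, `Ifmd`): each daughter lineage — matannensis
  at `t_pt`, the plumbeus+matannensis ancestor at `t_root` — is founded at
  a fraction $f \sim U(0.01, 0.2)$ of its size and recovers after a
  bottleneck of duration $d \sim U(10^4, 5 \times 10^5)$ years. We
  parameterize the bottleneck by its duration after the founding event
  because an absolute recovery time in the $10^4$–$5 \times 10^5$ year
  window can never intersect the ancestor lineage's lifetime
  (`t_pt`–`t_root`, both $\geq 10^6$ years); the ancestor's window is
  additionally clamped so it cannot extend below `t_pt`.

Default priors (all uniform): murphyi $N_e \in (5 \times 10^5, 2 \times
10^6)$, plumbeus and matannensis $N_e \in (10^5, 1.5 \times 10^6)$; both
divergence times in $(1, 6)$ Myr (each split's prior is independently
configurable, since posterior mass for the younger split can concentrate
near or below a shared floor); mtDNA mutation rate fixed at $10^{-8}$,
nuclear rates $U(5 \times 10^{-10}, 1.5 \times 10^{-9})$ per site per
generation. The seven default loci carry the empirical structure: cyt-b
(118 sequences, 1117 bp, mtDNA), BNC1 (53, 1949), PRLR (96, 553), WFIKKN
(62, 1300), RAG2 (48, 1100), VPS13B (80, 855), AGBL5 (65, 627). Only per-locus
totals are known, so each total is allocated across the three
populations proportionally to the overall specimen counts 120:42:21
(murphyi:plumbeus:matannensis), rounding the two smaller shares and giving
the remainder to murphyi.

The engine is event-driven C++: between demographic events, competing
exponentials decide whether the next event is a coalescence or a
migration; at event times, sizes step or populations join. Genealogy-level
checks (pairwise TMRCA of $2N$ generations, Watterson's $E[S] = \theta
a_{n-1}$, the neutral site-frequency spectrum, and a two-sample
distributional comparison against an independent coalescent simulator) are
part of the test suite.

## Summary statistics

Each simulated or observed dataset is reduced to a fixed 76-entry vector:
25 statistics for the mtDNA locus, and the across-locus mean and variance
of the same 25 for the nuclear loci, plus a counter of undefined entries.
The 25 are: segregating sites (total, per population, private per
population), per-site $\pi$ (total, per population), per-locus Watterson's
$\theta_W$ (total, per population), pooled Tajima's D, and per population
pair Hudson's $F_{ST}$ ($1 - H_w/H_b$, clipped below at $-0.1$), shared
polymorphisms, and fixed differences. The layout is versioned (`ssv1`) in
the reference-table header so observed and simulated vectors can never
silently misalign. Undefined statistics (a population with fewer than two
sequences, Tajima's D below four) are encoded as 0 and counted in the
trailing entry rather than dropping the simulation — rejection ABC needs
complete rows; the counter column is constant in practice and therefore
excluded from distances by the MAD rule below.

Observed alignments are reduced to biallelic matrices under the
infinite-sites conventions: bases outside A/C/G/T are missing; sites with
more than two observed bases, or missing in more than half the sequences,
are dropped (with counts logged); remaining segregating sites are coded
major/minor. Polarity does not matter because every statistic in the
vector is allele-frequency symmetric. Missing calls are handled by
pairwise deletion, with per-site sample sizes entering each estimator.

## Rejection ABC

Statistic columns are divided by their median absolute deviation over the
reference table (zero-MAD columns carry no information and are excluded,
with a record). The accepted set is the `max(1, round(tolerance * rows))`
simulations closest to the observed vector in Euclidean distance, ties
broken by row index; model support is the within-accepted proportion of
each model — the plain-rejection estimator. No regression adjustment is
applied by default, so the reported support is exactly that proportion; a
local-linear adjustment would change the parameter posteriors but not the
acceptance step itself, and is deliberately left out to keep model support
interpretable.
Posterior parameter summaries are means, medians, and 2.5/97.5 percent
linear-interpolation quantiles of the accepted draws. Cross-validation
holds out simulated datasets as pseudo-observations and classifies each
against the remaining rows (rejection-based, in the style of `cv4postpr`
from the abc package, rather than a supervised classifier: the rejection
route keeps the classifier identical to the selection step, so the
cross-validation measures exactly the procedure being used). Goodness of fit projects simulations onto their first two
principal components and reports whether the observed vector falls inside
their convex hull.

Tolerance is applied to the pooled multi-model table, which is what makes
the within-accepted proportion a model posterior. A full-scale analysis
runs 50,000 simulations per model with tolerance 0.001; desk-scale runs in
this package use 5,000 per model with tolerance 0.01, which keeps roughly
the same number of accepted simulations per comparison. The acceptance
script and test suite use the desk-scale sizes; the full-scale run is a
matter of `nsims` and patience, not of different code.

## Niche quantification

The two species' occurrences and the pooled background are projected onto
the first two axes of a standardized PCA of background environmental
conditions (PCA-env). Occurrence and background densities are Gaussian
kernel estimates on an R x R grid (R = 100 by default) spanning the
background extent, with Silverman-rule bandwidths on the occurrence
scores; corrected occupancy is $z = (o/e) / \max(o/e)$ on the background
support and 0 elsewhere, so sampling effort in environment space cannot
masquerade as preference. Overlap is Schoener's
$D = 1 - \tfrac12 \sum |p_1 - p_2|$ on the normalized grids.

The equivalency test pools both occurrence sets, re-splits at the original
sizes, and recomputes D; the p-value is the lower-tail
$(\#\{D_{null} \le D_{obs}\} + 1)/(reps + 1)$, so small p means the niches
are less interchangeable than random splits. The similarity (background)
test replaces one species' occurrences with random draws from its own
available background and recomputes D, upper-tailed: small p means the
observed overlap exceeds what a randomly placed niche in that background
would produce. It is run in both directions and both p-values are
reported. The background-randomization null is exactly calibrated when
occurrences are random with respect to the environment, which the test
suite verifies as a type-I experiment. Adding one to numerator and
denominator keeps p in (0, 1] and never exactly 0.

COUE indices use occupied cells defined by corrected occupancy above a
10 percent density-trim threshold within the shared support: expansion is
the density-weighted fraction of the invaded niche outside the native
niche, stability its complement, unfilling the mirror image for the native
niche, and the centroid shift the vector between density-weighted
centroids. Variable pruning removes, greedily and deterministically, one
member of the worst |Pearson r| > 0.80 pair (the one with the larger mean
absolute correlation to the remaining layers) until no pair exceeds the
threshold. Climate envelopes are five-number summaries (type-7,
linear-interpolation quantiles) of each retained layer at each species'
occurrence cells.

Rasters are read and written as ESRI ASCII grids — a plain-text format
sufficient for bioclim-style layers. Maxent suitability modeling, model
evaluation (AUC, Boyce), paleoclimate projections, and spatial thinning
are out of scope: they precede or follow the quantification implemented
here and are well served by dedicated tools.

## Morphospace

Preprocessing removes juveniles (total length < 300 mm), encodes
categorical variables as integer state codes from supplied level
dictionaries, log-transforms every variable (natural log; +1 offset only
for columns containing zeros), and drops invariant columns plus any
supplied exclusion list. The variable set comes from the table header
rather than a hard-coded list. PCA is on standardized variables. LDA uses
proportional group priors and reports each discriminant axis's share of
the between-group variance; the confusion matrix is in-sample
(resubstitution), so the accuracy describes how separable the groups are
in the fitted discriminant space. An arithmetic anchor for this scheme:
the Clopper–Pearson exact interval for 84 correct of 86 is
[91.85%, 99.72%], and the test suite asserts that identity.
The accuracy test against the no-information rate (the largest group's
share, 44/86) is a one-sided exact binomial test.

## Synthetic data: what it does and does not emulate

`gen_sequences` simulates haplotype matrices under a chosen scenario with
the empirical locus structure and writes phased FASTA plus a population
map; monomorphic positions carry a fixed reference base and derived
alleles a single alternate base, so the files are structurally realistic
but carry no substitution-model complexity (no indels, no multiple hits,
no rate heterogeneity). `gen_env_occurrences` builds spatially
autocorrelated layers as moving-average-smoothed Gaussian random fields
and samples occurrences with probability proportional to a Gaussian
suitability kernel in environment space — it reproduces the statistical
shape the niche machinery assumes (smooth availability, unimodal niches)
but not real bioclim covariance structure, coastlines, or sampling bias.
`gen_morphology` draws groups from multivariate normals with a shared
covariance and can write a configurable fraction of each group as
juveniles. Consequently, green tests demonstrate correctness of the
machinery under its own assumptions, parameter recovery at realistic
sample sizes, and calibration of the permutation tests; they do not
demonstrate robustness to phase error, rate variation, spatial sampling
bias, or non-normal trait distributions.

## Numerical choices and problem sizes

Monte-Carlo checks in the test suite use 2,000 replicates for engine-level
expectations (three standard errors), 500 or fewer for directional
comparisons, and a 200-run type-I experiment for the similarity test. The
classification experiment simulates 5,000 datasets per model and holds out
50 pseudo-observations per model — large enough that the binomial standard
error on overall accuracy (about 0.018) sits well inside the comparison
band, small enough to run on one CPU in minutes. Degenerate inputs are
errors, not silent zeros, except where a convention is stated (Tajima's D
at S = 0; Fst at Hb = 0; sub-minimal subsets warn and return 0 inside the
vector with the undefined counter incremented). Ties are deterministic
everywhere (row index in rejection, lowest model index in classification
votes, alphabetical major allele, later layer dropped in pruning), so a
fixed seed reproduces every result bit for bit.

## Known limitations

Model identifiability is asymmetric under the default priors. The
classification experiment in the test suite recovers the presence or
absence of migration essentially perfectly, but the no-change,
size-change, and founder variants within each migration class overlap
heavily: with the ancestral size of a step redrawn from the same prior as
the current size, changes are symmetric and often small, and both steps
and bottlenecks are confined to the most recent 10–500 thousand years of
coalescent histories whose expected depths run to millions of generations.
The resulting summary-statistic distributions are nearly coincident across
those variants, which caps the accuracy of any classifier — a
random-forest check on the same statistics does no better than the
rejection classifier. Distinguishing such variants in practice requires
directional, externally informed change priors (for example from a skyline
analysis of the mtDNA data); the package accepts narrowed per-population
priors for exactly that purpose via `demographic_model()`, but ships
neutral symmetric defaults rather than inventing magnitudes.

No intra-locus recombination, selection, or more than three populations;
founder-event parameterizations differ among existing wrapper pipelines,
and the founder models here are specified cleanly on their own terms
rather than mirroring any one of them; the
statistic set emulates an msABC-style vector without claiming identity to
any particular msABC invocation; and the niche stage assumes lon/lat
inputs on congruent grids with no reprojection.
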