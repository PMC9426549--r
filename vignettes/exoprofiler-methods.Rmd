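---
title: "Methods: metaexoproteome inference and SCG community profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaexoproteome inference and SCG community profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the defaults and why they were chosen, what
the synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The analysis problem

A metaexoproteomic study of a plant–soil system asks two linked questions:
*who is there* (community composition, from metagenome read coverage) and
*who is doing what* (community activity, from the secreted proteins
captured in soil). The statistical machinery in this package covers the
path from a search engine's peptide-spectrum matches (PSMs) and an ORF
catalog's coverage table to compartment-level conclusions: which proteins
are enriched near roots, whether the proteome and the community profile
separate by compartment, and which taxa carry and express marker genes
such as alkaline phosphatases.

## Sequence clustering for database reduction

Metagenome ORF catalogs are heavily redundant; searching spectra against
them inflates both runtime and the decoy space. `greedy_cluster()`
reduces redundancy the way incremental clusterers do: sequences sorted
longest-first (ties broken by id, so input order never matters), each
sequence joins the first established representative it matches, else
founds a cluster. Two rules govern joining:

* **identity** — identical aligned residues divided by the *shorter*
  sequence length, under a global alignment with match = 1, mismatch = 0,
  linear gap −1. The shorter-sequence denominator means a fragment fully
  contained in a longer sequence has identity 1, which is the behaviour
  wanted when collapsing partial ORFs onto full-length ones.
* **coverage** — at least `min_short_coverage` (default 0.80) of the
  shorter sequence must sit in non-gap alignment columns, preventing
  spurious merges of short repeats.

Among score-optimal alignments the one with the most matched columns is
used (then most aligned columns), so identity is a deterministic function
of the pair; the dynamic program lives in `src/align.cpp`. Typical
thresholds are 0.90 for proteome-database reduction and 0.95 for
single-copy gene clustering. No k-mer prefilter is applied: at the
catalog sizes this package targets (10²–10⁴ sequences) exact alignment of
every candidate pair is affordable and removes a whole class of
heuristic-dependent behaviour. Tests compare the clusterer against a
brute-force oracle that materializes all pairwise identities and applies
the same greedy rule.

## Two-tier FDR and protein grouping

Both tiers use the plain target–decoy estimator
`FDR(t) = D(t)/max(T(t), 1)` capped at 1, converted to q-values by the
step-down running minimum so q never increases with score and tied scores
share a q-value. The `+1` decoy correction is available
(`pi_correction = TRUE`) but off by default: with the decoy set sizes
used here the uncorrected estimator is already mildly conservative
whenever spurious target matches are rarer than decoys, and calibration
is verified by simulation rather than assumed.

Grouping applies two parsimony rules: proteins with identical peptide
sets merge, and a protein whose peptide set is a strict subset of
another's is absorbed into that protein's group. When several
incomparable supersets exist the largest wins, with ties to the
lexicographically smallest founder — an arbitrary but deterministic
choice, mirrored exactly by the test oracle. A peptide mapping into more
than one group is *shared* and counts as unique to none; there is no
razor reassignment, because the only uniqueness rule enforced downstream
is the ≥ 2 unique-peptides filter. Representative selection takes the
member with most unique peptides, then the higher aggregate PSM score
(the stand-in for a search engine's protein probability, which is not
reimplemented here), then the smallest id.

Filters run in a fixed order — contaminant, modified-only, minimum unique
peptides — and each removed group is tallied under the first rule it
fails, so the audit table always sums to input minus output. The
modified-only flag is evaluated at group level (every PSM of every
peptide modified), since a protein identified solely through modified
peptides is the object the rule targets.

## Quantification

NSAF divides each protein's spectral count by its length and renormalizes
per sample, so columns are exact simplex weights; percent abundance is
100 × NSAF. The label-free intensity route log2-transforms non-zero
intensities and shifts each sample's median to the global median. This
median-centring is a deliberately transparent stand-in for
search-software LFQ (delayed normalization over pairwise peptide ratios
is out of scope) and is recorded as the abundance mode on the object.
Zeros denote missing observations and stay `NA`; nothing is imputed,
because imputation would manufacture power in the downstream tests.
Z-score profiles average replicates per condition first, then standardize
each protein across condition means — rows with zero variance are set to
zero rather than `NaN`.

## Enrichment and community statistics

Per-protein compartment tests are Welch (unequal-variance) t tests on
log2 values, chosen over the pooled test because equal variances across
compartments is exactly the assumption a rhizosphere contrast should not
make. Proteins observed fewer than `min_obs = 2` times in either
compartment are excluded from testing but reported, and
Benjamini–Hochberg correction runs over the tested set only. The calls
are asymmetric by design: rhizosphere-enriched requires q < 0.05 and
fold change > 2, bulk-enriched q < 0.05 and inverse fold change > 1.5.

Bray–Curtis dissimilarities come from `vegan::vegdist()`. ANOSIM ranks
all n(n−1)/2 distances (average ranks on ties) and PERMANOVA partitions
squared dissimilarities; both obtain p-values by permuting group labels
with the observed statistic included — `p = (1 + #[stat* ≥ stat])/(1 +
n_perm)` — so p is never zero and never below `1/(n_perm + 1)`. For
small n, `exhaustive = TRUE` enumerates every distinct label permutation
and returns the exact p. Permutations are reproducible under an explicit
seed that never disturbs the caller's RNG stream. Degenerate PERMANOVA
inputs with zero within-group sums of squares report `R² = 1` and an
infinite pseudo-F, with the p-value still computed by permutation.

## SCG-based taxonomic profiling

The profiler assumes the 36 single-copy core gene families occur exactly
once per genome, so family coverage is proportional to cell abundance
regardless of genome size. Per sample it (i) sums coverage within each
(taxon, family) cell at the requested rank, (ii) takes the *median*
across a taxon's detected families — one repeat-inflated or mis-mapped
family cannot shift a median — and (iii) divides by the sample
normalizer, the median of the 36 per-family total coverages. Two
conventions were genuinely open and are resolved as follows:

* the per-taxon median runs over families with non-zero coverage by
  default (`include_zero_families = FALSE`): counting undetected families
  as zeros would bias every low-abundance taxon toward zero at shallow
  depth; the other behaviour is available behind the flag.
* profiles are recomputed per rank rather than summed from child taxa,
  because medians do not commute with summation; the two agree only when
  each child's detected families are disjoint.

Cluster representatives are assigned to the reference taxon at minimal
cosine distance between length-normalized k-mer (k = 4) frequency
vectors, ties to the smallest reference id. This replaces per-family
phylogenetic placement — tree construction is out of scope — while
preserving the contract (argmin over references carrying lineages); the
distance function is pluggable, and assignments always land on a leaf
reference, never an internal ancestor. The recovery simulations in the
test suite show ≥ 95% correct reassignment at 5% sequence divergence.

Marker profiling follows the same normalizer: ORFs are classified to the
marker family of maximal score among families whose threshold they
*strictly* exceed, taxonomy comes from the best (lowest e-value) hit at
e ≤ 1e-20 with unassigned ORFs removed and counted, and abundances are
family coverage sums divided by the sample's SCG normalizer — the median
rather than the sum, for consistency with the community profile.

## The synthetic-data generator

The generator's defaults define the study conditions every test runs
under. Communities draw taxon abundances from a log-normal (meanlog 0,
sdlog 1) — heavy-tailed, as soil communities are — with log-normal
per-sample noise (sdlog 0.25) and renormalization to the simplex.
Samples come in two equal compartments; a per-taxon enrichment factor
multiplies abundance in rhizosphere samples *before* renormalization, so
factor 1 everywhere means compartments identical in distribution.
Metagenomes give every taxon exactly one ORF per SCG family (ancestral
family sequences diverged ~15% per taxon, ~1% within-taxon noise),
accessory ORFs proportional to genome size, and Poisson coverage with
mean depth × abundance (negative binomial behind an overdispersion
switch). PSM tables use tryptic-style peptides (7–25 residues ending
K/R), reversed-peptide decoys preserving the terminal residue, Gaussian
score separation between correct and spurious matches, spectral counts
proportional to abundance × length, and log-normal intensities carrying
the configured rhizosphere fold change for the enriched subset
(σ_log2 = 0.5 replicate noise, 5% missing intensities by default).

All randomness flows from one integer seed through fixed per-stage
offsets, so regeneration is bit-identical and a pipeline rerun reproduces
every output byte-for-byte.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: fragmentation spectra and search
engine score semantics, retention-time or match-between-runs structure,
chimeric spectra, correlated peptide detectability, real lineage
structure (taxonomy is a synthetic balanced hierarchy), strain-level
microdiversity within clusters, and compositional coupling between the
proteome and the metagenome beyond what the scenario encodes. Passing
calibration here means the *statistics* behave as specified under their
own assumptions, not that any specific field result is reproduced.

## Problem sizes and runtime choices

The default end-to-end scenario uses 10 taxa, 6 samples per compartment,
depth 80, 300 simulated proteins and ~500 ORFs — sizes chosen so a full
run finishes in about a minute and the whole verification suite in a few
minutes on a single core, while keeping every estimator away from its
small-sample degeneracies (≥ 2 samples per compartment, ≥ 36 SCG ORFs
per taxon, permutation counts of 199–999 with exact enumeration where
n ≤ 7). Calibration checks use 50 replicates of 10,000-target /
10,000-decoy PSM sets and 200 replicates of the permutation null with
5-vs-5 designs; the 5-vs-5 choice matters because with 4-vs-4 only 70
distinct label assignments exist and the attainable p-values are too
discrete for a rejection rate near the nominal 5%.

## Known limitations

* The LFQ stand-in removes only constant per-sample log shifts; it cannot
  correct intensity-dependent (non-linear) biases.
* FDR estimates inherit the usual target–decoy assumptions (decoys
  exchangeable with false targets); group-level FDR is classic
  target–decoy competition, not the picked-pair variant.
* One-way designs only: ANOSIM/PERMANOVA permute labels freely, so
  blocked or stratified designs are out of scope.
* The k-mer placement is a coarse proxy for phylogenetic placement and
  will degrade for references more divergent than the simulated ~15%.
* Manual curation steps of real studies (e.g. spectral inspection of
  borderline identifications) are represented only by the filter audit
  table, not automated.
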