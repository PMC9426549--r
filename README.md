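# exoprofiler

Tools for analysing the **metaexoproteome** — the secreted/extracellular
protein fraction of a microbial community — alongside shotgun-metagenome
profiles of the same soil samples, with the rhizosphere (root-influenced
soil) versus bulk-soil contrast as the motivating design. The package is
aimed at microbial ecologists who want a tested, fully reproducible
implementation of the statistical core of such studies, exercised
end-to-end on synthetic communities with known ground truth.

## What it implements

**Search-database reduction.** Greedy incremental clustering of protein/ORF
catalogs (longest-first, first-fit), with identity defined CD-HIT-style as
identical aligned residues over the length of the *shorter* sequence under
a global alignment (match = 1, mismatch = 0, gap = −1), plus an aligned-
coverage rule (default ≥ 0.8 of the shorter sequence).

**Two-tier FDR protein inference.** Peptide-level target–decoy q-values

    FDR(t) = D(t) / max(T(t), 1),  q(t) = min over thresholds ≥ t of FDR

(step-down, capped at 1, ties share a q-value; accept at q ≤ 0.05), then
parsimonious protein grouping (identical peptide sets merge; strict-subset
sets are absorbed; shared peptides are unique to no group), protein-group
q-values by the same construction on best scores (accept at q ≤ 0.10),
removal of contaminants, modified-only evidence and groups with < 2 unique
peptides, and deterministic representative selection.

**Quantification.** NSAF, the normalized spectral abundance factor

    NSAF_is = (SpC_is / L_i) / Σ_j (SpC_js / L_j),

percent abundance (100 × NSAF), per-protein Z-score profiles over condition
means, median-centred log2 label-free intensities (zeros stay missing, no
imputation), and taxonomic/functional rollups by protein count
("diversity") or summed abundance.

**Compartment enrichment and community statistics.** Per-protein Welch
tests on log2 values with Benjamini–Hochberg correction and asymmetric
fold-change calls (rhizosphere: q < 0.05 and FC > 2; bulk: q < 0.05 and
1/FC > 1.5); Bray–Curtis dissimilarity; one-way ANOSIM
(R = (r̄_B − r̄_W)/(n(n−1)/4) on tied-average ranks) and one-way PERMANOVA
(pseudo-F, R² = SS_A/SS_T) with seeded permutation p-values that include
the observed statistic, or exact enumeration of all label permutations for
small n.

**Taxonomic profiling from single-copy core genes (SCGs).** Coverage of 36
single-copy core gene families is summed per (taxon, family, sample) at any
lineage rank, aggregated per taxon by the *median* across detected families
(robust to a repeat-inflated family), and normalized per sample by the
median total coverage of the 36 families — an estimator insensitive to
genome size. Cluster representatives are placed on reference taxa by k-mer
cosine distance; marker genes (e.g. the alkaline phosphatases PhoX, PhoD,
PhoA) are classified by score thresholds, taxonomically assigned by best
hit at e ≤ 1e-20, and reported as SCG-normalized abundances.

**Synthetic data with ground truth.** `simulate_community()`,
`simulate_metagenome()`, `simulate_psm_table()` and
`simulate_marker_evidence()` generate every pipeline input (log-normal
community abundances, Poisson ORF coverage, exactly one copy of each of the
36 SCG families per genome, reversed-peptide decoys with Gaussian score
separation, configurable rhizosphere intensity fold changes) from a single
seed, so every downstream claim is testable without any downloads.

## Worked example

```r
library(exoprofiler)

sc <- simulate_community(n_taxa = 10, n_samples = 6, depth = 80, seed = 17)
ps <- simulate_psm_table(sc, list(n_proteins = 300,
                                  fraction_enriched = 0.15, fold_change = 4))

groups <- infer_protein_groups(ps, pep_fdr = 0.05, prot_fdr = 0.10)
groups
#> <protein_groups> 269 groups, 274 proteins

gq  <- quantify_groups(groups, ps$psms, ps$proteins[, c("protein", "length")])
enr <- differential_enrichment(lfq_normalize(gq), sc$samples)
glance(enr)
#> # A tibble: 1 × 4
#>   n_proteins n_tested n_rhizosphere n_bulk
#>        <int>    <int>         <int>  <int>
#> 1        269      261            38      5

d  <- bray_curtis(nsaf(gq))
permanova(d, sc$samples$compartment[match(labels(d), sc$samples$sample)],
          n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F = 17.493, R2 = 0.636, P = 0.002 (999 permutations)

mg   <- simulate_metagenome(sc, orfs_per_megabase = 3)
catl <- build_scg_catalog(mg)
prof <- normalize_profile(scg_taxon_profile(mg$coverage, catl, rank = "order"))
dmg  <- bray_curtis(tibble::as_tibble(prof), feature = "taxon",
                    value = "abundance")
permanova(dmg, sc$samples$compartment[match(labels(dmg), sc$samples$sample)],
          n_perm = 999, seed = 2)
#> PERMANOVA: pseudo-F = 1.634, R2 = 0.140, P = 0.156 (999 permutations)
```

Reading the output: of 269 inferred protein groups, 38 are
rhizosphere-enriched versus 5 bulk-enriched, and the proteome separates
sharply by compartment (R² = 0.64, P = 0.002) while the SCG-based
community profile of the *same* samples shows no compartment effect
(P = 0.16) — the activity of the community shifts near roots even though
its composition does not, which is exactly the effect the bundled scenario
encodes (the 4-fold enrichment acts on protein intensities only).

`run_pipeline(run_config(seed = 17), out_dir = "run")` executes the whole
chain — simulate, cluster, infer, quantify, enrich, SCG profile, marker
profile, statistics — writing every stage's TSV table with seed and
config-hash provenance comments; reruns are byte-identical.

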