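AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# n random amino-acid strings with lengths drawn uniformly in len_range
random_aa_strings <- function(n, len_range) {
  if (n == 0) return(character(0))
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n)
          else sample(len_range[1]:len_range[2], n, replace = TRUE)
  chars <- sample(AA_ALPHABET, sum(lens), replace = TRUE)
  vapply(split(chars, rep.int(seq_len(n), lens)),
         paste0, character(1), collapse = "")
}

# tryptic-style peptides: length 7-25, terminal residue K or R
random_peptides <- function(n) {
  if (n == 0) return(character(0))
  body <- random_aa_strings(n, c(6, 24))
  paste0(body, sample(c("K", "R"), n, replace = TRUE))
}

# point-mutate each sequence at the given per-residue rate
mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(orig) {
        sample(setdiff(AA_ALPHABET, orig), 1)
      }, character(1))
    }
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# reverse a tryptic peptide keeping the C-terminal residue in place,
# the standard decoy construction
reverse_peptide <- function(pep) {
  n <- nchar(pep)
  body <- substr(pep, 1, n - 1)
  paste0(
    vapply(strsplit(body, "", fixed = TRUE),
           function(x) paste0(rev(x), collapse = ""), character(1)),
    substr(pep, n, n)
  )
}

#' Simulate a soil community scenario with known ground truth
#'
#' Draws per-taxon relative abundances from a heavy-tailed log-normal prior
#' (the shape typical of soil communities), adds per-sample log-normal noise,
#' and renormalizes every sample to sum to one. Samples come in two
#' compartments, bulk and rhizosphere; a per-taxon `enrichment_factor`
#' multiplies abundance in rhizosphere samples before renormalization, so a
#' factor of 1 for every taxon yields compartments identical in distribution.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_samples Number of samples per compartment (>= 2); the scenario
#'   has `2 * n_samples` samples in total.
#' @param depth Expected read coverage for a taxon at relative abundance 1;
#'   must be positive. Used downstream by [simulate_metagenome()].
#' @param effect_config Optional list: `enrichment_factor` (scalar or length
#'   `n_taxa`, default 1 — no compositional shift), `sample_sigma`
#'   (log-scale sd of per-sample noise, default 0.25) and `abundance_sigma`
#'   (log-scale sd of the across-taxa abundance prior, default 1; 0 gives a
#'   perfectly even community).
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   scenario exactly.
#' @return An object of class `community_scenario`: a list with `taxa`
#'   (tibble with seven-rank lineages, genome sizes and enrichment factors),
#'   `samples` (tibble of sample ids and compartments), `abundance`
#'   (taxon-by-sample matrix, columns summing to 1), `depth` and `seed`.
#' @examples
#' sc <- simulate_community(5, 3, depth = 50, seed = 1)
#' colSums(sc$abundance)
#' @export
simulate_community <- function(n_taxa, n_samples, depth = 50,
                               effect_config = list(), seed = 1) {
  if (n_taxa < 2) abort("`n_taxa` must be at least 2.")
  if (n_samples < 2) abort("Need at least 2 samples per compartment.")
  if (depth <= 0) abort("`depth` must be positive.")
  ef <- effect_config$enrichment_factor %||% 1
  if (length(ef) == 1) ef <- rep(ef, n_taxa)
  if (length(ef) != n_taxa || any(ef < 0))
    abort("`enrichment_factor` must be non-negative, length 1 or `n_taxa`.")
  sample_sigma <- effect_config$sample_sigma %||% 0.25
  abundance_sigma <- effect_config$abundance_sigma %||% 1

  with_seed(stage_seed(seed, "community"), {
    taxon <- sprintf("t%03d", seq_len(n_taxa))
    taxa <- tibble::tibble(
      taxon = taxon,
      domain = "Bacteria",
      phylum = sprintf("Phylum_%d", (seq_len(n_taxa) - 1) %/% 4 + 1),
      class = sprintf("Class_%d", (seq_len(n_taxa) - 1) %/% 2 + 1),
      order = sprintf("Order_%d", seq_len(n_taxa)),
      family = sprintf("Family_%d", seq_len(n_taxa)),
      genus = sprintf("Genus_%d", seq_len(n_taxa)),
      species = sprintf("Species_%d", seq_len(n_taxa)),
      genome_size = sample(2e6:8e6, n_taxa, replace = TRUE),
      enrichment_factor = ef
    )
    samples <- tibble::tibble(
      sample = c(sprintf("bulk_%d", seq_len(n_samples)),
                 sprintf("rhizo_%d", seq_len(n_samples))),
      compartment = rep(c("bulk", "rhizosphere"), each = n_samples)
    )
    base <- rlnorm(n_taxa, meanlog = 0, sdlog = abundance_sigma)
    ab <- vapply(seq_len(nrow(samples)), function(s) {
      w <- base * rlnorm(n_taxa, 0, sample_sigma)
      if (samples$compartment[s] == "rhizosphere") w <- w * ef
      w / sum(w)
    }, double(n_taxa))
    dimnames(ab) <- list(taxon, samples$sample)
    structure(
      list(taxa = taxa, samples = samples, abundance = ab,
           depth = depth, seed = as.integer(seed)),
      class = "community_scenario"
    )
  })
}

#' @export
print.community_scenario <- function(x, ...) {
  cat(sprintf(
    "<community_scenario> %d taxa, %d samples (%s), depth %g, seed %d\n",
    nrow(x$taxa), nrow(x$samples),
    paste(table(x$samples$compartment), collapse = " + "),
    x$depth, x$seed
  ))
  invisible(x)
}

N_SCG_FAMILIES <- 36L

scg_family_names <- function() sprintf("SCG-%d", seq_len(N_SCG_FAMILIES))

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

# seven-rank lineage collapsed to a single `;`-separated string
taxon_lineage <- function(taxa) {
  do.call(paste, c(unname(as.list(taxa[LINEAGE_RANKS])), list(sep = ";")))
}

#' Simulate a metagenome ORF catalog with coverage profiles
#'
#' Builds an ORF catalog for a [simulate_community()] scenario: every taxon
#' carries exactly one copy of each of the 36 single-copy core gene (SCG)
#' families, a number of accessory ("other") ORFs proportional to its genome
#' size, and optionally marker-gene ORFs (e.g. alkaline phosphatase
#' families). SCG and marker sequences are derived from per-family ancestral
#' sequences with per-taxon divergence, so identity clustering and
#' nearest-reference assignment can recover the generating taxon. Per-sample
#' ORF coverage is Poisson with mean `depth * abundance(taxon, sample)`
#' (negative binomial if `overdispersion` is finite), mimicking read-mapping
#' depth.
#'
#' @param scenario A `community_scenario`.
#' @param orfs_per_megabase Accessory ORFs per megabase of genome (> 0).
#' @param seed Integer seed; defaults to one derived from the scenario seed.
#' @param overdispersion Negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson coverage noise.
#' @param marker_config Optional list describing marker families:
#'   `families` (character), and either `copies` (taxa-by-family integer
#'   matrix) or `prevalence` (probability a taxon carries one copy,
#'   default 0.6).
#' @return An object of class `synthetic_metagenome`: `orfs` (tibble: orf,
#'   taxon, family, length, sequence), `coverage` (ORF-by-sample matrix),
#'   `references` (per taxon-family reference sequences with lineages) and
#'   the `scenario`.
#' @export
simulate_metagenome <- function(scenario, orfs_per_megabase = 5, seed = NULL,
                                overdispersion = Inf, marker_config = NULL) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (orfs_per_megabase <= 0) abort("`orfs_per_megabase` must be positive.")
  seed <- seed %||% stage_seed(scenario$seed, "metagenome")

  with_seed(seed, {
    taxa <- scenario$taxa
    n_taxa <- nrow(taxa)
    fams <- scg_family_names()

    # family ancestral sequences; taxa diverge ~15% within a family
    scg_base <- setNames(random_aa_strings(N_SCG_FAMILIES, c(120, 180)), fams)
    ref_rows <- tidyr::expand_grid(taxon = taxa$taxon, family = fams)
    ref_rows$sequence <- mutate_seqs(scg_base[ref_rows$family], rate = 0.15)

    marker_rows <- NULL
    if (!is.null(marker_config)) {
      mf <- marker_config$families %||% c("PhoA", "PhoD", "PhoX")
      if (!is.null(marker_config$copies)) {
        copies <- marker_config$copies
        stopifnot(nrow(copies) == n_taxa, ncol(copies) == length(mf))
      } else {
        prev <- marker_config$prevalence %||% 0.6
        copies <- matrix(stats::rbinom(n_taxa * length(mf), 1, prev),
                         n_taxa, length(mf))
      }
      mk_base <- setNames(random_aa_strings(length(mf), c(150, 200)), mf)
      mk_ref <- tidyr::expand_grid(taxon = taxa$taxon, family = mf)
      mk_ref$sequence <- mutate_seqs(mk_base[mk_ref$family], rate = 0.15)
      cp <- tibble::tibble(
        taxon = rep(taxa$taxon, times = length(mf)),
        family = rep(mf, each = n_taxa),
        n_copies = as.vector(copies)
      )
      mk_ref <- dplyr::left_join(mk_ref, cp, by = c("taxon", "family"))
      marker_rows <- mk_ref[rep(seq_len(nrow(mk_ref)), mk_ref$n_copies), ]
      ref_rows <- dplyr::bind_rows(
        ref_rows, dplyr::select(mk_ref, "taxon", "family", "sequence")
      )
    }

    scg_orfs <- tibble::tibble(
      taxon = rep(taxa$taxon, each = N_SCG_FAMILIES),
      family = rep(fams, times = n_taxa)
    )
    key <- paste(scg_orfs$taxon, scg_orfs$family)
    refkey <- paste(ref_rows$taxon, ref_rows$family)
    scg_orfs$sequence <- mutate_seqs(
      ref_rows$sequence[match(key, refkey)], rate = 0.01
    )

    n_other <- round(taxa$genome_size * orfs_per_megabase / 1e6)
    other_orfs <- tibble::tibble(
      taxon = rep(taxa$taxon, times = n_other),
      family = "other",
      sequence = random_aa_strings(sum(n_other), c(40, 80))
    )

    orfs <- dplyr::bind_rows(
      scg_orfs,
      if (!is.null(marker_rows))
        dplyr::select(marker_rows, "taxon", "family", "sequence"),
      other_orfs
    )
    orfs$orf <- sprintf("orf_%05d", seq_len(nrow(orfs)))
    orfs$length <- nchar(orfs$sequence)
    orfs <- dplyr::select(orfs, "orf", "taxon", "family", "length", "sequence")

    lam <- scenario$depth *
      scenario$abundance[orfs$taxon, , drop = FALSE]
    cov <- if (is.finite(overdispersion)) {
      matrix(rnbinom(length(lam), mu = lam, size = overdispersion),
             nrow(lam), ncol(lam))
    } else {
      matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
    }
    dimnames(cov) <- list(orfs$orf, colnames(scenario$abundance))

    references <- ref_rows
    references$reference <- sprintf("ref_%s_%s",
                                    references$taxon, references$family)
    references <- dplyr::left_join(
      dplyr::select(references, "reference", "taxon", "family", "sequence"),
      tibble::tibble(taxon = taxa$taxon, lineage = taxon_lineage(taxa)),
      by = "taxon"
    )

    structure(
      list(orfs = orfs, coverage = cov, references = references,
           scenario = scenario, seed = as.integer(seed)),
      class = "synthetic_metagenome"
    )
  })
}

#' @export
print.synthetic_metagenome <- function(x, ...) {
  cat(sprintf("<synthetic_metagenome> %d ORFs (%d SCG) x %d samples\n",
              nrow(x$orfs), sum(x$orfs$family %in% scg_family_names()),
              ncol(x$coverage)))
  invisible(x)
}

default_proteome_config <- function() {
  list(
    n_proteins = 500,
    peptides_per_protein = 4,   # mean; every protein gets at least 2
    shared_peptide_fraction = 0.05,
    length_mean = 300, length_sd = 80, length_min = 60,
    target_score_mean = 3.5, decoy_score_mean = 0, score_sd = 1,
    fraction_false = 0.1,       # spurious target identifications
    decoy_fraction = 0.5,       # decoy PSMs per target PSM
    fraction_enriched = 0.1, fold_change = 4,
    sigma_log2 = 0.5,           # replicate noise of log2 intensity
    intensity_scale = 1e6, count_scale = 60,
    missing_rate = 0.05,
    modified_fraction = 0.02,   # proteins with exclusively modified evidence
    n_contaminants = 5, contaminant_ids = NULL
  )
}

#' Simulate a peptide-spectrum-match table
#'
#' Emulates the output of a database search over the synthetic community:
#' target PSMs with scores from the target distribution (spurious targets
#' score like decoys), reversed-peptide decoy PSMs, contaminant proteins,
#' proteins evidenced only by modified peptides, per-sample spectral counts
#' proportional to protein abundance times length, and log-normal intensities
#' carrying a configurable rhizosphere fold change for a subset of enriched
#' proteins. The returned truth set records which proteins are genuinely
#' present and which are enriched.
#'
#' @param scenario A `community_scenario`.
#' @param proteome_config Named list overriding entries of the default
#'   configuration (see Details in the vignette); `target_score_mean` must
#'   exceed `decoy_score_mean`, and contaminant ids must not collide with
#'   target ids.
#' @param seed Integer seed; defaults to one derived from the scenario seed.
#' @return An object of class `synthetic_psm_set`: `psms` (tibble: spectrum,
#'   peptide, proteins — `;`-separated, score, is_decoy, is_modified,
#'   is_contaminant, sample, spectral_count, intensity), `proteins`
#'   (metadata incl. taxon and length), `truth` (`present`, `enriched`),
#'   the effective `config`, `samples` and `seed`.
#' @export
simulate_psm_table <- function(scenario, proteome_config = list(),
                               seed = NULL) {
  stopifnot(inherits(scenario, "community_scenario"))
  cfg <- utils::modifyList(default_proteome_config(), proteome_config)
  if (cfg$target_score_mean <= cfg$decoy_score_mean)
    abort("`target_score_mean` must exceed `decoy_score_mean`.")
  if (cfg$fold_change <= 0) abort("`fold_change` must be positive.")
  seed <- seed %||% stage_seed(scenario$seed, "psm")

  with_seed(seed, {
    n <- cfg$n_proteins
    target_ids <- sprintf("P%05d", seq_len(n))
    cont_ids <- cfg$contaminant_ids %||%
      sprintf("CONT_%02d", seq_len(cfg$n_contaminants))
    if (length(intersect(target_ids, cont_ids)) > 0)
      abort("Contaminant ids overlap target protein ids.")

    mean_ab <- rowMeans(scenario$abundance)
    proteins <- tibble::tibble(
      protein = c(target_ids, cont_ids),
      taxon = c(sample(scenario$taxa$taxon, n, replace = TRUE,
                       prob = mean_ab),
                rep(NA_character_, length(cont_ids))),
      length = pmax(cfg$length_min,
                    round(rnorm(n + length(cont_ids),
                                cfg$length_mean, cfg$length_sd))),
      is_contaminant = c(rep(FALSE, n), rep(TRUE, length(cont_ids)))
    )
    proteins$present <- TRUE
    false_idx <- sample(n, round(cfg$fraction_false * n))
    proteins$present[false_idx] <- FALSE
    proteins$modified_only <- FALSE
    mod_pool <- which(proteins$present & !proteins$is_contaminant)
    mod_idx <- sample(mod_pool,
                      round(cfg$modified_fraction * length(mod_pool)))
    proteins$modified_only[mod_idx] <- TRUE
    proteins$enriched <- FALSE
    enr_pool <- which(proteins$present & !proteins$is_contaminant &
                        !proteins$modified_only)
    if (cfg$fold_change != 1) {
      enr_idx <- sample(enr_pool,
                        round(cfg$fraction_enriched * length(enr_pool)))
      proteins$enriched[enr_idx] <- TRUE
    }
    proteins$base_abundance <- rlnorm(nrow(proteins), 0, 1) *
      c(mean_ab[proteins$taxon[seq_len(n)]], rep(mean(mean_ab),
                                                 length(cont_ids)))

    # peptide assignment: >= 2 unique peptides per protein, a few shared
    k_pep <- 2 + rpois(nrow(proteins), max(cfg$peptides_per_protein - 2, 0))
    pep_protein <- rep(proteins$protein, k_pep)
    peptides <- random_peptides(length(pep_protein))
    dup <- duplicated(peptides)
    while (any(dup)) { # regenerate rare collisions
      peptides[dup] <- random_peptides(sum(dup))
      dup <- duplicated(peptides)
    }
    pep_tbl <- tibble::tibble(peptide = peptides, protein = pep_protein)
    n_shared <- round(cfg$shared_peptide_fraction * nrow(pep_tbl))
    if (n_shared > 0) {
      sh <- sample(nrow(pep_tbl), n_shared)
      extra <- tibble::tibble(
        peptide = pep_tbl$peptide[sh],
        protein = sample(proteins$protein, n_shared, replace = TRUE)
      )
      extra <- extra[extra$protein != pep_tbl$protein[sh], ]
      pep_tbl <- dplyr::bind_rows(pep_tbl, extra)
    }
    pep_map <- pep_tbl |>
      dplyr::group_by(.data$peptide) |>
      dplyr::summarise(proteins = paste(sort(unique(.data$protein)),
                                        collapse = ";"),
                       protein1 = dplyr::first(.data$protein),
                       .groups = "drop")

    samples <- scenario$samples
    pi <- match(pep_map$protein1, proteins$protein)

    rows <- tidyr::expand_grid(pep = seq_len(nrow(pep_map)),
                               s = seq_len(nrow(samples)))
    p <- pi[rows$pep]
    rhizo <- samples$compartment[rows$s] == "rhizosphere"
    q <- proteins$base_abundance[p] *
      rlnorm(nrow(rows), 0, cfg$sigma_log2 * log(2)) *
      ifelse(proteins$enriched[p] & rhizo, cfg$fold_change, 1)
    k_of_p <- k_pep[p]
    lam <- cfg$count_scale * q * proteins$length[p] / 300 / k_of_p
    cnt <- rpois(nrow(rows), lam)
    intensity <- cfg$intensity_scale * q * rlnorm(nrow(rows), 0, 0.2)
    intensity[runif(nrow(rows)) < cfg$missing_rate | cnt == 0] <- 0

    psms <- tibble::tibble(
      peptide = pep_map$peptide[rows$pep],
      proteins = pep_map$proteins[rows$pep],
      protein1 = pep_map$protein1[rows$pep],
      sample = samples$sample[rows$s],
      spectral_count = cnt,
      intensity = intensity
    )
    psms <- psms[psms$spectral_count > 0, ]

    # guarantee every present protein at least one PSM somewhere
    seen <- unique(psms$protein1)
    missing <- setdiff(proteins$protein[proteins$present], seen)
    if (length(missing) > 0) {
      mp <- match(missing, pep_map$protein1)
      mp <- mp[!is.na(mp)]
      if (length(mp) > 0) {
        rescue_int <- cfg$intensity_scale *
          proteins$base_abundance[match(pep_map$protein1[mp],
                                        proteins$protein)]
        psms <- dplyr::bind_rows(psms, tibble::tibble(
          peptide = pep_map$peptide[mp],
          proteins = pep_map$proteins[mp],
          protein1 = pep_map$protein1[mp],
          sample = samples$sample[1],
          spectral_count = 1L,
          intensity = rescue_int
        ))
      }
    }

    p <- match(psms$protein1, proteins$protein)
    correct <- proteins$present[p]
    psms$score <- ifelse(
      correct,
      rnorm(nrow(psms), cfg$target_score_mean, cfg$score_sd),
      rnorm(nrow(psms), cfg$decoy_score_mean, cfg$score_sd)
    )
    psms$is_decoy <- FALSE
    psms$is_contaminant <- proteins$is_contaminant[p]
    psms$is_modified <- proteins$modified_only[p] |
      runif(nrow(psms)) < 0.03
    psms$spectrum <- sprintf("scan_%06d", seq_len(nrow(psms)))

    # decoy PSMs: reversed peptides mapped to mirrored decoy proteins
    n_dec <- round(cfg$decoy_fraction * nrow(psms))
    if (n_dec > 0) {
      di <- sample(nrow(psms), n_dec)
      dec <- psms[di, ]
      dec$peptide <- reverse_peptide(dec$peptide)
      dec$proteins <- vapply(strsplit(dec$proteins, ";", fixed = TRUE),
                             function(x) paste0("DECOY_", x, collapse = ";"),
                             character(1))
      dec$protein1 <- paste0("DECOY_", dec$protein1)
      dec$score <- rnorm(n_dec, cfg$decoy_score_mean, cfg$score_sd)
      dec$is_decoy <- TRUE
      dec$is_contaminant <- FALSE
      dec$spectral_count <- 1L
      dec$spectrum <- sprintf("scan_%06d", nrow(psms) + seq_len(n_dec))
      psms <- dplyr::bind_rows(psms, dec)
    }

    psms <- dplyr::select(
      psms, "spectrum", "peptide", "proteins", "score", "is_decoy",
      "is_modified", "is_contaminant", "sample", "spectral_count",
      "intensity"
    )

    structure(
      list(
        psms = psms,
        proteins = dplyr::select(proteins, -"base_abundance"),
        truth = list(
          present = proteins$protein[proteins$present &
                                       !proteins$is_contaminant],
          enriched = proteins$protein[proteins$enriched]
        ),
        samples = samples,
        config = cfg,
        seed = as.integer(seed)
      ),
      class = "synthetic_psm_set"
    )
  })
}

#' @export
print.synthetic_psm_set <- function(x, ...) {
  cat(sprintf(
    "<synthetic_psm_set> %d PSMs (%d decoy) over %d proteins, %d samples\n",
    nrow(x$psms), sum(x$psms$is_decoy), nrow(x$proteins), nrow(x$samples)
  ))
  invisible(x)
}

#' Simulate marker-gene scores and reference hits
#'
#' For every marker-family ORF in a synthetic metagenome, emits profile
#' scores against each marker family (high for the ORF's true family, low
#' otherwise), plus a table of reference hits with e-values whose best hit
#' points back to the generating taxon. A small fraction of ORFs receive
#' only weak hits and are expected to be removed by the e-value cutoff
#' downstream. A sample of accessory ORFs is included with background scores.
#'
#' @param metagenome A `synthetic_metagenome` built with a `marker_config`.
#' @param config Optional list: `true_score_mean` (150), `false_score_mean`
#'   (40), `score_sd` (12), `threshold` (100), `weak_hit_fraction` (0.02),
#'   `n_background` (50).
#' @param seed Integer seed; defaults to one derived from the metagenome seed.
#' @return A list with `scores` (tibble: orf, family, score), `hits`
#'   (tibble: orf, reference, taxon, evalue) and `thresholds` (named vector).
#' @export
simulate_marker_evidence <- function(metagenome, config = list(),
                                     seed = NULL) {
  stopifnot(inherits(metagenome, "synthetic_metagenome"))
  cfg <- utils::modifyList(
    list(true_score_mean = 150, false_score_mean = 40, score_sd = 12,
         threshold = 100, weak_hit_fraction = 0.02, n_background = 50),
    config
  )
  fams <- setdiff(unique(metagenome$orfs$family),
                  c(scg_family_names(), "other"))
  if (length(fams) == 0)
    abort("Metagenome has no marker-family ORFs; build it with `marker_config`.")
  fams <- sort(fams)
  seed <- seed %||% stage_seed(metagenome$seed, "marker")

  with_seed(seed, {
    mk <- metagenome$orfs[metagenome$orfs$family %in% fams, ]
    bg_pool <- metagenome$orfs$orf[metagenome$orfs$family == "other"]
    bg <- utils::head(bg_pool, cfg$n_background)
    scores <- tidyr::expand_grid(orf = c(mk$orf, bg), family = fams)
    true_fam <- mk$family[match(scores$orf, mk$orf)]
    is_true <- !is.na(true_fam) & true_fam == scores$family
    scores$score <- ifelse(
      is_true,
      rnorm(nrow(scores), cfg$true_score_mean, cfg$score_sd),
      rnorm(nrow(scores), cfg$false_score_mean, cfg$score_sd)
    )

    refs <- metagenome$references
    weak <- runif(nrow(mk)) < cfg$weak_hit_fraction
    best_ref <- sprintf("ref_%s_%s", mk$taxon, mk$family)
    other_taxon <- vapply(mk$taxon, function(t) {
      sample(setdiff(metagenome$scenario$taxa$taxon, t), 1)
    }, character(1))
    second_ref <- sprintf("ref_%s_%s", other_taxon, mk$family)
    hits <- dplyr::bind_rows(
      tibble::tibble(
        orf = mk$orf, reference = best_ref, taxon = mk$taxon,
        evalue = 10^ifelse(weak, runif(nrow(mk), -15, -5),
                           runif(nrow(mk), -60, -25))
      ),
      tibble::tibble(
        orf = mk$orf, reference = second_ref, taxon = other_taxon,
        evalue = 10^runif(nrow(mk), -18, -5)
      )
    )
    hits <- hits[hits$reference %in% refs$reference, ]
    list(
      scores = scores,
      hits = hits,
      thresholds = setNames(rep(cfg$threshold, length(fams)), fams)
    )
  })
}
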