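# required columns and types per table kind; extra columns pass through
TABLE_SCHEMAS <- list(
  psm = c(spectrum = "character", peptide = "character",
          proteins = "character", score = "numeric", is_decoy = "logical",
          is_modified = "logical", is_contaminant = "logical",
          sample = "character", spectral_count = "numeric",
          intensity = "numeric"),
  coverage = c(orf = "character", sample = "character",
               coverage = "numeric"),
  lineages = c(taxon = "character", domain = "character",
               phylum = "character", class = "character",
               order = "character", family = "character",
               genus = "character", species = "character"),
  catalog = c(orf = "character", family = "character",
              cluster = "character", lineage = "character"),
  scores = c(orf = "character", family = "character", score = "numeric"),
  hits = c(orf = "character", reference = "character",
           taxon = "character", evalue = "numeric"),
  meta = c(sample = "character", compartment = "character"),
  clusters = c(cluster = "numeric", representative = "character",
               member = "character", identity = "numeric"),
  groups = c(group = "character", representative = "character",
             members = "character", n_proteins = "numeric",
             n_unique = "numeric", best_score = "numeric",
             qvalue = "numeric"),
  abundance = c(protein = "character", sample = "character"),
  profile = c(taxon = "character", sample = "character",
              abundance = "numeric"),
  enrichment = c(protein = "character", log2_fc = "numeric",
                 p.value = "numeric", q.value = "numeric",
                 enriched_in = "character"),
  stats = c(test = "character", metric = "character", value = "numeric")
)

#' Read a protein FASTA file
#'
#' Parses an amino-acid FASTA file with [Biostrings::readAAStringSet()]
#' after validating the raw text: duplicate ids and empty records are
#' rejected with the offending line numbers. Wrapped sequence lines are
#' joined and residues upper-cased; the id is the first whitespace-delimited
#' token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort("Not a FASTA file: no '>' headers found.")
  ids <- sub("^>(\\S*).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("Duplicate FASTA id '%s' (lines %s).", dup,
                  paste(hdr[ids == dup], collapse = ", ")))
  }
  ends <- c(hdr[-1] - 1, length(lines))
  widths <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < hdr[i] + 1) 0L
    else sum(nchar(gsub("\\s", "", lines[(hdr[i] + 1):ends[i]])))
  }, integer(1))
  if (any(widths == 0))
    abort(sprintf("Empty FASTA record(s) at line(s): %s.",
                  paste(hdr[widths == 0], collapse = ", ")))
  ss <- Biostrings::readAAStringSet(path)
  seqs <- unname(toupper(as.character(ss)))
  tibble::tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) abort("Sequence ids must be unique.")
  ss <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Read a typed pipeline table
#'
#' Reads a TSV table (header comments starting with `#` are skipped),
#' checks that every column required by the schema is present, and coerces
#' columns to their declared types, reporting the first offending row on
#' failure. Unknown columns are preserved as character.
#'
#' @param path Path to a TSV file.
#' @param schema Table kind: one of psm, coverage, lineages, catalog,
#'   scores, hits, meta, clusters, groups, abundance, profile, enrichment,
#'   stats.
#' @return A tibble.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(TABLE_SCHEMAS))
    abort(paste0("Unknown schema `", schema, "`."))
  if (!file.exists(path)) abort(paste("No such file:", path))
  spec <- TABLE_SCHEMAS[[schema]]
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing <- setdiff(names(spec), names(d))
  if (length(missing) > 0)
    abort(sprintf("Table '%s' is missing required column(s): %s.",
                  basename(path), paste(missing, collapse = ", ")))
  for (col in names(spec)) {
    type <- spec[[col]]
    raw <- d[[col]]
    if (type == "numeric") {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
      if (length(bad) > 0)
        abort(sprintf("Non-numeric value '%s' in column `%s`, row %d.",
                      raw[bad[1]], col, bad[1]))
      d[[col]] <- val
    } else if (type == "logical") {
      val <- as.logical(raw)
      bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
      if (length(bad) > 0)
        abort(sprintf("Non-logical value '%s' in column `%s`, row %d.",
                      raw[bad[1]], col, bad[1]))
      d[[col]] <- val
    }
  }
  d
}

#' Write a pipeline table with provenance header comments
#'
#' List columns are collapsed with `;`. Provenance (seed, config hash,
#' stage) is embedded as `# key: value` comment lines above the header.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list written as header comments.
#' @return The path, invisibly.
#' @export
write_table <- function(x, path, meta = list()) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]]))
      x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ";")
  }
  con <- file(path, "w")
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  close(con)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: the synthetic scenario
#' (taxa, samples per compartment, coverage depth, compartment effects),
#' clustering identities, the two FDR tiers, enrichment thresholds, the
#' profiling rank and the permutation count. All randomness derives from
#' the single `seed`.
#'
#' @param seed Master seed (integer).
#' @param n_taxa,n_samples,depth,orfs_per_megabase Scenario size.
#' @param effect_config,proteome_config,marker_config Passed to the
#'   generators (see [simulate_community()], [simulate_psm_table()],
#'   [simulate_metagenome()]).
#' @param db_identity,scg_identity,min_short_coverage Clustering settings.
#' @param pep_fdr,prot_fdr,min_unique Inference settings.
#' @param fc_rhizo,fc_bulk,alpha,min_obs Enrichment settings.
#' @param rank Profiling rank.
#' @param n_perm Permutations for ANOSIM/PERMANOVA.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 17, n_taxa = 10, n_samples = 6, depth = 80,
                       orfs_per_megabase = 3, effect_config = list(),
                       proteome_config = list(n_proteins = 300,
                                              fraction_enriched = 0.15,
                                              fold_change = 4),
                       marker_config = list(prevalence = 0.6),
                       db_identity = 0.9, scg_identity = 0.95,
                       min_short_coverage = 0.8,
                       pep_fdr = 0.05, prot_fdr = 0.10, min_unique = 2,
                       fc_rhizo = 2, fc_bulk = 1.5, alpha = 0.05,
                       min_obs = 2, rank = "order", n_perm = 999) {
  cfg <- list(
    seed = as.integer(seed), n_taxa = n_taxa, n_samples = n_samples,
    depth = depth, orfs_per_megabase = orfs_per_megabase,
    effect_config = effect_config, proteome_config = proteome_config,
    marker_config = marker_config, db_identity = db_identity,
    scg_identity = scg_identity, min_short_coverage = min_short_coverage,
    pep_fdr = pep_fdr, prot_fdr = prot_fdr, min_unique = min_unique,
    fc_rhizo = fc_rhizo, fc_bulk = fc_bulk, alpha = alpha,
    min_obs = min_obs, rank = rank, n_perm = n_perm
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A configuration list.
#' @export
validate_run_config <- function(config) {
  check01 <- function(x, name, open_low = TRUE) {
    lo_ok <- if (open_low) x > 0 else x >= 0
    if (!is.numeric(x) || !lo_ok || x > 1)
      abort(sprintf("`%s` must be in (0, 1]; got %s.", name,
                    format(x)))
  }
  check01(config$db_identity, "db_identity")
  check01(config$scg_identity, "scg_identity")
  check01(config$min_short_coverage, "min_short_coverage")
  check01(config$pep_fdr, "pep_fdr")
  check01(config$prot_fdr, "prot_fdr")
  check01(config$alpha, "alpha")
  if (config$n_taxa < 2) abort("`n_taxa` must be at least 2.")
  if (config$n_samples < 2) abort("`n_samples` must be at least 2.")
  if (config$depth <= 0) abort("`depth` must be positive.")
  if (config$n_perm < 1) abort("`n_perm` must be at least 1.")
  if (!config$rank %in% LINEAGE_RANKS)
    abort(paste0("Unknown rank `", config$rank, "`."))
  invisible(config)
}

#' Aggregate PSM evidence to protein groups for quantification
#'
#' Sums spectral counts and intensities of each group's peptides per sample
#' (decoy PSMs excluded), keyed to the group's representative protein, and
#' joins protein lengths; the result feeds straight into [nsaf()] and
#' [lfq_normalize()]. Protein-sample pairs without evidence are filled with
#' zeros.
#'
#' @param groups A `protein_groups` tibble from [infer_protein_groups()].
#' @param psms The PSM tibble the groups were inferred from.
#' @param protein_lengths A data frame with columns `protein` and `length`.
#' @return A tibble `protein`, `sample`, `spectral_count`, `intensity`,
#'   `length`.
#' @export
quantify_groups <- function(groups, psms, protein_lengths) {
  stopifnot(is.data.frame(groups), is.data.frame(psms))
  pep_of_group <- tibble::tibble(
    representative = rep(groups$representative, lengths(groups$peptides)),
    peptide = unlist(groups$peptides, use.names = FALSE)
  )
  q <- psms |>
    dplyr::filter(!.data$is_decoy) |>
    dplyr::inner_join(pep_of_group, by = "peptide",
                      relationship = "many-to-many") |>
    dplyr::group_by(protein = .data$representative, .data$sample) |>
    dplyr::summarise(spectral_count = sum(.data$spectral_count),
                     intensity = sum(.data$intensity), .groups = "drop")
  q |>
    dplyr::left_join(protein_lengths, by = "protein") |>
    tidyr::complete(protein = unique(q$protein),
                    sample = unique(psms$sample),
                    fill = list(spectral_count = 0, intensity = 0)) |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(length = max(.data$length, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Run the full synthetic metaexoproteomics pipeline
#'
#' Executes every stage in order — simulate, cluster, infer, quantify,
#' enrich, SCG profile, marker profile, community statistics — writing each
#' stage's tables (with seed and config-hash provenance comments) into
#' `out_dir`. Rerunning with an identical configuration reproduces
#' identical outputs. Any stage failure halts the run naming the stage.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`scenario`,
#'   `metagenome`, `psm_set`, `clusters`, `groups`, `nsaf`, `lfq`,
#'   `enrichment`, `catalog`, `profile`, `marker_abundance`, `stats`) and
#'   `paths` of the written tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  if (missing(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(unclass(config))
  prov <- function(stage) list(stage = stage, seed = config$seed,
                               config_hash = hash)
  paths <- list()
  emit <- function(x, name, stage) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_table(x, p, prov(stage))
    paths[[name]] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- simulate ------------------------------------------------------------
  res <- stage("simulate", {
    scenario <- simulate_community(
      config$n_taxa, config$n_samples, depth = config$depth,
      effect_config = config$effect_config, seed = config$seed
    )
    mg <- simulate_metagenome(scenario, config$orfs_per_megabase,
                              marker_config = config$marker_config)
    psm_set <- simulate_psm_table(scenario, config$proteome_config)
    marker_ev <- simulate_marker_evidence(mg)
    list(scenario = scenario, mg = mg, psm_set = psm_set,
         marker_ev = marker_ev)
  })
  scenario <- res$scenario; mg <- res$mg
  psm_set <- res$psm_set; marker_ev <- res$marker_ev

  stage("simulate", {
    emit(scenario$samples, "meta", "simulate")
    emit(scenario$taxa, "lineages", "simulate")
    emit(psm_set$psms, "psm", "simulate")
    cov_long <- tibble::tibble(
      orf = rep(rownames(mg$coverage), ncol(mg$coverage)),
      sample = rep(colnames(mg$coverage), each = nrow(mg$coverage)),
      coverage = as.vector(mg$coverage)
    )
    emit(cov_long, "coverage", "simulate")
    emit(marker_ev$scores, "scores", "simulate")
    emit(marker_ev$hits, "hits", "simulate")
    emit(tibble::tibble(
      protein = psm_set$proteins$protein,
      present = psm_set$proteins$present,
      enriched = psm_set$proteins$enriched
    ), "truth", "simulate")
    write_fasta(dplyr::select(mg$orfs, id = "orf", "sequence"),
                file.path(out_dir, "orfs.fasta"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  })

  # -- cluster: search-database reduction ----------------------------------
  clusters <- stage("cluster", {
    cl <- greedy_cluster(
      dplyr::select(mg$orfs, id = "orf", "sequence"),
      identity_threshold = config$db_identity,
      min_short_coverage = config$min_short_coverage
    )
    emit(cl, "clusters", "cluster")
    cl
  })

  # -- infer ---------------------------------------------------------------
  groups <- stage("infer", {
    g <- infer_protein_groups(
      psm_set, pep_fdr = config$pep_fdr, prot_fdr = config$prot_fdr,
      min_unique = config$min_unique
    )
    emit(dplyr::select(g, "group", "representative", "members",
                       "n_proteins", "peptides", "n_unique", "best_score",
                       "qvalue"), "groups", "infer")
    emit(attr(g, "audit"), "audit", "infer")
    g
  })

  # -- quant ---------------------------------------------------------------
  quant <- stage("quant", {
    lens <- dplyr::select(psm_set$proteins, "protein", "length")
    gq <- quantify_groups(groups, psm_set$psms, lens)
    ns <- nsaf(gq)
    lf <- lfq_normalize(gq)
    emit(ns, "abundance_nsaf", "quant")
    emit(lf, "abundance_lfq", "quant")
    list(gq = gq, nsaf = ns, lfq = lf)
  })

  # -- enrich --------------------------------------------------------------
  enrichment <- stage("enrich", {
    e <- differential_enrichment(
      quant$lfq, scenario$samples, fc_rhizo = config$fc_rhizo,
      fc_bulk = config$fc_bulk, alpha = config$alpha,
      min_obs = config$min_obs
    )
    emit(e, "enrichment", "enrich")
    e
  })

  # -- scg-profile ---------------------------------------------------------
  prof_res <- stage("scg-profile", {
    catalog <- build_scg_catalog(
      mg, identity_threshold = config$scg_identity,
      min_short_coverage = config$min_short_coverage
    )
    emit(catalog, "catalog", "scg-profile")
    p <- scg_taxon_profile(mg$coverage, catalog, rank = config$rank)
    rel <- normalize_profile(p)
    emit(rel, "profile", "scg-profile")
    list(catalog = catalog, rel = rel)
  })
  catalog <- prof_res$catalog
  prof <- prof_res$rel

  # -- marker-profile ------------------------------------------------------
  marker_abundance <- stage("marker-profile", {
    cls <- classify_markers(marker_ev$scores, marker_ev$thresholds)
    cls <- cls[!is.na(cls$family), ]
    tax <- assign_marker_taxonomy(marker_ev$hits)
    mk <- dplyr::inner_join(
      dplyr::select(cls, "orf", "family"),
      dplyr::select(tax, "orf", "taxon"), by = "orf"
    )
    cov_mk <- tibble::tibble(
      orf = rep(rownames(mg$coverage), ncol(mg$coverage)),
      sample = rep(colnames(mg$coverage), each = nrow(mg$coverage)),
      coverage = as.vector(mg$coverage)
    ) |>
      dplyr::inner_join(mk, by = "orf")
    ma <- marker_relative_abundance(cov_mk, scg_normalizers(prof))
    emit(ma, "marker_abundance", "marker-profile")
    ma
  })

  # -- stats ---------------------------------------------------------------
  stats_tbl <- stage("stats", {
    sseed <- stage_seed(config$seed, "stats")
    d_prot <- bray_curtis(quant$nsaf)
    comp_prot <- scenario$samples$compartment[
      match(labels(d_prot), scenario$samples$sample)]
    d_mg <- bray_curtis(tibble::as_tibble(prof), feature = "taxon",
                        value = "abundance")
    comp_mg <- scenario$samples$compartment[
      match(labels(d_mg), scenario$samples$sample)]
    an_p <- anosim(d_prot, comp_prot, n_perm = config$n_perm, seed = sseed)
    pm_p <- permanova(d_prot, comp_prot, n_perm = config$n_perm,
                      seed = sseed + 1)
    an_m <- anosim(d_mg, comp_mg, n_perm = config$n_perm, seed = sseed + 2)
    pm_m <- permanova(d_mg, comp_mg, n_perm = config$n_perm,
                      seed = sseed + 3)
    st <- dplyr::bind_rows(
      tibble::tibble(test = "protein_anosim",
                     metric = c("R", "p"),
                     value = c(an_p$statistic, an_p$p.value)),
      tibble::tibble(test = "protein_permanova",
                     metric = c("pseudo_F", "R2", "p"),
                     value = c(pm_p$statistic, pm_p$R2, pm_p$p.value)),
      tibble::tibble(test = "metagenome_anosim",
                     metric = c("R", "p"),
                     value = c(an_m$statistic, an_m$p.value)),
      tibble::tibble(test = "metagenome_permanova",
                     metric = c("pseudo_F", "R2", "p"),
                     value = c(pm_m$statistic, pm_m$R2, pm_m$p.value))
    )
    emit(st, "stats", "stats")
    st
  })

  invisible(list(
    scenario = scenario, metagenome = mg, psm_set = psm_set,
    clusters = clusters, groups = groups, nsaf = quant$nsaf,
    lfq = quant$lfq, enrichment = enrichment, catalog = catalog,
    profile = prof, marker_abundance = marker_abundance,
    stats = stats_tbl, paths = paths, config = config,
    config_hash = hash
  ))
}
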