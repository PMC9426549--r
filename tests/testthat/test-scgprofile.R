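toy_catalog <- function(n_taxa, families, coverage_value = 10) {
  # one ORF per taxon per family, lineage distinct at every rank
  orfs <- tidyr::expand_grid(
    t = seq_len(n_taxa), family = families
  )
  orfs$orf <- sprintf("o%04d", seq_len(nrow(orfs)))
  orfs$lineage <- sprintf(
    "Bacteria;P%d;C%d;O%d;F%d;G%d;S%d", orfs$t, orfs$t, orfs$t,
    orfs$t, orfs$t, orfs$t
  )
  tibble::tibble(orf = orfs$orf, family = orfs$family,
                 cluster = paste0(orfs$family, "_c", orfs$t),
                 lineage = orfs$lineage)
}

test_that("nearest-reference assignment recovers identity and ties", {
  refs <- tibble::tibble(
    reference = c("refB", "refA"),
    sequence = c(strrep("ACDEFGHIKLMNPQRSTVWY", 10),
                 strrep("YWVTSRQPNMLKIHGFEDCA", 10)),
    taxon = c("tB", "tA")
  )
  reps <- tibble::tibble(id = "x", sequence = refs$sequence[1])
  out <- assign_nearest_reference(reps, refs)
  expect_equal(out$reference, "refB")
  expect_equal(out$distance, 0)
  expect_equal(out$taxon, "tB")

  # exact tie: identical references, lexicographically first id wins
  tierefs <- tibble::tibble(
    reference = c("zeta", "alpha"),
    sequence = rep(refs$sequence[1], 2)
  )
  expect_equal(assign_nearest_reference(reps, tierefs)$reference, "alpha")

  expect_error(
    assign_nearest_reference(reps, tierefs[0, ]),
    "empty"
  )
})

test_that("mutated representatives are assigned back to their source", {
  set.seed(10)
  n_ref <- 10
  refs <- tibble::tibble(
    reference = sprintf("r%02d", seq_len(n_ref)),
    sequence = exoprofiler:::random_aa_strings(n_ref, c(200, 250))
  )
  hits <- 0
  trials <- 200
  for (i in seq_len(trials)) {
    src <- sample(n_ref, 1)
    mut <- exoprofiler:::mutate_seqs(refs$sequence[src], rate = 0.05)
    out <- assign_nearest_reference(
      tibble::tibble(id = "q", sequence = mut), refs
    )
    hits <- hits + (out$reference == refs$reference[src])
  }
  expect_gte(hits / trials, 0.95)
})

test_that("taxon profile takes medians over detected families", {
  fams <- sprintf("SCG-%d", 1:36)
  cat1 <- toy_catalog(1, fams)
  cov1 <- tibble::tibble(orf = cat1$orf, sample = "s1", coverage = 10)
  p <- scg_taxon_profile(cov1, cat1, rank = "species")
  expect_equal(p$abundance, 10)

  # a single repeat-inflated family does not move the median
  cov2 <- cov1
  cov2$coverage[cov2$orf == cat1$orf[cat1$family == "SCG-7"]] <- 1000
  p2 <- scg_taxon_profile(cov2, cat1, rank = "species")
  expect_equal(p2$abundance, 10)

  expect_error(scg_taxon_profile(cov1, cat1, rank = "tribe"), "Unknown rank")
  expect_error(scg_taxon_profile(cov1[-1, ], cat1, rank = "order"),
               "missing")
})

test_that("profile medians equal a brute-force recomputation", {
  set.seed(40)
  fams <- sprintf("SCG-%d", 1:36)
  cat3 <- toy_catalog(5, fams)
  cov <- tidyr::expand_grid(orf = cat3$orf, sample = c("s1", "s2"))
  cov$coverage <- rpois(nrow(cov), 12)
  p <- scg_taxon_profile(cov, cat3, rank = "genus")

  joined <- dplyr::inner_join(cov, cat3, by = "orf")
  joined$taxon <- vapply(strsplit(joined$lineage, ";"),
                         function(x) paste(x[1:6], collapse = ";"),
                         character(1))
  for (i in seq_len(nrow(p))) {
    v <- joined$coverage[joined$taxon == p$taxon[i] &
                           joined$sample == p$sample[i]]
    sums <- tapply(v, joined$family[joined$taxon == p$taxon[i] &
                                      joined$sample == p$sample[i]], sum)
    expect_equal(p$abundance[i], median(sums[sums > 0]))
  }
})

test_that("normalization divides by the median family total", {
  fams <- sprintf("SCG-%d", 1:36)
  cat2 <- toy_catalog(2, fams)
  cov <- tibble::tibble(orf = cat2$orf, sample = "s1", coverage = 10)
  p <- scg_taxon_profile(cov, cat2, rank = "species")
  rel <- normalize_profile(p)
  # each family totals 20 across the two taxa, so N = 20 and each taxon 0.5
  expect_equal(scg_normalizers(rel)$normalizer, 20)
  expect_equal(rel$abundance, c(0.5, 0.5))

  # single-taxon community: relative abundance 1 at every rank
  cat1 <- toy_catalog(1, fams)
  cov1 <- tibble::tibble(orf = cat1$orf, sample = "s1",
                         coverage = rpois(36, 30) + 1)
  for (rk in c("phylum", "order", "species")) {
    r <- normalize_profile(scg_taxon_profile(cov1, cat1, rank = rk))
    expect_equal(nrow(r), 1)
    expect_equal(r$abundance, 1)
  }

  # doubling coverage leaves the relative profile unchanged
  cov2x <- cov
  cov2x$coverage <- cov2x$coverage * 2
  rel2 <- normalize_profile(scg_taxon_profile(cov2x, cat2,
                                              rank = "species"))
  expect_equal(rel2$abundance, rel$abundance)
})

test_that("profiles are insensitive to genome size", {
  # two taxa, equal cell abundance, 5x different genome size
  sc <- simulate_community(2, 3, depth = 100, seed = 60,
                           effect_config = list(sample_sigma = 0))
  sc$abundance[] <- 0.5
  sc$taxa$genome_size <- c(2e6, 1e7)
  mg <- simulate_metagenome(sc, orfs_per_megabase = 20, seed = 61)
  catl <- tibble::tibble(
    orf = mg$orfs$orf[mg$orfs$family != "other"],
    family = mg$orfs$family[mg$orfs$family != "other"],
    cluster = NA_character_,
    lineage = exoprofiler:::taxon_lineage(sc$taxa)[
      match(mg$orfs$taxon[mg$orfs$family != "other"], sc$taxa$taxon)]
  )
  rel <- normalize_profile(scg_taxon_profile(mg$coverage, catl,
                                             rank = "species"))
  w <- tidyr::pivot_wider(tibble::as_tibble(rel), names_from = sample,
                          values_from = abundance)
  vals <- as.matrix(w[, -1])
  # both taxa near 0.5 despite the size difference
  expect_lt(max(abs(vals - 0.5)), 0.15)
})

test_that("synthetic scenarios are recovered with high fidelity", {
  sc <- simulate_community(10, 3, depth = 80, seed = 71)
  mg <- simulate_metagenome(sc, orfs_per_megabase = 2)
  catl <- build_scg_catalog(mg)
  rel <- normalize_profile(scg_taxon_profile(mg$coverage, catl,
                                             rank = "species"))
  w <- tidyr::pivot_wider(tibble::as_tibble(rel), names_from = sample,
                          values_from = abundance)
  sp <- vapply(strsplit(w$taxon, ";"), function(x) x[7], character(1))
  truth <- sc$abundance[match(sp, sc$taxa$species), colnames(w)[-1]]
  est <- as.matrix(w[, -1])
  est[is.na(est)] <- 0
  cors <- vapply(seq_len(ncol(est)),
                 function(j) cor(est[, j], truth[, j]), double(1))
  expect_true(all(cors >= 0.95))
})
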