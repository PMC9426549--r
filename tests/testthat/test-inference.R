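test_that("peptide q-values follow the step-down target-decoy construction", {
  # enumeration over the four score thresholds: FDRs are 0, 0, 1/2, 1/3
  # and the running minimum gives targets (0, 0, 1/3)
  psms <- tibble::tibble(
    score = c(10, 9, 8, 8.5),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE)
  )
  q <- peptide_qvalues(psms)
  expect_equal(q$qvalue[1:3], c(0, 0, 1 / 3))

  # no decoys: all q are zero
  clean <- tibble::tibble(score = c(3, 2, 1), is_decoy = FALSE)
  expect_equal(peptide_qvalues(clean)$qvalue, c(0, 0, 0))

  # top-scoring decoy: FDR capped at 1 at the top threshold
  topdec <- tibble::tibble(score = c(5, 4), is_decoy = c(TRUE, FALSE))
  expect_equal(peptide_qvalues(topdec)$fdr[1], 1)

  # ties share a q-value
  tied <- tibble::tibble(score = c(5, 5, 4), is_decoy = c(FALSE, TRUE, FALSE))
  qt <- peptide_qvalues(tied)
  expect_equal(qt$qvalue[1], qt$qvalue[2])

  expect_error(peptide_qvalues(tibble::tibble(score = 1, is_decoy = TRUE)),
               "target")
})

test_that("q-values are monotone non-increasing in score", {
  set.seed(15)
  psms <- tibble::tibble(
    score = c(rnorm(500, 2), rnorm(500, 0)),
    is_decoy = rep(c(FALSE, TRUE), each = 500)
  )
  q <- peptide_qvalues(psms)
  ord <- order(q$score, decreasing = TRUE)
  expect_true(all(diff(q$qvalue[ord]) >= -1e-12))
  expect_true(all(q$qvalue <= 1))
})

test_that("protein grouping applies equality and subset-absorption rules", {
  eq <- tibble::tibble(
    peptide = c("A", "B", "A", "B"),
    protein = c("P1", "P1", "P2", "P2")
  )
  g <- group_proteins(eq)
  expect_equal(nrow(g), 1)
  expect_equal(g$members[[1]], c("P1", "P2"))

  sub <- tibble::tibble(
    peptide = c("A", "B", "C", "A"),
    protein = c("P1", "P1", "P1", "P2")
  )
  g2 <- group_proteins(sub)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$members[[1]], c("P1", "P2"))
  expect_equal(g2$n_unique, 3L)

  # shared peptide between two groups is unique to neither
  shared <- tibble::tibble(
    peptide = c("A", "B", "S", "C", "D", "S"),
    protein = c("P1", "P1", "P1", "P2", "P2", "P2")
  )
  g3 <- group_proteins(shared)
  expect_equal(nrow(g3), 2)
  expect_equal(sort(g3$n_unique), c(2L, 2L))

  expect_equal(nrow(group_proteins(tibble::tibble(peptide = character(),
                                                  protein = character()))), 0)
})

test_that("grouping matches the exhaustive parsimony oracle on random maps", {
  set.seed(23)
  for (i in 1:60) {
    pm <- random_peptide_map(sample(2:6, 1), sample(2:8, 1))
    expect_identical(groups_partition(group_proteins(pm)),
                     brute_force_group(pm))
  }
})

test_that("grouping is idempotent and order-independent", {
  set.seed(31)
  pm <- random_peptide_map(6, 8)
  a <- groups_partition(group_proteins(pm))
  b <- groups_partition(group_proteins(pm[sample(nrow(pm)), ]))
  expect_identical(a, b)
})

test_that("protein-group FDR mirrors the peptide construction", {
  g <- tibble::tibble(
    best_score = 10:1,
    is_decoy = c(rep(FALSE, 9), TRUE)
  )
  out <- protein_group_fdr(g)
  expect_equal(out$qvalue[1:9], rep(0, 9))
  expect_error(
    protein_group_fdr(tibble::tibble(best_score = 1, is_decoy = TRUE)),
    "target"
  )
})

test_that("evidence filters remove by rule and tally removals", {
  g <- tibble::tibble(
    group = sprintf("G%d", 1:5),
    n_unique = c(1, 2, 3, 2, 2),
    modified_only = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    is_contaminant = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    members = list("a", "b", "c", "d", "e")
  )
  out <- apply_evidence_filters(g)
  expect_equal(out$group, c("G2", "G5"))
  audit <- attr(out, "filter_audit")
  expect_equal(audit$n[audit$rule == "min_unique"], 1)
  expect_equal(audit$n[audit$rule == "contaminant"], 1)
  expect_equal(audit$n[audit$rule == "modified_only"], 1)
  # tallies sum to input minus output
  removed <- sum(audit$n[audit$rule %in%
                           c("contaminant", "modified_only", "min_unique")])
  expect_equal(removed, nrow(g) - nrow(out))

  # contaminants can also be matched by id through members
  out2 <- apply_evidence_filters(g[, setdiff(names(g), "is_contaminant")],
                                 contaminant_ids = "d")
  expect_false("G4" %in% out2$group)
})

test_that("representative selection is deterministic with documented tie-breaks", {
  mi <- tibble::tibble(protein = c("X", "Y"),
                       n_unique_peptides = c(3L, 2L),
                       aggregate_score = c(1, 100))
  expect_equal(select_representative(mi), "X")
  tie <- tibble::tibble(protein = c("B7", "A2"),
                        n_unique_peptides = c(2L, 2L),
                        aggregate_score = c(5, 5))
  expect_equal(select_representative(tie), "A2")
  score_tie <- tibble::tibble(protein = c("B", "A"),
                              n_unique_peptides = c(2L, 2L),
                              aggregate_score = c(9, 5))
  expect_equal(select_representative(score_tie), "B")
  single <- tibble::tibble(protein = "Z", n_unique_peptides = 1L)
  expect_equal(select_representative(single), "Z")
})

test_that("full inference keeps truly present proteins and drops decoys", {
  sc <- simulate_community(5, 3, seed = 19)
  ps <- simulate_psm_table(sc, list(n_proteins = 200), seed = 19)
  g <- infer_protein_groups(ps)
  reps <- g$representative
  expect_false(any(grepl("^DECOY_", unlist(g$members))))
  expect_true(all(g$n_unique >= 2))
  # representatives are overwhelmingly from the truly present set
  expect_gt(mean(reps %in% ps$truth$present), 0.95)
  audit <- attr(g, "audit")
  expect_true(all(c("peptide_fdr_rejected", "retained") %in% audit$rule))
})
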