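# Independent reference implementations used to validate the fast paths.

# Greedy clustering oracle: materializes the full pairwise identity /
# coverage tables via alignment_stats(), then applies the longest-first,
# first-fit rule in plain loops.
brute_force_cluster <- function(records, identity_threshold,
                                min_short_coverage = 0.8) {
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- toupper(records$sequence[ord])
  n <- length(ids)
  ident <- matrix(1, n, n)
  cov <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      st <- alignment_stats(seqs[i], seqs[j])
      ident[i, j] <- st$identity
      cov[i, j] <- st$coverage
    }
  }
  reps <- integer(0)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (ident[i, reps[k]] >= identity_threshold &&
          cov[i, reps[k]] >= min_short_coverage) {
        cluster[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  # return the partition as a canonical list of sorted member sets
  parts <- lapply(split(ids, cluster), sort)
  unname(parts[order(vapply(parts, min, character(1)))])
}

partition_of <- function(cluster_tbl) {
  parts <- lapply(split(cluster_tbl$member, cluster_tbl$cluster), sort)
  unname(parts[order(vapply(parts, min, character(1)))])
}

# Protein grouping oracle: exhaustive application of the two parsimony
# rules (identical sets merge; strict subsets are absorbed into the
# largest containing set, ties by smallest founder id).
brute_force_group <- function(peptide_map) {
  pm <- unique(peptide_map[, c("peptide", "protein")])
  sets <- lapply(split(pm$peptide, pm$protein), function(x) sort(unique(x)))
  prots <- names(sets)
  sig <- vapply(sets, paste, character(1), collapse = "\r")
  merged <- split(prots, sig)
  merged <- lapply(merged, sort)
  mset <- lapply(names(merged), function(s) sets[[merged[[s]][1]]])
  founder <- vapply(merged, `[`, character(1), 1)
  G <- length(mset)
  owner <- integer(G)
  for (i in seq_len(G)) {
    sup <- integer(0)
    for (j in seq_len(G)) {
      if (j != i && length(mset[[j]]) > length(mset[[i]]) &&
          all(mset[[i]] %in% mset[[j]]))
        sup <- c(sup, j)
    }
    if (length(sup) == 0) owner[i] <- i
    else {
      big <- sup[lengths(mset)[sup] == max(lengths(mset)[sup])]
      owner[i] <- big[order(founder[big])][1]
    }
  }
  groups <- lapply(sort(unique(owner)), function(o) {
    sort(unlist(merged[owner == o], use.names = FALSE))
  })
  unname(groups[order(vapply(groups, min, character(1)))])
}

groups_partition <- function(group_tbl) {
  parts <- lapply(group_tbl$members, sort)
  unname(parts[order(vapply(parts, min, character(1)))])
}

# random peptide-to-protein bipartite map with every peptide mapped
random_peptide_map <- function(n_prot, n_pep) {
  prots <- sprintf("P%d", seq_len(n_prot))
  peps <- sprintf("pep%d", seq_len(n_pep))
  rows <- do.call(rbind, lapply(peps, function(p) {
    k <- sample(n_prot, 1)
    data.frame(peptide = p, protein = sample(prots, k))
  }))
  tibble::as_tibble(rows)
}

# small random sequence catalogs for clustering tests: mixture of unrelated
# sequences and mutated copies so clusters of size > 1 occur
random_catalog <- function(n, len = 30, mutate_fraction = 0.5) {
  base <- exoprofiler:::random_aa_strings(n, c(len, len))
  seqs <- base
  idx <- which(runif(n) < mutate_fraction & seq_len(n) > 1)
  for (i in idx) {
    donor <- sample(i - 1, 1)
    seqs[i] <- exoprofiler:::mutate_seqs(seqs[donor], rate = 0.08)
  }
  tibble::tibble(id = sprintf("s%03d", seq_len(n)), sequence = seqs)
}
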