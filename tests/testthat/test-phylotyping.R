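test_that("distance corrections follow their definitions", {
  set.seed(51)
  a <- rand_aa(50)
  b <- mutated_at(a, 5)     # 90% identity -> p = 0.10
  c_ <- rand_aa(50)
  recs <- protein_records(c("a", "b", "c"), c(a, b, c_))
  d <- distance_matrix(recs, correction = "p")
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], 0.10)
  dp <- distance_matrix(recs, correction = "poisson")
  expect_equal(dp["a", "b"], -log(0.9))        # 0.10536
  expect_equal(dp["a", "b"], 0.10536, tolerance = 1e-4)
  expect_equal(d, t(d))
})

test_that("saturated Poisson distances are capped with a warning", {
  # AAAA vs WWWW: 0% identity -> p = 1
  recs <- protein_records(c("x", "y", "z"),
                          c(strrep("A", 20), strrep("W", 20),
                            strrep("C", 20)))
  expect_warning(dp <- distance_matrix(recs, correction = "poisson"),
                 "capped")
  expect_equal(dp["x", "y"], 10)
})

test_that("neighbor joining is exact on an additive matrix", {
  # tree ((A:1,B:2):1,C:3,D:4); path lengths give the additive matrix
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- build_tree(d)
  expect_s3_class(tr, "phylo")
  cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-9)        # additivity oracle
  # AB form a cherry
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  # non-symmetric input rejected
  bad <- d; bad[1, 2] <- 99
  expect_error(build_tree(bad), "symmetric")
})

test_that("three taxa give the unique unrooted topology", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
})

test_that("random additive matrices are reconstructed exactly", {
  set.seed(52)
  for (rep in 1:5) {
    tr0 <- ape::rtree(sample(5:9, 1))
    d0 <- ape::cophenetic.phylo(tr0)
    cd <- ape::cophenetic.phylo(build_tree(d0))[rownames(d0), colnames(d0)]
    expect_equal(cd, d0, tolerance = 1e-8)
  }
})

test_that("two planted clades are recovered exactly at k = 2", {
  set.seed(53)
  a <- rand_aa(60); b <- mutated_at(a, 40)
  seqs <- c(vapply(1:4, function(i) mutated_at(a, i), ""),
            vapply(1:4, function(i) mutated_at(b, i), ""))
  recs <- protein_records(paste0("s", 1:8), seqs)
  d <- distance_matrix(recs)
  asg <- cut_phylotypes(d, k = 2, min_cluster_size = 2)
  truth <- rep(c("cl1", "cl2"), each = 4)
  expect_equal(adjusted_rand_index(asg$labels[recs$id], truth), 1)
  expect_equal(asg$k, 2L)
  # partition: every id labeled exactly once
  expect_setequal(names(asg$labels), recs$id)
})

test_that("labels are stable under input permutation", {
  set.seed(54)
  a <- rand_aa(60); b <- mutated_at(a, 40)
  seqs <- c(vapply(1:3, function(i) mutated_at(a, i), ""),
            vapply(1:3, function(i) mutated_at(b, i), ""))
  recs <- protein_records(paste0("s", 1:6), seqs)
  d <- distance_matrix(recs)
  asg1 <- cut_phylotypes(d, k = 2)
  perm <- sample(6)
  asg2 <- cut_phylotypes(d[perm, perm], k = 2)
  expect_equal(asg1$labels[sort(names(asg1$labels))],
               asg2$labels[sort(names(asg2$labels))])
})

test_that("small clusters and incoherent sequences route to the outlier label", {
  set.seed(55)
  a <- rand_aa(60); b <- mutated_at(a, 40)
  seqs <- c(vapply(1:4, function(i) mutated_at(a, i), ""),
            vapply(1:4, function(i) mutated_at(b, i), ""),
            rand_aa(60))                      # a singleton oddball
  recs <- protein_records(paste0("s", 1:9), seqs)
  d <- distance_matrix(recs)
  asg <- cut_phylotypes(d, k = 3, min_cluster_size = 2)
  expect_equal(unname(asg$labels["s9"]), "T0")
  expect_equal(asg$k, 2L)
})

test_that("degenerate all-identical input is flagged", {
  recs <- protein_records(paste0("s", 1:4), rep(strrep("MKLV", 10), 4))
  d <- distance_matrix(recs)
  asg <- cut_phylotypes(d, k = 2)
  expect_true(asg$degenerate)
  expect_setequal(names(asg$labels), recs$id)
  expect_error(cut_phylotypes(d, k = 4), "smaller")
})

test_that("eight planted clades recover with ARI >= 0.90", {
  cfg <- sim_config(seed = 12, n_genera = 8, strains_per_genus = 5)
  ref <- generate_reference_set(cfg)
  fam <- ref$records[ref$records$id %in% ref$truth$id, ]
  d <- distance_matrix(fam)
  asg <- cut_phylotypes(d, k = 8)
  ari <- adjusted_rand_index(asg$labels[fam$id],
                             ref$truth$clade[match(fam$id, ref$truth$id)])
  expect_gte(ari, 0.90)
})

test_that("new sequences are assigned to their nearest phylotype", {
  set.seed(56)
  a <- rand_aa(60); b <- mutated_at(a, 40)
  refs <- protein_records(paste0("s", 1:6),
                          c(vapply(1:3, function(i) mutated_at(a, i), ""),
                            vapply(1:3, function(i) mutated_at(b, i), "")))
  d <- distance_matrix(refs)
  asg <- cut_phylotypes(d, k = 2)
  # identical to a classified sequence -> that label
  lab <- assign_phylotype(refs$sequence[1], asg, refs)
  expect_equal(as.character(lab), unname(asg$labels["s1"]))
  expect_equal(attr(lab, "distance"), 0)
  # far beyond the ceiling -> outlier
  far <- assign_phylotype(strrep("W", 60), asg, refs, ceiling = 0.5)
  expect_equal(as.character(far), "T0")
  # held-out clade members recover their clade label (>= 95%)
  held <- vapply(1:8, function(i) mutated_at(a, i), "")
  got <- vapply(held, function(s)
    as.character(assign_phylotype(s, asg, refs)), "")
  expect_gte(mean(got == unname(asg$labels["s1"])), 0.95)
})

test_that("phylotype census counts sequences, strains, and paralog spread", {
  labels <- setNames(c("T1", "T1", "T2", "T2", "T0"),
                     c("p1", "p2", "p3", "p4", "p5"))
  strain_of <- setNames(c("sA", "sA", "sB", "sC", "sC"),
                        names(labels))
  cen <- phylotype_census(labels, strain_of)
  tab <- cen$table
  expect_equal(tab$n_sequences[tab$phylotype == "T1"], 2L)
  expect_equal(tab$n_strains[tab$phylotype == "T1"], 1L)
  expect_equal(cen$total_sequences, 5L)
  # sA: both paralogs in T1 (same); sC: T2 + T0 (cross)
  expect_equal(unname(cen$paralog_strains),
               c(1L, 1L))
  # the published per-phylotype counts sum to 156
  counts <- c(27, 19, 6, 14, 23, 46, 14, 7)
  labels2 <- setNames(rep(paste0("T", c(1:7, 0)), counts),
                      sprintf("q%03d", seq_len(sum(counts))))
  expect_equal(phylotype_census(labels2)$total_sequences, 156L)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  set.seed(57)
  a <- sample(1:4, 400, replace = TRUE)
  b <- sample(1:4, 400, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
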