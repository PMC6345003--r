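test_that("catalog merges identical and 96%-identical proteins, splits 94%", {
  set.seed(41)
  base <- rand_aa(100)
  recs <- protein_records(
    c("a1", "a2", "b96", "c94", "solo"),
    c(base, base, mutated_at(base, 4), mutated_at(base, 6), rand_aa(100)))
  # constructed identities verified against the alignment contract
  expect_equal(pairwise_identity(base, mutated_at(base, 4),
                                 mode = "global")$pct_identity, 96)
  expect_equal(pairwise_identity(base, mutated_at(base, 6),
                                 mode = "global")$pct_identity, 94)
  cat <- build_nr_catalog(recs, min_identity = 95, min_overlap = 90)
  cl <- setNames(cat$clusters$representative, cat$clusters$member)
  expect_equal(cl[["a2"]], cl[["a1"]])
  expect_equal(cl[["b96"]], cl[["a1"]])     # 96% merges
  expect_false(cl[["c94"]] == cl[["a1"]])   # 94% founds its own cluster
  expect_false(cl[["solo"]] == cl[["a1"]])
  # every member in exactly one cluster; representatives are members
  expect_setequal(cat$clusters$member, recs$id)
  expect_true(all(names(cat$lengths) %in% cat$clusters$member))
})

test_that("mutually dissimilar proteins give singleton clusters", {
  set.seed(42)
  recs <- protein_records(paste0("r", 1:6),
                          vapply(1:6, function(i) rand_aa(80), ""))
  cat <- build_nr_catalog(recs)
  expect_equal(length(cat$lengths), 6L)
})

test_that("reads map to their source gene; foreign reads stay unmapped", {
  genes <- c(geneA = back_translate(rand_aa(40, seed = 43)),
             geneB = back_translate(rand_aa(40, seed = 44)))
  r1 <- substr(genes[["geneA"]], 10, 39)
  r2 <- substr(genes[["geneB"]], 50, 79)
  foreign <- paste(rep("ACGT", 8), collapse = "")
  res <- map_reads(c(r1, r2, foreign), genes)
  expect_equal(unname(res$counts), c(1L, 1L))
  expect_equal(res$unmapped, 1L)
  expect_error(map_reads("ACGU", genes), "malformed")
  expect_error(map_reads(r1, character(0)), "empty")
})

test_that("planted counts are recovered exactly from error-free reads", {
  cfg <- small_sim_config(seed = 7)
  ref <- generate_reference_set(cfg)
  mg <- generate_metagenomes(cfg, ref)
  counts <- map_reads(mg$reads[1:3], mg$gene_nt)
  expect_equal(unname(attr(counts, "unmapped")), rep(0, 3))
  # mapped counts equal the planted per-gene read counts
  expect_equal(counts[, colnames(mg$read_counts)],
               mg$read_counts[rownames(counts), ],
               ignore_attr = TRUE)
})

test_that("relative abundance implements the length-normalized formula", {
  # hand-computed densities: 10/100 = 0.1 vs 10/200 = 0.05 -> 2/3 and 1/3
  counts <- matrix(c(10, 10), 1, dimnames = list("s1", c("g1", "g2")))
  am <- relative_abundance(counts, c(g1 = 100, g2 = 200))
  expect_equal(unname(am$ra[1, ]), c(2, 1) / 3)
  # single positive gene -> RA 1
  am1 <- relative_abundance(c(g1 = 7), c(g1 = 321))
  expect_equal(unname(am1$ra[1, 1]), 1)
  # scale invariance
  am2 <- relative_abundance(counts * 17, c(g1 = 100, g2 = 200))
  expect_equal(am2$ra, am$ra, ignore_attr = TRUE)
  # zero-total samples are flagged, not zero-filled
  cz <- rbind(s1 = c(g1 = 5, g2 = 5), s2 = c(g1 = 0, g2 = 0))
  amz <- relative_abundance(cz, c(g1 = 100, g2 = 200))
  expect_equal(amz$excluded, "s2")
  expect_equal(amz$samples, "s1")
})

test_that("RA rows sum to 1 and preserve planted rank order", {
  cfg <- small_sim_config(seed = 8, coverage_per_gene = 50)
  ref <- generate_reference_set(cfg)
  mg <- generate_metagenomes(cfg, ref)
  counts <- map_reads(mg$reads, mg$gene_nt)
  lengths <- setNames(nchar(mg$gene_nt) / 3, names(mg$gene_nt))
  am <- relative_abundance(counts, lengths)
  expect_equal(unname(rowSums(am$ra)), rep(1, length(am$samples)),
               tolerance = 1e-9)
  # rank preservation at sequencing depth >= 50 reads per gene on average
  rho <- vapply(am$samples, function(s)
    cor(am$ra[s, ], mg$true_abundance[s, colnames(am$ra)],
        method = "spearman"), numeric(1))
  expect_true(all(rho >= 0.95))
})

test_that("detection applies the 62% rule", {
  set.seed(45)
  base <- rand_aa(100)
  reference <- protein_records(c("ref1", "ref2"),
                               c(base, rand_aa(100)))
  sample_genes <- protein_records(
    c("present", "at60"),
    c(base, mutated_at(base, 40)))     # 60% identity to ref1
  expect_equal(pairwise_identity(base, sample_genes$sequence[2],
                                 mode = "global")$pct_identity, 60)
  det <- detect_family_members(sample_genes, reference, mode = "global")
  expect_equal(det$detected, "ref1")
  expect_equal(det$pct_detected, 50)
  # the printed worked example: 156 of 591 -> 26.40
  expect_equal(detection_fraction(156, 591), 26.40)
})

test_that("per-sample detection mirrors planted presence", {
  cfg <- small_sim_config(seed = 9)
  ref <- generate_reference_set(cfg)
  fam <- ref$records[ref$records$id %in% ref$truth$id, ]
  # plant only genera 1-2 in the "population"; expect ~half detected
  planted <- fam[fam$genus %in% c("Genus01", "Genus02"), ]
  det <- detect_family_members(planted, fam)
  expect_setequal(det$detected, planted$id)
  expect_equal(det$pct_detected,
               detection_fraction(nrow(planted), nrow(fam)))
})

test_that("cumulative RA averages within populations and is additive", {
  ra <- rbind(s1 = c(gA = 0.06, gB = 0.04, gC = 0.9),
              s2 = c(gA = 0.24, gB = 0.06, gC = 0.7))
  am <- structure(list(ra = ra, counts = ra * 100,
                       samples = rownames(ra), genes = colnames(ra),
                       excluded = character(0)),
                  class = "abundance_matrix")
  meta <- data.frame(sample_id = c("s1", "s2"), population = "US")
  groups <- c(gA = "fam", gB = "fam", gC = "bg")
  cra <- cumulative_ra(am, meta, groups)
  fam_val <- cra$value[cra$group == "fam"]
  expect_equal(fam_val, mean(c(0.1, 0.3)))           # hand average
  # additivity: group values sum to the all-genes value
  all_val <- cumulative_ra(am, meta, "all")$value
  expect_equal(sum(cra$value), all_val)
  # sum aggregation selectable
  cras <- cumulative_ra(am, meta, groups, agg = "sum")
  expect_equal(cras$value[cras$group == "fam"], 0.4)
  # unlabeled gene errors with the offending id
  expect_error(cumulative_ra(am, meta, c(gA = "fam")), "gB")
  # zero-abundance group contributes 0
  groups0 <- c(gA = "none", gB = "none", gC = "bg")
  am0 <- am; am0$ra[, c("gA", "gB")] <- 0
  cra0 <- cumulative_ra(am0, meta, groups0)
  expect_equal(cra0$value[cra0$group == "none"], 0)
})
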