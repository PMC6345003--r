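test_that("healthy-set screening applies strict bounds and keeps missing", {
  meta <- data.frame(
    sample_id = paste0("s", 1:7),
    age = c(30, 12, 75, NA, 30, 30, 30),
    bmi = c(25, 25, 25, 25, 29.9, 18.5, NA),
    status = c("healthy", "healthy", "healthy", "healthy", "healthy",
               "healthy", "T2D"))
  sc <- screen_individuals(meta)
  expect_setequal(sc$retained$sample_id, c("s1", "s4"))
  expect_equal(sc$excluded$reason[sc$excluded$sample_id == "s2"], "age")
  expect_equal(sc$excluded$reason[sc$excluded$sample_id == "s5"], "bmi")
  expect_equal(sc$excluded$reason[sc$excluded$sample_id == "s7"], "disease")
})

test_that("Mann-Whitney matches enumeration at the pinned examples", {
  r <- mann_whitney_fdr(list(same = list(x = c(1, 2, 3), y = c(1, 2, 3)),
                             sep = list(x = c(1, 2, 3), y = c(4, 5, 6))))
  expect_equal(r$p_raw[r$factor == "same"], 1)
  expect_equal(r$p_raw[r$factor == "sep"], 0.1)  # 2/20 extreme orderings
  expect_error(mann_whitney_fdr(list(bad = list(x = numeric(0), y = 1))),
               "bad")
})

test_that("Mann-Whitney equals full permutation enumeration for n1+n2 <= 10", {
  set.seed(61)
  for (rep in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- if (rep %% 2) rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- bshprof:::mw_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_mw_p(x, y), info = paste("rep", rep))
  }
})

test_that("BH step-up matches the direct computation and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  set.seed(62)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # step-up monotonicity
    expect_true(all(q >= 0 & q <= 1))
  }
  # m = 1: q equals p
  expect_equal(bh_adjust(0.037), 0.037)
})

test_that("Spearman correlation hits the rank-formula value and the limits", {
  ph <- data.frame(population = paste0("P", 1:5),
                   ind = c(1, 3, 2, 5, 4))
  ra <- setNames(c(1, 2, 3, 4, 5), paste0("P", 1:5))
  r <- spearman_phenotype(ra, ph, "ind")
  expect_equal(r$statistic, 0.8)       # 1 - 6*4/(125-5)
  # monotone limits
  ph$up <- c(10, 20, 30, 40, 50)
  expect_equal(spearman_phenotype(ra, ph, "up")$statistic, 1)
  ph$down <- -ph$up
  expect_equal(spearman_phenotype(ra, ph, "down")$statistic, -1)
  expect_error(spearman_phenotype(ra[1:2], ph, "up"), "3 overlapping")
})

test_that("chi-squared presence test matches hand computations", {
  r <- chisq_presence(rbind(c(20, 10), c(10, 20)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  r2 <- chisq_presence(rbind(c(10, 0), c(0, 10)))
  expect_equal(r2$statistic, 20)
  r3 <- chisq_presence(rbind(c(5, 7), c(5, 7)))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_raw, 1)
  expect_error(chisq_presence(rbind(c(0, 0), c(5, 7))), "marginal")
  expect_error(chisq_presence(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("multivariable adjustment: pure population signal explains ~100%", {
  set.seed(63)
  d <- data.frame(population = rep(c("A", "B", "C"), each = 30),
                  gender = sample(c("m", "f"), 90, TRUE),
                  age = runif(90, 20, 70), bmi = runif(90, 18, 30))
  d$ra <- c(A = 0, B = 2, C = 5)[d$population]     # zero noise
  mv <- multivariable_adjust(d, response = "ra")
  ve <- setNames(mv$variance_explained, mv$factor)
  expect_gt(ve[["population"]], 99.99)
  expect_lt(max(ve[c("gender", "age", "bmi")]), 1)
  expect_true(all(mv$variance_explained >= 0 &
                    mv$variance_explained <= 100))
})

test_that("planted partial R2 of 35% is recovered within 5 points at n = 500", {
  co <- simulate_cohort_ra(500, r2_population = 0.35, seed = 64)
  mv <- multivariable_adjust(co, response = "ra")
  got <- mv$variance_explained[mv$factor == "population"]
  expect_gte(got, 30)
  expect_lte(got, 40)
})

test_that("null p values are near-uniform for the linear partial F test", {
  set.seed(65)
  rep_seeds <- sample.int(1e6, 120)   # pre-drawn: simulators re-seed the RNG
  ps <- vapply(rep_seeds, function(s) {
    d <- simulate_cohort_ra(60, populations = paste0("P", 1:4),
                            r2_population = 0, seed = s)
    mv <- multivariable_adjust(d, response = "ra")
    mv$p_raw[mv$factor == "population"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})

test_that("collinear factors are rejected with the aliased term named", {
  d <- data.frame(population = rep(c("A", "B"), each = 20),
                  gender = rep(c("m", "f"), each = 20),   # aliased
                  age = runif(40), bmi = runif(40), ra = rnorm(40))
  expect_error(multivariable_adjust(d, response = "ra"), "collinearity")
})

test_that("cohort comparison flags planted effects and controls type I error", {
  # planted effect: strong case/control fold change on T2
  sim <- simulate_case_control_ra(40, n_phylotypes = 4,
                                  effect = c(T2 = 6), seed = 66)
  res <- cohort_compare(sim$phylo_ra, sim$meta,
                        contrast = c("healthy", "disease"))
  expect_lt(res$q_fdr[res$factor == "T2"], 0.05)
  expect_equal(sort(res$factor), paste0("T", 1:4))
  # identical arms: no phylotype flagged in most replicates
  set.seed(67)
  rep_seeds <- sample.int(1e6, 60)
  flagged <- vapply(rep_seeds, function(sd_) {
    s <- simulate_case_control_ra(25, n_phylotypes = 4, seed = sd_)
    r <- cohort_compare(s$phylo_ra, s$meta,
                        contrast = c("healthy", "disease"))
    any(r$q_fdr < 0.05)
  }, logical(1))
  expect_lte(mean(flagged), 0.10)
  # zero-inflated phylotypes are routed to the chi-squared branch
  zi <- simulate_case_control_ra(40, n_phylotypes = 3,
                                 zero_inflation = 0.7, seed = 68)
  rz <- cohort_compare(zi$phylo_ra, zi$meta,
                       contrast = c("healthy", "disease"))
  expect_true(all(rz$test_name == "chisq"))
  expect_error(cohort_compare(zi$phylo_ra, zi$meta,
                              contrast = c("healthy", "ghost")), "ghost")
})
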