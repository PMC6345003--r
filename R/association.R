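# Cohort statistics: healthy-individual screening, Mann-Whitney with BH-FDR,
# Spearman phenotype correlation, chi-squared presence tests, and
# multivariable-adjusted linear models with per-factor variance explained.

#' Screen individuals for the healthy analysis set
#'
#' Strict-inequality bounds on BMI and age; records with a missing value pass
#' that criterion (cohorts lacking metadata stay in, matching how population
#' panels with absent covariates are handled); records whose status is not in
#' `healthy_labels` are excluded.
#'
#' @param meta data.frame with `sample_id`, `status`, and optional `age`,
#'   `bmi` columns (missing values as NA).
#' @param bmi_range,age_range open intervals (strict bounds).
#' @param healthy_labels status values considered healthy.
#' @return list: `retained` (subset of `meta`), `excluded` (subset with a
#'   `reason` column).
#' @export
screen_individuals <- function(meta, bmi_range = c(18.5, 29.9),
                               age_range = c(12, 75),
                               healthy_labels = "healthy") {
  reason <- rep(NA_character_, nrow(meta))
  bmi <- meta$bmi %||% rep(NA_real_, nrow(meta))
  age <- meta$age %||% rep(NA_real_, nrow(meta))
  bad_bmi <- !is.na(bmi) & !(bmi > bmi_range[1] & bmi < bmi_range[2])
  bad_age <- !is.na(age) & !(age > age_range[1] & age < age_range[2])
  bad_status <- !(meta$status %in% healthy_labels)
  reason[bad_status] <- "disease"
  reason[bad_age] <- "age"
  reason[bad_bmi] <- "bmi"
  keep <- is.na(reason)
  excluded <- meta[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = meta[keep, , drop = FALSE], excluded = excluded)
}

# Two-sided Mann-Whitney U test. Exact null by full enumeration of the
# choose(n, n1) group assignments whenever that count is <= max_enum (this
# covers both-groups-<=-8 and handles ties exactly); otherwise the normal
# approximation with tie correction and continuity correction.
mw_test <- function(x, y, max_enum = 20000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(all_v)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal"
  }
  list(statistic = u, p = p, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p values (one family).
#' @return q values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Mann-Whitney U tests with FDR correction across a family
#'
#' @param tests named list; each element a list/two-element list with `x` and
#'   `y` numeric group samples.
#' @return data.frame of class `association_result`: `factor`, `test_name`,
#'   `statistic` (U), `p_raw`, `q_fdr`.
#' @examples
#' mann_whitney_fdr(list(a = list(x = 1:3, y = 4:6)))
#' @export
mann_whitney_fdr <- function(tests) {
  stopifnot(is.list(tests), length(tests) > 0)
  res <- lapply(names(tests) %||% seq_along(tests), function(nm) {
    t <- tests[[nm]]
    if (length(t$x) == 0 || length(t$y) == 0)
      stop("empty group in comparison '", nm, "'")
    r <- mw_test(t$x, t$y)
    data.frame(factor = nm, test_name = "mannwhitney",
               statistic = r$statistic, p_raw = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_fdr <- bh_adjust(out$p_raw)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Spearman correlation of population family abundance with a phenotype
#'
#' Matches populations between the abundance vector and the phenotype table,
#' requires at least 3 overlapping populations, mid-ranks ties, and reports
#' Spearman's r with the t-approximation p (exact null when n <= 9 and no
#' ties).
#'
#' @param ra_by_population named numeric: population -> family abundance.
#' @param phenotype data.frame with a `population` column and indicator
#'   columns.
#' @param indicator name of the indicator column to correlate.
#' @return one-row `association_result` data.frame with `statistic` = r.
#' @export
spearman_phenotype <- function(ra_by_population, phenotype, indicator) {
  stopifnot(indicator %in% names(phenotype))
  common <- intersect(names(ra_by_population), phenotype$population)
  if (length(common) < 3)
    stop("need at least 3 overlapping populations (got ", length(common), ")")
  x <- ra_by_population[common]
  y <- phenotype[[indicator]][match(common, phenotype$population)]
  n <- length(common)
  exact <- n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  out <- data.frame(factor = indicator, test_name = "spearman",
                    statistic = unname(ct$estimate), p_raw = ct$p.value,
                    q_fdr = NA_real_, n_used = n, stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Pearson chi-squared test on a presence/absence table
#'
#' No continuity correction by default (selectable); degrees of freedom
#' (r-1)(c-1). Zero marginals make expected counts undefined and are
#' rejected.
#'
#' @param presence_table matrix of nonnegative integer counts (typically 2x2
#'   present/absent x group).
#' @param correct apply Yates continuity correction.
#' @return one-row `association_result` data.frame.
#' @export
chisq_presence <- function(presence_table, correct = FALSE) {
  tab <- as.matrix(presence_table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out <- data.frame(factor = "presence", test_name = "chisq",
                    statistic = unname(ct$statistic),
                    p_raw = ct$p.value, q_fdr = NA_real_,
                    df = unname(ct$parameter), stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Multivariable-adjusted analysis with per-factor variance explained
#'
#' Ordinary least squares of a per-individual response (family cumulative
#' RA) on gender, age, BMI and population, categorical factors dummy-coded.
#' Each factor's p comes from the partial F test (the factor added to the
#' model holding the remaining ones) and its variance explained is the
#' partial R-squared, (SSE_reduced - SSE_full) / SSE_reduced * 100.
#' Complete-case analysis per model; the dropped n is reported.
#'
#' @param data data.frame containing the response and the factors.
#' @param response response column name.
#' @param factors factor column names (character/factor columns are treated
#'   as categorical).
#' @return `association_result` data.frame, one row per factor, with
#'   `variance_explained` and `n_used`.
#' @export
multivariable_adjust <- function(data, response = "ra",
                                 factors = c("gender", "age", "bmi",
                                             "population")) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  d <- data[, c(response, factors)]
  d <- d[complete.cases(d), , drop = FALSE]
  for (f in factors)
    if (is.character(d[[f]])) d[[f]] <- factor(d[[f]])
  for (f in factors)
    if (is.factor(d[[f]]) && nlevels(droplevels(d[[f]])) < 2)
      stop("factor '", f, "' has fewer than 2 levels after complete cases")
  full_fml <- stats::reformulate(factors, response)
  full <- lm(full_fml, data = d)
  if (any(is.na(stats::coef(full)))) {
    aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("perfect collinearity; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(d) <= length(stats::coef(full)))
    stop("n must exceed the number of model parameters")
  sse_full <- sum(stats::residuals(full)^2)
  # degenerate (zero-noise) fits leave numerical dust in the SSEs; anything
  # below tol relative to the total sum of squares is treated as exactly 0
  tol <- 1e-10 * sum((d[[response]] - mean(d[[response]]))^2)
  if (sse_full <= tol) sse_full <- 0
  res <- lapply(factors, function(f) {
    reduced <- lm(stats::reformulate(setdiff(factors, f), response), data = d)
    sse_red <- sum(stats::residuals(reduced)^2)
    if (sse_red <= tol) sse_red <- 0
    df1 <- reduced$df.residual - full$df.residual
    fstat <- ((sse_red - sse_full) / df1) /
      max(sse_full / full$df.residual, .Machine$double.xmin)
    p <- pf(fstat, df1, full$df.residual, lower.tail = FALSE)
    ve <- if (sse_red == 0) 0 else 100 * (sse_red - sse_full) / sse_red
    data.frame(factor = f, test_name = "linear", statistic = fstat,
               p_raw = p, variance_explained = min(max(ve, 0), 100),
               n_used = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_fdr <- NA_real_
  class(out) <- c("association_result", "data.frame")
  out
}

#' Case-control comparison of phylotype abundances
#'
#' Per-individual per-phylotype cumulative RA is compared between the two
#' contrast arms. Phylotypes absent (zero RA) in more than
#' `absence_threshold` of all individuals are zero-inflated and routed to a
#' presence/absence chi-squared test; the rest form one Mann-Whitney family
#' with BH correction (mirroring the p^c / p^u split).
#'
#' @param phylo_ra individuals x phylotypes matrix of per-individual
#'   cumulative RA (rownames = sample ids).
#' @param meta data.frame with `sample_id` and `status`.
#' @param contrast length-2 character: c(control_status, case_status).
#' @param absence_threshold zero-inflation routing threshold.
#' @return `association_result` data.frame, one row per phylotype.
#' @export
cohort_compare <- function(phylo_ra, meta, contrast = c("healthy", "disease"),
                           absence_threshold = 0.5) {
  status <- meta$status[match(rownames(phylo_ra), meta$sample_id)]
  if (anyNA(status)) stop("samples missing from metadata")
  if (!all(contrast %in% status))
    stop("contrast label(s) missing from metadata: ",
         paste(setdiff(contrast, status), collapse = ", "))
  in_ctrl <- status == contrast[1]
  in_case <- status == contrast[2]
  absent_frac <- colMeans(phylo_ra[in_ctrl | in_case, , drop = FALSE] == 0)
  zi <- absent_frac > absence_threshold
  res <- list()
  mw_cols <- colnames(phylo_ra)[!zi]
  if (length(mw_cols)) {
    tests <- lapply(mw_cols, function(ph)
      list(x = phylo_ra[in_ctrl, ph], y = phylo_ra[in_case, ph]))
    names(tests) <- mw_cols
    res$mw <- mann_whitney_fdr(tests)
  }
  chi_cols <- colnames(phylo_ra)[zi]
  if (length(chi_cols)) {
    chi <- lapply(chi_cols, function(ph) {
      tab <- rbind(control = c(present = sum(phylo_ra[in_ctrl, ph] > 0),
                               absent = sum(phylo_ra[in_ctrl, ph] == 0)),
                   case = c(present = sum(phylo_ra[in_case, ph] > 0),
                            absent = sum(phylo_ra[in_case, ph] == 0)))
      r <- chisq_presence(tab)
      r$factor <- ph
      r$df <- NULL
      r
    })
    chi <- do.call(rbind, chi)
    chi$q_fdr <- bh_adjust(chi$p_raw)
    res$chi <- chi
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}
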