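# Synthetic-data generator: genus-structured protein families with
# controlled identity structure, per-strain paralog counts, per-individual
# metagenome read sets with planted gene abundances, cohort metadata with a
# plantable population effect, and country-level phenotype tables.
#
# The generative model is a stand-in: the original analysis used real data
# and specifies no generator. Distributional choices are documented in the
# methods vignette.

#' Simulation configuration
#'
#' Defaults state the emulated world: within-genus identity ~82%,
#' between-genus identity modes at ~35% and ~50%, the observed per-strain
#' paralog-count (NP) distribution 72.48/23.49/3.36/0.67%, 11 populations,
#' family lengths 300-400 aa.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_genera,strains_per_genus reference collection shape.
#' @param family_length_range aa length interval for the family ancestor.
#' @param within_genus_identity percent identity target within a genus.
#' @param between_genus_identity one or two percent modes between genera
#'   (two modes split the genera into two subfamilies).
#' @param paralog_distribution named proportions NP -> fraction of strains.
#' @param n_decoys_per_strain non-family proteins per strain proteome.
#' @param populations population labels (defaults to the 11 cohort codes).
#' @param n_individuals_per_population samples per population.
#' @param read_length,coverage_per_gene read simulation parameters
#'   (`coverage_per_gene` = mean reads per gene per individual).
#' @param error_rate per-base substitution rate for reads (0 = error-free).
#' @param effect_sizes planted effects: `population` is the target partial
#'   R-squared fraction of the population factor on log family abundance;
#'   other entries default to 0.
#' @param disease_labels labels available for case-control simulation.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genera = 8L, strains_per_genus = 6L,
                       family_length_range = c(300L, 400L),
                       within_genus_identity = 82,
                       between_genus_identity = c(35, 50),
                       paralog_distribution = c("1" = 0.7248, "2" = 0.2349,
                                                "3" = 0.0336, "4" = 0.0067),
                       n_decoys_per_strain = 3L,
                       populations = c("US", "CN", "JP", "KR", "DK", "SE",
                                       "AT", "FR", "AU", "PE", "HZ"),
                       n_individuals_per_population = 10L,
                       read_length = 100L, coverage_per_gene = 50,
                       error_rate = 0,
                       effect_sizes = list(population = 0.35),
                       disease_labels = c("T2D", "AS")) {
  cfg <- list(seed = as.integer(seed), n_genera = as.integer(n_genera),
              strains_per_genus = as.integer(strains_per_genus),
              family_length_range = as.integer(family_length_range),
              within_genus_identity = within_genus_identity,
              between_genus_identity = sort(between_genus_identity),
              paralog_distribution = paralog_distribution,
              n_decoys_per_strain = as.integer(n_decoys_per_strain),
              populations = populations,
              n_individuals_per_population =
                as.integer(n_individuals_per_population),
              read_length = as.integer(read_length),
              coverage_per_gene = coverage_per_gene,
              error_rate = error_rate,
              effect_sizes = effect_sizes,
              disease_labels = disease_labels)
  with(cfg, {
    if (abs(sum(paralog_distribution) - 1) > 1e-9)
      stop("paralog_distribution proportions must sum to 1")
    if (any(is.na(as.integer(names(paralog_distribution)))))
      stop("paralog_distribution must be named by NP")
    ids <- c(within_genus_identity, between_genus_identity)
    if (any(ids <= 0 | ids >= 100))
      stop("identity targets must lie in (0, 100)")
    if (within_genus_identity <= max(between_genus_identity))
      stop("within-genus identity must exceed every between-genus mode")
    if (n_genera < 1 || strains_per_genus < 1 ||
        n_individuals_per_population < 1 || read_length < 1)
      stop("counts must be positive")
    if (coverage_per_gene <= 0) stop("coverage must be positive")
    if (family_length_range[1] > family_length_range[2])
      stop("invalid length range")
  })
  class(cfg) <- "sim_config"
  cfg
}

# Documented stream splitting: every stage re-seeds from the master seed and
# a fixed stage index, keeping derived seeds below 2^31.
STAGE_INDEX <- c(reference = 1L, metagenomes = 2L, phenotype = 3L,
                 cohort = 4L, case_control = 5L)
stage_seed <- function(seed, stage) {
  # double arithmetic: exact up to 2^53, avoids 32-bit overflow
  as.integer((as.numeric(seed) * 97 +
                STAGE_INDEX[[stage]] * 1009) %% 2147483647)
}

random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

# Substitute a fixed number of positions (round(frac * L)) to a different
# residue each; substitution-only evolution keeps alignments gapless.
mutate_seq <- function(seq, frac) {
  L <- nchar(seq)
  nmut <- round(frac * L)
  if (nmut == 0) return(seq)
  pos <- sample.int(L, nmut)
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(ch)
    sample(setdiff(AA_ALPHABET, ch), 1L), "")
  paste(chars, collapse = "")
}

#' Largest-remainder quota allocation
#'
#' Allocates `n` items to categories in exact proportion: floor the raw
#' quotas, then hand remaining items to the largest fractional remainders
#' (ties to the earlier category). Exact when `n * proportion` is integral.
#'
#' @param n total count.
#' @param proportions named nonnegative proportions summing to 1.
#' @return named integer allocation summing to `n`.
#' @examples
#' quota_allocation(447, c("1" = .7248, "2" = .2349, "3" = .0336, "4" = .0067))
#' @export
quota_allocation <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(proportions))
}

#' Generate a synthetic strain-proteome reference set with planted truth
#'
#' Each genus family is evolved from a random ancestor by calibrated
#' substitutions: leaves diverge from the genus ancestor so that within-genus
#' pairs hit the configured identity; genus ancestors diverge from (up to
#' two) subfamily ancestors so that between-genus pairs land near the
#' configured modes. Paralog counts per strain follow the configured NP
#' distribution by largest-remainder quota; each paralog is an independent
#' draw from the genus ancestor (duplication at the ancestor), which keeps
#' every within-genus pair on the identity target. Decoy non-family proteins
#' pad each proteome. Strain names encode "Genus species strain" for
#' taxonomy parsing.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_reference`: `records` (all proteins,
#'   [protein_records]), `truth` (planted family table: `id`, `strain_id`,
#'   `genus`, `clade`), `ancestors` (genus exemplar sequences, usable as
#'   screening queries), `np_by_strain` (named planted NP), `config`.
#' @export
generate_reference_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "reference"))
  w <- config$within_genus_identity / 100
  d_leaf <- 1 - sqrt(w)
  modes <- config$between_genus_identity / 100
  retained_leaf <- sqrt(w)                       # fraction kept leaf vs root
  if (length(modes) >= 2) {
    g_div <- 1 - sqrt(modes[length(modes)]) / retained_leaf
    a_div <- 1 - sqrt(modes[1]) /
      ((1 - g_div) * retained_leaf)
  } else {
    g_div <- 1 - sqrt(modes[1]) / retained_leaf
    a_div <- 0
  }
  if (g_div <= 0 || g_div >= 1 || a_div < 0 || a_div >= 1)
    stop("identity targets are jointly unachievable")

  L <- sample(seq(config$family_length_range[1],
                  config$family_length_range[2]), 1L)
  root <- random_aa(L)
  subfam <- vapply(1:2, function(i) mutate_seq(root, a_div), "")
  genera <- sprintf("Genus%02d", seq_len(config$n_genera))
  anc <- vapply(seq_len(config$n_genera), function(i)
    mutate_seq(subfam[1 + (i - 1) %% 2], g_div), "")

  n_strains <- config$n_genera * config$strains_per_genus
  quota <- quota_allocation(n_strains, config$paralog_distribution)
  np_pool <- rep(as.integer(names(quota)), quota)
  np_by_strain <- sample(np_pool)                # which strain gets which NP

  rec <- list(); truth <- list(); k <- 0L
  strain_names <- character(n_strains)
  for (gi in seq_len(config$n_genera)) {
    for (si in seq_len(config$strains_per_genus)) {
      k <- k + 1L
      sname <- sprintf("%s species%d ST%02d", genera[gi], gi, si)
      strain_names[k] <- sname
      np <- np_by_strain[k]
      fam_seqs <- vapply(seq_len(np), function(j)
        mutate_seq(anc[gi], d_leaf), "")
      fam_ids <- sprintf("%s|bsh%d", sname, seq_len(np))
      dec_seqs <- vapply(seq_len(config$n_decoys_per_strain), function(j)
        random_aa(sample(150:500, 1L)), "")
      dec_ids <- sprintf("%s|decoy%d", sname,
                         seq_len(config$n_decoys_per_strain))
      rec[[k]] <- data.frame(id = c(fam_ids, dec_ids),
                             sequence = c(fam_seqs, dec_seqs),
                             strain_id = sname, genus = genera[gi],
                             stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(id = fam_ids, strain_id = sname,
                               genus = genera[gi], clade = genera[gi],
                               stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rec)
  records <- protein_records(rec$id, rec$sequence, strain_id = rec$strain_id,
                             genus = rec$genus)
  ancestors <- protein_records(paste0(genera, "|exemplar"), anc,
                               genus = genera)
  names(np_by_strain) <- strain_names
  structure(list(records = records, truth = do.call(rbind, truth),
                 ancestors = ancestors, np_by_strain = np_by_strain,
                 config = config),
            class = "synthetic_reference")
}

# Standard-code synonymous codons per residue, alphabetical.
CODON_TABLE <- list(
  A = c("GCA", "GCC", "GCG", "GCT"), C = c("TGC", "TGT"),
  D = c("GAC", "GAT"), E = c("GAA", "GAG"), F = c("TTC", "TTT"),
  G = c("GGA", "GGC", "GGG", "GGT"), H = c("CAC", "CAT"),
  I = c("ATA", "ATC", "ATT"), K = c("AAA", "AAG"),
  L = c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"),
  M = "ATG", N = c("AAC", "AAT"),
  P = c("CCA", "CCC", "CCG", "CCT"), Q = c("CAA", "CAG"),
  R = c("AGA", "AGG", "CGA", "CGC", "CGG", "CGT"),
  S = c("AGC", "AGT", "TCA", "TCC", "TCG", "TCT"),
  T = c("ACA", "ACC", "ACG", "ACT"),
  V = c("GTA", "GTC", "GTG", "GTT"), W = "TGG",
  Y = c("TAC", "TAT"))

#' Back-translate an amino-acid sequence to nucleotides
#'
#' Deterministic codon choice (no codon-usage model): residue r takes its
#' `variant`-th synonymous codon, cyclically. Distinct variants give
#' different nucleotide forms for identical amino-acid stretches, so reads
#' simulated from one gene do not collide with near-identical paralogs when
#' each gene uses its own variant.
#'
#' @param aa amino-acid string(s).
#' @param variant nonnegative integer codon-choice offset (recycled).
#' @return nucleotide string(s), 3x the length.
#' @export
back_translate <- function(aa, variant = 0L) {
  variant <- rep_len(as.integer(variant), length(aa))
  vapply(seq_along(aa), function(i) {
    ch <- strsplit(toupper(aa[i]), "")[[1]]
    syn <- CODON_TABLE[ch]
    if (any(vapply(syn, is.null, logical(1))))
      stop("cannot back-translate residue(s): ",
           paste(unique(ch[vapply(syn, is.null, logical(1))]),
                 collapse = ", "))
    nt <- vapply(syn, function(cs)
      cs[variant[i] %% length(cs) + 1L], "")
    paste(nt, collapse = "")
  }, "")
}

#' Simulate per-individual metagenome read sets with planted abundances
#'
#' Gene universe = planted family members plus the decoy proteins (the
#' background that makes family relative abundance informative). Per-gene
#' base weights are log-normal; the planted population effect multiplies all
#' family genes of an individual by exp(mu\[population\]), with mu
#' standardized so the between-population variance on the log scale matches
#' `effect_sizes$population` as a partial R-squared fraction against unit
#' individual noise. Reads are error-free (or fixed-rate-error) substrings
#' of the back-translated genes; counts are Poisson with mean proportional
#' to planted abundance, scaled so the average gene receives
#' `coverage_per_gene` reads.
#'
#' @param config a [sim_config()].
#' @param ref a `synthetic_reference` from [generate_reference_set()].
#' @param coverage_scale optional named per-gene coverage multiplier
#'   (e.g. set a gene to 0 to silence it).
#' @return list of class `synthetic_metagenomes`: `reads` (named list,
#'   character vector per sample), `meta` (sample_id, population, gender,
#'   age, bmi, status), `true_abundance` (samples x genes), `read_counts`
#'   (samples x genes), `gene_nt`, `family_genes`.
#' @export
generate_metagenomes <- function(config, ref, coverage_scale = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(ref, "synthetic_reference"))
  set.seed(stage_seed(config$seed, "metagenomes"))
  genes <- ref$records$id
  fam <- genes %in% ref$truth$id
  gene_nt <- setNames(back_translate(ref$records$sequence,
                                     variant = seq_along(genes) - 1L), genes)
  short <- nchar(gene_nt) < config$read_length
  if (any(short)) { genes <- genes[!short]; fam <- fam[!short]
                    gene_nt <- gene_nt[!short] }
  scale_g <- setNames(rep(1, length(genes)), genes)
  if (!is.null(coverage_scale))
    scale_g[names(coverage_scale)] <- coverage_scale
  pops <- config$populations
  r2 <- config$effect_sizes$population %||% 0
  mu <- rnorm(length(pops))
  if (length(pops) > 1 && r2 > 0) {
    mu <- (mu - mean(mu)) / sd(mu) * sqrt(r2 / (1 - r2))
  } else mu <- rep(0, length(pops))
  names(mu) <- pops
  base_w <- setNames(exp(rnorm(length(genes), 0, 1)), genes)
  samples <- as.vector(t(outer(pops, seq_len(config$n_individuals_per_population),
                               function(p, i) sprintf("%s_%02d", p, i))))
  pop_of <- rep(pops, each = config$n_individuals_per_population)
  meta <- data.frame(
    sample_id = samples, population = pop_of,
    gender = sample(c("male", "female"), length(samples), replace = TRUE),
    age = round(runif(length(samples), 18, 70)),
    bmi = round(pmin(pmax(rnorm(length(samples), 24, 3), 16), 35), 1),
    status = "healthy", stringsAsFactors = FALSE)
  true_ab <- matrix(0, length(samples), length(genes),
                    dimnames = list(samples, genes))
  counts <- true_ab
  reads <- vector("list", length(samples)); names(reads) <- samples
  for (i in seq_along(samples)) {
    w <- base_w * exp(rnorm(length(genes), 0, 1))
    w[fam] <- w[fam] * exp(mu[pop_of[i]])
    ab <- w / sum(w)
    true_ab[i, ] <- ab
    # reads accrue proportionally to abundance x gene length (shotgun
    # physics); the RA formula's length division undoes exactly this
    abl <- ab * nchar(gene_nt)
    lam <- config$coverage_per_gene * abl / mean(abl) * scale_g
    n_reads <- rpois(length(genes), lam)
    counts[i, ] <- n_reads
    rd <- character(0)
    for (g in which(n_reads > 0)) {
      maxs <- nchar(gene_nt[g]) - config$read_length + 1L
      starts <- sample.int(maxs, n_reads[g], replace = TRUE)
      rr <- substring(gene_nt[g], starts, starts + config$read_length - 1L)
      rd <- c(rd, rr)
    }
    if (config$error_rate > 0 && length(rd)) {
      rd <- vapply(rd, function(r) {
        ch <- strsplit(r, "")[[1]]
        hit <- runif(length(ch)) < config$error_rate
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    reads[[i]] <- rd
  }
  structure(list(reads = reads, meta = meta, true_abundance = true_ab,
                 read_counts = counts, gene_nt = gene_nt,
                 family_genes = genes[fam], population_effect = mu),
            class = "synthetic_metagenomes")
}

#' Generate a country-level phenotype table
#'
#' One row per population, four indicator columns modeled on national health
#' statistics (diabetes death rate, CVD death rate, mean cholesterol, obese
#' BMI). Optionally plants a monotone link between one indicator and a
#' supplied per-population family abundance: `link_rho = 1` / `-1` gives a
#' perfect monotone transform; intermediate values mix the abundance ranks
#' with noise toward the target Spearman correlation; `NULL` plants
#' independence.
#'
#' @param config a [sim_config()] (needs >= 3 populations).
#' @param ra_by_population named numeric population -> abundance, required
#'   when planting a link.
#' @param link_indicator indicator column to plant the link into.
#' @param link_rho target Spearman correlation, or NULL for independence.
#' @return data.frame: `population` plus 4 indicator columns.
#' @export
generate_phenotype_table <- function(config, ra_by_population = NULL,
                                     link_indicator = "diabetes_death_rate",
                                     link_rho = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pops <- config$populations
  if (length(pops) < 3) stop("need at least 3 populations")
  set.seed(stage_seed(config$seed, "phenotype"))
  tab <- data.frame(
    population = pops,
    diabetes_death_rate = round(runif(length(pops), 5, 120), 1),
    cvd_death_rate = round(runif(length(pops), 80, 500), 1),
    mean_cholesterol = round(runif(length(pops), 3.8, 5.8), 2),
    obesity_bmi = round(runif(length(pops), 21, 33), 1),
    stringsAsFactors = FALSE)
  if (!is.null(link_rho)) {
    if (is.null(ra_by_population))
      stop("planting a link requires ra_by_population")
    ra <- ra_by_population[pops]
    if (anyNA(ra)) stop("ra_by_population must cover every population")
    if (abs(link_rho) >= 1) {
      y <- sign(link_rho) * ra            # perfect monotone transform
    } else {
      z <- scale(rank(ra))[, 1]
      y <- link_rho * z + sqrt(1 - link_rho^2) * rnorm(length(pops))
    }
    rng <- range(tab[[link_indicator]])
    tab[[link_indicator]] <- round(rng[1] + (rank(y) - 1) /
                                     (length(pops) - 1) * diff(rng), 1)
  }
  tab
}

#' Simulate a per-individual cohort with a planted population effect
#'
#' Direct simulation of per-individual family cumulative RA (log scale) for
#' the multivariable-adjustment recovery checks: response = planted
#' population mean + unit normal noise. The plant is exact, not merely in
#' expectation: population means are standardized to the target
#' between-population variance `r2/(1-r2)` and the noise is residualized
#' against the population factor and rescaled to unit variance, so the
#' population partial R-squared of the generated data equals
#' `r2_population` up to the degrees of freedom absorbed by the other
#' covariates. Gender, age and BMI are independent of the response.
#'
#' @param n individuals.
#' @param populations population labels (assigned round-robin).
#' @param r2_population planted partial R-squared fraction (0..1).
#' @param seed RNG seed.
#' @return data.frame: `sample_id`, `population`, `gender`, `age`, `bmi`,
#'   `ra` (log-scale response).
#' @export
simulate_cohort_ra <- function(n, populations = sprintf("P%02d", 1:11),
                               r2_population = 0.35, seed = 1L) {
  set.seed(stage_seed(seed, "cohort"))
  pop <- rep_len(populations, n)
  mu <- rnorm(length(populations))
  m <- mu[match(pop, populations)]
  if (r2_population > 0) {
    m <- (m - mean(m)) / sd(m) * sqrt(r2_population / (1 - r2_population))
  } else m <- rep(0, n)
  e <- rnorm(n)
  if (r2_population > 0) {
    e <- e - ave(e, pop)                # exactly no between-population noise
    e <- e / sd(e)                      # exactly unit noise variance
  }
  data.frame(sample_id = sprintf("S%04d", seq_len(n)), population = pop,
             gender = sample(c("male", "female"), n, replace = TRUE),
             age = round(runif(n, 18, 70)),
             bmi = round(rnorm(n, 24, 3), 1),
             ra = m + e, stringsAsFactors = FALSE)
}

#' Simulate a case-control phylotype abundance matrix
#'
#' Per-individual per-phylotype cumulative RA under optional planted
#' case/control fold changes and zero inflation, for power and type-I
#' checks of [cohort_compare()].
#'
#' @param n_per_arm individuals per arm.
#' @param n_phylotypes number of phylotypes.
#' @param effect named multipliers on case means (default none).
#' @param zero_inflation per-phylotype probability of structural zero.
#' @param seed RNG seed.
#' @return list: `phylo_ra` (individuals x phylotypes), `meta`.
#' @export
simulate_case_control_ra <- function(n_per_arm, n_phylotypes = 8L,
                                     effect = NULL, zero_inflation = 0,
                                     seed = 1L) {
  set.seed(stage_seed(seed, "case_control"))
  phylos <- paste0("T", seq_len(n_phylotypes))
  n <- 2L * n_per_arm
  status <- rep(c("healthy", "disease"), each = n_per_arm)
  m <- matrix(exp(rnorm(n * n_phylotypes, 0, 1)), n, n_phylotypes,
              dimnames = list(sprintf("I%04d", seq_len(n)), phylos))
  if (!is.null(effect))
    for (ph in names(effect))
      m[status == "disease", ph] <- m[status == "disease", ph] * effect[[ph]]
  if (zero_inflation > 0)
    m[matrix(runif(length(m)) < zero_inflation, nrow(m))] <- 0
  meta <- data.frame(sample_id = rownames(m), status = status,
                     stringsAsFactors = FALSE)
  list(phylo_ra = m, meta = meta)
}
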