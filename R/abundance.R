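# Gene catalog construction, read mapping and the length-normalized
# relative-abundance (RA) statistic.

#' Build a non-redundant gene catalog
#'
#' Greedy clustering in decreasing length order (ties by id): each protein
#' joins the first existing representative it matches at `>= min_identity`
#' over `>= min_overlap` percent of the shorter sequence, else founds a new
#' cluster. Representatives are therefore always the longest member, and the
#' outcome is deterministic. Identity is measured on an overlap (free end
#' gap) alignment, so near-identical proteins cannot sneak over the
#' threshold by trimming to a locally conserved core.
#'
#' @param proteins [protein_records] collection.
#' @param min_identity percent identity threshold (default 95).
#' @param min_overlap minimum alignment coverage of the shorter sequence, in
#'   percent (default 90).
#' @param matrix_name substitution matrix for the local alignments.
#' @return object of class `gene_catalog`: `clusters` data.frame
#'   (`representative`, `member`), `lengths` (named aa lengths of
#'   representatives).
#' @export
build_nr_catalog <- function(proteins, min_identity = 95, min_overlap = 90,
                             matrix_name = "BLOSUM62") {
  proteins <- as_protein_records(proteins)
  if (nrow(proteins) == 0) stop("empty protein collection")
  ord <- order(-proteins$length, proteins$id)
  proteins <- proteins[ord, , drop = FALSE]
  reps <- integer(0)              # row indices of representatives
  member_of <- character(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    assigned <- NA_character_
    if (length(reps)) {
      r <- align_to_subject(proteins$sequence[reps], proteins$sequence[i],
                            mode = "overlap", matrix_name = matrix_name)
      shorter <- pmin(proteins$length[reps], proteins$length[i])
      ok <- r$pct_identity >= min_identity &
            100 * r$aln_length / shorter >= min_overlap
      if (any(ok)) assigned <- proteins$id[reps[which(ok)[1]]]
    }
    if (is.na(assigned)) {
      reps <- c(reps, i)
      assigned <- proteins$id[i]
    }
    member_of[i] <- assigned
  }
  clusters <- data.frame(representative = member_of, member = proteins$id,
                         stringsAsFactors = FALSE)
  lengths <- setNames(proteins$length[reps], proteins$id[reps])
  structure(list(clusters = clusters, lengths = lengths),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("Gene catalog: %d clusters over %d members\n",
              length(x$lengths), nrow(x$clusters)))
  invisible(x)
}

#' Map reads onto catalog genes by exact substring matching
#'
#' Each read is assigned to at most one gene: the first gene (lexicographic
#' id order) containing it as an exact substring (or within `max_mismatch`
#' mismatches). Reads matching nothing are counted as unmapped. This stands
#' in for a short-read aligner at desk scale; the profiling contract is the
#' count vector, not a specific mapper.
#'
#' @param reads character vector / `DNAStringSet` of reads, or a named list
#'   of them (one element per sample).
#' @param genes named character vector of gene nucleotide sequences
#'   (typically back-translated catalog representatives, see
#'   [back_translate()]).
#' @param max_mismatch allowed mismatches per read (default 0).
#' @return for a single sample, a list `counts` (named per-gene integer) and
#'   `unmapped`; for a list input, a samples x genes count matrix with an
#'   `unmapped` attribute.
#' @export
map_reads <- function(reads, genes, max_mismatch = 0L) {
  if (length(genes) == 0) stop("catalog is empty")
  if (is.null(names(genes))) stop("genes must be named")
  genes <- genes[order(names(genes))]
  if (is.list(reads) && !inherits(reads, "DNAStringSet")) {
    per <- lapply(reads, map_reads, genes = genes, max_mismatch = max_mismatch)
    counts <- do.call(rbind, lapply(per, `[[`, "counts"))
    rownames(counts) <- names(reads)
    attr(counts, "unmapped") <- vapply(per, `[[`, numeric(1), "unmapped")
    return(counts)
  }
  reads <- as.character(reads)
  if (length(reads) && any(!grepl("^[ACGT]+$", reads)))
    stop("malformed read records (non-ACGT characters)")
  counts <- setNames(integer(length(genes)), names(genes))
  unmapped <- 0L
  if (length(reads)) {
    widths <- nchar(reads)
    subj <- Biostrings::DNAStringSet(genes)
    if (length(unique(widths)) == 1L) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads),
                              max.mismatch = if (max_mismatch > 0) max_mismatch else NA)
      hit <- Biostrings::vcountPDict(pd, subj, max.mismatch = max_mismatch) > 0
      # hit: patterns x subjects; assign each read to first gene with a match
      first_gene <- apply(hit, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
    } else {
      first_gene <- vapply(reads, function(rd) {
        z <- Biostrings::vcountPattern(rd, subj, max.mismatch = max_mismatch) > 0
        if (any(z)) which(z)[1] else NA_integer_
      }, integer(1))
    }
    unmapped <- sum(is.na(first_gene))
    tb <- table(factor(first_gene, levels = seq_along(genes)))
    counts[] <- as.integer(tb)
  }
  list(counts = counts, unmapped = unmapped)
}

#' Length-normalized relative abundance
#'
#' For sample i and gene g with mapped count c(g,i) and protein length L(g),
#' RA(g,i) = (c(g,i)/L(g)) / sum_g' (c(g',i)/L(g')). Rows sum to 1 for every
#' retained sample; samples whose total mapped count falls below `min_total`
#' are excluded and listed in the `excluded` attribute rather than silently
#' zero-filled. RA is invariant to uniform count scaling within a sample.
#'
#' @param counts samples x genes count matrix (or a single named count
#'   vector, treated as one sample).
#' @param lengths named per-gene lengths in amino acids (nucleotide lengths
#'   would rescale every density by 3 and cancel in the normalization).
#' @param min_total minimum total mapped count to retain a sample.
#' @return object of class `abundance_matrix`: `ra` and `counts` matrices
#'   (retained samples only), `samples`, `genes`, `excluded`.
#' @export
relative_abundance <- function(counts, lengths, min_total = 1L) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, 1L, dimnames = list("sample1", names(counts)))
  genes <- colnames(counts)
  if (is.null(genes) || !all(genes %in% names(lengths)))
    stop("every counted gene needs a length")
  L <- lengths[genes]
  if (any(L <= 0)) stop("gene lengths must be positive")
  dens <- sweep(counts, 2L, L, "/")
  tot <- rowSums(dens)
  keep <- rowSums(counts) >= min_total & tot > 0
  ra <- dens[keep, , drop = FALSE] / tot[keep]
  structure(list(ra = ra, counts = counts[keep, , drop = FALSE],
                 samples = rownames(counts)[keep], genes = genes,
                 excluded = rownames(counts)[!keep]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d samples x %d genes (%d excluded)\n",
              length(x$samples), length(x$genes), length(x$excluded)))
  invisible(x)
}

#' Detect family members present in per-individual data
#'
#' Screens each sample's predicted proteins against the curated family at a
#' stricter identity cutoff (default 62% with BLOSUM62, the per-individual
#' detection rule). The detected set is the set of reference members whose
#' best alignment appears in a sample; the union across samples gives the
#' population-detected subset of the reference.
#'
#' @param sample_proteins a [protein_records] collection or a named list of
#'   them (one per sample).
#' @param reference the curated family as [protein_records].
#' @param min_identity,min_score,matrix_name,mode screening parameters
#'   (see [homology_screen()]).
#' @return list of class `family_detection`: `per_sample` (named list of
#'   detected reference-id sets), `detected` (union), `n_reference`,
#'   `pct_detected`.
#' @export
detect_family_members <- function(sample_proteins, reference,
                                  min_identity = 62, min_score = 100,
                                  matrix_name = "BLOSUM62",
                                  mode = c("local", "global")) {
  mode <- match.arg(mode)
  reference <- as_protein_records(reference)
  if (nrow(reference) == 0) stop("curated reference is empty")
  if (inherits(sample_proteins, "protein_records") ||
      is.data.frame(sample_proteins))
    sample_proteins <- list(sample1 = sample_proteins)
  per_sample <- lapply(sample_proteins, function(sp) {
    if (nrow(sp) == 0) return(character(0))
    hits <- homology_screen(reference, sp, min_identity = min_identity,
                            min_score = min_score, mode = mode,
                            matrix_name = matrix_name)
    sort(unique(hits$query_id))
  })
  detected <- sort(unique(unlist(per_sample)))
  structure(list(per_sample = per_sample, detected = detected,
                 n_reference = nrow(reference),
                 pct_detected = detection_fraction(length(detected),
                                                   nrow(reference))),
            class = "family_detection")
}

#' Detected fraction of a reference family
#'
#' @param n_detected number of reference members detected (or a character
#'   vector of detected ids).
#' @param n_reference reference family size.
#' @return percent, rounded to 2 decimals (e.g. 156 of 591 -> 26.40).
#' @export
detection_fraction <- function(n_detected, n_reference) {
  if (is.character(n_detected)) n_detected <- length(unique(n_detected))
  if (n_reference <= 0) stop("reference size must be positive")
  round(100 * n_detected / n_reference, 2)
}

#' Cumulative relative abundance by gene group and population
#'
#' Per sample, RA is summed over the genes of each group (genus, phylotype,
#' or the whole family); per population these within-sample sums are then
#' aggregated across samples — by mean by default, since per-population
#' scalars must be comparable across unequal sample sizes (`agg = "sum"`
#' selectable). Additivity holds exactly: over any disjoint grouping the
#' group values sum to the all-genes value.
#'
#' @param am an `abundance_matrix` from [relative_abundance()].
#' @param sample_meta data.frame with `sample_id` and `population`.
#' @param groups named character vector gene id -> group label, or the
#'   string `"all"` to treat all genes as one group.
#' @param agg `"mean"` or `"sum"` across samples within a population.
#' @return data.frame of class `cumulative_ra`: `group`, `population`,
#'   `value`.
#' @export
cumulative_ra <- function(am, sample_meta, groups = "all", agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  stopifnot(inherits(am, "abundance_matrix"))
  if (identical(groups, "all"))
    groups <- setNames(rep("all", length(am$genes)), am$genes)
  missing_genes <- setdiff(am$genes, names(groups))
  if (length(missing_genes))
    stop("unlabeled genes: ", paste(head(missing_genes, 5), collapse = ", "))
  pop <- sample_meta$population[match(am$samples, sample_meta$sample_id)]
  if (anyNA(pop)) stop("every sample needs a population label")
  glab <- factor(groups[am$genes])
  # per-sample group sums: samples x groups
  gs <- t(rowsum(t(am$ra), glab))
  res <- expand.grid(group = colnames(gs), population = unique(pop),
                     stringsAsFactors = FALSE)
  res$value <- mapply(function(g, p) {
    v <- gs[pop == p, g]
    if (agg == "mean") mean(v) else sum(v)
  }, res$group, res$population)
  class(res) <- c("cumulative_ra", "data.frame")
  res
}
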