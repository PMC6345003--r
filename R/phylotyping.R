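# Phylotype reclassification: alignment distances, neighbor-joining tree,
# average-linkage cut with an unclassifiable outlier group (the "T0"
# phenomenon), and nearest-reference assignment of new sequences.

#' Pairwise alignment distance matrix
#'
#' Distances from global pairwise alignments: p-distance = 1 - identity/100,
#' optionally Poisson-corrected d = -ln(1 - p) (multiple-hit correction).
#' p = 1 under Poisson correction is capped at `cap` with a warning.
#'
#' @param records [protein_records], at least 3.
#' @param correction `"p"` or `"poisson"`.
#' @param matrix_name substitution matrix for the alignments.
#' @param cap maximum distance substituted when the Poisson correction
#'   diverges (p = 1).
#' @return symmetric named distance matrix, zero diagonal.
#' @export
distance_matrix <- function(records, correction = c("p", "poisson"),
                            matrix_name = "BLOSUM62", cap = 10) {
  correction <- match.arg(correction)
  records <- as_protein_records(records)
  if (nrow(records) < 3) stop("need at least 3 sequences")
  p <- 1 - identity_matrix(records, mode = "global",
                           matrix_name = matrix_name) / 100
  if (correction == "poisson") {
    sat <- p >= 1
    if (any(sat)) {
      warning("p-distance of 1 capped at ", cap, " under Poisson correction")
      p[sat] <- NA
    }
    p <- -log(1 - p)
    p[is.na(p)] <- cap
  }
  diag(p) <- 0
  p
}

#' Neighbor-joining tree from a distance matrix
#'
#' Unrooted binary tree via neighbor-joining (the clustering-structure
#' surrogate for the original maximum-likelihood tree; phylotype membership
#' depends on clustering structure, not on ML branch lengths). On an
#' additive matrix the reconstruction is exact: tree path lengths reproduce
#' the input distances.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return an [ape::phylo] tree, serializable with [ape::write.tree()].
#' @export
build_tree <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  ape::nj(d)
}

#' Cut sequences into phylotypes with an outlier group
#'
#' Average-linkage hierarchical clustering on the distance matrix, cut at
#' `k` clusters. Two outlier rules then route sequences to the
#' unclassifiable label (default `"T0"`): clusters smaller than
#' `min_cluster_size`, and sequences whose mean within-cluster distance
#' exceeds the `outlier_quantile` of all pairwise distances. Remaining
#' clusters are labeled T1..Tk' by decreasing size (ties by smallest member
#' id). Ids are sorted before clustering, so labels are stable under input
#' permutation.
#'
#' @param d symmetric distance matrix.
#' @param k number of clusters to cut (2 <= k < n).
#' @param outlier_quantile quantile of the global distance distribution used
#'   as the within-cluster coherence ceiling.
#' @param min_cluster_size clusters below this size go to the outlier label.
#' @param outlier_label label for unclassifiable sequences.
#' @return object of class `phylotype_assignment`: `labels` (named character,
#'   a partition), `k` (regular phylotypes), `outlier_label`, `degenerate`
#'   flag (all distances zero).
#' @export
cut_phylotypes <- function(d, k = 8L, outlier_quantile = 0.95,
                           min_cluster_size = 2L, outlier_label = "T0") {
  n <- nrow(d)
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of sequences")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  degenerate <- all(d == 0)
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = k)
  ids <- rownames(d)
  thr <- quantile(d[upper.tri(d)], outlier_quantile, names = FALSE)
  outlier <- logical(n)
  for (g in unique(cl)) {
    m <- cl == g
    if (sum(m) < min_cluster_size) { outlier[m] <- TRUE; next }
    if (sum(m) > 1) {
      wd <- rowMeans(d[m, m, drop = FALSE]) * sum(m) / (sum(m) - 1)
      outlier[m][wd > thr] <- TRUE
    }
  }
  keep <- !outlier
  sizes <- table(cl[keep])
  first_member <- tapply(ids[keep], cl[keep], min)
  lab_order <- names(sizes)[order(-as.integer(sizes),
                                  first_member[names(sizes)])]
  relab <- setNames(paste0("T", seq_along(lab_order)), lab_order)
  labels <- setNames(rep(outlier_label, n), ids)
  labels[keep] <- relab[as.character(cl[keep])]
  structure(list(labels = labels, k = length(lab_order),
                 outlier_label = outlier_label, degenerate = degenerate),
            class = "phylotype_assignment")
}

#' @export
print.phylotype_assignment <- function(x, ...) {
  cat(sprintf("Phylotype assignment: %d sequences, %d regular phylotypes\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Assign a new sequence to an existing phylotype scheme
#'
#' Nearest-classified-sequence rule on global alignment p-distance. Ties
#' between phylotypes break toward the smaller phylotype index (then the
#' outlier label) and are flagged in the `tie` attribute. A nearest distance
#' above `ceiling` routes the query to the outlier label.
#'
#' @param query a single sequence (string or one-row [protein_records]).
#' @param assignment a `phylotype_assignment`.
#' @param refs the classified sequences as [protein_records] (ids matching
#'   `assignment$labels`).
#' @param ceiling maximum acceptable p-distance to the nearest reference.
#' @param matrix_name substitution matrix.
#' @return the phylotype label, with attributes `distance`, `nearest`, `tie`.
#' @export
assign_phylotype <- function(query, assignment, refs, ceiling = 1,
                             matrix_name = "BLOSUM62") {
  refs <- as_protein_records(refs)
  if (nrow(refs) == 0) stop("empty classified reference set")
  lab <- assignment$labels[refs$id]
  if (anyNA(lab)) stop("refs contain sequences missing from the assignment")
  r <- align_to_subject(refs$sequence, seq_of(query)[1], mode = "global",
                        matrix_name = matrix_name)
  dist <- 1 - r$pct_identity / 100
  dmin <- min(dist)
  if (dmin > ceiling)
    return(structure(assignment$outlier_label, distance = dmin,
                     nearest = NA_character_, tie = FALSE))
  cand <- unique(lab[dist == dmin])
  tie <- length(cand) > 1
  # smaller phylotype index first; outlier label sorts last
  idx <- suppressWarnings(as.integer(sub("^T", "", cand)))
  idx[cand == assignment$outlier_label] <- .Machine$integer.max
  chosen <- cand[order(idx, cand)][1]
  structure(chosen, distance = dmin,
            nearest = refs$id[which(dist == dmin)[1]], tie = tie)
}

#' Per-phylotype census and paralog cross-classification
#'
#' Counts sequences and distinct strains per phylotype and, for strains with
#' multiple family copies, whether the paralogs fall in one phylotype or
#' across several.
#'
#' @param assignment a `phylotype_assignment` (or a named character vector of
#'   labels).
#' @param strain_of named character vector sequence id -> strain id.
#' @return list of class `phylotype_census`: `table` (phylotype,
#'   n_sequences, n_strains), `total_sequences`, `paralog_strains`
#'   (n_same_phylotype, n_cross_phylotype).
#' @export
phylotype_census <- function(assignment, strain_of = NULL) {
  labels <- if (inherits(assignment, "phylotype_assignment"))
    assignment$labels else assignment
  ids <- names(labels)
  if (is.null(strain_of)) strain_of <- setNames(ids, ids)
  st <- strain_of[ids]
  if (anyNA(st)) stop("every classified sequence needs a strain")
  ns <- tapply(ids, labels, length)
  nst <- tapply(st, labels, function(x) length(unique(x)))
  tab <- data.frame(phylotype = names(ns), n_sequences = as.integer(ns),
                    n_strains = as.integer(nst), stringsAsFactors = FALSE)
  tab <- tab[order(tab$phylotype), , drop = FALSE]
  rownames(tab) <- NULL
  multi <- split(labels, st)
  multi <- multi[vapply(multi, length, 1L) >= 2]
  same <- sum(vapply(multi, function(x) length(unique(x)) == 1, logical(1)))
  structure(list(table = tab, total_sequences = length(ids),
                 paralog_strains = c(n_same_phylotype = same,
                                     n_cross_phylotype = length(multi) - same)),
            class = "phylotype_census")
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones. Used to score planted-clade recovery.
#'
#' @param a,b two label vectors over the same items (order-aligned).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
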