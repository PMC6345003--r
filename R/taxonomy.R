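# Strain-name taxonomy parsing and the paralog census (NP distribution).

#' Parse taxonomy out of strain names
#'
#' Strain proteome collections carry taxonomy only in their record names
#' ("Genus species strain tokens..."). The first whitespace token becomes the
#' genus, the second the species, the remainder the strain token. Underscores
#' and square brackets are normalized away before splitting. Names that do
#' not yield at least genus + species are flagged (`parsed = FALSE`), never
#' dropped.
#'
#' @param raw_name character vector of strain names.
#' @param phylum_lookup optional named character vector genus -> phylum (see
#'   [genus_phylum_lookup()]).
#' @return data.frame: `strain_id` (normalized full name), `raw_name`,
#'   `genus`, `species`, `strain_token`, `phylum`, `parsed`.
#' @examples
#' parse_strain_taxonomy("Bacteroides uniformis ATCC 8492")
#' parse_strain_taxonomy("Lactobacillus_salivarius LMG14476")
#' @export
parse_strain_taxonomy <- function(raw_name, phylum_lookup = NULL) {
  if (any(!nzchar(raw_name))) stop("empty strain names are not allowed")
  norm <- gsub("[][]", "", gsub("_", " ", raw_name))
  norm <- gsub("\\s+", " ", trimws(norm))
  toks <- strsplit(norm, " ", fixed = TRUE)
  genus <- vapply(toks, `[`, "", 1L)
  species <- vapply(toks, function(t) if (length(t) >= 2) t[2L] else NA_character_, "")
  strain_token <- vapply(toks, function(t)
    if (length(t) >= 3) paste(t[-(1:2)], collapse = " ") else NA_character_, "")
  parsed <- !is.na(species)
  phylum <- NA_character_
  if (!is.null(phylum_lookup))
    phylum <- unname(phylum_lookup[genus])
  data.frame(strain_id = norm, raw_name = raw_name, genus = genus,
             species = species, strain_token = strain_token,
             phylum = phylum, parsed = parsed, stringsAsFactors = FALSE)
}

#' Bundled genus-to-phylum lookup
#'
#' Strain names encode genus and species but not phylum; phylum-level rollups
#' use this editable lookup (a two-column TSV bundled with the package,
#' covering common gut genera).
#'
#' @param path TSV with columns `genus`, `phylum`; defaults to the bundled
#'   table.
#' @return named character vector genus -> phylum.
#' @export
genus_phylum_lookup <- function(path = system.file("extdata",
                                                   "genus_phylum.tsv",
                                                   package = "bshprof")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$phylum, tab$genus)
}

#' Per-strain paralog census
#'
#' NP (number of paralogs) is the number of distinct hit sequences per
#' strain, counted by sequence id (identical paralog sequences with distinct
#' ids count separately). Accepts either a hit table from
#' [homology_screen()] (columns `subject_id`, `strain_id`) or a named
#' numeric vector of pre-tabulated strain counts by NP
#' (e.g. `c("1" = 324, "2" = 105, "3" = 15, "4" = 3)`).
#'
#' @param hits hit data.frame or named NP -> strain-count vector.
#' @return object of class `paralog_census`: `np_counts` (named integer),
#'   `total_strains`, `total_sequences`, `pct_by_np`, `pct_multi` (percent of
#'   strains with NP >= 2).
#' @export
paralog_census <- function(hits) {
  if (is.numeric(hits) && !is.null(names(hits))) {
    np <- as.integer(names(hits))
    if (any(is.na(np)) || any(np < 1)) stop("NP names must be positive integers")
    np_counts <- setNames(as.integer(hits), names(hits))
  } else {
    stopifnot(is.data.frame(hits),
              all(c("subject_id", "strain_id") %in% names(hits)))
    if (any(is.na(hits$strain_id)))
      stop("every hit must carry a strain_id")
    per_strain <- tapply(hits$subject_id, hits$strain_id,
                         function(x) length(unique(x)))
    tab <- table(per_strain)
    np_counts <- setNames(as.integer(tab), names(tab))
  }
  np <- as.integer(names(np_counts))
  total_strains <- sum(np_counts)
  total_sequences <- sum(np * np_counts)
  pct_by_np <- round(100 * np_counts / total_strains, 2)
  pct_multi <- round(100 * sum(np_counts[np >= 2]) / total_strains, 2)
  structure(list(np_counts = np_counts, total_strains = total_strains,
                 total_sequences = total_sequences, pct_by_np = pct_by_np,
                 pct_multi = pct_multi),
            class = "paralog_census")
}

#' @export
print.paralog_census <- function(x, ...) {
  cat(sprintf("Paralog census: %d sequences in %d strains\n",
              x$total_sequences, x$total_strains))
  for (np in names(x$np_counts))
    cat(sprintf("  NP=%s: %d strains (%.2f%%)\n", np, x$np_counts[[np]],
                x$pct_by_np[[np]]))
  cat(sprintf("  multi-copy strains: %.2f%%\n", x$pct_multi))
  invisible(x)
}

#' Fraction of the strain universe encoding the family
#'
#' @param hits hit table with `strain_id` (duplicated hits on one protein id
#'   do not change the result).
#' @param all_strains strain universe: a data.frame with `strain_id` (e.g.
#'   from [parse_strain_taxonomy()]) or a character vector.
#' @return percent of strains with at least one hit.
#' @export
encoding_fraction <- function(hits, all_strains) {
  universe <- if (is.data.frame(all_strains)) all_strains$strain_id
              else as.character(all_strains)
  universe <- unique(universe)
  if (length(universe) == 0) stop("strain universe is empty")
  hit_strains <- unique(hits$strain_id)
  missing <- setdiff(hit_strains, universe)
  if (length(missing))
    stop("hit strains absent from the universe: ",
         paste(head(missing, 5), collapse = ", "))
  100 * length(hit_strains) / length(universe)
}

#' Genus- and phylum-level rollups of family hits
#'
#' @param hits hit table with `strain_id`.
#' @param strains strain table from [parse_strain_taxonomy()] (with `genus`,
#'   optionally `phylum`).
#' @return list with `genus` and `phylum` data.frames (`n_sequences`,
#'   `n_strains`), sorted by sequence count descending, ties lexicographic.
#' @export
genus_summary <- function(hits, strains) {
  if (nrow(hits) == 0)
    return(list(genus = data.frame(genus = character(),
                                   n_sequences = integer(),
                                   n_strains = integer()),
                phylum = data.frame(phylum = character(),
                                    n_sequences = integer(),
                                    n_strains = integer())))
  idx <- match(hits$strain_id, strains$strain_id)
  if (anyNA(idx))
    stop("hits reference strains missing from the strain table")
  roll <- function(lab) {
    lab[is.na(lab)] <- "unassigned"
    d <- data.frame(lab = lab, strain = hits$strain_id, id = hits$subject_id)
    ns <- tapply(d$id, d$lab, function(x) length(unique(x)))
    st <- tapply(d$strain, d$lab, function(x) length(unique(x)))
    out <- data.frame(label = names(ns), n_sequences = as.integer(ns),
                      n_strains = as.integer(st), stringsAsFactors = FALSE)
    out[order(-out$n_sequences, out$label), , drop = FALSE]
  }
  g <- roll(strains$genus[idx]); names(g)[1] <- "genus"
  p <- roll(strains$phylum[idx] %||% NA_character_); names(p)[1] <- "phylum"
  rownames(g) <- rownames(p) <- NULL
  list(genus = g, phylum = p)
}
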