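#' Construct a collection of protein records
#'
#' A `protein_records` object is a plain `data.frame` with one row per
#' sequence and columns `id`, `sequence`, `length`, `strain_id`, `genus` and
#' `phylum`. It is the unit that gets length-filtered, screened, clustered and
#' phylotyped.
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence amino-acid sequences (20-letter alphabet, `X` allowed).
#' @param strain_id,genus,phylum optional taxonomy labels, recycled to length.
#' @return a `data.frame` of class `protein_records`.
#' @examples
#' protein_records(c("a", "b"), c("MKLV", "MKIV"), strain_id = "s1")
#' @export
protein_records <- function(id, sequence, strain_id = NA_character_,
                            genus = NA_character_, phylum = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have equal length")
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequences are not allowed")
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "X]*$"),
                sequence)
  if (any(bad))
    stop("non-amino-acid characters in sequences: ",
         paste(head(id[bad], 5), collapse = ", "))
  out <- data.frame(
    id = id,
    sequence = sequence,
    length = nchar(sequence),
    strain_id = rep_len(as.character(strain_id), length(id)),
    genus = rep_len(as.character(genus), length(id)),
    phylum = rep_len(as.character(phylum), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Validate and coerce to protein_records
#' @param x a `protein_records` object or a data.frame with at least
#'   `id` and `sequence` columns.
#' @return a `protein_records` object.
#' @export
as_protein_records <- function(x) {
  if (inherits(x, "protein_records")) return(x)
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  protein_records(x$id, x$sequence,
                  strain_id = x$strain_id %||% NA_character_,
                  genus = x$genus %||% NA_character_,
                  phylum = x$phylum %||% NA_character_)
}

#' Keep records whose length falls in an inclusive window
#'
#' The reference curation step restricts candidate family members to the
#' family's plausible size range (default 300-400 aa for bile salt
#' hydrolases); both bounds are inclusive.
#'
#' @param records a [protein_records] collection.
#' @param min_aa,max_aa inclusive bounds in amino acids.
#' @return the retained subset, same class.
#' @export
filter_by_length <- function(records, min_aa = 300L, max_aa = 400L) {
  records <- as_protein_records(records)
  if (min_aa > max_aa) stop("min_aa must be <= max_aa")
  out <- records[records$length >= min_aa & records$length <= max_aa, ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

#' Read protein sequences from a FASTA file
#'
#' Record descriptions are kept as ids; if `parse_taxonomy = TRUE` the
#' description is interpreted as a strain name (`"Genus species strain"`) for
#' the strain fields, with the sequence id taken from the first token.
#'
#' @param path FASTA file path.
#' @param strain_id optional single strain id applied to all records (the one
#'   proteome per file layout).
#' @param parse_taxonomy parse genus/species from record names.
#' @return a [protein_records] collection.
#' @export
read_protein_fasta <- function(path, strain_id = NA_character_,
                               parse_taxonomy = FALSE) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- names(ss)
  recs <- protein_records(ids, as.character(ss), strain_id = strain_id)
  if (parse_taxonomy) {
    tax <- parse_strain_taxonomy(ids)
    recs$genus <- tax$genus
    if (all(is.na(recs$strain_id))) recs$strain_id <- tax$strain_id
  }
  recs
}

#' Write protein records to FASTA
#' @param records a [protein_records] collection.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path, width = 70L) {
  records <- as_protein_records(records)
  ss <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}
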