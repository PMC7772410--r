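#' Read a protein FASTA file into a protein table
#'
#' Each FASTA entry becomes one row. The header token before the first
#' whitespace is the locus tag (normalized to lowercase); the remainder of
#' the header line is the free-text description.
#'
#' @param path Path to a protein FASTA file.
#' @param allow_ambiguous If `TRUE`, ambiguity codes (B, Z, X, U) are
#'   tolerated in sequences; downstream physicochemical formulas exclude
#'   them from property sums. Default `FALSE`: any such residue is an error,
#'   because the property formulas are defined only over the 20 standard
#'   residues.
#' @return A `data.frame` with columns `locus_tag`, `description`,
#'   `sequence`.
#' @export
read_fasta <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) {
    return(data.frame(locus_tag = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(nonblank[1], ">")) {
    stop("malformed FASTA: first non-blank character is not '>' in ", path,
         call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  locus_tag <- tolower(sub("\\s.*$", "", headers))
  description <- trimws(sub("^\\S+\\s*", "", headers))
  sequence <- toupper(unname(as.character(aas)))
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("empty sequence body for FASTA entry '", headers[which(empty)[1]],
         "'", call. = FALSE)
  }
  if (anyDuplicated(locus_tag)) {
    stop("duplicate locus tags in ", path, ": ",
         paste(unique(locus_tag[duplicated(locus_tag)]), collapse = ", "),
         call. = FALSE)
  }
  records <- data.frame(locus_tag = locus_tag, description = description,
                        sequence = sequence, stringsAsFactors = FALSE)
  validate_protein_sequences(records$sequence, records$locus_tag,
                             allow_ambiguous = allow_ambiguous)
  records
}

#' Write a protein table to FASTA
#'
#' @param records Protein `data.frame` with `locus_tag`, `description`,
#'   `sequence` columns (as returned by [read_fasta()] or
#'   [gen_proteome()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("locus_tag", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(nzchar(desc),
                   paste(records$locus_tag, desc),
                   records$locus_tag)
  aas <- Biostrings::AAStringSet(records$sequence)
  names(aas) <- header
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}

# residue-alphabet validation shared by IO and physchem
validate_protein_sequences <- function(sequences, ids = NULL,
                                       allow_ambiguous = FALSE) {
  allowed <- if (allow_ambiguous) c(AA20, AA_AMBIGUOUS) else AA20
  pattern <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- grepl(pattern, sequences)
  if (any(bad)) {
    i <- which(bad)[1]
    offender <- regmatches(sequences[i], regexpr(pattern, sequences[i]))
    label <- if (!is.null(ids)) ids[i] else paste0("sequence ", i)
    stop("non-standard residue '", offender, "' in ", label,
         if (!allow_ambiguous) " (set allow_ambiguous = TRUE to tolerate B/Z/X/U)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Select hypothetical-protein candidates by description keywords
#'
#' Case-insensitive substring match of any keyword against the description
#' field only. The default keyword set is the conventional quartet used to
#' retrieve operome candidates from public annotation:
#' "hypothetical protein", "unknown", "uncharacterized", "putative".
#' Order of the input is preserved; the operation is idempotent.
#'
#' @param records Protein `data.frame` (see [read_fasta()]).
#' @param keywords Character vector of keywords; must be nonempty.
#' @return The subset of `records` whose description matches any keyword.
#' @export
select_hypothetical <- function(records,
                                keywords = c("hypothetical protein",
                                             "unknown",
                                             "uncharacterized",
                                             "putative")) {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    stop("keywords must be a nonempty character vector", call. = FALSE)
  }
  desc <- tolower(records$description)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    grepl(k, desc, fixed = TRUE)
  }))
  records[hit, , drop = FALSE]
}
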