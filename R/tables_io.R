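#' Normalize a locus tag
#'
#' Lowercases tags and expands bare 4-digit forms (as printed in curated
#' annotation tables) to the `mru_XXXX` form used by the source genome.
#'
#' @param x Character vector of locus tags.
#' @param prefix Prefix used to expand bare digit forms.
#' @return Normalized character vector.
#' @export
normalize_locus_tag <- function(x, prefix = "mru_") {
  x <- tolower(trimws(x))
  bare <- grepl("^[0-9]{1,4}$", x)
  x[bare] <- paste0(prefix, formatC(as.integer(x[bare]), width = 4, flag = "0"))
  x
}

#' Read a prediction-evidence table
#'
#' Expects a TSV with header columns `locus_tag`, `channel`,
#' `function_label`, `identifier`, `evalue`, `source`. An optional
#' `signal_peptide` column (0/1 or TRUE/FALSE) carries ingested
#' signal-peptide calls, and an optional `fold` column carries externally
#' assigned fold classes.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of evidence records with `evalue` numeric.
#' @export
read_evidence_table <- function(path) {
  df <- read_tsv_strict(path, c("locus_tag", "channel", "function_label",
                                "identifier", "evalue", "source"))
  bad_channel <- !(df$channel %in% EVIDENCE_CHANNELS)
  if (any(bad_channel)) {
    stop("unknown evidence channel '", df$channel[which(bad_channel)[1]],
         "' at row ", which(bad_channel)[1], " of ", basename(path),
         " (allowed: ", paste(EVIDENCE_CHANNELS, collapse = ", "), ")",
         call. = FALSE)
  }
  ev <- suppressWarnings(as.numeric(df$evalue))
  bad_ev <- is.na(ev) | ev < 0
  if (any(bad_ev)) {
    stop("unparseable or negative evalue '", df$evalue[which(bad_ev)[1]],
         "' at row ", which(bad_ev)[1], " of ", basename(path), call. = FALSE)
  }
  df$evalue <- ev
  df$locus_tag <- normalize_locus_tag(df$locus_tag)
  if ("signal_peptide" %in% names(df)) {
    df$signal_peptide <- df$signal_peptide %in% c("1", "TRUE", "true", TRUE, 1)
  }
  df
}

#' Write a prediction-evidence table
#'
#' @param evidence Evidence `data.frame` (see [read_evidence_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  out <- evidence
  out$evalue <- format(out$evalue, scientific = TRUE, digits = 6, trim = TRUE)
  write_tsv_plain(out, path)
}

#' Read a literature-evidence table
#'
#' TSV with columns `locus_tag`, `function_label`, `provenance_level`,
#' `reference`. Provenance levels follow the six-level taxonomic scale:
#' 6 = same organism, 5 = phylogenetic neighbors, 4 = methanogens,
#' 3 = archaea, 2 = bacteria, 1 = eukaryotes.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of literature records.
#' @export
read_literature_table <- function(path) {
  df <- read_tsv_strict(path, c("locus_tag", "function_label",
                                "provenance_level", "reference"))
  lv <- suppressWarnings(as.integer(df$provenance_level))
  if (any(is.na(lv) | lv < 1L | lv > 6L)) {
    bad <- which(is.na(lv) | lv < 1L | lv > 6L)[1]
    stop("provenance_level must be an integer in 1..6 (row ", bad, " of ",
         basename(path), ")", call. = FALSE)
  }
  df$provenance_level <- lv
  df$locus_tag <- normalize_locus_tag(df$locus_tag)
  df
}

#' Read a genome gene-layout table
#'
#' TSV with columns `locus_tag`, `start`, `end`, `strand` (1-based
#' inclusive coordinates, GFF3 convention). Optional columns `is_hp`
#' (0/1) and `label` are carried through for neighborhood analysis.
#' Loci are returned sorted by `start`; overlapping genes are permitted
#' but reported with a warning.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of gene loci sorted by start.
#' @export
read_gene_layout <- function(path) {
  df <- read_tsv_strict(path, c("locus_tag", "start", "end", "strand"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end))) {
    stop("non-integer coordinates in ", basename(path), call. = FALSE)
  }
  bad <- df$start > df$end
  if (any(bad)) {
    stop("start > end for locus '", df$locus_tag[which(bad)[1]], "' in ",
         basename(path), call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' in ", basename(path), call. = FALSE)
  }
  if ("is_hp" %in% names(df)) {
    df$is_hp <- df$is_hp %in% c("1", "TRUE", "true", TRUE, 1)
  } else {
    df$is_hp <- TRUE
  }
  if (!("label" %in% names(df))) df$label <- NA_character_
  df <- df[order(df$start, df$end, df$locus_tag), , drop = FALSE]
  rownames(df) <- NULL
  ov <- which(df$start[-1] <= df$end[-nrow(df)])
  if (length(ov) > 0) {
    warning("overlapping gene coordinates detected for ", length(ov),
            " adjacent pair(s) in ", basename(path), call. = FALSE)
  }
  df
}

#' Load the curated operome annotation tables
#'
#' Returns machine-readable reproductions of the curated functional
#' annotations of Methanobrevibacter ruminantium M1 hypothetical proteins:
#' cell-division proteins, transcriptional regulators, and metabolic
#' enzymes grouped by subsystem heading. Multi-locus cells are
#' pipe-separated in the files and split here into normalized tag lists.
#'
#' @param tables Which tables to load; any of `"cell_division"`,
#'   `"regulators"`, `"metabolic"`.
#' @return A `data.frame` with columns `table`, `locus_tags` (list column
#'   of normalized tags), `assigned_function`, `gene_symbol`, `ec_number`,
#'   `section_label`.
#' @export
load_annotation_tables <- function(tables = c("cell_division", "regulators",
                                              "metabolic")) {
  tables <- match.arg(tables, several.ok = TRUE)
  files <- c(cell_division = "annotation_cell_division.tsv",
             regulators = "annotation_regulators.tsv",
             metabolic = "annotation_metabolic.tsv")
  out <- lapply(tables, function(tb) {
    df <- read_tsv_strict(extdata_path(files[[tb]]),
                          c("locus_tags", "assigned_function", "gene_symbol",
                            "ec_number", "section_label"))
    df$table <- tb
    df
  })
  df <- do.call(rbind, out)
  if (any(!nzchar(trimws(df$locus_tags)))) {
    stop("annotation table row with empty locus_tags cell", call. = FALSE)
  }
  df$locus_tags <- lapply(strsplit(df$locus_tags, "|", fixed = TRUE),
                          function(x) normalize_locus_tag(x))
  validate_ec_numbers(df$ec_number)
  rownames(df) <- NULL
  df[, c("table", "locus_tags", "assigned_function", "gene_symbol",
         "ec_number", "section_label")]
}

# EC cells may hold several numbers separated by '|' or '/'; each must have
# exactly 4 dot-separated fields (dashes allowed for partial numbers)
validate_ec_numbers <- function(ec) {
  ec <- trimws(ec[!is.na(ec)])
  for (cell in ec[nzchar(ec)]) {
    parts <- trimws(unlist(strsplit(cell, "[|/]")))
    ok <- grepl("^[0-9-]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$", parts)
    if (!all(ok)) {
      stop("malformed EC number '", parts[!ok][1], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' All distinct locus tags referenced by an annotation table
#'
#' @param annotation Output of [load_annotation_tables()].
#' @return Sorted character vector of distinct normalized locus tags.
#' @export
annotation_locus_tags <- function(annotation) {
  sort(unique(unlist(annotation$locus_tags)))
}

#' Recorded headline counts for the source operome dataset
#'
#' Key printed totals about the study dataset (candidate counts, annotated
#' fraction, subsystem totals), including internally inconsistent pairs,
#' which are recorded as printed and deliberately not reconciled.
#'
#' @return A `data.frame` with columns `key`, `value`, `note`.
#' @export
dataset_notes <- function() {
  df <- read_tsv_strict(extdata_path("dataset_notes.tsv"),
                        c("key", "value", "note"))
  df$value <- as.numeric(df$value)
  df
}
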