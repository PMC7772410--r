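#' Load the subsystem vocabulary map
#'
#' Maps metabolic section headings (as used in the bundled annotation
#' tables) to the controlled subsystem codes of the study's summary
#' figure vocabulary (AAB, AAT, ACD, C1UA, CHB, CSB, CPEB, FALB, GPME,
#' INM, NNB, PMR, RR, SMD, tRR, OTR). User-extensible: pass extra rows
#' with the same two columns.
#'
#' @param extra Optional `data.frame` with columns `section_label`,
#'   `subsystem` appended to (and overriding) the bundled map.
#' @return A `data.frame` with columns `section_label`, `subsystem`.
#' @export
load_subsystem_map <- function(extra = NULL) {
  map <- read_tsv_strict(extdata_path("subsystem_map.tsv"),
                         c("section_label", "subsystem"))
  if (!is.null(extra)) {
    stopifnot(all(c("section_label", "subsystem") %in% names(extra)))
    map <- rbind(extra[, c("section_label", "subsystem")], map)
    map <- map[!duplicated(map$section_label), , drop = FALSE]
  }
  map
}

FUNCTION_CATEGORIES <- c("metabolic_enzyme", "transcriptional_regulator",
                         "transporter", "binding_protein", "cell_division",
                         "other")

#' Assign a functional category (and metabolic subsystem) to a protein
#'
#' Ordered rule list over the assigned function label and EC number:
#' an EC number wins and gives `metabolic_enzyme`; then
#' regulator/repressor/transcription-factor keywords give
#' `transcriptional_regulator`; transporter/permease/antiporter/
#' translocase keywords give `transporter`; binding keywords give
#' `binding_protein`; cell-cycle keywords give `cell_division`; anything
#' else falls back to `other`. The subsystem code is resolved from the
#' section heading through the subsystem map and only set for metabolic
#' enzymes.
#'
#' @param label Function label(s) (free text).
#' @param ec EC number cell(s) (`""` or `NA` when absent).
#' @param section_label Optional metabolic section heading(s) used to
#'   resolve the subsystem code.
#' @param subsystem_map Output of [load_subsystem_map()].
#' @return A `data.frame` with columns `category` and `subsystem`
#'   (`NA` unless the category is `metabolic_enzyme`).
#' @export
assign_category <- function(label, ec = "", section_label = NA_character_,
                            subsystem_map = load_subsystem_map()) {
  if (length(label) == 0) {
    return(data.frame(category = character(), subsystem = character(),
                      stringsAsFactors = FALSE))
  }
  n <- max(length(label), length(ec), length(section_label))
  label <- rep_len(label, n)
  ec <- rep_len(ifelse(is.na(ec), "", ec), n)
  section_label <- rep_len(section_label, n)
  low <- tolower(label)
  category <- rep("other", n)
  rules <- list(
    cell_division = "cell division|cell cycle|chromosome partition|septum|cytokinesis",
    binding_protein = "binding",
    transporter = "transporter|permease|antiporter|translocase|transport protein",
    transcriptional_regulator = "regulator|repressor|transcription factor|transcriptional activator"
  )
  # applied lowest-priority first so stronger rules overwrite weaker ones
  for (cat in names(rules)) category[grepl(rules[[cat]], low)] <- cat
  category[nzchar(trimws(ec))] <- "metabolic_enzyme"
  subsystem <- rep(NA_character_, n)
  is_met <- category == "metabolic_enzyme"
  hit <- match(section_label[is_met], subsystem_map$section_label)
  sub <- ifelse(is.na(hit), "OTR", subsystem_map$subsystem[hit])
  subsystem[is_met] <- sub
  data.frame(category = category, subsystem = subsystem,
             stringsAsFactors = FALSE)
}

#' Categorize the bundled annotation tables
#'
#' Expands the curated annotation tables to one row per locus tag and
#' assigns category and subsystem to each.
#'
#' @param annotation Output of [load_annotation_tables()].
#' @param subsystem_map Output of [load_subsystem_map()].
#' @return A `data.frame` with columns `locus_tag`, `assigned_function`,
#'   `gene_symbol`, `ec_number`, `section_label`, `table`, `category`,
#'   `subsystem`.
#' @export
categorize_annotation <- function(annotation,
                                  subsystem_map = load_subsystem_map()) {
  n_loci <- vapply(annotation$locus_tags, length, integer(1))
  flat <- data.frame(
    locus_tag = unlist(annotation$locus_tags),
    assigned_function = rep(annotation$assigned_function, n_loci),
    gene_symbol = rep(annotation$gene_symbol, n_loci),
    ec_number = rep(annotation$ec_number, n_loci),
    section_label = rep(annotation$section_label, n_loci),
    table = rep(annotation$table, n_loci),
    stringsAsFactors = FALSE
  )
  cs <- assign_category(flat$assigned_function, flat$ec_number,
                        flat$section_label, subsystem_map)
  flat$category <- cs$category
  flat$subsystem <- cs$subsystem
  flat
}

count_axis <- function(values, total = length(values)) {
  if (length(values) == 0 || total == 0) {
    return(data.frame(level = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  tab <- table(values, useNA = "no")
  df <- data.frame(level = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$percent <- round(100 * df$count / total, 1)
  df <- df[order(-df$count, df$level), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarize functional assignments
#'
#' Per-axis counts and percentages (rounded to 1 decimal) over the
#' functional-category, subsystem, fold and transmembrane-topology axes,
#' ordered by descending count then label, plus overall totals. When
#' `n_candidates` is given, the summary also reports the annotated
#' fraction of the candidate set as a percentage (e.g. 257 assignments
#' of 756 candidates report 34.0).
#'
#' @param assignments `data.frame` with a `category` column and
#'   optionally `subsystem` and `fold` columns (e.g. from
#'   [categorize_annotation()]); one row per assigned protein.
#' @param topologies Optional topology `data.frame` (see
#'   [topology_profile()]) tallied on its `localization_class`.
#' @param n_candidates Optional size of the candidate set the
#'   assignments were drawn from.
#' @return A list of class `operome_summary` with elements `category`,
#'   `subsystem`, `fold`, `topology` (each a count/percent table) and
#'   `totals` (named list with `n_assigned`, `n_candidates`,
#'   `pct_annotated`).
#' @export
summarize_assignments <- function(assignments, topologies = NULL,
                                  n_candidates = NULL) {
  n <- if (is.null(assignments)) 0L else nrow(assignments)
  cat_axis <- count_axis(if (n > 0) assignments$category else character())
  sub_vals <- if (n > 0 && "subsystem" %in% names(assignments)) {
    assignments$subsystem[!is.na(assignments$subsystem)]
  } else character()
  fold_vals <- if (n > 0 && "fold" %in% names(assignments)) {
    assignments$fold[!is.na(assignments$fold) & nzchar(assignments$fold)]
  } else character()
  topo_vals <- if (!is.null(topologies) && nrow(topologies) > 0) {
    topologies$localization_class
  } else character()
  pct <- if (!is.null(n_candidates) && n_candidates > 0) {
    round(100 * n / n_candidates, 1)
  } else NA_real_
  structure(list(
    category = cat_axis,
    subsystem = count_axis(sub_vals),
    fold = count_axis(fold_vals),
    topology = count_axis(topo_vals),
    totals = list(n_assigned = n,
                  n_candidates = if (is.null(n_candidates)) NA_integer_
                                 else as.integer(n_candidates),
                  pct_annotated = pct)
  ), class = "operome_summary")
}

#' @export
print.operome_summary <- function(x, ...) {
  cat("Operome annotation summary\n")
  cat(sprintf("  assigned: %d", x$totals$n_assigned))
  if (!is.na(x$totals$pct_annotated)) {
    cat(sprintf(" of %d candidates (%.1f%%)", x$totals$n_candidates,
                x$totals$pct_annotated))
  }
  cat("\n")
  for (axis in c("category", "subsystem", "fold", "topology")) {
    tab <- x[[axis]]
    if (nrow(tab) == 0) next
    cat("  by ", axis, ":\n", sep = "")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-28s %4d  (%.1f%%)\n", tab$level[i], tab$count[i],
                  tab$percent[i]))
    }
  }
  invisible(x)
}
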