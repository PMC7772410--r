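#' Filter prediction evidence by e-value and DUF status
#'
#' Keeps records whose e-value does not exceed the cutoff (default 1e-5,
#' inclusive) and, when `drop_duf` is set, removes hits to domains of
#' unknown function, i.e. records whose label or identifier matches a
#' `DUF<number>` token. Input order is preserved.
#'
#' @param evidence Evidence `data.frame` (see [read_evidence_table()]).
#' @param e_cutoff Inclusive e-value cutoff (> 0).
#' @param drop_duf Remove DUF hits.
#' @return The filtered evidence `data.frame`.
#' @export
filter_evidence <- function(evidence, e_cutoff = 1e-5, drop_duf = TRUE) {
  stopifnot(e_cutoff > 0)
  keep <- evidence$evalue <= e_cutoff
  if (drop_duf) {
    duf <- grepl("\\bDUF[0-9]+\\b", evidence$function_label,
                 ignore.case = TRUE) |
      grepl("\\bDUF[0-9]+\\b", evidence$identifier, ignore.case = TRUE)
    keep <- keep & !duf
  }
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a function label to canonical form
#'
#' Casefolds, strips punctuation, sorts tokens, and applies an optional
#' synonym map (a `data.frame` with columns `variant`, `canonical`;
#' variants are matched after normalization). Deterministic; labels that
#' are empty after normalization map to `"unassigned"`.
#'
#' @param label Character vector of free-text labels.
#' @param synonyms Optional synonym map `data.frame`.
#' @return Canonical labels, same length as `label`.
#' @export
normalize_label <- function(label, synonyms = NULL) {
  canon <- vapply(label, function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    toks <- strsplit(trimws(x), " +")[[1]]
    if (length(toks) == 0 || all(!nzchar(toks))) return("unassigned")
    paste(sort(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(synonyms) && nrow(synonyms) > 0) {
    variant_canon <- normalize_label(synonyms$variant)
    target_canon <- normalize_label(synonyms$canonical)
    hit <- match(canon, variant_canon)
    canon[!is.na(hit)] <- target_canon[hit[!is.na(hit)]]
  }
  canon
}

#' Load the bundled default synonym map
#'
#' @return A `data.frame` with columns `variant`, `canonical`.
#' @export
default_synonym_map <- function() {
  read_tsv_strict(extdata_path("synonym_map_default.tsv"),
                  c("variant", "canonical"))
}

#' Prediction-agreement score for one protein
#'
#' For each canonical label in the (already filtered) evidence of one
#' protein, counts the number of distinct channels supporting it; the
#' winning label is the one with the highest channel count and the
#' prediction component equals that count (0-6; full agreement across
#' all six channels scores 6). Ties are broken by the lowest best
#' e-value, then lexicographically by label. Multiple hits within one
#' channel count once.
#'
#' @param evidence Evidence `data.frame` for one protein.
#' @param synonyms Optional synonym map for label normalization.
#' @return A list with `label` (canonical winning label) and `score`
#'   (integer 0-6). No evidence gives `label = "unassigned"`, `score = 0`.
#' @export
prediction_agreement_score <- function(evidence, synonyms = NULL) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(list(label = "unassigned", score = 0L))
  }
  canon <- normalize_label(evidence$function_label, synonyms)
  per_label <- split(seq_len(nrow(evidence)), canon)
  n_channels <- vapply(per_label, function(i) {
    length(unique(evidence$channel[i]))
  }, integer(1))
  best_e <- vapply(per_label, function(i) min(evidence$evalue[i]), numeric(1))
  labs <- names(per_label)
  ord <- order(-n_channels, best_e, labs)
  list(label = labs[ord[1]], score = as.integer(n_channels[ord[1]]))
}

#' Literature-confidence component for one protein
#'
#' The maximum taxonomic provenance level (1-6; 6 = same organism) among
#' literature records whose normalized label matches the winning
#' prediction label; 0 when none match.
#'
#' @param literature Literature `data.frame` for one protein (see
#'   [read_literature_table()]); may be `NULL` or empty.
#' @param winning_label Canonical winning label from
#'   [prediction_agreement_score()].
#' @param synonyms Optional synonym map.
#' @return Integer 0-6.
#' @export
literature_score <- function(literature, winning_label, synonyms = NULL) {
  if (is.null(literature) || nrow(literature) == 0) return(0L)
  canon <- normalize_label(literature$function_label, synonyms)
  hit <- canon == winning_label
  if (!any(hit)) return(0L)
  as.integer(max(literature$provenance_level[hit]))
}

#' Combine prediction and literature confidence components
#'
#' Combined score = prediction + literature (maximum 12). A predicted
#' function is retained only when both components reach the minimum
#' (default 3); a component below it rejects the assignment.
#'
#' @param pred Prediction component(s), integers 0-6.
#' @param lit Literature component(s), integers 0-6.
#' @param retention_min Minimum per-component score for retention.
#' @return A `data.frame` with columns `prediction_component`,
#'   `literature_component`, `combined`, `retained`.
#' @export
combined_confidence <- function(pred, lit, retention_min = 3L) {
  if (any(pred < 0 | pred > 6) || any(lit < 0 | lit > 6)) {
    stop("confidence components must lie in 0..6", call. = FALSE)
  }
  n <- max(length(pred), length(lit))
  pred <- as.integer(rep_len(pred, n))
  lit <- as.integer(rep_len(lit, n))
  data.frame(
    prediction_component = pred,
    literature_component = lit,
    combined = pred + lit,
    retained = pred >= retention_min & lit >= retention_min
  )
}

#' Score every protein in an evidence set
#'
#' Vectorized driver: filters evidence, normalizes labels, computes the
#' winning label and prediction component per protein, matches literature
#' records, and applies the retention rule. Proteins present in `records`
#' but absent from the evidence score 0 and are rejected.
#'
#' @param records Protein `data.frame` (see [read_fasta()]).
#' @param evidence Evidence `data.frame` (unfiltered; filtering applied
#'   here with `e_cutoff` / `drop_duf`).
#' @param literature Literature `data.frame`, or `NULL`.
#' @param synonyms Optional synonym map.
#' @inheritParams filter_evidence
#' @inheritParams combined_confidence
#' @return A `data.frame` with one row per protein: `locus_tag`,
#'   `winning_label`, `prediction_component`, `literature_component`,
#'   `combined`, `retained`.
#' @export
score_proteins <- function(records, evidence, literature = NULL,
                           synonyms = NULL, e_cutoff = 1e-5,
                           drop_duf = TRUE, retention_min = 3L) {
  ev <- filter_evidence(evidence, e_cutoff, drop_duf)
  tags <- records$locus_tag
  win_label <- rep("unassigned", length(tags))
  pred <- integer(length(tags))

  if (nrow(ev) > 0) {
    canon <- normalize_label(ev$function_label, synonyms)
    # distinct (locus, label, channel) triples, then channel counts per pair
    key <- paste(ev$locus_tag, canon, sep = "\r")
    trip <- !duplicated(paste(key, ev$channel, sep = "\r"))
    cnt <- tapply(ev$channel[trip], key[trip], length)
    best_e <- tapply(ev$evalue, key, min)
    pair_tag <- sub("\r.*$", "", names(cnt))
    pair_lab <- sub("^.*\r", "", names(cnt))
    ord <- order(pair_tag, -as.integer(cnt), as.numeric(best_e[names(cnt)]),
                 pair_lab)
    first <- !duplicated(pair_tag[ord])
    winners <- data.frame(locus_tag = pair_tag[ord][first],
                          label = pair_lab[ord][first],
                          score = as.integer(cnt)[ord][first],
                          stringsAsFactors = FALSE)
    hit <- match(tags, winners$locus_tag)
    got <- !is.na(hit)
    win_label[got] <- winners$label[hit[got]]
    pred[got] <- winners$score[hit[got]]
  }

  lit <- integer(length(tags))
  if (!is.null(literature) && nrow(literature) > 0) {
    lcanon <- normalize_label(literature$function_label, synonyms)
    lkey <- paste(literature$locus_tag, lcanon, sep = "\r")
    lmax <- tapply(literature$provenance_level, lkey, max)
    qkey <- paste(tags, win_label, sep = "\r")
    hit <- match(qkey, names(lmax))
    lit[!is.na(hit)] <- as.integer(lmax[hit[!is.na(hit)]])
  }

  conf <- combined_confidence(pred, lit, retention_min)
  cbind(data.frame(locus_tag = tags, winning_label = win_label,
                   stringsAsFactors = FALSE),
        conf)
}
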