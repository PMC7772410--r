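#' Run the full operome annotation pipeline
#'
#' Orchestrates the stages in order: candidate selection by keyword,
#' evidence filtering, physicochemical profiling, transmembrane topology,
#' confidence scoring with retention, functional categorization,
#' gene-neighborhood clustering, and summary. Every stage logs its
#' input/output cardinalities to stderr; results go to files only.
#' Numeric TSV columns are written with fixed 4-decimal formatting so
#' re-running on identical inputs is byte-identical.
#'
#' @param input Either a list with elements `proteome`, `evidence`,
#'   `literature`, `layout` (data frames, e.g. from [gen_dataset()]), or
#'   a named character vector of file paths with those names (FASTA for
#'   the proteome, TSV for the rest). `literature` and `layout` are
#'   optional.
#' @param out_dir Output directory; created if missing. Files written:
#'   `properties.tsv`, `topology.tsv`, `scores.tsv`, `assignments.tsv`,
#'   `clusters.tsv`, `summary.json`.
#' @param keywords Candidate-selection keywords (see
#'   [select_hypothetical()]).
#' @param e_cutoff Evidence e-value cutoff (inclusive; default 1e-5).
#' @param drop_duf Remove DUF evidence (default `TRUE`).
#' @param retention_min Minimum per-component confidence for retention
#'   (default 3).
#' @param synonyms Optional synonym map for label normalization.
#' @param tm_window,tm_threshold,tm_min_len Transmembrane-caller
#'   parameters (see [predict_tm_segments()]).
#' @param max_gap,min_size,require_same_strand Neighborhood-detector
#'   parameters (see [detect_clusters()]).
#' @param physchem Physicochemical configuration ([physchem_config()]).
#' @return Invisibly, a list with the stage outputs (`candidates`,
#'   `properties`, `topology`, `scores`, `assignments`, `clusters`,
#'   `summary`) and the written file paths.
#' @export
run_pipeline <- function(input, out_dir,
                         keywords = c("hypothetical protein", "unknown",
                                      "uncharacterized", "putative"),
                         e_cutoff = 1e-5, drop_duf = TRUE,
                         retention_min = 3L, synonyms = NULL,
                         tm_window = 19L, tm_threshold = 1.6,
                         tm_min_len = 15L,
                         max_gap = 200L, min_size = 2L,
                         require_same_strand = TRUE,
                         physchem = physchem_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_msg <- function(...) message("[operomer] ", sprintf(...))

  dat <- stage("load", load_pipeline_input(input))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  candidates <- stage("select", select_hypothetical(dat$proteome, keywords))
  log_msg("select: %d of %d proteins match candidate keywords",
          nrow(candidates), nrow(dat$proteome))

  properties <- stage("physchem", physchem_profile(candidates, physchem))
  log_msg("physchem: %d profiles computed", nrow(properties))

  sp <- NULL
  if ("signal_peptide" %in% names(dat$evidence)) {
    sp_rows <- dat$evidence[dat$evidence$signal_peptide %in% TRUE, ]
    sp <- setNames(rep(TRUE, nrow(sp_rows)), sp_rows$locus_tag)
  }
  topo <- stage("topology", topology_profile(candidates, sp, tm_window,
                                             tm_threshold, tm_min_len,
                                             physchem))
  log_msg("topology: %d membrane candidates of %d",
          sum(topo$tm_count >= 1), nrow(topo))

  scores <- stage("score", score_proteins(candidates, dat$evidence,
                                          dat$literature, synonyms,
                                          e_cutoff, drop_duf, retention_min))
  log_msg("score: %d of %d retained (prediction and literature >= %d)",
          sum(scores$retained), nrow(scores), retention_min)

  assignments <- stage("categorize", {
    ret <- scores[scores$retained, , drop = FALSE]
    cs <- assign_category(ret$winning_label)
    cbind(ret[, c("locus_tag", "winning_label")], cs)
  })
  log_msg("categorize: %d retained proteins categorized", nrow(assignments))

  clusters <- NULL
  creport <- NULL
  if (!is.null(dat$layout)) {
    clusters <- stage("neighborhood",
                      detect_clusters(dat$layout, max_gap, min_size,
                                      require_same_strand))
    creport <- cluster_report(clusters)
    log_msg("neighborhood: %d clusters over %d genes",
            nrow(creport), nrow(clusters))
  }

  summary <- stage("summarize",
                   summarize_assignments(assignments, topo,
                                         n_candidates = nrow(candidates)))

  paths <- c(properties = file.path(out_dir, "properties.tsv"),
             topology = file.path(out_dir, "topology.tsv"),
             scores = file.path(out_dir, "scores.tsv"),
             assignments = file.path(out_dir, "assignments.tsv"),
             summary = file.path(out_dir, "summary.json"))
  prop_out <- properties
  for (col in c("molecular_weight", "theoretical_pi", "instability_index",
                "aliphatic_index", "gravy")) {
    prop_out[[col]] <- fmt_num(prop_out[[col]])
  }
  write_tsv_plain(prop_out, paths[["properties"]])
  write_tsv_plain(topo, paths[["topology"]])
  write_tsv_plain(scores, paths[["scores"]])
  write_tsv_plain(assignments, paths[["assignments"]])
  if (!is.null(creport)) {
    paths[["clusters"]] <- file.path(out_dir, "clusters.tsv")
    write_tsv_plain(creport, paths[["clusters"]])
  }
  jsonlite::write_json(
    list(totals = summary$totals, category = summary$category,
         subsystem = summary$subsystem, topology = summary$topology),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(candidates = candidates, properties = properties,
                 topology = topo, scores = scores,
                 assignments = assignments, clusters = clusters,
                 cluster_report = creport, summary = summary,
                 paths = paths))
}

load_pipeline_input <- function(input) {
  if (is.character(input)) {
    if (!("proteome" %in% names(input)) || !("evidence" %in% names(input))) {
      stop("path input must name at least 'proteome' and 'evidence'",
           call. = FALSE)
    }
    list(
      proteome = read_fasta(input[["proteome"]]),
      evidence = read_evidence_table(input[["evidence"]]),
      literature = if ("literature" %in% names(input))
        read_literature_table(input[["literature"]]) else NULL,
      layout = if ("layout" %in% names(input))
        read_gene_layout(input[["layout"]]) else NULL
    )
  } else if (is.list(input)) {
    if (is.null(input$proteome) || is.null(input$evidence)) {
      stop("list input must contain 'proteome' and 'evidence'", call. = FALSE)
    }
    list(proteome = input$proteome, evidence = input$evidence,
         literature = input$literature, layout = input$layout)
  } else {
    stop("input must be a list of data frames or a named path vector",
         call. = FALSE)
  }
}
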