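#' Synthetic-data generator configuration
#'
#' Defines the simulated study conditions for end-to-end testing of the
#' annotation pipeline: a proteome of hypothetical-protein candidates,
#' six prediction channels with a controllable per-channel agreement
#' probability, literature provenance drawn over the six-level taxonomic
#' scale, log-uniform e-values, a DUF contamination fraction, and genome
#' layouts with planted gene clusters.
#'
#' Defaults emulate the source study's candidate set size (756 proteins)
#' with an even coin per prediction channel (agreement 0.5), a uniform
#' literature-level distribution over 0-6 (0 = no literature record),
#' e-values well below the 1e-5 evidence cutoff, and 5 % DUF hits.
#'
#' @param n_proteins Number of candidate proteins.
#' @param seed Integer seed; mandatory for every stochastic call.
#' @param length_range Uniform residue-length bounds.
#' @param composition Named residue-probability vector over the 20
#'   standard residues; `NULL` = uniform.
#' @param keyword_fraction Fraction of descriptions carrying a
#'   hypothetical-protein keyword.
#' @param channel_agreement Probability that each channel reports the
#'   planted label (vs a decoy).
#' @param literature_level_probs Probabilities over literature levels
#'   0..6 (level 0 = no record); must sum to 1.
#' @param evalue_range Log-uniform e-value bounds for evidence records.
#' @param fraction_duf Probability that a record gets a DUF identifier.
#' @param decoy_mode `"distinct"` (decoys unique per protein and channel,
#'   so planted truth is unambiguous) or `"colliding"` (decoys drawn from
#'   a small shared pool, for stress tests).
#' @param evalue_signal If `TRUE`, true-label records draw from the lower
#'   e-value decade (for tie-break testing); by default e-values are
#'   independent of correctness.
#' @param e_cutoff_ref Reference e-value cutoff used to compute the
#'   realized supporting-channel count in the truth table.
#' @param cluster_spec Two-column `data.frame` (`size`, `gap`) of planted
#'   gene clusters for [gen_genome_layout()].
#' @param intercluster_gap Separation (bp) between planted clusters;
#'   must exceed the cluster-detection gap to keep clusters distinct.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 756L, seed = 1L,
                             length_range = c(60L, 400L),
                             composition = NULL,
                             keyword_fraction = 1,
                             channel_agreement = 0.5,
                             literature_level_probs = rep(1 / 7, 7),
                             evalue_range = c(1e-20, 1e-8),
                             fraction_duf = 0.05,
                             decoy_mode = c("distinct", "colliding"),
                             evalue_signal = FALSE,
                             e_cutoff_ref = 1e-5,
                             cluster_spec = data.frame(
                               size = c(5L, 4L, 5L, 6L, 4L, 8L),
                               gap = 50L),
                             intercluster_gap = 5000L) {
  stopifnot(n_proteins >= 1, length_range[1] >= 2,
            length_range[1] <= length_range[2],
            keyword_fraction >= 0, keyword_fraction <= 1,
            channel_agreement >= 0, channel_agreement <= 1,
            fraction_duf >= 0, fraction_duf <= 1,
            evalue_range[1] > 0, evalue_range[1] <= evalue_range[2])
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (abs(sum(literature_level_probs) - 1) > 1e-8 ||
      length(literature_level_probs) != 7) {
    stop("literature_level_probs must be 7 probabilities (levels 0..6) summing to 1",
         call. = FALSE)
  }
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(all(AA20 %in% names(composition)))
  structure(list(
    n_proteins = as.integer(n_proteins), seed = as.integer(seed),
    length_range = as.integer(length_range),
    composition = composition[AA20] / sum(composition[AA20]),
    keyword_fraction = keyword_fraction,
    channel_agreement = channel_agreement,
    literature_level_probs = literature_level_probs,
    evalue_range = evalue_range, fraction_duf = fraction_duf,
    decoy_mode = match.arg(decoy_mode), evalue_signal = evalue_signal,
    e_cutoff_ref = e_cutoff_ref, cluster_spec = cluster_spec,
    intercluster_gap = as.integer(intercluster_gap)
  ), class = "generator_config")
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# the planted label is a pure function of the locus tag so every
# generator stage agrees on it without shared state
planted_label <- function(locus_tag) {
  if (length(locus_tag) == 0) return(character(0))
  paste("planted function", locus_tag)
}

#' Generate a synthetic candidate proteome
#'
#' Residue-i.i.d. sequences drawn from the configured composition, with
#' hypothetical-protein keywords in a configurable fraction of the
#' descriptions. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return Protein `data.frame` (`locus_tag`, `description`, `sequence`).
#' @export
gen_proteome <- function(config) {
  with_seed(config$seed + 1L, {
    n <- config$n_proteins
    tags <- sprintf("syn_%04d", seq_len(n))
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = config$composition),
            collapse = "")
    }, character(1))
    kw <- c("hypothetical protein", "uncharacterized protein",
            "unknown function protein", "putative protein")
    is_hp <- runif(n) < config$keyword_fraction
    desc <- ifelse(is_hp,
                   sample(kw, n, replace = TRUE),
                   "annotated enzyme of known function")
    data.frame(locus_tag = tags, description = desc, sequence = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic prediction evidence with a planted truth table
#'
#' Each protein gets a planted true label; each of the six channels
#' independently reports it with probability `channel_agreement`, else a
#' decoy label. E-values are log-uniform within the configured bounds;
#' a `fraction_duf` share of records receive DUF identifiers. The truth
#' table records the planted label and the realized supporting-channel
#' count, i.e. the number of channels whose true-label record survives
#' the reference evidence filter (e-value cutoff + DUF removal).
#'
#' @param proteome Output of [gen_proteome()].
#' @param config A [generator_config()].
#' @return A list with `evidence` (evidence `data.frame`) and `truth`
#'   (`locus_tag`, `planted_label`, `n_support`).
#' @export
gen_evidence <- function(proteome, config) {
  with_seed(config$seed + 2L, {
    tags <- proteome$locus_tag
    n <- length(tags)
    k <- length(EVIDENCE_CHANNELS)
    locus <- rep(tags, each = k)
    channel <- rep(EVIDENCE_CHANNELS, times = n)
    reports_true <- runif(n * k) < config$channel_agreement
    truth_lab <- planted_label(locus)
    decoy <- if (config$decoy_mode == "distinct") {
      paste("decoy", locus, channel)
    } else {
      paste("shared decoy", sample(1:5, n * k, replace = TRUE))
    }
    label <- ifelse(reports_true, truth_lab, decoy)
    lo <- log10(config$evalue_range[1]); hi <- log10(config$evalue_range[2])
    ev <- 10^runif(n * k, lo, hi)
    if (config$evalue_signal) {
      ev[reports_true] <- 10^runif(sum(reports_true), lo, lo + 1)
    }
    is_duf <- runif(n * k) < config$fraction_duf
    identifier <- ifelse(is_duf,
                         sprintf("DUF%04d", sample(1000:9999, n * k, replace = TRUE)),
                         sprintf("SYN%05d", seq_len(n * k)))
    evidence <- data.frame(
      locus_tag = locus, channel = channel, function_label = label,
      identifier = identifier, evalue = ev,
      source = paste0("sim_", channel), stringsAsFactors = FALSE
    )
    survives <- reports_true & !is_duf & ev <= config$e_cutoff_ref
    n_support <- as.integer(tapply(survives, factor(locus, levels = tags), sum))
    truth <- data.frame(locus_tag = tags,
                        planted_label = planted_label(tags),
                        n_support = n_support, stringsAsFactors = FALSE)
    list(evidence = evidence, truth = truth)
  })
}

#' Generate synthetic literature evidence
#'
#' Each protein draws a literature level from the configured distribution
#' over 0..6; level 0 produces no record, any other level produces one
#' record for the planted label at that provenance level.
#'
#' @param proteome Output of [gen_proteome()].
#' @param config A [generator_config()].
#' @return A list with `literature` (literature `data.frame`) and
#'   `levels` (named integer vector of drawn levels, 0 = no record).
#' @export
gen_literature <- function(proteome, config) {
  with_seed(config$seed + 3L, {
    tags <- proteome$locus_tag
    lv <- sample(0:6, length(tags), replace = TRUE,
                 prob = config$literature_level_probs)
    has <- lv > 0
    literature <- data.frame(
      locus_tag = tags[has],
      function_label = planted_label(tags[has]),
      provenance_level = lv[has],
      reference = sprintf("simref_%s", tags[has]),
      stringsAsFactors = FALSE
    )
    list(literature = literature, levels = setNames(as.integer(lv), tags))
  })
}

#' Generate a synthetic genome layout with planted gene clusters
#'
#' Plants the clusters given in `cluster_spec` (same-strand HP genes with
#' intra-cluster gaps at the specified value) separated by more than the
#' detection gap, with one known-function filler gene in each separation.
#'
#' @param config A [generator_config()].
#' @return A gene-layout `data.frame` with planted cluster memberships in
#'   the `label` column (`"cluster_<i>"`) and fillers labelled `NA`.
#' @export
gen_genome_layout <- function(config) {
  spec <- config$cluster_spec
  if (nrow(spec) == 0) {
    return(data.frame(locus_tag = character(), start = integer(),
                      end = integer(), strand = character(),
                      is_hp = logical(), label = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(spec$gap >= config$intercluster_gap)) {
    stop("generation error: intra-cluster gap must be smaller than the ",
         "inter-cluster separation", call. = FALSE)
  }
  with_seed(config$seed + 4L, {
    rows <- list()
    pos <- 1L
    gi <- 0L
    for (ci in seq_len(nrow(spec))) {
      strand <- sample(c("+", "-"), 1)
      for (j in seq_len(spec$size[ci])) {
        glen <- sample(300:1200, 1)
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          locus_tag = sprintf("sgl_%04d", gi), start = pos,
          end = pos + glen - 1L, strand = strand, is_hp = TRUE,
          label = sprintf("cluster_%d", ci), stringsAsFactors = FALSE)
        pos <- pos + glen + spec$gap[ci]
      }
      # known-function filler inside the separation region
      pos <- pos + config$intercluster_gap
      glen <- sample(300:1200, 1)
      gi <- gi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        locus_tag = sprintf("sgl_%04d", gi), start = pos,
        end = pos + glen - 1L, strand = "+", is_hp = FALSE,
        label = NA_character_, stringsAsFactors = FALSE)
      pos <- pos + glen + config$intercluster_gap
    }
    layout <- do.call(rbind, rows)
    if (any(layout$start[-1] <= layout$end[-nrow(layout)])) {
      stop("generation error: planted gene spans overlap", call. = FALSE)
    }
    layout
  })
}

#' Generate and optionally write a full synthetic input bundle
#'
#' Produces the proteome FASTA, evidence TSV, literature TSV, genome
#' layout TSV and planted-truth TSV that the pipeline consumes.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; created if missing. When given,
#'   files `proteome.fasta`, `evidence.tsv`, `literature.tsv`,
#'   `layout.tsv`, `truth.tsv` are written there.
#' @return A list with elements `proteome`, `evidence`, `truth`,
#'   `literature`, `literature_levels`, `layout`, and `paths` (named
#'   file paths when `dir` was given).
#' @export
gen_dataset <- function(config, dir = NULL) {
  proteome <- gen_proteome(config)
  ev <- gen_evidence(proteome, config)
  lit <- gen_literature(proteome, config)
  layout <- gen_genome_layout(config)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(proteome = file.path(dir, "proteome.fasta"),
               evidence = file.path(dir, "evidence.tsv"),
               literature = file.path(dir, "literature.tsv"),
               layout = file.path(dir, "layout.tsv"),
               truth = file.path(dir, "truth.tsv"))
    write_fasta(proteome, paths[["proteome"]])
    write_evidence_table(ev$evidence, paths[["evidence"]])
    write_tsv_plain(lit$literature, paths[["literature"]])
    write_tsv_plain(layout, paths[["layout"]])
    write_tsv_plain(ev$truth, paths[["truth"]])
  }
  list(proteome = proteome, evidence = ev$evidence, truth = ev$truth,
       literature = lit$literature, literature_levels = lit$levels,
       layout = layout, paths = paths)
}
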