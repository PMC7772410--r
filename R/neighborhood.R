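#' Detect operon-like gene clusters
#'
#' Single linear scan over start-sorted loci. A growing cluster of
#' hypothetical-protein (HP) genes breaks when the intergenic gap to the
#' next HP gene exceeds `max_gap`, when the strand changes (if
#' `require_same_strand`), or when a non-HP gene intervenes (if
#' `break_on_non_hp`). Clusters smaller than `min_size` are discarded.
#' Clusters are disjoint and cover only HP genes. Defaults (gap 200 bp,
#' minimum 2 genes, same strand) are typical prokaryotic operon
#' heuristics.
#'
#' @param loci Gene-layout `data.frame` (see [read_gene_layout()]); must
#'   have columns `locus_tag`, `start`, `end`, `strand`, and optionally
#'   `is_hp` (default all `TRUE`) and `label`.
#' @param max_gap Maximum intergenic gap in bp (`next start - previous
#'   end - 1`).
#' @param min_size Minimum number of genes per cluster (>= 2).
#' @param require_same_strand Break clusters on strand change.
#' @param break_on_non_hp Break clusters when a non-HP gene intervenes.
#' @return A `data.frame` with one row per clustered gene: `cluster_id`,
#'   `locus_tag`, `start`, `end`, `strand`, `label`; zero rows when
#'   nothing clusters.
#' @export
detect_clusters <- function(loci, max_gap = 200L, min_size = 2L,
                            require_same_strand = TRUE,
                            break_on_non_hp = TRUE) {
  stopifnot(max_gap >= 0, min_size >= 2)
  if (!("is_hp" %in% names(loci))) loci$is_hp <- TRUE
  if (!("label" %in% names(loci))) loci$label <- NA_character_
  loci <- loci[order(loci$start, loci$end, loci$locus_tag), , drop = FALSE]
  rownames(loci) <- NULL

  out <- list()
  current <- integer(0)  # row indices of the growing cluster
  cluster_id <- 0L
  flush <- function() {
    if (length(current) >= min_size) {
      cluster_id <<- cluster_id + 1L
      out[[cluster_id]] <<- cbind(data.frame(cluster_id = cluster_id),
                                  loci[current, c("locus_tag", "start", "end",
                                                  "strand", "label")])
    }
    current <<- integer(0)
  }
  for (i in seq_len(nrow(loci))) {
    if (!loci$is_hp[i]) {
      if (break_on_non_hp) flush()
      next
    }
    if (length(current) > 0) {
      prev <- current[length(current)]
      gap <- loci$start[i] - loci$end[prev] - 1L
      strand_break <- require_same_strand && loci$strand[i] != loci$strand[prev]
      if (gap > max_gap || strand_break) flush()
    }
    current <- c(current, i)
  }
  flush()
  if (length(out) == 0) {
    return(data.frame(cluster_id = integer(), locus_tag = character(),
                      start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label a gene cluster by its dominant member label
#'
#' The most frequent member label wins; ties go to the earliest tied
#' label by coordinate; clusters whose members are all unlabeled get
#' `"unlabeled"`.
#'
#' @param members Cluster member `data.frame` (rows of one `cluster_id`
#'   from [detect_clusters()]), sorted by start.
#' @return The cluster label (scalar character).
#' @export
label_cluster <- function(members) {
  labs <- members$label[!is.na(members$label) & nzchar(members$label)]
  if (length(labs) == 0) return("unlabeled")
  counts <- table(labs)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  # tie: first tied label in coordinate order
  labs[labs %in% top][1]
}

#' Cluster report table
#'
#' One row per detected cluster: id, dominant label, size, members
#' (comma-joined tags in coordinate order) and genomic span.
#'
#' @param clusters Output of [detect_clusters()].
#' @return A `data.frame` with columns `cluster_id`, `label`, `n_genes`,
#'   `members`, `span_start`, `span_end`.
#' @export
cluster_report <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(data.frame(cluster_id = integer(), label = character(),
                      n_genes = integer(), members = character(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- sort(unique(clusters$cluster_id))
  rows <- lapply(ids, function(id) {
    m <- clusters[clusters$cluster_id == id, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    data.frame(cluster_id = id, label = label_cluster(m),
               n_genes = nrow(m),
               members = paste(m$locus_tag, collapse = ","),
               span_start = min(m$start), span_end = max(m$end),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Load the bundled synthetic operon-layout fixture
#'
#' A synthetic genome layout realizing six operon-like gene arrangements
#' (32 HP genes in total, labelled hsp, TRAM, dsr, cbs, anti-toxin and
#' cas, flanked by known-function genes). Coordinates are synthetic: the
#' study genome's printed record states the cluster structure but no
#' coordinates, so this fixture realizes that structure with plausible
#' gene sizes and spacings.
#'
#' @return A gene-layout `data.frame` (see [read_gene_layout()]).
#' @export
load_operon_layout_fixture <- function() {
  read_gene_layout(extdata_path("gene_layout_operons_synthetic.tsv"))
}
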