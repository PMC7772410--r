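#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Computes the mean Kyte-Doolittle hydropathy in a sliding window at
#' every full-window center, takes maximal runs of centers whose mean
#' exceeds the threshold, extends each run to the window bounds, merges
#' overlapping extensions, and keeps segments at least `min_len` residues
#' long. Defaults are the classic Kyte-Doolittle transmembrane heuristics
#' (window 19, threshold 1.6, minimum length 15).
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width >= 5.
#' @param threshold Mean-hydropathy threshold a window center must exceed.
#' @param min_len Minimum segment length in residues.
#' @param config A [physchem_config()] supplying the hydropathy scale.
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive);
#'   zero rows when no segment is found. Sequences shorter than the window
#'   yield an empty result with a warning.
#' @export
predict_tm_segments <- function(sequence, window = 19L, threshold = 1.6,
                                min_len = 15L, config = physchem_config()) {
  if (window %% 2 != 1 || window < 5) {
    stop("window must be an odd integer >= 5", call. = FALSE)
  }
  res <- split_residues(sequence)
  L <- length(res)
  empty <- data.frame(start = integer(), end = integer())
  if (L < window) {
    warning("sequence shorter than window (", L, " < ", window,
            "); no transmembrane call made", call. = FALSE)
    return(empty)
  }
  h <- as.numeric(config$hydropathy[res])
  half <- (window - 1L) %/% 2L
  # rolling mean over all full windows; center positions half+1 .. L-half
  cs <- c(0, cumsum(h))
  wmean <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
  centers <- seq.int(half + 1L, L - half)
  above <- wmean > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- which(r$values)
  seg <- data.frame(start = centers[starts_idx[runs]] - half,
                    end = centers[ends_idx[runs]] + half)
  # merge overlapping/adjacent extended runs
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg$start[i] <= merged$end[last] + 1L) {
        merged$end[last] <- max(merged$end[last], seg$end[i])
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Classify coarse subcellular localization
#'
#' Rule-based classifier over a topology profile: membrane if at least one
#' transmembrane segment; secreted if a signal peptide was ingested as
#' evidence and there is no transmembrane segment; otherwise cytoplasmic.
#' Signal peptides are ingested evidence (an optional evidence-table
#' column), never predicted here.
#'
#' @param tm_count Number of transmembrane segments.
#' @param signal_peptide Logical; ingested signal-peptide call.
#' @return `"membrane"`, `"secreted"` or `"cytoplasmic"` (vectorized).
#' @export
classify_localization <- function(tm_count, signal_peptide = FALSE) {
  n <- max(length(tm_count), length(signal_peptide))
  tm_count <- rep_len(tm_count, n)
  signal_peptide <- rep_len(signal_peptide, n)
  ifelse(tm_count >= 1, "membrane",
         ifelse(signal_peptide, "secreted", "cytoplasmic"))
}

#' Batch topology profile
#'
#' @param records Protein `data.frame` (see [read_fasta()]).
#' @param signal_peptides Named logical vector of ingested signal-peptide
#'   calls (names = locus tags); missing tags default to `FALSE`.
#' @inheritParams predict_tm_segments
#' @return A `data.frame` with columns `locus_tag`, `tm_count`,
#'   `tm_segments` (intervals formatted `"s-e;s-e"`), `signal_peptide`,
#'   `localization_class`.
#' @export
topology_profile <- function(records, signal_peptides = NULL,
                             window = 19L, threshold = 1.6, min_len = 15L,
                             config = physchem_config()) {
  segs <- lapply(records$sequence, function(s) {
    suppressWarnings(predict_tm_segments(s, window, threshold, min_len, config))
  })
  tm_count <- vapply(segs, nrow, integer(1))
  sp <- rep(FALSE, nrow(records))
  if (!is.null(signal_peptides)) {
    hit <- match(records$locus_tag, names(signal_peptides))
    sp[!is.na(hit)] <- as.logical(signal_peptides[hit[!is.na(hit)]])
  }
  data.frame(
    locus_tag = records$locus_tag,
    tm_count = tm_count,
    tm_segments = vapply(segs, function(s) {
      if (nrow(s) == 0) "" else paste(sprintf("%d-%d", s$start, s$end),
                                      collapse = ";")
    }, character(1)),
    signal_peptide = sp,
    localization_class = classify_localization(tm_count, sp),
    stringsAsFactors = FALSE
  )
}
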