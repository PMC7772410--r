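#' Combine per-source evidence probabilities (noisy-OR)
#'
#' The evolutionary-trace confidence for a query protein combines the
#' per-source probabilities that a domain carries function f as
#' S(f) = 1 - prod(1 - s_i). An empty list combines to 0; the combined
#' value never falls below any individual source.
#'
#' @param scores Numeric vector of probabilities in \[0, 1\].
#' @return Combined probability in \[0, 1\].
#' @export
sifter_combine <- function(scores) {
  if (length(scores) == 0) return(0)
  if (any(scores < 0 | scores > 1)) {
    stop("evidence probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - scores)
}

#' Composite structural-model quality score
#'
#' Linear combination of the five component scores of a homology model:
#' torsion (3-residue), pairwise C-beta/SSE, solvation C-beta, secondary
#' structure agreement, and solvent accessibility agreement. The default
#' coefficients (0.3, 0.17, 0.7, 80, 45) follow the composite-score
#' definition used in this annotation procedure; they differ from the
#' coefficients of the original QMEAN publication (Benkert et al. 2008),
#' so alternative weights can be supplied via `coefficients`.
#'
#' @param torsion,pairwise,solvation,sse,acc The five component scores;
#'   all must be finite.
#' @param coefficients Named numeric vector of weights with elements
#'   `torsion`, `pairwise`, `solvation`, `sse`, `acc`.
#' @return The composite score.
#' @export
qmean5 <- function(torsion, pairwise, solvation, sse, acc,
                   coefficients = c(torsion = 0.3, pairwise = 0.17,
                                    solvation = 0.7, sse = 80, acc = 45)) {
  comps <- c(torsion = torsion, pairwise = pairwise, solvation = solvation,
             sse = sse, acc = acc)
  if (any(!is.finite(comps))) {
    stop("all five model-score components must be finite", call. = FALSE)
  }
  needed <- c("torsion", "pairwise", "solvation", "sse", "acc")
  if (!all(needed %in% names(coefficients))) {
    stop("coefficients must name torsion, pairwise, solvation, sse, acc",
         call. = FALSE)
  }
  sum(coefficients[needed] * comps[needed])
}

#' Quality-weighted average of model GDT_TS scores
#'
#' S = sum_i(GDT_TS_i * QMEAN_i) / sum_i(QMEAN_i): candidate homology
#' models are averaged with their composite quality as weight.
#'
#' @param gdt_ts Numeric vector of per-model GDT_TS scores.
#' @param qmean Numeric vector of per-model composite quality weights,
#'   same length, with a nonzero sum.
#' @return The weighted average.
#' @export
weighted_model_average <- function(gdt_ts, qmean) {
  if (length(gdt_ts) == 0 || length(gdt_ts) != length(qmean)) {
    stop("gdt_ts and qmean must be equal-length nonempty vectors",
         call. = FALSE)
  }
  if (sum(qmean) == 0) {
    stop("degenerate input: model quality weights sum to zero", call. = FALSE)
  }
  sum(gdt_ts * qmean) / sum(qmean)
}
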