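#' Physicochemical configuration
#'
#' Bundles the constant tables behind the sequence-derived property
#' formulas: the 400-entry Guruprasad dipeptide instability weight table
#' (DIWV), the Kyte-Doolittle hydropathy scale, average residue masses,
#' the EMBOSS pKa set for the theoretical pI, the aliphatic-index
#' coefficients (Ikai's a = 2.9 for Val, b = 3.9 for Ile + Leu), and the
#' instability-index stability threshold (40).
#'
#' @param aliphatic_a Coefficient for the Val mole percent.
#' @param aliphatic_b Coefficient for the Ile + Leu mole percent.
#' @param stability_threshold Instability-index boundary; values strictly
#'   below it classify as stable, values at or above as unstable.
#' @return A list of class `physchem_config`.
#' @export
physchem_config <- function(aliphatic_a = 2.9, aliphatic_b = 3.9,
                            stability_threshold = 40) {
  stopifnot(aliphatic_a > 0, aliphatic_b > 0)
  diwv_df <- read_tsv_strict(extdata_path("diwv_guruprasad.tsv"),
                             c("dipeptide", "weight"))
  if (nrow(diwv_df) != 400L || anyDuplicated(diwv_df$dipeptide)) {
    stop("DIWV table must cover exactly the 400 standard dipeptides",
         call. = FALSE)
  }
  kd_df <- read_tsv_strict(extdata_path("kyte_doolittle.tsv"),
                           c("residue", "hydropathy"))
  mass_df <- read_tsv_strict(extdata_path("residue_masses.tsv"),
                             c("residue", "avg_mass"))
  pka_df <- read_tsv_strict(extdata_path("pka_emboss.tsv"),
                            c("group", "pka", "charge"))
  structure(list(
    diwv = setNames(as.numeric(diwv_df$weight), diwv_df$dipeptide),
    hydropathy = setNames(as.numeric(kd_df$hydropathy), kd_df$residue),
    masses = setNames(as.numeric(mass_df$avg_mass), mass_df$residue),
    pka = pka_df,
    water_mass = 18.0153,
    aliphatic_a = aliphatic_a,
    aliphatic_b = aliphatic_b,
    stability_threshold = stability_threshold
  ), class = "physchem_config")
}

split_residues <- function(sequence, permissive = FALSE) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (permissive) {
    res <- res[res %in% AA20]
  } else {
    validate_protein_sequences(sequence)
  }
  res
}

#' Instability index (II)
#'
#' II = (10 / L) * sum of dipeptide instability weights DIWV over the
#' L - 1 overlapping dipeptides of the sequence.
#'
#' @param sequence Amino-acid string, length >= 2.
#' @param config A [physchem_config()].
#' @param permissive Drop ambiguity codes instead of erroring.
#' @return The instability index.
#' @export
instability_index <- function(sequence, config = physchem_config(),
                              permissive = FALSE) {
  res <- split_residues(sequence, permissive)
  L <- length(res)
  if (L < 2) {
    stop("instability index undefined for sequences shorter than 2 residues",
         call. = FALSE)
  }
  dipep <- paste0(res[-L], res[-1])
  (10 / L) * sum(config$diwv[dipep])
}

#' Classify protein stability from the instability index
#'
#' Stable iff II is strictly below the threshold (default 40); values at
#' or above the threshold classify as unstable.
#'
#' @param ii Instability index value(s); must be finite.
#' @param config A [physchem_config()].
#' @return Character vector, `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(ii, config = physchem_config()) {
  if (any(!is.finite(ii))) stop("instability index must be finite", call. = FALSE)
  ifelse(ii < config$stability_threshold, "stable", "unstable")
}

#' Aliphatic index
#'
#' X(Ala) + a * X(Val) + b * (X(Ile) + X(Leu)) with X in mole percent
#' (100 * mole fraction) over the full sequence length.
#'
#' @inheritParams instability_index
#' @return The aliphatic index (>= 0).
#' @export
aliphatic_index <- function(sequence, config = physchem_config(),
                            permissive = FALSE) {
  res <- split_residues(sequence, permissive)
  if (length(res) == 0) stop("empty sequence", call. = FALSE)
  mp <- function(aa) 100 * sum(res == aa) / length(res)
  mp("A") + config$aliphatic_a * mp("V") +
    config$aliphatic_b * (mp("I") + mp("L"))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Sum of the Kyte-Doolittle hydropathy values of all residues divided by
#' the number of residues.
#'
#' @inheritParams instability_index
#' @return Mean hydropathy.
#' @export
gravy <- function(sequence, config = physchem_config(), permissive = FALSE) {
  res <- split_residues(sequence, permissive)
  if (length(res) == 0) stop("empty sequence", call. = FALSE)
  mean(config$hydropathy[res])
}

#' Molecular weight (average mass, daltons)
#'
#' Sum of average residue masses plus one water mass for the free termini.
#'
#' @inheritParams instability_index
#' @return Mass in daltons.
#' @export
molecular_weight <- function(sequence, config = physchem_config(),
                             permissive = FALSE) {
  res <- split_residues(sequence, permissive)
  if (length(res) == 0) stop("empty sequence", call. = FALSE)
  sum(config$masses[res]) + config$water_mass
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over the termini and ionizable side chains with
#' the configured pKa set. Strictly decreasing in pH, which guarantees a
#' unique isoelectric point.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s).
#' @inheritParams instability_index
#' @return Net charge at each pH.
#' @export
net_charge <- function(sequence, pH, config = physchem_config(),
                       permissive = FALSE) {
  res <- split_residues(sequence, permissive)
  if (length(res) == 0) stop("empty sequence", call. = FALSE)
  counts <- c(table(res))
  vapply(pH, function(p) {
    q <- 0
    for (i in seq_len(nrow(config$pka))) {
      grp <- config$pka$group[i]
      pka <- config$pka$pka[i]
      n <- if (grp == "Nterm" || grp == "Cterm") 1 else
        if (grp %in% names(counts)) counts[[grp]] else 0
      if (n == 0) next
      if (config$pka$charge[i] == "positive") {
        q <- q + n / (1 + 10^(p - pka))
      } else {
        q <- q - n / (1 + 10^(pka - p))
      }
    }
    q
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the net charge is zero, found by bisection on the
#' 0-14 pH range to a tolerance of 1e-4 pH units.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
theoretical_pi <- function(sequence, config = physchem_config(),
                           permissive = FALSE) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, config, permissive)
  f_hi <- net_charge(sequence, hi, config, permissive)
  if (f_lo <= 0) return(lo)
  if (f_hi >= 0) return(hi)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, config, permissive) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Batch physicochemical profile
#'
#' Computes molecular weight, theoretical pI, instability index,
#' aliphatic index, GRAVY and the stability class for every protein in a
#' table. Values are retained at full precision; writers round to 2
#' decimals for reporting.
#'
#' @param records Protein `data.frame` (see [read_fasta()]).
#' @inheritParams instability_index
#' @return A `data.frame` with one row per protein.
#' @export
physchem_profile <- function(records, config = physchem_config(),
                             permissive = FALSE) {
  ii <- vapply(records$sequence, instability_index, numeric(1),
               config = config, permissive = permissive, USE.NAMES = FALSE)
  data.frame(
    locus_tag = records$locus_tag,
    molecular_weight = vapply(records$sequence, molecular_weight, numeric(1),
                              config = config, permissive = permissive,
                              USE.NAMES = FALSE),
    theoretical_pi = vapply(records$sequence, theoretical_pi, numeric(1),
                            config = config, permissive = permissive,
                            USE.NAMES = FALSE),
    instability_index = ii,
    aliphatic_index = vapply(records$sequence, aliphatic_index, numeric(1),
                             config = config, permissive = permissive,
                             USE.NAMES = FALSE),
    gravy = vapply(records$sequence, gravy, numeric(1),
                   config = config, permissive = permissive,
                   USE.NAMES = FALSE),
    stability_class = classify_stability(ii, config),
    stringsAsFactors = FALSE
  )
}
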