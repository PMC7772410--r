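# independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations

oracle_instability <- function(sequence, config) {
  res <- strsplit(sequence, "")[[1]]
  total <- 0
  for (i in seq_len(length(res) - 1)) {
    total <- total + config$diwv[[paste0(res[i], res[i + 1])]]
  }
  (10 / length(res)) * total
}

oracle_gravy <- function(sequence, config) {
  res <- strsplit(sequence, "")[[1]]
  total <- 0
  for (r in res) total <- total + config$hydropathy[[r]]
  total / length(res)
}

oracle_mw <- function(sequence, config) {
  res <- strsplit(sequence, "")[[1]]
  total <- config$water_mass
  for (r in res) total <- total + config$masses[[r]]
  total
}

oracle_aliphatic <- function(sequence, config) {
  res <- strsplit(sequence, "")[[1]]
  x <- function(aa) 100 * sum(res == aa) / length(res)
  x("A") + config$aliphatic_a * x("V") +
    config$aliphatic_b * (x("I") + x("L"))
}

# dense grid scan for the isoelectric point: finest pH with charge >= 0
oracle_pi_grid <- function(sequence, config, step = 0.001) {
  grid <- seq(0, 14, by = step)
  q <- operomer::net_charge(sequence, grid, config)
  if (q[1] <= 0) return(0)
  if (q[length(q)] >= 0) return(14)
  i <- max(which(q > 0))
  (grid[i] + grid[i + 1]) / 2
}

# inclusion-exclusion expansion of P(union of independent events)
oracle_sifter <- function(scores) {
  k <- length(scores)
  if (k == 0) return(0)
  total <- 0
  for (m in 1:k) {
    for (subset in utils::combn(k, m, simplify = FALSE)) {
      total <- total + (-1)^(m + 1) * prod(scores[subset])
    }
  }
  total
}

# all-pairs transitive-closure clustering oracle: adjacency between
# consecutive HP genes (in full layout order) that satisfy the gap/strand
# rules with no breaking non-HP gene between them
oracle_clusters <- function(loci, max_gap = 200, min_size = 2,
                            require_same_strand = TRUE,
                            break_on_non_hp = TRUE) {
  loci <- loci[order(loci$start, loci$end, loci$locus_tag), , drop = FALSE]
  hp_idx <- which(loci$is_hp)
  m <- length(hp_idx)
  if (m == 0) return(list())
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1)) {
    b <- a + 1
    i <- hp_idx[a]; j <- hp_idx[b]
    between <- setdiff(seq(i, j), c(i, j))
    blocked <- break_on_non_hp && any(!loci$is_hp[between])
    gap_ok <- (loci$start[j] - loci$end[i] - 1) <= max_gap
    strand_ok <- !require_same_strand || loci$strand[i] == loci$strand[j]
    adj[a, b] <- adj[b, a] <- !blocked && gap_ok && strand_ok
  }
  # transitive closure by repeated boolean multiplication
  reach <- adj | diag(m)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comps <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  groups <- lapply(comps, function(s) {
    hp_idx[as.integer(strsplit(s, ",")[[1]])]
  })
  groups <- Filter(function(g) length(g) >= min_size, groups)
  lapply(groups, function(g) sort(loci$locus_tag[g]))
}

random_protein <- function(len, alphabet = c("A","C","D","E","F","G","H","I",
                                             "K","L","M","N","P","Q","R","S",
                                             "T","V","W","Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_layout <- function(n_genes, hp_prob = 0.7) {
  starts <- integer(n_genes); ends <- integer(n_genes)
  pos <- 1
  for (i in seq_len(n_genes)) {
    glen <- sample(100:600, 1)
    starts[i] <- pos
    ends[i] <- pos + glen - 1
    pos <- pos + glen + sample(0:500, 1)
  }
  data.frame(locus_tag = sprintf("rl_%03d", seq_len(n_genes)),
             start = starts, end = ends,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             is_hp = runif(n_genes) < hp_prob,
             label = sample(c("hsp", "cas", NA), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}
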