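# Independent oracles used across tests.

# Adjusted Rand index between two partitions (closed form on the
# contingency table; independent of any clustering code in the package).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sab <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maximum <- (sa + sb) / 2
  if (maximum == expected) return(1)
  (sab - expected) / (maximum - expected)
}

# Brute-force single-linkage clusters at a cutoff: connected components of
# the graph joining points at pairwise distance <= cutoff (union-find).
components_at_cutoff <- function(mat, cutoff) {
  n <- nrow(mat)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  d <- as.matrix(stats::dist(mat))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Small balanced noise-free metabolite table: `n_met` metabolites, groups
# given as data.frame(strain, batch, log_scale), optional per-strain effect
# matrix (metabolite x strain, log scale).
make_balanced_table <- function(n_met = 12, groups, effects = NULL, reps = 2) {
  mets <- sprintf("m%02d", seq_len(n_met))
  baseline <- seq(4, 8, length.out = n_met)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    for (r in seq_len(reps)) {
      eff <- if (is.null(effects)) 0 else effects[, groups$strain[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_r%d", groups$strain[g], groups$batch[g], r),
        mutant_id = groups$strain[g],
        experiment_id = groups$batch[g],
        replicate = r,
        metabolite_id = mets,
        peak_area = exp(baseline + eff + groups$log_scale[g]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
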