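# Independent brute-force reference implementations used as oracles.
# These are deliberately naive and kept separate from the package code paths.

# O(m^2) Benjamini-Hochberg step-up adjustment.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    i <- o[k]
    # smallest over j >= k of p_(j) * m / j
    cands <- vapply(k:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[i] <- min(1, min(cands))
  }
  adj
}

# Welch two-sample t statistic and p-value from the textbook formulas.
welch_naive <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Pooled-SD Cohen's d.
cohens_d_naive <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# Pearson chi-square on a 2x2 table, no continuity correction.
chisq_naive <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# All-pairs AUC with ties counted 1/2.
auc_naive <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# All amino acids reachable from a codon by exactly one nucleotide change.
snv_neighbors_naive <- function(codon) {
  gc <- nucleateR::genetic_code()
  nt <- c("A", "C", "G", "T")
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) for (b in nt) {
    if (b != s[i]) {
      x <- s; x[i] <- b
      out <- c(out, unname(gc[paste(x, collapse = "")]))
    }
  }
  unique(out)
}

# Direct double-log-ratio score (totals cancel), the scoring oracle.
score_naive <- function(c_in, c_out, ref_in, ref_out) {
  log((c_out * ref_in) / (c_in * ref_out))
}

# Random peptide sequences over the 20 canonical residues.
random_peptides <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

# Small count table with strictly positive random counts.
random_count_table <- function(n_var = 5, reps = 3, seed = 1) {
  set.seed(seed)
  ids <- c("ref", paste0("v", seq_len(n_var - 1)))
  inp <- matrix(sample(50:500, n_var * reps, replace = TRUE), n_var, reps,
                dimnames = list(ids, NULL))
  out <- matrix(sample(50:500, n_var * reps, replace = TRUE), n_var, reps,
                dimnames = list(ids, NULL))
  count_table(inp, out)
}
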