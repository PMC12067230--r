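#' Default physicochemical amino-acid class scheme
#'
#' aliphatic = A,V,L,I,M; aromatic = F,W,Y; polar = S,T,N,Q;
#' positive = K,R,H; negative = D,E; special = C,G,P. Every canonical amino
#' acid belongs to exactly one class; pass your own named vector to any
#' function accepting a `scheme` to change the grouping.
#'
#' @return Named character vector: amino acid -> class.
#' @export
aa_class_scheme <- function() {
  c(A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
    M = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    S = "polar", T = "polar", N = "polar", Q = "polar",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    C = "special", G = "special", P = "special")
}

#' Residue scales (hydropathy and beta-sheet propensity)
#'
#' Loads the per-residue scale tables shipped with the package:
#' Kyte-Doolittle hydropathy and Kanehisa-Tsong beta-sheet propensity,
#' stored as editable TSV files under `inst/extdata/`.
#'
#' @param scale `"hydropathy"` or `"beta_propensity"`.
#' @return Named numeric vector over the 20 amino acids.
#' @export
aa_scale <- function(scale = c("hydropathy", "beta_propensity")) {
  scale <- match.arg(scale)
  file <- switch(scale,
                 hydropathy = "kyte_doolittle.tsv",
                 beta_propensity = "kanehisa_tsong.tsv")
  path <- system.file("extdata", file, package = "nucleateR", mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(df$value, df$aa)
}

#' Per-sequence residue composition in percent
#'
#' @param seqs Character vector of peptide sequences (length >= 1 each).
#' @return Matrix (sequences x 20 amino acids) of percentages; each row sums
#'   to 100.
#' @export
composition_percent <- function(seqs) {
  if (any(nchar(seqs) < 1L)) stop("sequences must have length >= 1")
  m <- t(vapply(strsplit(seqs, "", fixed = TRUE), function(aa) {
    bad <- setdiff(unique(aa), AA20)
    if (length(bad)) stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
    100 * tabulate(match(aa, AA20), nbins = 20L) / length(aa)
  }, numeric(20L)))
  colnames(m) <- AA20
  m
}

#' Cohen's d standardised mean difference
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. Returns 0 when both
#' groups are constant and equal.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Per-residue composition differences between two sequence groups
#'
#' For each of the 20 amino acids, compares the per-sequence percent
#' composition of the two groups (typically nucleators vs nonnucleators) by
#' a Welch two-sample t-test, reporting the effect size (Cohen's d with
#' pooled SD) and the raw difference in mean frequency (percentage points,
#' group1 - group2).
#'
#' @param group1,group2 Character vectors of peptide sequences (>= 2 each).
#' @return A data.frame with columns `aa`, `mean1`, `mean2`, `t`, `p`,
#'   `cohens_d`, `freq_difference`.
#' @export
group_composition_test <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L)
    stop("both groups need at least 2 sequences")
  c1 <- composition_percent(group1)
  c2 <- composition_percent(group2)
  out <- do.call(rbind, lapply(AA20, function(aa) {
    x <- c1[, aa]; y <- c2[, aa]
    if (var(x) == 0 && var(y) == 0) {
      tt <- list(statistic = if (mean(x) == mean(y)) 0 else NA_real_,
                 p.value = if (mean(x) == mean(y)) 1 else NA_real_)
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
    }
    data.frame(aa = aa, mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               cohens_d = cohens_d(x, y),
               freq_difference = mean(x) - mean(y),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Position-wise amino-acid class enrichment between groups
#'
#' For each position and physicochemical class, counts sequences carrying a
#' residue of that class at the position in each group and tests the 2x2
#' contingency (group x class membership) by chi-square without continuity
#' correction. Sequences shorter than the position are excluded there; tests
#' with any expected cell below 1 are skipped.
#'
#' @param group1,group2 Character vectors of peptide sequences.
#' @param scheme Named amino acid -> class vector (default
#'   [aa_class_scheme()]).
#' @param positions Integer positions to test (default: 1 to the longest
#'   sequence).
#' @return A data.frame with columns `position`, `class`, counts
#'   (`n1_in`, `n1_out`, `n2_in`, `n2_out`), `chisq`, `p`, `stars`,
#'   `freq_difference` (proportion in group1 - group2) and `skipped`.
#' @export
positionwise_class_test <- function(group1, group2, scheme = aa_class_scheme(),
                                    positions = NULL) {
  if (is.null(positions))
    positions <- seq_len(max(nchar(c(group1, group2))))
  classes <- sort(unique(scheme))
  rows <- list()
  for (pos in positions) {
    a1 <- substr(group1[nchar(group1) >= pos], pos, pos)
    a2 <- substr(group2[nchar(group2) >= pos], pos, pos)
    if (length(a1) == 0L || length(a2) == 0L) next
    for (cl in classes) {
      in1 <- sum(scheme[a1] == cl); in2 <- sum(scheme[a2] == cl)
      tab <- matrix(c(in1, length(a1) - in1, in2, length(a2) - in2), 2L, 2L)
      skipped <- FALSE
      chisq <- p <- NA_real_
      if (sum(tab[1, ]) + sum(tab[2, ]) == 0 || in1 + in2 == 0) {
        skipped <- TRUE
      } else {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 1)) {
          skipped <- TRUE
        } else {
          ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
          chisq <- unname(ct$statistic)
          p <- ct$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, class = cl,
        n1_in = in1, n1_out = length(a1) - in1,
        n2_in = in2, n2_out = length(a2) - in2,
        chisq = chisq, p = p, stars = p_stars(p),
        freq_difference = in1 / length(a1) - in2 / length(a2),
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Class fractions per peptide length
#'
#' Stratifies a classified random-extension library by peptide length and
#' reports per-length counts and class fractions (nonnucleator, nucleator,
#' top-tier nucleator). Fractions of nucleators and nonnucleators sum to 1
#' within each length; the top tier is a subset of the nucleators.
#'
#' @param classes A data.frame with columns `sequence`, `label`, `top10`.
#' @return A data.frame with columns `length`, `n`, `frac_nonnucleator`,
#'   `frac_nucleator`, `frac_top10`.
#' @export
length_stratify <- function(classes) {
  stopifnot(all(c("sequence", "label") %in% colnames(classes)))
  if (is.null(classes$top10)) classes$top10 <- FALSE
  len <- nchar(classes$sequence)
  out <- do.call(rbind, lapply(sort(unique(len)), function(L) {
    x <- classes[len == L, ]
    data.frame(length = L, n = nrow(x),
               frac_nonnucleator = mean(x$label == "nonnucleator"),
               frac_nucleator = mean(x$label == "nucleator"),
               frac_top10 = mean(x$top10),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean residue-scale properties of peptide sequences
#'
#' Arithmetic mean of a per-residue scale (hydropathy or beta-sheet
#' propensity) over the full peptide or over the extension region only.
#'
#' @param seqs Character vector of peptide sequences.
#' @param scale Scale name passed to [aa_scale()], or a named numeric vector.
#' @param from First position included (default 1 = full peptide; 23 for the
#'   extension of a 22-residue base).
#' @return Numeric vector of per-sequence means (NA for sequences shorter
#'   than `from`).
#' @export
sequence_properties <- function(seqs, scale = "hydropathy", from = 1L) {
  if (is.character(scale) && length(scale) == 1L) scale <- aa_scale(scale)
  vapply(seqs, function(s) {
    if (nchar(s) < from) return(NA_real_)
    aa <- strsplit(substr(s, from, nchar(s)), "", fixed = TRUE)[[1]]
    mean(scale[aa])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Correlate scores of two peptides under an alignment
#'
#' Pairs per-position (or per-residue-aggregated) mean scores of two
#' peptides under an N-terminal anchor (position i <-> i), a C-terminal
#' anchor (i <-> i + L_b - L_a) or an explicit externally computed position
#' map, and reports the Pearson correlation.
#'
#' @param scores_a,scores_b Numeric vectors of mean scores indexed by
#'   position (or by residue when using an explicit named map).
#' @param alignment `"n_anchor"`, `"c_anchor"` or `"map"`.
#' @param map For `alignment = "map"`: a two-column matrix/data.frame of
#'   paired indices into `scores_a` and `scores_b`.
#' @return A list with `r`, `p` and `n` (pairs used).
#' @export
cross_peptide_correlation <- function(scores_a, scores_b,
                                      alignment = c("n_anchor", "c_anchor", "map"),
                                      map = NULL) {
  alignment <- match.arg(alignment)
  La <- length(scores_a); Lb <- length(scores_b)
  pairs <- switch(alignment,
    n_anchor = cbind(seq_len(min(La, Lb)), seq_len(min(La, Lb))),
    c_anchor = {
      off <- Lb - La
      i <- seq_len(min(La, Lb))
      if (off >= 0) cbind(i, i + off) else cbind(i - off, i)
    },
    map = {
      if (is.null(map)) stop("alignment = 'map' requires a map")
      as.matrix(map)
    })
  x <- scores_a[pairs[, 1L]]
  y <- scores_b[pairs[, 2L]]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3L) stop("fewer than 3 paired observations")
  ct <- cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' ROC AUC of a predictor against nucleator labels
#'
#' Rank-based (Mann-Whitney) area under the ROC curve: the probability that
#' a randomly chosen positive outranks a randomly chosen negative, with ties
#' counted 1/2. The SD is estimated over seeded bootstrap resamples.
#'
#' @param scores Numeric predictor scores (higher = more nucleator-like).
#' @param labels Logical (or 0/1) nucleator labels.
#' @param n_boot Bootstrap resamples for the SD (default 100).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `auc`, `sd` and `n` = c(positives, negatives).
#' @export
predictor_auc <- function(scores, labels, n_boot = 100L, seed = NULL) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  if (!any(labels) || all(labels)) stop("both label classes must be present")
  auc1 <- function(s, l) {
    r <- rank(s)
    n1 <- sum(l)
    (sum(r[l]) - n1 * (n1 + 1) / 2) / (n1 * sum(!l))
  }
  if (!is.null(seed)) set.seed(seed)
  boots <- replicate(n_boot, {
    i <- sample.int(length(scores), replace = TRUE)
    if (any(labels[i]) && !all(labels[i])) auc1(scores[i], labels[i]) else NA_real_
  })
  list(auc = auc1(scores, labels), sd = sd(boots, na.rm = TRUE),
       n = c(positives = sum(labels), negatives = sum(!labels)))
}
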