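#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); a hypothesis is rejected at level q when its
#' adjusted p-value is at most q.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify designed-library variants against the wild type
#'
#' Two-sided Z-test of each variant's nucleation score against 0 (the
#' wild-type score after centering), with Benjamini-Hochberg FDR control.
#' Significant variants are labelled `NS_inc` (score > 0) or `NS_dec`
#' (score < 0); the rest are `WT_like`. Afterwards the sigma/IQR reliability
#' filter excludes WT-like variants whose error, normalised to the
#' interquartile range of the score distribution, exceeds `iqr_sigma_cutoff`
#' (an imprecise score near 0 cannot be confidently called wild-type-like).
#'
#' @param fit An [ns_fit()] with wt centering, or a data.frame with columns
#'   `variant`, `ns`, `sigma`.
#' @param fdr FDR level for the Z-test (default 0.1).
#' @param iqr_sigma_cutoff Normalised-sigma cutoff for the WT-like
#'   reliability filter (default 0.2).
#' @return A data.frame with columns `variant`, `ns`, `sigma`, `z`, `p`,
#'   `p_adj`, `label`, `norm_sigma` and `excluded` (WT-like entries removed
#'   by the reliability filter). Unmeasured variants are dropped.
#' @export
classify_designed <- function(fit, fdr = 0.1, iqr_sigma_cutoff = 0.2) {
  s <- scores_frame(fit)
  s <- s[is.finite(s$ns) & is.finite(s$sigma), ]
  if (any(s$sigma <= 0)) stop("sigma must be positive")
  s$z <- s$ns / s$sigma
  s$p <- 2 * pnorm(-abs(s$z))
  s$p_adj <- bh_adjust(s$p)
  sig <- s$p_adj <= fdr
  s$label <- ifelse(sig & s$ns > 0, "NS_inc",
                    ifelse(sig & s$ns < 0, "NS_dec", "WT_like"))
  sigma_iqr_filter(s, iqr_sigma_cutoff)
}

#' Sigma/IQR reliability filter for WT-like variants
#'
#' Normalises each variant's error to the interquartile range of the merged
#' score distribution and flags WT-like variants with normalised sigma above
#' the cutoff as excluded. Significant variants (NS_inc/NS_dec) are never
#' excluded by this filter.
#'
#' @param classes A data.frame with columns `ns`, `sigma`, `label`.
#' @param iqr_sigma_cutoff Cutoff on `sigma / IQR(ns)` (default 0.2).
#' @return `classes` with added `norm_sigma` and logical `excluded` columns.
#' @export
sigma_iqr_filter <- function(classes, iqr_sigma_cutoff = 0.2) {
  if (nrow(classes) < 4L) stop("need at least 4 entries to define the IQR")
  iqr <- IQR(classes$ns, na.rm = TRUE)
  if (iqr == 0) stop("IQR of the score distribution is zero")
  classes$norm_sigma <- classes$sigma / iqr
  classes$excluded <- classes$label == "WT_like" &
    classes$norm_sigma > iqr_sigma_cutoff
  classes
}

#' Classify random-library sequences as nucleators or nonnucleators
#'
#' One-sided Z-test of each sequence's (mode-centered) nucleation score
#' against 0, Benjamini-Hochberg corrected: sequences with score
#' significantly greater than 0 at the given FDR are nucleators, all others
#' nonnucleators. Imputed (output-dropout) sequences are always
#' nonnucleators. The strongest `top_fraction` of the library by score is
#' additionally flagged `top10`, intersected with the nucleator set so the
#' flag never marks a nonnucleator.
#'
#' @param fit An [ns_fit()] with mode centering, or a data.frame with columns
#'   `variant`, `ns`, `sigma` (and optionally `imputed`).
#' @param fdr FDR level (default 0.05).
#' @param top_fraction Fraction flagged as top nucleators (default 0.10).
#' @return A data.frame with columns `variant`, `ns`, `sigma`, `imputed`,
#'   `z`, `p`, `p_adj`, `label` (`"nucleator"`/`"nonnucleator"`) and `top10`.
#' @export
classify_random <- function(fit, fdr = 0.05, top_fraction = 0.10) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)")
  s <- scores_frame(fit)
  if (is.null(s$imputed)) s$imputed <- FALSE
  s <- s[is.finite(s$ns) & is.finite(s$sigma), ]
  if (any(s$sigma <= 0)) stop("sigma must be positive")
  s$z <- s$ns / s$sigma
  s$p <- pnorm(s$z, lower.tail = FALSE)
  s$p_adj <- bh_adjust(s$p)
  s$label <- ifelse(s$p_adj <= fdr & !s$imputed, "nucleator", "nonnucleator")
  k <- round(top_fraction * nrow(s))
  s$top10 <- FALSE
  if (k > 0L) {
    top_idx <- order(s$ns, decreasing = TRUE)[seq_len(k)]
    s$top10[top_idx] <- s$label[top_idx] == "nucleator"
  }
  s
}

scores_frame <- function(fit) {
  if (inherits(fit, "ns_fit")) fit$scores
  else if (is.data.frame(fit)) {
    stopifnot(all(c("variant", "ns", "sigma") %in% colnames(fit)))
    fit
  } else stop("expected an ns_fit object or a scores data.frame")
}

#' Merge duplicate sequences after classification
#'
#' Sequences observed multiple times (within or across experiments) are
#' merged: the nucleation score is the arithmetic mean, the label is the
#' modal status (ties break conservatively to nonnucleator) and the error is
#' propagated as the standard error of the mean. Afterwards, unreliable
#' nonnucleators — normalised sigma above `iqr_sigma_cutoff` and mean score
#' above the minimum nucleator score — are discarded.
#'
#' @param classes A data.frame from [classify_random()] with an added
#'   `sequence` column giving the protein sequence of each entry.
#' @param iqr_sigma_cutoff Reliability cutoff quantifying "big errors"
#'   (default 0.2, the same notion as [sigma_iqr_filter()]).
#' @return A data.frame with one row per unique sequence (columns `sequence`,
#'   `ns`, `sigma`, `n_obs`, `label`, `top10`) and discarded entries in
#'   `attr(, "discarded")`.
#' @export
merge_duplicates <- function(classes, iqr_sigma_cutoff = 0.2) {
  stopifnot("sequence" %in% colnames(classes))
  grp <- split(seq_len(nrow(classes)), classes$sequence)
  merged <- do.call(rbind, lapply(grp, function(i) {
    x <- classes[i, ]
    n_nuc <- sum(x$label == "nucleator")
    label <- if (n_nuc > length(i) - n_nuc) "nucleator" else "nonnucleator"
    data.frame(sequence = x$sequence[1L],
               ns = mean(x$ns),
               sigma = sqrt(sum(x$sigma^2)) / length(i),
               n_obs = length(i),
               label = label,
               top10 = label == "nucleator" && any(x$top10),
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  norm_sigma <- merged$sigma / IQR(merged$ns)
  nuc_ns <- merged$ns[merged$label == "nucleator"]
  drop <- merged$label == "nonnucleator" &
    norm_sigma > iqr_sigma_cutoff &
    length(nuc_ns) > 0 & merged$ns > suppressWarnings(min(nuc_ns))
  out <- merged[!drop, ]
  rownames(out) <- NULL
  attr(out, "discarded") <- merged[drop, ]
  out
}

#' Count score-increasing and score-decreasing mutations per position
#'
#' Tallies, for every peptide position, the number of missense variants
#' labelled NS_inc and NS_dec, and flags gatekeeper positions — positions
#' where mutations are more likely to increase nucleation than to decrease
#' it (`n_inc > n_dec`).
#'
#' @param classes Output of [classify_designed()] joined with the variant
#'   table, i.e. containing columns `position`, `class`, `label` and
#'   `excluded`.
#' @param positions Positions to report (default: all present).
#' @return A data.frame with columns `position`, `n_inc`, `n_dec`,
#'   `gatekeeper`.
#' @export
count_gatekeepers <- function(classes, positions = NULL) {
  stopifnot(all(c("position", "label") %in% colnames(classes)))
  x <- classes
  if ("excluded" %in% colnames(x)) x <- x[!x$excluded, ]
  if ("class" %in% colnames(x)) x <- x[x$class == "missense", ]
  if (is.null(positions)) positions <- sort(unique(classes$position))
  out <- data.frame(position = positions)
  out$n_inc <- vapply(positions, function(p)
    sum(x$position == p & x$label == "NS_inc"), numeric(1))
  out$n_dec <- vapply(positions, function(p)
    sum(x$position == p & x$label == "NS_dec"), numeric(1))
  out$gatekeeper <- out$n_inc > out$n_dec
  out
}

#' Position x mutant-residue score matrix
#'
#' Arranges merged nucleation scores of a designed library as the standard
#' heatmap matrix: one row per mutant residue (stop last), one column per
#' position.
#'
#' @param classes Classified designed variants with columns `position`,
#'   `mut_aa`, `ns`.
#' @return A 21 x L numeric matrix (NA where unmeasured/excluded).
#' @export
heatmap_matrix <- function(classes) {
  stopifnot(all(c("position", "mut_aa", "ns") %in% colnames(classes)))
  x <- classes
  if ("excluded" %in% colnames(x)) x <- x[!x$excluded, ]
  positions <- seq_len(max(x$position))
  m <- matrix(NA_real_, nrow = 21L, ncol = length(positions),
              dimnames = list(c(AA20, STOP_CHAR), positions))
  m[cbind(match(x$mut_aa, rownames(m)), x$position)] <- x$ns
  m
}
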