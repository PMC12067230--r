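#' Fit nucleation scores to a variant count table
#'
#' Estimates per-variant amyloid nucleation scores from paired input/output
#' sequencing counts of a selection experiment. For each replicate the
#' enrichment score of variant i is the log-ratio
#' \deqn{ES_i = \ln F_i^{out} - \ln F_i^{in}}
#' of its pseudocounted read frequencies. With wild-type centering
#' (designed libraries) the replicate nucleation score is \eqn{ES_i - ES_{wt}};
#' with mode centering (random libraries, no meaningful wild type) raw
#' enrichment scores are used and the fitted scores are shifted so the mode
#' of their kernel-density estimate — the non-nucleating bulk — sits at 0.
#'
#' Per-replicate errors come from a Poisson delta method,
#' \eqn{\sigma_r^2 = 1/c_i^{in} + 1/c_i^{out}} (plus the reference-count terms
#' under wild-type centering), on pseudocounted counts. Replicates are merged
#' by the error-weighted (inverse-variance) mean,
#' \eqn{NS = \sum_r w_r NS_r / \sum_r w_r}, \eqn{w_r = 1/\sigma_r^2}, with
#' merged error \eqn{\sigma = (\sum_r w_r)^{-1/2}}.
#'
#' Variants present in the input but absent from the output of every
#' replicate (full dropouts) cannot be scored; when `impute = TRUE` (the
#' default under mode centering) they receive the mode score (0 after
#' centering) and the largest observed merged error, so they can never be
#' called significant.
#'
#' All scores are in natural-log units.
#'
#' @param counts A [count_table()].
#' @param centering `"wt"` (designed libraries; requires `reference`) or
#'   `"mode"` (random libraries).
#' @param reference Variant id of the wild-type/reference sequence
#'   (wt centering).
#' @param pseudocount Added to every count before frequencies (default 0.5;
#'   0 is allowed, in which case replicates with zero counts are treated as
#'   missing).
#' @param impute Impute full output-dropouts with the mode score (default:
#'   `TRUE` under mode centering).
#' @return An object of class `ns_fit` with components `scores` (a data.frame
#'   with columns `variant`, `ns`, `sigma`, `imputed`, `n_rep`), matrices
#'   `ns_rep` and `sigma_rep` of per-replicate values, and the fit settings.
#' @seealso [classify_designed()], [classify_random()], [simulate_selection()]
#' @examples
#' inp <- matrix(100, 2, 2, dimnames = list(c("wt", "v1"), NULL))
#' out <- matrix(c(100, 200), 2, 2, dimnames = list(c("wt", "v1"), NULL))
#' fit <- ns_fit(count_table(inp, out), centering = "wt", reference = "wt",
#'               pseudocount = 0)
#' coef(fit)
#' @export
ns_fit <- function(counts, centering = c("wt", "mode"), reference = NULL,
                   pseudocount = 0.5, impute = NULL) {
  stopifnot(inherits(counts, "count_table"))
  centering <- match.arg(centering)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (is.null(impute)) impute <- centering == "mode"
  variants <- rownames(counts$input)
  R <- ncol(counts$input)
  if (centering == "wt") {
    if (is.null(reference) || !reference %in% variants)
      stop("wt centering requires a 'reference' variant present in the counts")
    ref_i <- match(reference, variants)
  }

  cin <- counts$input + pseudocount
  cout <- counts$output + pseudocount
  tot_in <- colSums(cin)
  tot_out <- colSums(cout)
  if (any(tot_in == 0) || any(tot_out == 0))
    stop("a sample has zero total reads")
  es <- log(sweep(cout, 2L, tot_out, "/")) - log(sweep(cin, 2L, tot_in, "/"))
  var_rep <- 1 / cin + 1 / cout
  if (centering == "wt") {
    if (pseudocount == 0 && any(counts$input[ref_i, ] == 0 | counts$output[ref_i, ] == 0))
      stop("reference variant has zero counts in some replicate")
    es <- sweep(es, 2L, es[ref_i, ], "-")
    var_rep <- sweep(var_rep, 2L, var_rep[ref_i, ], "+")
  }
  ns_rep <- es
  sigma_rep <- sqrt(var_rep)
  ## with pseudocount 0, zero counts give non-finite scores: mark missing
  miss <- !is.finite(ns_rep) | !is.finite(sigma_rep)
  ns_rep[miss] <- NA_real_
  sigma_rep[miss] <- NA_real_

  merged <- merge_replicates(ns_rep, sigma_rep)
  ns <- merged$ns
  sigma <- merged$sigma
  n_rep <- merged$n_rep

  shift <- 0
  if (centering == "wt") {
    shift <- ns[ref_i]
    if (is.na(shift)) stop("reference variant is unmeasured")
  } else {
    measured <- is.finite(ns)
    if (sum(measured) < 50L)
      stop("mode centering requires at least 50 measured variants")
    shift <- density_mode(ns[measured])
  }
  ns <- ns - shift

  imputed <- rep(FALSE, length(variants))
  if (impute) {
    full_dropout <- rowSums(counts$output) == 0 & rowSums(counts$input) > 0
    if (any(full_dropout)) {
      max_sigma <- max(sigma[is.finite(sigma) & !full_dropout], na.rm = TRUE)
      ns[full_dropout] <- 0
      sigma[full_dropout] <- max_sigma
      imputed <- full_dropout
    }
  }

  structure(list(
    scores = data.frame(variant = variants, ns = unname(ns),
                        sigma = unname(sigma), imputed = unname(imputed),
                        n_rep = unname(n_rep), stringsAsFactors = FALSE),
    ns_rep = ns_rep, sigma_rep = sigma_rep,
    centering = centering, reference = reference, shift = shift,
    pseudocount = pseudocount, replicates = R,
    counts = counts),
    class = "ns_fit")
}

#' Error-weighted merge of per-replicate scores
#'
#' Inverse-variance weighted mean across replicates with merged error
#' `sqrt(1 / sum(1 / sigma^2))`; `NA` replicates are skipped.
#'
#' @param ns_rep,sigma_rep Matrices (variants x replicates) of per-replicate
#'   scores and errors.
#' @return A list with vectors `ns`, `sigma` and `n_rep` (replicates used);
#'   variants with no usable replicate get `NA` (unmeasured).
#' @export
merge_replicates <- function(ns_rep, sigma_rep) {
  ns_rep <- rbind(ns_rep)
  sigma_rep <- rbind(sigma_rep)
  w <- 1 / sigma_rep^2
  w[is.na(ns_rep) | is.na(sigma_rep)] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  n_rep <- rowSums(!is.na(w))
  ns <- rowSums(w * ns_rep, na.rm = TRUE) / sw
  sigma <- sqrt(1 / sw)
  ns[n_rep == 0L] <- NA_real_
  sigma[n_rep == 0L] <- NA_real_
  nm <- rownames(ns_rep)
  if (identical(nm, "ns_rep")) nm <- NULL  # vector input: no real names
  list(ns = setNames(unname(ns), nm), sigma = setNames(unname(sigma), nm),
       n_rep = setNames(unname(n_rep), nm))
}

#' Mode of a distribution by Gaussian kernel density
#'
#' Argmax of a Gaussian KDE (Silverman's rule-of-thumb bandwidth, 512-point
#' grid spanning the data range), robust to the heavy nucleator tail of
#' selection-score distributions.
#'
#' @param x Numeric vector (NAs removed).
#' @return The mode location.
#' @export
density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values")
  d <- density(x, bw = "nrd0", kernel = "gaussian", n = 512L)
  d$x[which.max(d$y)]
}

#' @export
print.ns_fit <- function(x, ...) {
  cat("Nucleation-score fit (", x$centering, "-centered, ",
      x$replicates, " replicate(s), pseudocount ", x$pseudocount, ")\n", sep = "")
  cat("  variants: ", nrow(x$scores),
      " (", sum(x$scores$imputed), " imputed, ",
      sum(!is.finite(x$scores$ns)), " unmeasured)\n", sep = "")
  qs <- quantile(x$scores$ns, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  cat("  NS quartiles: ", paste(signif(qs, 3), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @method summary ns_fit
#' @export
summary.ns_fit <- function(object, ...) {
  s <- object$scores
  out <- list(
    centering = object$centering,
    reference = object$reference,
    shift = object$shift,
    n_variants = nrow(s),
    n_imputed = sum(s$imputed),
    n_unmeasured = sum(!is.finite(s$ns)),
    replicates = object$replicates,
    ns_quantiles = quantile(s$ns, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE),
    median_sigma = stats::median(s$sigma, na.rm = TRUE),
    replicate_cor = if (object$replicates >= 2L)
      suppressWarnings(cor(object$ns_rep, use = "pairwise.complete.obs"))
    else NULL)
  class(out) <- "summary.ns_fit"
  out
}

#' @export
print.summary.ns_fit <- function(x, ...) {
  cat("Nucleation-score fit summary\n")
  cat("  centering:", x$centering,
      if (!is.null(x$reference)) paste0("(reference ", x$reference, ")"), "\n")
  cat("  variants:", x$n_variants, "| imputed:", x$n_imputed,
      "| unmeasured:", x$n_unmeasured, "\n")
  cat("  NS quantiles:\n")
  print(signif(x$ns_quantiles, 4))
  cat("  median sigma:", signif(x$median_sigma, 4), "\n")
  if (!is.null(x$replicate_cor)) {
    cat("  between-replicate score correlations:\n")
    print(signif(x$replicate_cor, 3))
  }
  invisible(x)
}

#' @method coef ns_fit
#' @export
coef.ns_fit <- function(object, ...) {
  setNames(object$scores$ns, object$scores$variant)
}

#' Replicate-consistency residuals of a nucleation-score fit
#'
#' Standardised deviations of each replicate score from the merged score,
#' `(ns_rep - ns) / sigma_rep`; approximately standard normal when the
#' Poisson error model holds.
#'
#' @param object An [ns_fit()] object.
#' @param ... Unused.
#' @return Variants x replicates matrix.
#' @method residuals ns_fit
#' @export
residuals.ns_fit <- function(object, ...) {
  (object$ns_rep - object$shift - object$scores$ns) / object$sigma_rep
}

#' @method plot ns_fit
#' @export
plot.ns_fit <- function(x, ...) {
  ns <- x$scores$ns[is.finite(x$scores$ns)]
  d <- density(ns, bw = "nrd0", n = 512L)
  graphics::hist(ns, breaks = 50, freq = FALSE, col = "grey85", border = "white",
                 main = "Nucleation score distribution",
                 xlab = "nucleation score (natural log)", ...)
  graphics::lines(d, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Simulate new count tables from a fitted score set
#'
#' Parametric resampling: uses the fitted nucleation scores as true effects
#' in the synthetic selection model, at the depths of the original
#' experiment.
#'
#' @param object An [ns_fit()] object.
#' @param nsim Number of simulated count tables.
#' @param seed Integer seed.
#' @param ... Passed to [sim_config()] (e.g. `abundance_dispersion`).
#' @return A list of `nsim` [count_table()] objects.
#' @method simulate ns_fit
#' @export
simulate.ns_fit <- function(object, nsim = 1, seed = 1L, ...) {
  s <- object$scores[is.finite(object$scores$ns), ]
  ts <- data.frame(variant = s$variant, true_ns = s$ns,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(replicates = object$replicates,
                      input_depth = sum(object$counts$input[, 1L]),
                      output_depth = sum(object$counts$output[, 1L]),
                      seed = seed + i - 1L, ...)
    simulate_selection(ts, cfg)
  })
}

#' Write fitted scores to a tab-separated file
#'
#' @param fit An [ns_fit()] object.
#' @param path Output path.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "ns_fit"))
  df <- fit$scores
  for (r in seq_len(fit$replicates)) {
    df[[paste0("ns_rep", r)]] <- fit$ns_rep[, r]
    df[[paste0("sigma_rep", r)]] <- fit$sigma_rep[, r]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
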