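#' Variant read-count table
#'
#' Container for selection-assay sequencing counts: one row per variant, one
#' column per replicate, separately for the pre-selection (input) and
#' post-selection (output) phases.
#'
#' @param input,output Non-negative integer matrices of identical dimensions
#'   with matching rownames (variant ids) and one column per replicate.
#' @return An object of class `count_table`: a list with elements `input` and
#'   `output`.
#' @export
count_table <- function(input, output) {
  input <- as.matrix(input)
  output <- as.matrix(output)
  if (!identical(dim(input), dim(output)))
    stop("input and output must have identical dimensions")
  if (nrow(input) > 0L && is.null(rownames(input)))
    stop("input must have variant ids as rownames")
  if (is.null(rownames(output))) rownames(output) <- rownames(input)
  if (!identical(rownames(input), rownames(output)))
    stop("input and output rownames must match")
  for (m in list(input, output)) {
    if (any(m < 0) || any(m != round(m)) || anyNA(m))
      stop("counts must be non-negative integers")
  }
  if (is.null(colnames(input)))
    colnames(input) <- colnames(output) <- paste0("rep", seq_len(ncol(input)))
  storage.mode(input) <- "double"
  storage.mode(output) <- "double"
  structure(list(input = input, output = output), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Variant count table:", nrow(x$input), "variants x",
      ncol(x$input), "replicate(s)\n")
  cat("  input depth(s): ", paste(colSums(x$input), collapse = ", "), "\n", sep = "")
  cat("  output depth(s): ", paste(colSums(x$output), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$input)

#' Write a count table to a tab-separated file
#'
#' Columns: `variant`, then `input_<rep>` and `output_<rep>` per replicate.
#'
#' @param ct A [count_table()].
#' @param path Output file path.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(variant = rownames(ct$input),
                   ct$input, ct$output,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("variant",
                    paste0("input_", colnames(ct$input)),
                    paste0("output_", colnames(ct$output)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path Path to the TSV file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  inp <- as.matrix(df[, grep("^input_", colnames(df)), drop = FALSE])
  out <- as.matrix(df[, grep("^output_", colnames(df)), drop = FALSE])
  rownames(inp) <- rownames(out) <- df$variant
  colnames(inp) <- sub("^input_", "", colnames(inp))
  colnames(out) <- sub("^output_", "", colnames(out))
  count_table(inp, out)
}
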