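#' Read-processing configuration
#'
#' QC rules applied when converting raw amplicon reads to variant counts:
#' constant-region trimming with a bounded mismatch fraction, a per-base
#' Phred filter over the variable region, and rejection of non-designed
#' variants (designed libraries) or off-length interiors (random libraries).
#'
#' @param flank5,flank3 Constant flanking sequences.
#' @param max_flank_mismatch_frac Maximum tolerated mismatch fraction per
#'   flank; a flank with more than `floor(frac * flank_length)` mismatches is
#'   rejected (default 0.20).
#' @param min_phred Minimum per-base Phred quality over the variable region
#'   (default 30).
#' @param min_input_reads Input-read threshold for [input_read_filter()]
#'   (200 for designed libraries, 100 for random libraries).
#' @param min_input_mode `"all"` (default): remove a variant only when its
#'   input count is below threshold in every replicate; `"any"`: remove when
#'   below threshold in any replicate.
#' @param whitelist Optional character vector of designed variable-region
#'   nucleotide sequences; when supplied, interiors outside it are discarded
#'   (designed mode). When `NULL`, every distinct interior of length
#'   `variable_length` becomes a variant (random mode).
#' @param variable_length Expected variable-region length in random mode
#'   (default: inferred from the whitelist, else required).
#' @return An object of class `processing_config`.
#' @export
processing_config <- function(flank5 = default_flank5(),
                              flank3 = default_flank3(),
                              max_flank_mismatch_frac = 0.20,
                              min_phred = 30L,
                              min_input_reads = 200L,
                              min_input_mode = c("all", "any"),
                              whitelist = NULL,
                              variable_length = NULL) {
  if (max_flank_mismatch_frac < 0 || max_flank_mismatch_frac > 1)
    stop("max_flank_mismatch_frac must be in [0, 1]")
  if (min_phred < 0 || min_phred > 41) stop("min_phred must be in [0, 41]")
  min_input_mode <- match.arg(min_input_mode)
  if (is.null(variable_length) && !is.null(whitelist))
    variable_length <- unique(nchar(whitelist))
  structure(list(flank5 = flank5, flank3 = flank3,
                 max_flank_mismatch_frac = max_flank_mismatch_frac,
                 min_phred = as.integer(min_phred),
                 min_input_reads = min_input_reads,
                 min_input_mode = min_input_mode,
                 whitelist = whitelist,
                 variable_length = variable_length),
            class = "processing_config")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Trim constant flanking regions from reads
#'
#' Flanks are matched at fixed offsets (fixed-length amplicons, no indel
#' alignment). A read is accepted when each flank matches the reference with
#' at most `floor(max_flank_mismatch_frac * flank_length)` mismatches; the
#' interior (variable region) and its qualities are returned.
#'
#' @param reads Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (same lengths),
#'   or `NULL` when qualities are not tracked.
#' @param cfg A [processing_config()].
#' @return A data.frame with columns `interior`, `qual` and `reject`
#'   (`NA` for accepted reads, else one of `"too_short"`, `"flank5_fail"`,
#'   `"flank3_fail"`).
#' @export
trim_constant_regions <- function(reads, quals = NULL, cfg = processing_config()) {
  n5 <- nchar(cfg$flank5)
  n3 <- nchar(cfg$flank3)
  max5 <- floor(cfg$max_flank_mismatch_frac * n5)
  max3 <- floor(cfg$max_flank_mismatch_frac * n3)
  n <- length(reads)
  if (is.null(quals)) quals <- rep(NA_character_, n)
  interior <- rep(NA_character_, n)
  qual <- rep(NA_character_, n)
  reject <- rep(NA_character_, n)
  len <- nchar(reads)
  for (i in seq_len(n)) {
    if (len[i] <= n5 + n3) {
      reject[i] <- "too_short"
    } else if (hamming(substr(reads[i], 1L, n5), cfg$flank5) > max5) {
      reject[i] <- "flank5_fail"
    } else if (hamming(substr(reads[i], len[i] - n3 + 1L, len[i]), cfg$flank3) > max3) {
      reject[i] <- "flank3_fail"
    } else {
      interior[i] <- substr(reads[i], n5 + 1L, len[i] - n3)
      if (!is.na(quals[i]))
        qual[i] <- substr(quals[i], n5 + 1L, len[i] - n3)
    }
  }
  data.frame(interior = interior, qual = qual, reject = reject,
             stringsAsFactors = FALSE)
}

#' Per-base Phred quality filter over the variable region
#'
#' A read fails when any base of its variable region has Phred quality below
#' `min_phred`. The filter is scoped to the variable region because flank
#' bases are already validated by the mismatch tolerance and do not determine
#' variant identity.
#'
#' @param quals Character vector of Phred+33 quality strings (variable region
#'   only).
#' @param cfg A [processing_config()].
#' @return Logical vector: `TRUE` = pass.
#' @export
quality_filter <- function(quals, cfg = processing_config()) {
  if (anyNA(quals)) stop("missing qualities")
  vapply(quals, function(q) {
    if (nchar(q) == 0L) return(TRUE)
    min(utf8ToInt(q)) - 33L >= cfg$min_phred
  }, logical(1), USE.NAMES = FALSE)
}

#' Tally accepted variable regions into variant counts
#'
#' Designed mode (whitelist supplied): interiors not in the whitelist are
#' discarded and reported. Random mode: every distinct interior of the
#' expected length becomes a variant; off-length interiors are discarded.
#'
#' @param interiors Character vector of accepted variable-region sequences.
#' @param cfg A [processing_config()].
#' @return A list with `counts` (named integer vector) and `n_discarded`.
#' @export
count_variants <- function(interiors, cfg = processing_config()) {
  if (!is.null(cfg$whitelist)) {
    keep <- interiors %in% cfg$whitelist
  } else {
    if (is.null(cfg$variable_length))
      stop("random mode requires cfg$variable_length")
    keep <- nchar(interiors) %in% cfg$variable_length
  }
  counts <- table(interiors[keep])
  list(counts = setNames(as.integer(counts), names(counts)),
       n_discarded = sum(!keep))
}

#' Remove variants with insufficient input coverage
#'
#' Applies the input-read threshold: in `"all"` mode (default) a variant is
#' removed only when its input count is below `min_input_reads` in every
#' replicate; in `"any"` mode, when below threshold in any replicate. The
#' operation is idempotent.
#'
#' @param ct A [count_table()].
#' @param cfg A [processing_config()].
#' @return The filtered [count_table()]; removed variant ids are available in
#'   `attr(, "removed")`.
#' @export
input_read_filter <- function(ct, cfg = processing_config()) {
  stopifnot(inherits(ct, "count_table"))
  below <- ct$input < cfg$min_input_reads
  drop <- if (cfg$min_input_mode == "all") {
    rowSums(below) == ncol(ct$input)
  } else {
    rowSums(below) > 0L
  }
  out <- count_table(ct$input[!drop, , drop = FALSE],
                     ct$output[!drop, , drop = FALSE])
  attr(out, "removed") <- rownames(ct$input)[drop]
  out
}

#' Process FASTQ files into a filtered count table
#'
#' Full read-processing chain: parse FASTQ, trim constant regions, apply the
#' Phred filter, tally variants (designed or random mode) and apply the
#' input-read filter. The inverse of [emit_fastq()]: with no read corruption
#' and a whitelist equal to the design, the simulated count table is
#' recovered exactly.
#'
#' @param files A data.frame with columns `file`, `replicate`, `phase`
#'   (`"input"`/`"output"`) describing one FASTQ file per sample, e.g. the
#'   files written by [emit_fastq()].
#' @param cfg A [processing_config()].
#' @param ids Optional named character vector mapping nucleotide sequence ->
#'   variant id used for rownames (defaults to the nucleotide sequences
#'   themselves).
#' @param apply_input_filter Apply [input_read_filter()] at the end
#'   (default TRUE).
#' @return A [count_table()]; the per-sample QC tally is available in
#'   `attr(, "qc")` (reads total / accepted / rejected by reason / discarded
#'   as non-designed or off-length).
#' @export
process_fastq <- function(files, cfg = processing_config(), ids = NULL,
                          apply_input_filter = TRUE) {
  stopifnot(all(c("file", "replicate", "phase") %in% colnames(files)))
  reps <- sort(unique(files$replicate))
  tallies <- list()
  qc <- list()
  for (i in seq_len(nrow(files))) {
    fq <- read_fastq(files$file[i])
    tr <- trim_constant_regions(fq$seq, fq$qual, cfg)
    ok <- is.na(tr$reject)
    qpass <- rep(FALSE, nrow(tr))
    if (any(ok)) qpass[ok] <- quality_filter(tr$qual[ok], cfg)
    tal <- count_variants(tr$interior[ok & qpass], cfg)
    key <- paste0(files$replicate[i], "_", files$phase[i])
    tallies[[key]] <- tal$counts
    qc[[key]] <- data.frame(
      sample = key, total = length(fq$seq),
      too_short = sum(tr$reject == "too_short", na.rm = TRUE),
      flank5_fail = sum(tr$reject == "flank5_fail", na.rm = TRUE),
      flank3_fail = sum(tr$reject == "flank3_fail", na.rm = TRUE),
      low_quality = sum(ok & !qpass),
      discarded = tal$n_discarded,
      accepted = sum(tal$counts),
      stringsAsFactors = FALSE)
  }
  variants <- if (!is.null(cfg$whitelist)) cfg$whitelist else
    sort(unique(unlist(lapply(tallies, names))))
  grab <- function(phase) {
    m <- sapply(reps, function(r) {
      v <- tallies[[paste0(r, "_", phase)]]
      out <- setNames(numeric(length(variants)), variants)
      out[names(v)] <- v
      out
    })
    m <- matrix(m, nrow = length(variants),
                dimnames = list(variants, as.character(reps)))
    m
  }
  ct <- count_table(grab("input"), grab("output"))
  if (!is.null(ids)) {
    mapped <- ids[rownames(ct$input)]
    if (!anyNA(mapped)) rownames(ct$input) <- rownames(ct$output) <- unname(mapped)
  }
  if (apply_input_filter) ct <- input_read_filter(ct, cfg)
  attr(ct, "qc") <- do.call(rbind, qc)
  ct
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  if (length(lines) == 0L) return(list(seq = character(0), qual = character(0)))
  idx <- seq(2L, length(lines), 4L)
  list(seq = lines[idx], qual = lines[idx + 2L])
}
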