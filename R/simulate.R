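#' True-effect model for synthetic selection experiments
#'
#' Describes the bimodal structure of a nucleation library: a fraction
#' `p_nucleator` of variants are true nucleators whose nucleation scores (in
#' natural-log units) are drawn from a gamma distribution, while the rest are
#' nonnucleators with true score 0 (optionally jittered by `null_noise_sd`).
#'
#' @param p_nucleator Probability a variant is a nucleator, in \[0, 1\].
#' @param shape,scale Gamma parameters of the nucleator score distribution
#'   (defaults 2 and 1.5, i.e. mean 3 on the natural-log scale).
#' @param null_noise_sd SD of true scores around 0 for nonnucleators
#'   (default 0: exact nulls).
#' @param fixed Optional positive value; when given, every nucleator gets
#'   exactly this score (point-mass effect distribution) instead of a gamma
#'   draw.
#' @return An object of class `true_effect_model`.
#' @export
true_effect_model <- function(p_nucleator = 0.3, shape = 2, scale = 1.5,
                              null_noise_sd = 0, fixed = NULL) {
  if (p_nucleator < 0 || p_nucleator > 1) stop("p_nucleator must be in [0, 1]")
  if (shape <= 0 || scale <= 0) stop("gamma shape and scale must be positive")
  if (null_noise_sd < 0) stop("null_noise_sd must be non-negative")
  if (!is.null(fixed) && fixed <= 0) stop("fixed nucleator score must be > 0")
  structure(list(p_nucleator = p_nucleator, shape = shape, scale = scale,
                 null_noise_sd = null_noise_sd, fixed = fixed),
            class = "true_effect_model")
}

#' Assign true nucleation scores to variants
#'
#' @param variants Character vector of variant ids (or an integer count, in
#'   which case ids `v1..vn` are generated).
#' @param model A [true_effect_model()].
#' @param seed Optional integer seed.
#' @return A data.frame with columns `variant`, `nucleator` (logical) and
#'   `true_ns` (natural-log units).
#' @export
assign_true_scores <- function(variants, model = true_effect_model(),
                               seed = NULL) {
  stopifnot(inherits(model, "true_effect_model"))
  if (is.numeric(variants) && length(variants) == 1L)
    variants <- paste0("v", seq_len(variants))
  if (!is.null(seed)) set.seed(seed)
  n <- length(variants)
  nuc <- runif(n) < model$p_nucleator
  ns <- numeric(n)
  if (any(nuc)) {
    ns[nuc] <- if (!is.null(model$fixed)) model$fixed else
      rgamma(sum(nuc), shape = model$shape, scale = model$scale)
  }
  if (model$null_noise_sd > 0 && any(!nuc))
    ns[!nuc] <- rnorm(sum(!nuc), 0, model$null_noise_sd)
  data.frame(variant = variants, nucleator = nuc, true_ns = ns,
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic selection experiment
#'
#' @param replicates Number of biological replicates (default 3).
#' @param input_depth,output_depth Total sequencing reads per input/output
#'   sample.
#' @param abundance_dispersion Log-scale SD of the log-normal input-abundance
#'   model (uneven library representation; default 1).
#' @param dropout_rate Probability that a variant is lost from the output of
#'   every replicate (hard dropout, to stress score imputation; default 0 —
#'   dropout then arises only from finite sequencing depth).
#' @param seed Integer seed used for all randomness in [simulate_selection()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(replicates = 3L, input_depth = 2e6, output_depth = 2e6,
                       abundance_dispersion = 1, dropout_rate = 0,
                       seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (input_depth < 1 || output_depth < 1) stop("depths must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(replicates = as.integer(replicates),
                 input_depth = input_depth, output_depth = output_depth,
                 abundance_dispersion = abundance_dispersion,
                 dropout_rate = dropout_rate, seed = seed),
            class = "sim_config")
}

#' Simulate selection-assay read counts
#'
#' Generates a [count_table()] with the structure the scoring model assumes:
#' per replicate, input frequencies are drawn from a log-normal abundance
#' model and renormalised; output frequencies are proportional to input
#' frequency times `exp(true_ns)` (single-round selection); counts are
#' multinomial draws at the configured depths, so dropout of rare variants
#' emerges naturally from finite depth.
#'
#' @param true_scores A data.frame from [assign_true_scores()] (columns
#'   `variant`, `true_ns`).
#' @param cfg A [sim_config()].
#' @return A [count_table()] with one row per variant.
#' @export
simulate_selection <- function(true_scores, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(c("variant", "true_ns") %in% colnames(true_scores)))
    stop("true_scores must have columns 'variant' and 'true_ns'")
  set.seed(cfg$seed)
  n <- nrow(true_scores)
  sel <- exp(true_scores$true_ns)
  inp <- out <- matrix(0, n, cfg$replicates,
                       dimnames = list(true_scores$variant,
                                       paste0("rep", seq_len(cfg$replicates))))
  dropped <- runif(n) < cfg$dropout_rate
  for (r in seq_len(cfg$replicates)) {
    ab <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_dispersion)
    f_in <- ab / sum(ab)
    f_out <- f_in * sel
    f_out[dropped] <- 0
    if (sum(f_out) == 0) stop("all output frequencies are zero")
    f_out <- f_out / sum(f_out)
    inp[, r] <- rmultinom(1L, cfg$input_depth, f_in)
    out[, r] <- rmultinom(1L, cfg$output_depth, f_out)
  }
  if (all(inp == 0) || all(out == 0))
    warning("sequencing depth so small that all counts are zero")
  count_table(inp, out)
}

#' Write simulated reads as FASTQ files
#'
#' Emits one read per count: the variant's nucleotide sequence flanked by the
#' 5' and 3' constant regions, with uniform Phred qualities (Sanger +33
#' encoding). Optional per-base substitution errors corrupt reads for testing
#' the trimming/quality filters; corrupted bases keep the uniform quality.
#'
#' @param ct A [count_table()].
#' @param sequences Named character vector: variant id -> nucleotide sequence
#'   of the variable region. Every variant in `ct` must be present.
#' @param dir Output directory (created if needed). Files are named
#'   `<replicate>_<input|output>.fastq`.
#' @param flank5,flank3 Constant flanking regions (defaults: 25-nt upstream
#'   and 21-nt downstream regions used in amplicon cloning).
#' @param phred Uniform per-base Phred quality (default 37).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Optional integer seed (used when `error_rate > 0`).
#' @return Invisibly, a character vector of the files written.
#' @export
emit_fastq <- function(ct, sequences, dir,
                       flank5 = default_flank5(), flank3 = default_flank3(),
                       phred = 37L, error_rate = 0, seed = NULL) {
  stopifnot(inherits(ct, "count_table"))
  variants <- rownames(ct$input)
  if (!all(variants %in% names(sequences)))
    stop("missing nucleotide sequence for variant(s): ",
         paste(head(setdiff(variants, names(sequences)), 3L), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qchar <- rawToChar(as.raw(phred + 33L))
  files <- character(0)
  for (phase in c("input", "output")) {
    m <- ct[[phase]]
    for (r in seq_len(ncol(m))) {
      reads <- rep(paste0(flank5, sequences[variants], flank3), times = m[, r])
      if (error_rate > 0 && length(reads)) {
        reads <- vapply(reads, corrupt_read, character(1),
                        error_rate = error_rate, USE.NAMES = FALSE)
      }
      path <- file.path(dir, paste0(colnames(m)[r], "_", phase, ".fastq"))
      con <- file(path, open = "wt")
      if (length(reads)) {
        quals <- strrep(qchar, nchar(reads))
        writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", quals),
                   con)
      }
      close(con)
      files <- c(files, path)
    }
  }
  invisible(files)
}

corrupt_read <- function(read, error_rate) {
  s <- strsplit(read, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(s)) < error_rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  paste(s, collapse = "")
}

#' @rdname emit_fastq
#' @export
default_flank5 <- function() "ACTTTAAGAAGGAGATATACCATGG"

#' @rdname emit_fastq
#' @export
default_flank3 <- function() "TAAGGATCCGGCTGCTAACAA"
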