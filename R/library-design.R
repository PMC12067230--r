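#' @importFrom stats density IQR p.adjust pnorm chisq.test t.test cor.test
#'   rgamma rnorm rbinom rlnorm rmultinom runif quantile setNames sd var
#' @importFrom stats cor median simulate coef residuals
#' @importFrom utils read.delim write.table head
NULL

## The 20 canonical amino acids, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CHAR <- "*"

#' Standard genetic code as a named vector
#'
#' Codon -> one-letter amino acid (stop codons map to `"*"`), taken from
#' [Biostrings::GENETIC_CODE].
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' The 32 NNK codons
#'
#' NNK degenerate codons have any nucleotide at positions 1-2 and G or T at
#' position 3. The set encodes all 20 amino acids and contains exactly one
#' stop codon (TAG).
#'
#' @return Character vector of 32 codons, sorted.
#' @export
nnk_codons <- function() {
  nt <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(nt, nt, paste0), c("G", "T"), paste0)))
}

check_peptide <- function(residues, what = "peptide") {
  if (length(residues) != 1L || !is.character(residues) || is.na(residues))
    stop(what, " must be a single character string")
  if (nchar(residues) < 1L)
    stop(what, " must have length >= 1")
  aa <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), AA20)
  if (length(bad))
    stop(what, " contains non-canonical residues: ", paste(bad, collapse = ", "))
  invisible(aa)
}

#' Enumerate all single substitutions and truncations of a peptide
#'
#' For a wild-type peptide of length L this produces the designed
#' deep-mutational-scanning library: the 19 missense substitutions at every
#' position plus the stop (truncation) variant at every position, i.e. 20 * L
#' unique protein variants. For the 34-residue ADan/ABri peptides this gives
#' the 646 + 34 = 680 designed variants.
#'
#' @param wt Wild-type peptide as a one-letter amino-acid string.
#' @param parent_id Identifier recorded in the `parent` column.
#' @return A data.frame with one row per variant, ordered by position and then
#'   alphabetically by mutant residue (stop last), with columns `id`,
#'   `parent`, `position`, `wt_aa`, `mut_aa`, `class`
#'   (`"missense"`/`"nonsense"`) and `protein_seq` (truncated for nonsense;
#'   empty string for the position-1 truncation).
#' @examples
#' v <- enumerate_variants("AC")
#' nrow(v)  # 40
#' @export
enumerate_variants <- function(wt, parent_id = "wt") {
  aa <- check_peptide(wt, "wt")
  L <- length(aa)
  rows <- vector("list", L)
  for (pos in seq_len(L)) {
    muts <- c(setdiff(AA20, aa[pos]), STOP_CHAR)
    seqs <- vapply(muts, function(m) {
      if (m == STOP_CHAR) {
        substr(wt, 1L, pos - 1L)
      } else {
        s <- aa
        s[pos] <- m
        paste(s, collapse = "")
      }
    }, character(1))
    rows[[pos]] <- data.frame(
      id = paste0(aa[pos], pos, muts),
      parent = parent_id,
      position = pos,
      wt_aa = aa[pos],
      mut_aa = muts,
      class = ifelse(muts == STOP_CHAR, "nonsense", "missense"),
      protein_seq = unname(seqs),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translate a nucleotide sequence, stopping at the first stop codon
#'
#' @param nt Nucleotide string whose length is a multiple of 3.
#' @return One-letter amino-acid string (possibly empty if the first codon is
#'   a stop).
#' @export
translate_orf <- function(nt) {
  if (nchar(nt) %% 3L != 0L)
    stop("nucleotide length must be a multiple of 3")
  if (nchar(nt) == 0L) return("")
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aa <- genetic_code()[codons]
  if (anyNA(aa))
    stop("invalid codon(s): ", paste(codons[is.na(aa)], collapse = ", "))
  stop_at <- which(aa == STOP_CHAR)
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Sample random NNK codon extensions of a base peptide
#'
#' Emulates a random-extension library: `n_codons` codons drawn uniformly
#' from the 32-codon NNK set are appended to the base peptide's coding
#' sequence. Translation stops at the first TAG stop codon, so extension
#' lengths range from 0 to `n_codons` with P(length = k < n_codons) =
#' (31/32)^k * 1/32 and P(full length) = (31/32)^n_codons.
#'
#' @param base Base peptide (amino-acid string) to extend.
#' @param n Number of extensions to sample.
#' @param n_codons Number of NNK codons per extension (default 12).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `id`, `extension_nt` (the sampled
#'   codons), `extension_aa` (translated, truncated at the first stop),
#'   `peptide` (base + extension) and `length` (peptide length).
#' @export
sample_nnk_extensions <- function(base, n, n_codons = 12L, seed = NULL) {
  check_peptide(base, "base")
  if (n < 1L) stop("n must be >= 1")
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  codons <- nnk_codons()
  idx <- matrix(sample.int(32L, n * n_codons, replace = TRUE),
                nrow = n, ncol = n_codons)
  ext_nt <- apply(idx, 1L, function(i) paste(codons[i], collapse = ""))
  ext_aa <- vapply(ext_nt, translate_orf, character(1), USE.NAMES = FALSE)
  data.frame(
    id = sprintf("ext%0*d", nchar(n), seq_len(n)),
    extension_nt = ext_nt,
    extension_aa = ext_aa,
    peptide = paste0(base, ext_aa),
    length = nchar(base) + nchar(ext_aa),
    stringsAsFactors = FALSE
  )
}

single_nt_neighbors <- function(codon) {
  nt <- c("A", "C", "G", "T")
  s <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(nt, s[i])) {
      x <- s
      x[i] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

#' Flag variants reachable by a single nucleotide change
#'
#' Given the wild-type coding sequence, flags each missense/nonsense variant
#' as SNV-reachable if its target amino acid (or stop) is encoded by at least
#' one of the 9 single-nucleotide neighbours of the wild-type codon at that
#' position. Variants whose target equals the wild-type residue are flagged
#' `FALSE` (synonymous changes are handled separately).
#'
#' @param wt_nt Wild-type nucleotide sequence (length 3 * peptide length),
#'   which must translate to the variants' parent peptide.
#' @param variants A variant table from [enumerate_variants()].
#' @return `variants` with an added logical column `snv_reachable`.
#' @export
annotate_snv_reachability <- function(wt_nt, variants) {
  L <- max(variants$position)
  if (nchar(wt_nt) != 3L * L)
    stop("wt_nt length (", nchar(wt_nt), ") does not match 3 x peptide length (",
         3L * L, ")")
  gc <- genetic_code()
  codons <- substring(wt_nt, 3L * (seq_len(L) - 1L) + 1L, 3L * seq_len(L))
  wt_trans <- gc[codons]
  if (!identical(unname(wt_trans), variants$wt_aa[match(seq_len(L), variants$position)]))
    stop("wt_nt does not translate to the variants' parent peptide")
  reach <- lapply(codons, function(cd) unique(unname(gc[single_nt_neighbors(cd)])))
  variants$snv_reachable <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$mut_aa == v$wt_aa) return(FALSE)
    v$mut_aa %in% reach[[v$position]]
  }, logical(1))
  variants
}

#' Subset peptides carrying Ser at the first extension position
#'
#' Selects ABri-like members of a random-extension library: peptides whose
#' extension has length >= 1 and whose residue at position `base_length + 1`
#' (position 23 for the 22-residue Bri2 base) is serine, mimicking the
#' stop-loss products that generate ABri.
#'
#' @param peptides Character vector of full peptide sequences sharing the base.
#' @param base_length Length of the shared base peptide (default 22).
#' @return The subset of `peptides` (same order) that are ABri-like.
#' @export
subset_abri_like <- function(peptides, base_length = 22L) {
  peptides[nchar(peptides) >= base_length + 1L &
             substr(peptides, base_length + 1L, base_length + 1L) == "S"]
}

#' Read peptide sequences from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_peptide_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read nucleotide sequences from a FASTA file
#'
#' @param path Path to a DNA FASTA file.
#' @return Named character vector of sequences.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
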