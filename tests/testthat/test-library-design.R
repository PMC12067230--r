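test_that("substitution/truncation enumeration yields 20L unique variants", {
  adan <- unname(read_peptide_fasta(
    system.file("extdata", "adan.fasta", package = "nucleateR")))
  v <- enumerate_variants(adan, "ADan")
  expect_equal(nrow(v), 680)
  expect_equal(sum(v$class == "missense"), 646)
  expect_equal(sum(v$class == "nonsense"), 34)
  expect_equal(length(unique(paste(v$class, v$protein_seq))), 680)

  for (L in c(1L, 2L, 5L)) {
    wt <- paste(rep(c("A", "N", "F", "K", "C"), length.out = L), collapse = "")
    v <- enumerate_variants(wt)
    expect_equal(nrow(v), 20 * L)
    expect_false(any(duplicated(paste(v$class, v$protein_seq))))
  }
})

test_that("enumeration agrees with brute-force set enumeration at L = 2", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  wt <- "AC"
  brute <- character(0)
  for (pos in 1:2) for (m in aa) {
    s <- strsplit(wt, "")[[1]]
    if (m != s[pos]) {
      s[pos] <- m
      brute <- c(brute, paste0("M:", paste(s, collapse = "")))
    }
  }
  brute <- c(brute, paste0("N:", c("", "A")))
  v <- enumerate_variants(wt)
  got <- paste0(ifelse(v$class == "missense", "M:", "N:"), v$protein_seq)
  expect_setequal(got, unique(brute))
  expect_equal(nrow(v), 40)
})

test_that("variant records satisfy their structural invariants", {
  v <- enumerate_variants("NFKLC")
  non <- v[v$class == "nonsense", ]
  expect_true(all(nchar(non$protein_seq) == non$position - 1))
  mis <- v[v$class == "missense", ]
  wt <- strsplit("NFKLC", "")[[1]]
  ndiff <- vapply(seq_len(nrow(mis)), function(i) {
    sum(strsplit(mis$protein_seq[i], "")[[1]] != wt)
  }, numeric(1))
  expect_true(all(ndiff == 1))
  # position-major, residue-alphabetical ordering with stop last
  expect_equal(v$position, rep(1:5, each = 20))
  expect_error(enumerate_variants("AXB"), "non-canonical")
})

test_that("NNK codon set has the documented exact structure", {
  codons <- nnk_codons()
  gc <- genetic_code()
  expect_length(codons, 32)
  expect_equal(codons[gc[codons] == "*"], "TAG")
  expect_equal(sort(codons[gc[codons] == "S"]), c("AGT", "TCG", "TCT"))
  expect_setequal(setdiff(unique(gc[codons]), "*"),
                  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
})

test_that("NNK extension lengths follow the truncated geometric law", {
  n <- 1e5
  ext <- sample_nnk_extensions("EASNCFAIRHFENKFAVETLIC", n = n, seed = 11)
  len <- ext$length - 22L
  # per-position stop probability 1/32, within 3 binomial SE
  p_stop <- 1 / 32
  frac0 <- mean(len == 0)
  expect_lt(abs(frac0 - p_stop), 3 * sqrt(p_stop * (1 - p_stop) / n))
  # full length (31/32)^12
  p_full <- (31 / 32)^12
  expect_lt(abs(mean(len == 12) - p_full), 3 * sqrt(p_full * (1 - p_full) / n))
  for (k in 1:11) {
    pk <- (31 / 32)^k * (1 / 32)
    expect_lt(abs(mean(len == k) - pk), 3 * sqrt(pk * (1 - pk) / n))
  }
  # Ser at the first extension position: 3 of 32 codons
  first <- substr(ext$extension_aa, 1, 1)
  p_ser <- 3 / 32
  expect_lt(abs(mean(first == "S") - p_ser), 3 * sqrt(p_ser * (1 - p_ser) / n))
})

test_that("NNK sampling is reproducible and translations are canonical", {
  a <- sample_nnk_extensions("NFK", n = 200, seed = 5)
  b <- sample_nnk_extensions("NFK", n = 200, seed = 5)
  expect_identical(a, b)
  res <- unique(strsplit(paste(a$extension_aa, collapse = ""), "")[[1]])
  expect_true(all(res %in% c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))
  expect_true(all(a$peptide == paste0("NFK", a$extension_aa)))
})

test_that("SNV reachability matches the 9-neighbour brute-force oracle", {
  # GAA (Glu): Lys reachable via AAA, Trp not reachable
  v <- enumerate_variants("E")
  ann <- annotate_snv_reachability("GAA", v)
  expect_true(ann$snv_reachable[ann$mut_aa == "K"])
  expect_false(ann$snv_reachable[ann$mut_aa == "W"])

  wt_nt <- "AATTTTAAACTGTGT"  # NFKLC
  v <- enumerate_variants("NFKLC")
  ann <- annotate_snv_reachability(wt_nt, v)
  codons <- substring(wt_nt, c(1, 4, 7, 10, 13), c(3, 6, 9, 12, 15))
  for (i in seq_len(nrow(ann))) {
    reach <- snv_neighbors_naive(codons[ann$position[i]])
    expect_equal(ann$snv_reachable[i],
                 ann$mut_aa[i] %in% setdiff(reach, ann$wt_aa[i]) &&
                   ann$mut_aa[i] != ann$wt_aa[i])
  }
  expect_error(annotate_snv_reachability("AATTTT", v), "length")
})

test_that("ABri-like subsetting keeps extensions starting with Ser", {
  base <- "EASNCFAIRHFENKFAVETLIC"
  expect_equal(subset_abri_like(c(paste0(base, "SIV"))), paste0(base, "SIV"))
  expect_length(subset_abri_like(paste0(base, "FNL")), 0)
  expect_length(subset_abri_like(base), 0)
})

test_that("shipped peptide fixtures match the per-residue literature anchors", {
  fa <- function(f) unname(read_peptide_fasta(
    system.file("extdata", f, package = "nucleateR")))
  bri2 <- fa("bri2.fasta"); adan <- fa("adan.fasta"); abri <- fa("abri.fasta")
  expect_equal(nchar(bri2), 22)
  expect_equal(nchar(adan), 34)
  expect_equal(nchar(abri), 34)
  expect_equal(substr(adan, 1, 22), bri2)
  expect_equal(substr(abri, 1, 22), bri2)
  at <- function(s, i) substr(s, i, i)
  # ADan: F23 N24 L25 F26 L27 E31 K32
  expect_equal(vapply(c(23, 24, 25, 26, 27, 31, 32), at, "", s = adan),
               c("F", "N", "L", "F", "L", "E", "K"))
  # ABri: S23 R24 V26 E32
  expect_equal(vapply(c(23, 24, 26, 32), at, "", s = abri),
               c("S", "R", "V", "E"))
})

test_that("ORF translation stops at the first stop codon", {
  expect_equal(translate_orf("AATTAGAAA"), "N")
  expect_equal(translate_orf("TAGAAA"), "")
  expect_equal(translate_orf("AATTTT"), "NF")
  expect_error(translate_orf("AATT"), "multiple of 3")
})

test_that("the synthetic ADan coding fixture supports SNV annotation", {
  nt <- unname(read_dna_fasta(
    system.file("extdata", "adan_nt_synthetic.fasta", package = "nucleateR")))
  adan <- unname(read_peptide_fasta(
    system.file("extdata", "adan.fasta", package = "nucleateR")))
  expect_equal(translate_orf(nt), adan)
  ann <- annotate_snv_reachability(nt, enumerate_variants(adan, "ADan"))
  reach_per_pos <- tapply(ann$snv_reachable, ann$position, sum)
  # a codon has 9 single-nt neighbours, so 1..9 reachable targets per position
  expect_true(all(reach_per_pos >= 1 & reach_per_pos <= 9))
  # spot-check three positions against the brute-force oracle
  for (pos in c(1, 17, 34)) {
    codon <- substr(nt, 3 * pos - 2, 3 * pos)
    reach <- snv_neighbors_naive(codon)
    sub <- ann[ann$position == pos, ]
    expect_equal(sub$snv_reachable,
                 sub$mut_aa %in% setdiff(reach, sub$wt_aa[1]))
  }
})
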