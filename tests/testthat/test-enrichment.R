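test_that("composition percentages are exact and normalised", {
  m <- composition_percent("AAC")
  expect_equal(unname(m[1, "A"]), 200 / 3)
  expect_equal(unname(m[1, "C"]), 100 / 3)
  expect_equal(sum(m[1, setdiff(colnames(m), c("A", "C"))]), 0)
  seqs <- random_peptides(25, 12, seed = 61)
  expect_equal(unname(rowSums(composition_percent(seqs))), rep(100, 25),
               tolerance = 1e-9)
  expect_error(composition_percent(""), "length >= 1")
  expect_error(composition_percent("AXZ"), "non-canonical")
})

test_that("group composition statistics match naive references", {
  g1 <- random_peptides(50, 12, seed = 62)
  g2 <- random_peptides(50, 12, seed = 63)
  res <- group_composition_test(g1, g2)
  c1 <- composition_percent(g1); c2 <- composition_percent(g2)
  for (aa in res$aa) {
    x <- c1[, aa]; y <- c2[, aa]
    ref <- welch_naive(x, y)
    row <- res[res$aa == aa, ]
    expect_equal(row$t, ref$t, tolerance = 1e-9)
    expect_equal(row$p, ref$p, tolerance = 1e-9)
    expect_equal(row$cohens_d, cohens_d_naive(x, y), tolerance = 1e-9)
    expect_equal(row$freq_difference, mean(x) - mean(y), tolerance = 1e-12)
  }
  # identical groups: no effect
  same <- group_composition_test(g1, g1)
  expect_true(all(same$cohens_d == 0))
  expect_true(all(same$freq_difference == 0))
  # antisymmetry under group swap
  swapped <- group_composition_test(g2, g1)
  expect_equal(swapped$freq_difference, -res$freq_difference)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
})

test_that("Cohen's d follows the pooled-SD definition", {
  x <- c(4, 5, 6)   # mean 5, sd 1
  y <- c(2, 3, 4)   # mean 3, sd 1
  expect_equal(cohens_d(x, y), 2)
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
})

test_that("a planted composition shift is recovered", {
  set.seed(64)
  n <- 5000
  aa_pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  # group2 uniform (5% Asn); group1 with Asn boosted to 7% (+2 points)
  w2 <- rep(1, 20)
  w1 <- ifelse(aa_pool == "N", 1.4737, 1)  # 1.4737/(19+1.4737) ~ 0.07
  gen <- function(w) vapply(seq_len(n), function(i)
    paste(sample(aa_pool, 12, TRUE, prob = w), collapse = ""), character(1))
  res <- group_composition_test(gen(w1), gen(w2))
  asn <- res[res$aa == "N", ]
  expect_lt(abs(asn$freq_difference - 2), 0.3)
  expect_lt(asn$p, 1e-10)
  expect_gt(asn$cohens_d, 0)
})

test_that("position-wise class tests match the hand-computed chi-square", {
  # position 1: 50/100 polar in group1 vs 30/100 in group2
  g1 <- c(rep("NA", 50), rep("AA", 50))   # N = polar at position 1
  g2 <- c(rep("NA", 30), rep("AA", 70))
  res <- positionwise_class_test(g1, g2, positions = 1)
  polar <- res[res$class == "polar", ]
  expect_equal(polar$chisq, 200 * (50 * 70 - 50 * 30)^2 / (100 * 100 * 80 * 120),
               tolerance = 1e-9)
  expect_equal(polar$chisq, 8.3333, tolerance = 1e-4)
  ref <- chisq_naive(matrix(c(50, 50, 30, 70), 2, 2, byrow = TRUE))
  expect_equal(polar$p, ref$p, tolerance = 1e-9)
  expect_equal(polar$stars, "**")
  # identical frequencies: statistic 0, no stars
  res0 <- positionwise_class_test(g1, g1, positions = 1)
  polar0 <- res0[res0$class == "polar", ]
  expect_equal(polar0$chisq, 0)
  expect_equal(polar0$stars, "")
  # class absent from both groups is skipped
  arom <- res[res$class == "aromatic", ]
  expect_true(arom$skipped)
  # sequences shorter than the position are excluded there
  res2 <- positionwise_class_test(c("NN", "A"), c("N", "AA", "CC"), positions = 2)
  expect_equal(res2$n1_in[res2$class == "polar"] + res2$n1_out[res2$class == "polar"], 1)
})

test_that("length stratification conserves sequences and finds planted structure", {
  cl <- data.frame(
    sequence = c(rep(strrep("A", 24), 40), rep(strrep("C", 30), 60)),
    label = c(rep("nucleator", 40), rep("nonnucleator", 60)),
    top10 = c(rep(TRUE, 10), rep(FALSE, 90)),
    stringsAsFactors = FALSE)
  st <- length_stratify(cl)
  expect_equal(sum(st$n), 100)
  expect_equal(st$frac_nucleator[st$length == 24], 1)
  expect_equal(st$frac_nucleator[st$length == 30], 0)
  expect_equal(st$frac_top10[st$length == 24], 0.25)
  expect_equal(st$frac_nonnucleator + st$frac_nucleator, rep(1, 2))
  # a single stratum equals the global analysis
  one <- length_stratify(cl[cl$sequence == strrep("A", 24), ])
  expect_equal(one$n, 40)
})

test_that("sequence properties average the published residue scales", {
  expect_equal(sequence_properties("II", "hydropathy"), 4.5)
  expect_equal(sequence_properties("DD", "hydropathy"), -3.5)
  kd <- aa_scale("hydropathy")
  expect_equal(sequence_properties("INFKL", "hydropathy"),
               mean(kd[c("I", "N", "F", "K", "L")]))
  bt <- aa_scale("beta_propensity")
  expect_length(bt, 20)
  expect_equal(unname(bt["I"]), 1.48)
  # extension-only averaging
  expect_equal(sequence_properties("DDII", "hydropathy", from = 3), 4.5)
  expect_true(is.na(sequence_properties("DD", "hydropathy", from = 3)))
})

test_that("cross-peptide correlation honours anchoring and degeneracy rules", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cross_peptide_correlation(x, x)$r, 1)
  expect_equal(cross_peptide_correlation(x, -x)$r, -1)
  # C-terminal anchor of lengths 34 and 42 pairs position 1 <-> 9
  a <- seq_len(34)
  b <- c(rep(NA, 8), seq_len(34))  # position i+8 of b equals position i of a
  res <- cross_peptide_correlation(a, b, alignment = "c_anchor")
  expect_equal(res$r, 1)
  expect_equal(res$n, 34)
  # explicit map
  m <- cbind(1:5, c(2, 1, 4, 3, 5))
  res <- cross_peptide_correlation(x, x, alignment = "map", map = m)
  expect_equal(res$n, 5)
  expect_error(cross_peptide_correlation(c(1, 2), c(1, 2)), "3 paired")
})

test_that("rank AUC matches the all-pairs oracle and is monotone-invariant", {
  expect_equal(predictor_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0),
                             n_boot = 10, seed = 1)$auc, 1)
  set.seed(65)
  for (i in 1:5) {
    s <- sample(round(runif(30), 2), 30, TRUE)  # with ties
    l <- rbinom(30, 1, 0.4)
    if (!any(l) || all(l)) next
    a <- predictor_auc(s, l, n_boot = 5, seed = i)$auc
    expect_equal(a, auc_naive(s, l), tolerance = 1e-9)
    expect_equal(predictor_auc(exp(3 * s), l, n_boot = 5, seed = i)$auc, a,
                 tolerance = 1e-12)
  }
  # uninformative scores: AUC ~ 0.5 within 3 bootstrap SD
  set.seed(66)
  s <- runif(600); l <- rbinom(600, 1, 0.5)
  res <- predictor_auc(s, l, n_boot = 100, seed = 2)
  expect_lt(abs(res$auc - 0.5), 3 * res$sd + 1e-6)
  expect_error(predictor_auc(1:4, c(1, 1, 1, 1)), "both label classes")
})
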