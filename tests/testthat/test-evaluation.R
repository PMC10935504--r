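make_motif <- function(consensus, n = 10) {
  q <- rep(0.25, 4); names(q) <- c("A", "C", "G", "T")
  build_pwm(rep(consensus, n), q)
}

test_that("sequence scoring separates motif carriers from background", {
  set.seed(12)
  mm <- make_motif("ACGGTTACGGTTAC")
  flank <- function() paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  with_site <- paste0(flank(), "ACGGTTACGGTTAC", flank())
  without <- paste0(flank(), flank())
  expect_gt(score_sequence(with_site, mm), score_sequence(without, mm))
})

test_that("scoring scans both strands symmetrically", {
  set.seed(13)
  mm <- make_motif("ACGGTTACGGTTAC")
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_equal(score_sequence(s, mm), score_sequence(reverse_complement(s), mm))
  # a planted reverse-complement instance scores like a forward one
  site <- "ACGGTTACGGTTAC"
  fl <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  expect_equal(score_sequence(paste0(fl, site, fl), mm),
               score_sequence(reverse_complement(paste0(fl, site, fl)), mm))
})

test_that("a flat PWM scores zero and short sequences error", {
  q <- rep(0.25, 4); names(q) <- c("A", "C", "G", "T")
  mm <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), q)   # zero log-odds
  expect_equal(score_sequence("AAAACCCCGGGG", mm), 0, tolerance = 1e-12)
  expect_error(score_sequence("ACG", mm), "shorter")
})

test_that("partial AUC is exact for perfect separation", {
  roc <- partial_auc(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(roc$pauc_sensitivity, 1)
  expect_equal(roc$pauc_specificity, 1)
  expect_error(partial_auc(numeric(), 1:3), "nonempty")
})

test_that("identical score distributions give ~0.5 on both metrics", {
  set.seed(99)
  pos <- rnorm(500); neg <- rnorm(500)
  roc <- partial_auc(pos, neg)
  expect_equal(roc$pauc_sensitivity, 0.5, tolerance = 0.05)
  expect_equal(roc$pauc_specificity, 0.5, tolerance = 0.05)
})

test_that("partial AUC agrees with pROC on small score sets", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (rep in 1:5) {
    pos <- rnorm(12, mean = 1); neg <- rnorm(8)
    roc <- partial_auc(pos, neg)
    resp <- c(rep(1, 12), rep(0, 8)); sc <- c(pos, neg)
    spec_ref <- suppressWarnings(as.numeric(pROC::auc(resp, sc, partial.auc = c(1, 0.8),
                                     partial.auc.focus = "specificity",
                                     partial.auc.correct = TRUE,
                                     quiet = TRUE)))
    sens_ref <- suppressWarnings(as.numeric(pROC::auc(resp, sc, partial.auc = c(1, 0.8),
                                     partial.auc.focus = "sensitivity",
                                     partial.auc.correct = TRUE,
                                     quiet = TRUE)))
    if (!is.na(spec_ref)) {
      expect_equal(roc$pauc_specificity, spec_ref, tolerance = 1e-8)
    }
    if (!is.na(sens_ref)) {
      expect_equal(roc$pauc_sensitivity, sens_ref, tolerance = 1e-8)
    }
  }
})

test_that("both pAUCs are invariant to monotone score transforms", {
  set.seed(3)
  pos <- rnorm(30, 1); neg <- rnorm(30)
  a <- partial_auc(pos, neg)
  b <- partial_auc(exp(pos), exp(neg))
  c3 <- partial_auc(pos^3 + 5, neg^3 + 5)
  expect_equal(a$pauc_sensitivity, b$pauc_sensitivity, tolerance = 1e-12)
  expect_equal(a$pauc_specificity, b$pauc_specificity, tolerance = 1e-12)
  expect_equal(a$pauc_specificity, c3$pauc_specificity, tolerance = 1e-12)
})

test_that("negative sampling is deterministic, sized, and bounded", {
  set.seed(77)
  genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""),
              c2 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
  neg <- sample_negatives(genome, rep(100L, 10), seed = 4)
  expect_length(neg, 10)
  expect_true(all(nchar(neg$seq) == 100))
  neg2 <- sample_negatives(genome, rep(100L, 10), seed = 4)
  expect_identical(neg$seq, neg2$seq)
  neg3 <- sample_negatives(genome, rep(100L, 10), seed = 5)
  expect_false(identical(neg$seq, neg3$seq))
  expect_error(sample_negatives(genome, 10000L, seed = 1), "exceeds")
})

test_that("motif evaluation reports one row per motif", {
  sim <- generate_planted_dataset(plant_spec(m = 20, peak_len = 200, seed = 2))
  fit <- suppressMessages(exomotif(sim$peaks))
  set.seed(6)
  genome <- c(g = paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = ""))
  neg <- sample_negatives(genome, nchar(sim$peaks$seq), seed = 3)
  tab <- evaluate_motifs(fit, sim$peaks, neg)
  expect_equal(nrow(tab), length(fit$motifs))
  expect_true(all(tab$pauc_sensitivity >= 0 & tab$pauc_sensitivity <= 1))
  expect_true(all(tab$pauc_specificity >= 0 & tab$pauc_specificity <= 1))
  # an informative planted motif classifies well
  expect_gt(tab$pauc_specificity[1], 0.9)
})
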