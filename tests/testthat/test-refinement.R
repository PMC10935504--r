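test_that("background estimation counts mononucleotides and guards zeros", {
  q <- estimate_background(genome = c(c1 = "AACCGGTT"))
  expect_equal(unname(q), rep(0.25, 4))
  expect_equal(sum(q), 1)
  # absent letters are lifted off zero and renormalized
  q2 <- estimate_background(genome = c(c1 = "AAAA"))
  expect_true(all(q2 > 0))
  expect_equal(sum(q2), 1)
  expect_gt(q2[["A"]], 0.99)
  # peaks fallback is messaged
  ps <- peak_set("p", "ACGTN")
  expect_message(q3 <- estimate_background(ps), "peak")
  expect_equal(unname(q3), rep(0.25, 4))   # N excluded
  expect_error(estimate_background(genome = c(c1 = "NNN")), "usable")
})

test_that("PWM construction applies the quarter-spread pseudocount", {
  q <- rep(0.25, 4)
  names(q) <- c("A", "C", "G", "T")
  # all four bases equally often: zero log-odds everywhere
  mm <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), q)
  expect_equal(unname(mm$pwm), matrix(0, 4, 4), tolerance = 1e-12)

  # counts A:3 C:1 at a column -> p(A) = 3.25/5 = 0.8125? no: 3.25/5 = 0.65
  mm2 <- build_pwm(c("A", "A", "A", "C"), q)
  expect_equal(unname(mm2$counts["A", 1]), 3)
  expect_equal(unname(motif_freq(mm2)["A", 1]), 3.25 / 5)
  expect_equal(unname(mm2$pwm["A", 1]), log2((3.25 / 5) / 0.25))

  # consensus recovers identical instances
  mm3 <- build_pwm(rep("ACGGT", 10), q)
  expect_equal(mm3$consensus, "ACGGT")
  expect_equal(unname(apply(mm3$counts, 2, which.max)), c(1, 2, 3, 3, 4))

  # N spreads a quarter count to each base
  mm4 <- build_pwm(c("AN", "AA"), q)
  expect_equal(unname(mm4$counts[, 2]), c(1.25, 0.25, 0.25, 0.25))

  expect_error(build_pwm(c("ACG", "ACGT"), q), "length")
  expect_error(build_pwm("ACGT", q), "at least 2")
})

test_that("PWM reconstruction is idempotent on a fixed instance set", {
  q <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  segs <- c("ACGTA", "ACGTT", "ACCTA", "TCGTA")
  a <- build_pwm(segs, q)
  b <- build_pwm(segs, q)
  expect_identical(a$pwm, b$pwm)
  expect_identical(a$counts, b$counts)
})

test_that("match score reduces to the log-odds sum in basic mode", {
  ps <- peak_set(c("a", "b"), c("ACGTACGTAC", "TACGTACGTA"))
  sm <- build_strand_matrix(ps)
  w_norm <- lapply(sm$w, function(v) v)   # all ones already
  q <- rep(0.25, 4); names(q) <- c("A", "C", "G", "T")
  mm <- build_pwm(c("ACGT", "ACGT", "ACGA"), q)
  mm$l_o <- mm$width; mm$t <- 2L
  s <- match_score(mm, sm, w_norm, row = 1, start = 1)
  plain <- sum(vapply(1:4, function(j) mm$pwm[c("A", "C", "G", "T")[j], j], 0))
  expect_equal(s, plain, tolerance = 1e-12)
})

test_that("match score applies the two coverage windows by hand", {
  # toy: one row, width-4 motif, t = 2, l_o = 4
  ps <- peak_set("a", "ACGTACGTAC",
                 list(c(0.1, 0.2, 0.9, 0.4, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1)))
  ps$normalized <- TRUE
  sm <- build_strand_matrix(ps)
  w_norm <- lapply(sm$w, exomotif:::row_max_normalize)
  q <- rep(0.25, 4); names(q) <- c("A", "C", "G", "T")
  mm <- build_pwm(c("ACGT", "ACGT"), q)
  mm$l_o <- 4L; mm$t <- 2L
  s <- match_score(mm, sm, w_norm, row = 1, start = 5)
  # first window: positions 3..5 -> max w = 0.9/0.9 = 1
  # second window: positions 5..11 truncated at 10 -> max = 0.8/0.9
  w1 <- max(w_norm[[1]][3:5]); w2 <- max(w_norm[[1]][5:10])
  plain <- sum(vapply(1:4, function(j) mm$pwm[c("A", "C", "G", "T")[j], j], 0))
  expect_equal(s, 0.5 * (w1 + w2) * plain, tolerance = 1e-12)
  expect_error(match_score(mm, sm, w_norm, row = 1, start = 8), "bounds")
})

test_that("the consensus segment scores highest on its row", {
  set.seed(8)
  flank <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  target <- "ACGGTTACGGTTAC"
  ps <- peak_set("a", paste0(flank, target, flank))
  sm <- build_strand_matrix(ps)
  w_norm <- lapply(sm$w, function(v) v)
  q <- rep(0.25, 4); names(q) <- c("A", "C", "G", "T")
  mm <- build_pwm(rep(target, 10), q)
  mm$l_o <- mm$width; mm$t <- 2L
  sc <- exomotif:::score_all_segments(mm, sm, w_norm)
  best <- sc[sc$row == 1, ]
  expect_equal(best$start[which.max(best$score)], nchar(flank) + 1L)
})

test_that("expansion is monotone, recovers planted sites, fixes points", {
  sim <- generate_planted_dataset(plant_spec(m = 12, peak_len = 120, seed = 21))
  fit <- suppressMessages(exomotif(sim$peaks, expand = FALSE))
  mm <- fit$motifs[[1]]
  before <- mm$instances
  expanded <- expand_instances(mm, fit$sm, fit$w_norm, fit$background)
  expect_gte(expanded$nsites, mm$nsites)
  # original instances survive
  k_old <- paste(before$row, before$start)
  k_new <- paste(expanded$instances$row, expanded$instances$start)
  expect_true(all(k_old %in% k_new))
  # a second application with no new segments is a fixed point
  again <- expand_instances(expanded, fit$sm, fit$w_norm, fit$background)
  expect_equal(again$nsites, expand_instances(again, fit$sm, fit$w_norm,
                                              fit$background)$nsites)
})

test_that("expansion recovers a planted site missed by clique detection", {
  sim <- generate_planted_dataset(
    plant_spec(m = 15, peak_len = 150, seed = 31, plant_rate = 1))
  fit <- suppressMessages(exomotif(sim$peaks, expand = FALSE))
  rec0 <- site_recovery(fit, sim$truth, sim$peaks, 14)
  fit2 <- suppressMessages(exomotif(sim$peaks, expand = TRUE))
  rec1 <- site_recovery(fit2, sim$truth, sim$peaks, 14)
  expect_gte(rec1, rec0)
  expect_gte(rec1, 0.8)
})
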