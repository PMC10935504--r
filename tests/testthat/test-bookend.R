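pm <- function(rows, starts, width = 14L, l = 14L, score = 1) {
  structure(list(instances = data.frame(row = rows, start = starts,
                                        width = width),
                 l = l, score = score),
            class = "potential_motif")
}

test_that("co-occurrence counting follows the window and span rules", {
  seqlen <- rep(200L, 4)
  # same peak, starts 1 and 9 (forward rows): span 22 <= 25, overlap 6
  ci <- pm(c(1L, 3L), c(1L, 20L))
  cj <- pm(c(1L, 3L), c(9L, 150L))
  cc <- count_cooccurrence(ci, cj, 25L, seqlen)
  expect_equal(cc$o, 1L)
  expect_equal(cc$overlaps, 6L)
  # instances on different peaks never pair
  cc2 <- count_cooccurrence(pm(1L, 10L), pm(3L, 10L), 25L, seqlen)
  expect_equal(cc2$o, 0L)
  # span 54 > 25: not counted
  cc3 <- count_cooccurrence(pm(1L, 1L), pm(1L, 41L), 25L, seqlen)
  expect_equal(cc3$o, 0L)
})

test_that("minus-strand instances are mapped to forward coordinates", {
  seqlen <- rep(100L, 2)
  # row 2 is the reverse strand of peak 1; start 1 there = forward [87, 100]
  ci <- pm(1L, 80L)          # forward [80, 93]
  cj <- pm(2L, 1L)
  cc <- count_cooccurrence(ci, cj, 25L, seqlen)
  expect_equal(cc$o, 1L)
  expect_equal(cc$overlaps, 7L)   # [87,93] shared
})

test_that("pairing is one-to-one by nearest span", {
  seqlen <- 200L
  ci <- pm(1L, 50L)
  cj <- pm(c(1L, 1L), c(52L, 56L))
  cc <- count_cooccurrence(ci, cj, 25L, seqlen)
  expect_equal(cc$o, 1L)           # a cluster cannot inflate the count
  expect_equal(cc$pairs$b, 1L)     # nearest partner wins
})

test_that("co-occurrence p-value matches hand and enumeration oracles", {
  expect_equal(cooccurrence_pvalue(0, 5, 3, 25, 20, 200), 1)
  # p = (10 * 2) / (2 * 100) = 0.1; P(X >= 2 | n=2, p=0.1) = 0.01
  expect_equal(cooccurrence_pvalue(2, 2, 2, 10, 2, 100), 0.01)
  for (nj in c(4, 8, 12)) {
    for (o in c(0, 1, nj %/% 2, nj)) {
      p <- (25 * 12) / (20 * 200)
      expect_equal(cooccurrence_pvalue(o, 12, nj, 25, 20, 200),
                   oracle_cooccur_pvalue(o, nj, p), tolerance = 1e-12)
    }
  }
  expect_error(cooccurrence_pvalue(5, 10, 4, 25, 20, 200), "exceeds")
})

test_that("p-value decreases in o and the rate p is clamped", {
  pv <- vapply(0:6, cooccurrence_pvalue, 0, n_i = 8, n_j = 6,
               d = 25, m = 20, n = 200)
  expect_true(all(diff(pv) < 0))
  # degenerate geometry cannot push p above 1
  expect_lte(cooccurrence_pvalue(3, 50, 10, 1000, 2, 10), 1)
})

test_that("merging keeps the modal overlap and the width identity", {
  seqlen <- rep(200L, 10)
  rows <- seq(1L, 19L, by = 2L)[1:5]
  # overlaps 6,6,6,4 across peaks 1-4; pair on peak 5 too far
  ci <- pm(rows, c(10L, 10L, 10L, 10L, 10L))
  cj <- pm(rows, c(18L, 18L, 18L, 20L, 150L))
  res <- merge_pair(ci, cj, bookend_params(), seqlen, 10, 200)
  expect_true(res$merged)
  expect_equal(res$o, 4L)
  expect_equal(res$l_o, 6L)
  expect_equal(res$l_x, 22L)
  expect_true(all(res$motif$instances$width == 22L))

  # overlap tie {4,4,6,6}: larger overlap wins
  cj2 <- pm(rows[1:4], c(18L, 18L, 20L, 20L))
  res2 <- merge_pair(ci, cj2, bookend_params(), seqlen, 10, 200)
  expect_equal(res2$l_o, 6L)
  expect_equal(res2$l_x, 22L)
})

test_that("insignificant pairs pass through unmerged", {
  seqlen <- rep(200L, 20)
  ci <- pm(1L, 10L)
  cj <- pm(1L, 18L)
  # one co-occurring pair among single-instance motifs is not significant
  res <- merge_pair(ci, cj, bookend_params(), seqlen, 20, 200)
  expect_false(res$merged)
  expect_null(res$motif)
})

test_that("bookend on a single motif returns it with l_x = l", {
  out <- bookend_merge(list(pm(c(1L, 3L, 5L), c(5L, 9L, 30L))),
                       bookend_params(), rep(100L, 3))
  expect_length(out, 1)
  expect_equal(out[[1]]$l_x, 14L)
  expect_equal(out[[1]]$l_o, 14L)
})

test_that("motifs on disjoint peak sets never merge", {
  seqlen <- rep(200L, 12)
  ci <- pm(c(1L, 3L, 5L), rep(10L, 3))
  cj <- pm(c(7L, 9L, 11L), rep(12L, 3))
  out <- bookend_merge(list(ci, cj), bookend_params(), seqlen)
  expect_length(out, 2)
  expect_true(all(vapply(out, function(m) m$l_x, 0L) == 14L))
})

test_that("merged widths respect the union-span bound", {
  sim <- generate_split_motif_dataset(
    plant_spec(m = 20, peak_len = 200, seed = 6), total_width = 22)
  pot <- discover_potential_motifs(sim$peaks, alignment_params())
  seeds <- bookend_merge(pot, bookend_params(), nchar(sim$peaks$seq))
  for (s in seeds) {
    expect_true(s$l_x >= s$l)
    expect_true(s$l_x < 2 * max(vapply(seeds, function(x) x$l_x, 0L)))
    expect_true(all(s$instances$width == s$l_x))
    expect_true(all(s$instances$start >= 1))
  }
  # the planted 22-mer is reassembled
  expect_true(any(vapply(seeds, function(s) s$l_x, 0L) >= 20))
})

test_that("a window narrower than the segment warns", {
  expect_warning(
    count_cooccurrence(pm(1L, 1L), pm(1L, 2L), 10L, 100L),
    "narrower")
})
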