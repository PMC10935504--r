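#' Bookend parameters
#'
#' @param d co-occurrence window width in bp (default 25).
#' @param p_cutoff significance level for the binomial co-occurrence test
#'   (default 0.05).
#' @param rounds number of merge rounds (default 3). Later rounds test the
#'   merged motifs of earlier rounds against each other and against the
#'   originals, so a wide motif fragmented into several partially
#'   overlapping cliques is reassembled stepwise; a round that produces no
#'   new seed stops the iteration early.
#' @param max_seeds cap on the seed list carried between rounds and
#'   returned (default 40), keeping the strongest by instance mass
#'   (site count times width).
#' @return A list of class `bookend_params`.
#' @export
bookend_params <- function(d = 25L, p_cutoff = 0.05, rounds = 3L,
                           max_seeds = 40L) {
  if (d < 1L) stop("window width d must be at least 1")
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must lie in (0, 1)")
  if (rounds < 1L) stop("rounds must be at least 1")
  structure(list(d = as.integer(d), p_cutoff = p_cutoff,
                 rounds = as.integer(rounds),
                 max_seeds = as.integer(max_seeds)),
            class = "bookend_params")
}

#' Count co-occurring instance pairs of two potential motifs
#'
#' An instance of one motif co-occurs with an instance of the other when
#' both lie on the same peak (either strand; minus-strand coordinates are
#' mapped to the forward strand first) and their joint span fits inside a
#' window of `d` consecutive bases. Matching is one-to-one: candidate pairs
#' are taken in order of increasing joint span, and each instance
#' participates in at most one counted pair. For every counted pair the
#' signed nucleotide overlap of the two spans is recorded (positive =
#' shared bases, zero or negative = gap).
#'
#' @param ci,cj `potential_motif` objects.
#' @param d window width in bp.
#' @param seqlen integer vector of peak lengths (indexed by peak).
#' @return List with `o` (the co-occurrence count), `overlaps` (signed
#'   overlap per counted pair) and `pairs` (indices of the counted
#'   instance pairs in `ci` and `cj`).
#' @export
count_cooccurrence <- function(ci, cj, d, seqlen) {
  if (d < ci$l) {
    warning("window d = ", d, " is narrower than the segment length ", ci$l)
  }
  fi <- instances_forward(ci$instances, seqlen)
  fj <- instances_forward(cj$instances, seqlen)
  cand <- NULL
  for (a in seq_len(nrow(fi))) {
    same <- which(fj$seqidx == fi$seqidx[a])
    if (!length(same)) next
    span <- pmax(fi$fend[a], fj$fend[same]) - pmin(fi$fstart[a], fj$fstart[same]) + 1L
    cand <- rbind(cand, data.frame(a = a, b = same, span = span))
  }
  if (is.null(cand)) {
    return(list(o = 0L, overlaps = integer(), pairs = NULL))
  }
  cand <- cand[order(cand$span, cand$a, cand$b), ]
  used_a <- logical(nrow(fi)); used_b <- logical(nrow(fj))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$a[k]] && !used_b[cand$b[k]]) {
      keep[k] <- TRUE
      used_a[cand$a[k]] <- TRUE
      used_b[cand$b[k]] <- TRUE
    }
  }
  cand <- cand[keep & cand$span <= d, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(o = 0L, overlaps = integer(), pairs = NULL))
  }
  ov <- pmin(fi$fend[cand$a], fj$fend[cand$b]) -
    pmax(fi$fstart[cand$a], fj$fstart[cand$b]) + 1L
  list(o = nrow(cand), overlaps = as.integer(ov),
       pairs = cand[, c("a", "b")])
}

#' Binomial significance of a co-occurrence count
#'
#' Upper-tail binomial probability of observing at least `o` co-occurring
#' pairs among the `n_j` instances of the smaller motif, under a background
#' rate `p = d * n_i / (m * n)` (clamped into (0, 1]; with ragged peaks `n`
#' is the mean peak length): `P = sum_{k=o}^{n_j} C(n_j, k) p^k (1-p)^(n_j-k)`.
#'
#' @param o co-occurrence count, `0 <= o <= n_j`.
#' @param n_i,n_j instance counts of the two motifs with `n_i >= n_j`
#'   (swapped internally otherwise).
#' @param d window width.
#' @param m number of peaks.
#' @param n peak length (mean length when ragged).
#' @return The tail probability in `[0, 1]`; `o = 0` gives 1.
#' @export
cooccurrence_pvalue <- function(o, n_i, n_j, d, m, n) {
  if (n_i < n_j) { tmp <- n_i; n_i <- n_j; n_j <- tmp }
  if (o > n_j) stop("co-occurrence count exceeds the smaller instance count")
  p <- min(1, max(.Machine$double.eps, d * n_i / (m * n)))
  pbinom(o - 1, n_j, p, lower.tail = FALSE)
}

#' Merge a pair of potential motifs when their co-occurrence is significant
#'
#' When the co-occurrence tail probability falls below `p_cutoff`, the modal
#' positive overlap of the counted pairs (ties broken toward the larger
#' overlap) becomes `l_o`, and each counted pair with exactly that overlap
#' contributes the union span of its two instances — a merged instance of
#' width `l_x = w_i + w_j - l_o` (i.e. `2l - l_o` when both motifs still
#' have the segment width `l`), on the strand of the first motif's member.
#' If the test is not significant, no strictly positive overlap exists, or
#' fewer than two pairs attain the modal overlap, both motifs pass through
#' unmerged.
#'
#' @param ci,cj `potential_motif` objects of the same segment length.
#' @param params a [bookend_params()].
#' @param seqlen integer vector of peak lengths.
#' @param m,n peak count and (mean) peak length for the null rate.
#' @return A list with `merged` (flag), `o`, `p_value`, and when merged,
#'   `l_o`, `l_x` and a merged `potential_motif` in `$motif`.
#' @export
merge_pair <- function(ci, cj, params, seqlen, m, n) {
  if (ci$l != cj$l) stop("motifs must share a segment length to merge")
  cc <- count_cooccurrence(ci, cj, params$d, seqlen)
  ni <- nrow(ci$instances); nj <- nrow(cj$instances)
  pv <- cooccurrence_pvalue(cc$o, ni, nj, params$d, m, n)
  res <- list(merged = FALSE, o = cc$o, p_value = pv)
  if (pv >= params$p_cutoff) return(res)
  pos <- cc$overlaps[cc$overlaps > 0L]
  if (!length(pos)) return(res)
  tab <- table(pos)
  modal <- as.integer(names(tab))[tab == max(tab)]
  l_o <- max(modal)                       # tie -> larger overlap
  w_i <- ci$instances$width[1L]
  w_j <- cj$instances$width[1L]
  l_x <- w_i + w_j - l_o
  sel <- which(cc$overlaps == l_o)
  if (length(sel) < 2L) return(res)       # too little support to refit
  fi <- instances_forward(ci$instances, seqlen)
  fj <- instances_forward(cj$instances, seqlen)
  a <- cc$pairs$a[sel]; b <- cc$pairs$b[sel]
  fstart <- pmin(fi$fstart[a], fj$fstart[b])
  row <- ci$instances$row[a]              # strand from the ci member
  start <- vapply(seq_along(sel), function(k) {
    forward_to_row_start(row[k], fstart[k], l_x, seqlen)
  }, 0L)
  inst <- unique(data.frame(row = row, start = start, width = l_x))
  res$merged <- TRUE
  res$l_o <- l_o
  res$l_x <- l_x
  res$motif <- structure(
    list(instances = inst, l = ci$l, l_o = l_o, l_x = l_x,
         score = mean(c(ci$score, cj$score))),
    class = "potential_motif")
  res
}

#' Width-optimize a set of potential motifs by pairwise bookend merging
#'
#' All unordered pairs of potential motifs sharing a discovery segment
#' length are tested; every significant pair contributes one merged,
#' width-optimized motif (no exclusivity — a motif may take part in several
#' merges, and the downstream ranking after PWM refinement arbitrates among
#' redundant seeds). Further rounds repeat the all-pairs test over the
#' accumulated seed list so partial merges combine toward the full motif
#' span. Motifs that merge with no partner pass through unchanged with
#' `l_x = l` (and `l_o = l_x`); seeds with identical instance sets are
#' deduplicated.
#'
#' @param motifs list of `potential_motif` objects.
#' @param params a [bookend_params()].
#' @param seqlen integer vector of peak lengths.
#' @param verbose log each tested pair.
#' @return List of `potential_motif` seeds carrying `l_o` and `l_x`.
#' @export
bookend_merge <- function(motifs, params = bookend_params(), seqlen,
                          verbose = FALSE) {
  m <- length(seqlen)
  n <- mean(seqlen)
  seed_key <- function(mo) {
    inst <- mo$instances[order(mo$instances$row, mo$instances$start), ]
    paste(inst$row, inst$start, inst$width, collapse = ";")
  }
  seed_mass <- function(mo) nrow(mo$instances) * mo$instances$width[1L]

  seeds <- motifs
  participated <- logical(length(motifs))
  for (round in seq_len(params$rounds)) {
    nm <- length(seeds)
    if (nm < 2L) break
    merged <- list()
    pvals <- numeric()
    for (i in seq_len(nm - 1L)) {
      for (j in seq.int(i + 1L, nm)) {
        if (seeds[[i]]$l != seeds[[j]]$l) next
        mr <- merge_pair(seeds[[i]], seeds[[j]], params, seqlen, m, n)
        if (verbose) {
          message(sprintf("bookend r%d %d~%d: o=%d n_i=%d n_j=%d P=%.3g %s",
                          round, i, j, mr$o, nrow(seeds[[i]]$instances),
                          nrow(seeds[[j]]$instances), mr$p_value,
                          if (mr$merged) "merge" else "keep"))
        }
        if (mr$merged) {
          merged[[length(merged) + 1L]] <- mr$motif
          pvals <- c(pvals, mr$p_value)
          if (round == 1L) participated[i] <- participated[j] <- TRUE
        }
      }
    }
    if (!length(merged)) break
    merged <- merged[order(pvals)]
    pool <- if (round == 1L) {
      c(merged, motifs[!participated])
    } else {
      c(seeds, merged)
    }
    keys <- vapply(pool, seed_key, "")
    pool <- pool[!duplicated(keys)]
    if (length(pool) > params$max_seeds) {
      ord <- order(-vapply(pool, seed_mass, 0))
      pool <- pool[ord[seq_len(params$max_seeds)]]
    }
    if (round > 1L && length(pool) == length(seeds)) {
      seeds <- pool
      break               # no new seed: fixed point
    }
    seeds <- pool
  }
  lapply(seeds, function(mo) {
    if (is.null(mo$l_x)) {
      mo$l_x <- mo$instances$width[1L]
      mo$l_o <- mo$l_x
    }
    mo
  })
}
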