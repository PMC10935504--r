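# Independent reference implementations used to validate the optimized
# pipeline. Everything here is written directly from the definitions in
# plain R, sharing no code with the package internals it checks.

# Exact upper-tail binomial probability at success rate 1/4, as a ratio of
# integers: sum_{j=k}^{l} C(l,j) 3^(l-j) / 4^l. Exact in double for l <= 8
# (numerator and denominator < 2^16).
oracle_binom_tail <- function(k, l) {
  j <- k:l
  sum(choose(l, j) * 3^(l - j)) / 4^l
}

# Co-occurrence tail probability by exhaustive enumeration of all 2^n
# success/failure outcomes (feasible for n <= 12).
oracle_cooccur_pvalue <- function(o, n, p) {
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (bits >= o) total <- total + p^bits * (1 - p)^(n - bits)
  }
  total
}

# Straightforward O(m^2 n^2) reference of the two-stage alignment and graph
# construction. Rows: 2m character rows (odd forward, even revcomp) with
# weight vectors; all four strand combinations between distinct peaks.
oracle_rows <- function(peaks) {
  m <- length(peaks$id)
  rows <- list()
  for (k in seq_len(m)) {
    s <- strsplit(peaks$seq[k], "")[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    w <- if (is.null(peaks$coverage)) rep(1, length(s)) else peaks$coverage[[k]]
    rows[[2L * k - 1L]] <- list(ch = s, w = w, peak = k)
    rows[[2L * k]] <- list(ch = rev(unname(comp[s])), w = rev(w), peak = k)
  }
  rows
}

oracle_f <- function(k, l) {
  p <- sum(choose(l, k:l) * 0.25^(k:l) * 0.75^(l - (k:l)))
  -log10(p)
}

# One increment pass. weight_of(row_index) returns the per-start weight
# vector entering f' = f * (w_a[j] + w_b[q]). Returns per-row counts.
oracle_pass <- function(rows, l, f_threshold, alpha, weight_of) {
  l <- as.integer(l)
  nv <- vapply(rows, function(r) length(r$ch), 0L) - l + 1L
  counts <- lapply(nv, function(n) integer(n))
  fk <- vapply(0:l, oracle_f, 0, l = l)
  nrows <- length(rows)
  for (a in seq_len(nrows - 1L)) {
    for (b in seq.int(a + 1L, nrows)) {
      if (rows[[a]]$peak == rows[[b]]$peak) next
      wa <- weight_of(a); wb <- weight_of(b)
      fmat <- matrix(0, nv[a], nv[b])
      fpmat <- matrix(0, nv[a], nv[b])
      for (j in seq_len(nv[a])) {
        for (q in seq_len(nv[b])) {
          sa <- rows[[a]]$ch[j:(j + l - 1L)]
          sb <- rows[[b]]$ch[q:(q + l - 1L)]
          k <- sum(sa == sb & sa != "N" & sb != "N")
          fmat[j, q] <- fk[k + 1L]
          fpmat[j, q] <- fk[k + 1L] * (wa[j] + wb[q])
        }
      }
      pos <- fpmat[fpmat > 0]
      cut <- if (length(pos)) {
        sort(pos, decreasing = TRUE)[min(alpha, length(pos))]
      } else {
        Inf
      }
      for (j in seq_len(nv[a])) {
        for (q in seq_len(nv[b])) {
          if (fmat[j, q] > f_threshold ||
              (fpmat[j, q] > 0 && fpmat[j, q] >= cut)) {
            counts[[a]][j] <- counts[[a]][j] + 1L
            counts[[b]][q] <- counts[[b]][q] + 1L
          }
        }
      }
    }
  }
  counts
}

oracle_rownorm <- function(v) if (max(v) > 0) v / max(v) else v * 0

# Full two-stage reference: returns m1, m2 (combined weights) and the
# edge set of the similarity graph at rank cutoff beta.
oracle_stage <- function(peaks, l, f_threshold = 3, alpha = 5, beta = 3) {
  l <- as.integer(l)
  rows <- oracle_rows(peaks)
  nv <- vapply(rows, function(r) length(r$ch), 0L) - l + 1L
  m1 <- oracle_pass(rows, l, f_threshold, alpha,
                    function(i) rows[[i]]$w[seq_len(nv[i])])
  nbmax <- lapply(m1, function(v) {
    vapply(seq_along(v), function(j) {
      max(v[max(1L, j - 2L):min(length(v), j + 2L)])
    }, 0)
  })
  m2c <- oracle_pass(rows, l, f_threshold, alpha, function(i) nbmax[[i]])
  m2 <- lapply(seq_along(m2c), function(i) {
    oracle_rownorm(as.numeric(m2c[[i]])) +
      oracle_rownorm(rows[[i]]$w)[seq_len(nv[i])]
  })
  fk <- vapply(0:l, oracle_f, 0, l = l)
  edges <- NULL
  nrows <- length(rows)
  for (a in seq_len(nrows - 1L)) {
    for (b in seq.int(a + 1L, nrows)) {
      if (rows[[a]]$peak == rows[[b]]$peak) next
      fpmat <- matrix(0, nv[a], nv[b])
      for (j in seq_len(nv[a])) {
        for (q in seq_len(nv[b])) {
          sa <- rows[[a]]$ch[j:(j + l - 1L)]
          sb <- rows[[b]]$ch[q:(q + l - 1L)]
          k <- sum(sa == sb & sa != "N" & sb != "N")
          fpmat[j, q] <- fk[k + 1L] * (m2[[a]][j] + m2[[b]][q])
        }
      }
      pos <- fpmat[fpmat > 0]
      if (!length(pos)) next
      cut <- sort(pos, decreasing = TRUE)[min(beta, length(pos))]
      hit <- which(fpmat > 0 & fpmat >= cut, arr.ind = TRUE)
      edges <- rbind(edges, data.frame(
        row_a = a, pos_a = hit[, 1L], row_b = b, pos_b = hit[, 2L],
        weight = fpmat[hit]))
    }
  }
  list(m1 = m1, m2 = m2, edges = edges)
}

# Random small peak set with coverage, for oracle comparisons.
random_peak_set <- function(seed, m = 4L, n = 30L, with_cov = TRUE) {
  set.seed(seed)
  seqs <- vapply(seq_len(m), function(i) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
  cov <- if (with_cov) {
    lapply(seq_len(m), function(i) runif(n))
  } else {
    NULL
  }
  ps <- peak_set(sprintf("s%d", seq_len(m)), seqs, cov)
  ps$normalized <- with_cov   # treat raw uniforms as already-normalized weights
  ps
}

# Compare the package edge table to the oracle's, ignoring ordering.
edge_key <- function(e) {
  if (is.null(e) || nrow(e) == 0L) return(character())
  sort(sprintf("%d:%d-%d:%d=%.8f", e$row_a, e$pos_a, e$row_b, e$pos_b, e$weight))
}

# Build an alignment_graph object directly from an edge list; vertex i is
# placed on forward row 2i-1 so each lives on a distinct peak.
graph_from_edges <- function(nv, edges, l = 8L) {
  ed <- data.frame(row_a = 2L * edges$a - 1L,
                   pos_a = rep(1L, nrow(edges)),
                   row_b = 2L * edges$b - 1L,
                   pos_b = rep(1L, nrow(edges)),
                   weight = edges$w)
  verts <- data.frame(row = 2L * seq_len(nv) - 1L, start = 1L)
  structure(list(vertices = verts, edges = ed, l = l,
                 seqidx = rep(seq_len(nv), each = 2L)),
            class = "alignment_graph")
}

rc_pwm <- function(p) p[4:1, rev(seq_len(ncol(p))), drop = FALSE]

motif_freq <- function(mm) (mm$counts + 0.25) / (mm$nsites + 1)
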