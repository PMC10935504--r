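#' Normalize a raw coverage vector to [0, 1]
#'
#' Each value x is mapped to `log(1 + x) / max_j log(1 + x_j)`, so the
#' best-covered base of every peak gets weight 1 and the transform is
#' invariant to the logarithm base. An all-zero vector maps to all zeros.
#'
#' @param raw numeric vector of non-negative raw coverage values.
#' @return Numeric vector of the same length with values in `[0, 1]`.
#' @examples
#' normalize_coverage(c(1, 3))   # 0.5, 1
#' @export
normalize_coverage <- function(raw) {
  if (any(raw < 0)) stop("coverage values must be non-negative")
  lx <- log1p(raw)
  mx <- max(lx)
  if (mx == 0) return(numeric(length(raw)))
  lx / mx
}

#' Normalize coverage across a peak set
#'
#' Applies [normalize_coverage()] record-wise. Basic-mode sets are returned
#' unchanged.
#'
#' @param peaks a [peak_set()].
#' @return A `peak_set` with normalized coverage.
#' @export
normalize_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.null(peaks$coverage) || isTRUE(peaks$normalized)) return(peaks)
  out <- peak_set(peaks$id, peaks$seq,
                  lapply(peaks$coverage, normalize_coverage))
  out$normalized <- TRUE
  out
}

#' Reverse complement of a DNA string
#'
#' Alphabet `A/C/G/T/N`; `N` maps to `N`. Vectorized over its argument.
#'
#' @param seq character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    stop("invalid character in DNA sequence (alphabet is A/C/G/T/N)")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Build the strand-expanded coverage matrix
#'
#' For m peaks, constructs 2m rows: row 2k-1 carries the forward sequence of
#' peak k with its normalized coverage, row 2k its reverse complement with
#' the coverage vector reversed (the only position-consistent choice). In
#' basic mode every weight is 1, so similarity scores reduce to twice the
#' plain binomial statistic.
#'
#' @param peaks a normalized `peak_set`.
#' @return A list of class `strand_matrix` with `seq` (character rows),
#'   `w` (numeric weight rows), `seqidx` (original peak of each row) and
#'   `strand` (`"+"` or `"-"` per row).
#' @export
build_strand_matrix <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  m <- length(peaks)
  n <- nchar(peaks$seq)
  rc <- reverse_complement(peaks$seq)
  seqs <- character(2L * m)
  w <- vector("list", 2L * m)
  for (k in seq_len(m)) {
    seqs[2L * k - 1L] <- peaks$seq[k]
    seqs[2L * k] <- rc[k]
    wk <- if (is.null(peaks$coverage)) rep(1, n[k]) else peaks$coverage[[k]]
    w[[2L * k - 1L]] <- wk
    w[[2L * k]] <- rev(wk)
  }
  structure(
    list(seq = seqs, w = w,
         seqidx = rep(seq_len(m), each = 2L),
         strand = rep(c("+", "-"), m),
         nbase = rep(n, each = 2L)),
    class = "strand_matrix"
  )
}

# Map instances given in strand-matrix row coordinates (1-based start on the
# row's own orientation) to forward-strand coordinates on the original peak.
instances_forward <- function(inst, seqlen_by_peak) {
  seqidx <- (inst$row + 1L) %/% 2L
  n <- seqlen_by_peak[seqidx]
  minus <- inst$row %% 2L == 0L
  fstart <- ifelse(minus, n - (inst$start + inst$width - 1L) + 1L, inst$start)
  data.frame(seqidx = seqidx, fstart = fstart,
             fend = fstart + inst$width - 1L,
             strand = ifelse(minus, "-", "+"),
             stringsAsFactors = FALSE)
}

# Inverse of instances_forward for a single instance: forward span back to
# row-local start on the given row.
forward_to_row_start <- function(row, fstart, width, seqlen_by_peak) {
  n <- seqlen_by_peak[(row + 1L) %/% 2L]
  if (row %% 2L == 0L) n - (fstart + width - 1L) + 1L else fstart
}

# Encode A/C/G/T/N as 0/1/2/3/4 for the compiled alignment kernels.
encode_dna <- function(seq) {
  lapply(strsplit(seq, ""), function(ch) {
    v <- match(ch, c("A", "C", "G", "T")) - 1L
    v[is.na(v)] <- 4L
    v
  })
}
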