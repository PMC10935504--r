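#' Identical positions between two equal-length segments
#'
#' Positions where either base is `N` never count as identical.
#'
#' @param a,b DNA strings of equal length.
#' @return Integer count of identical positions.
#' @export
count_identities <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("segments must have equal length")
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  sum(ca == cb & ca != "N" & cb != "N")
}

#' Binomial segment-similarity statistic
#'
#' The significance of observing `k` identical positions between two
#' length-`l` segments under a uniform 0.25 background, as
#' `f = -log10 P(X >= k)` with `X ~ Binomial(l, 0.25)`. Computed in log
#' space so large `l` does not underflow. `f(0, l) = 0` (the full tail sums
#' to one) and `f(l, l) = l log10 4`.
#'
#' @param k integer count(s) of identical positions, `0 <= k <= l`.
#' @param l segment length.
#' @return Numeric statistic(s), `>= 0`, strictly increasing in `k`.
#' @examples
#' segment_similarity(4, 4)    # -log10(0.25^4) = 2.40824
#' @export
segment_similarity <- function(k, l) {
  if (any(k < 0) || any(k > l)) stop("k must lie in [0, l]")
  -pbinom(k - 1, l, 0.25, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# f(k) lookup for k = 0..l (index k + 1).
similarity_table <- function(l) segment_similarity(0:l, l)

# Smallest k with f(k) > threshold; l + 1 when no k qualifies.
threshold_k <- function(l, f_threshold) {
  fk <- similarity_table(l)
  hit <- which(fk > f_threshold)
  if (length(hit)) hit[1L] - 1L else l + 1L
}

#' Coverage-weighted first-stage score
#'
#' Combines the binomial similarity of a segment pair with the normalized
#' coverage at both segment start positions: `f' = f * (w_a + w_b)`. In
#' basic mode both weights are 1 and the score is `2 f`.
#'
#' @param f binomial similarity statistic.
#' @param w_a,w_b weights of the two segments.
#' @return Weighted score.
#' @export
weighted_similarity <- function(f, w_a, w_b) f * (w_a + w_b)

#' Alignment parameter set
#'
#' @param l segment length (default 14).
#' @param f_threshold similarity cutoff on `f` (default 3, i.e. upper-tail
#'   probability below 1e-3).
#' @param alpha per-row-pair rank cutoff for the weighted score (default 5).
#' @param l_range optional integer vector of segment lengths to iterate
#'   over; overrides `l` during discovery.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(l = 14L, f_threshold = 3, alpha = 5L,
                             l_range = NULL) {
  l <- as.integer(l)
  if (l < 4L) stop("segment length l must be at least 4")
  if (alpha < 1L) stop("alpha must be at least 1")
  if (f_threshold < 0) stop("f_threshold must be non-negative")
  if (!is.null(l_range)) {
    l_range <- as.integer(l_range)
    if (any(l_range < 4L)) stop("all lengths in l_range must be at least 4")
  }
  structure(list(l = l, f_threshold = f_threshold, alpha = as.integer(alpha),
                 l_range = l_range),
            class = "alignment_params")
}

check_l <- function(sm, l) {
  short <- which(sm$nbase < l)
  if (length(short)) {
    stop("segment length ", l, " exceeds sequence length of peak ",
         sm$seqidx[short[1L]])
  }
}

#' First alignment pass: coverage-weighted support counts
#'
#' For every pair of strand-matrix rows drawn from distinct peaks (all four
#' strand combinations), every pair of l-segments is scored; a segment start
#' earns one support count when the plain similarity `f` exceeds
#' `f_threshold` or the coverage-weighted score ranks within the top
#' `alpha` over that row pair (ties at the cutoff included; zero scores
#' never rank).
#'
#' @param sm a [build_strand_matrix()] result.
#' @param params an [alignment_params()].
#' @return List of integer support-count vectors, one per row, over valid
#'   segment starts.
#' @export
first_pass <- function(sm, params = alignment_params()) {
  check_l(sm, params$l)
  enc <- encode_dna(sm$seq)
  w <- lapply(sm$w, function(v) v[seq_len(length(v) - params$l + 1L)])
  cpp_all_pairs(enc, w, sm$seqidx, params$l,
                similarity_table(params$l),
                threshold_k(params$l, params$f_threshold),
                params$alpha, FALSE)
}

#' Second alignment pass and combined position weights
#'
#' Rescoring uses the first-pass support aggregated over a +/-2 bp
#' neighborhood of both segment starts: `f' = f * max(M1[a, j'] + M1[b, q'])`
#' over `j'` and `q'` within two bases of `j` and `q` (the window truncates
#' at row ends). The same increment rule as the first pass yields M2; then
#' both the coverage matrix and M2 are row-max normalized and summed, giving
#' the per-position weight matrix that drives graph construction.
#'
#' @param sm a [build_strand_matrix()] result.
#' @param m1 first-pass support counts, as returned by [first_pass()].
#' @param params an [alignment_params()].
#' @return List with `m2` (combined weights per row over valid starts) and
#'   `w_norm` (row-max-normalized coverage over all positions).
#' @export
second_pass <- function(sm, m1, params = alignment_params()) {
  check_l(sm, params$l)
  enc <- encode_dna(sm$seq)
  nb <- cpp_neighborhood(m1)
  m2 <- cpp_all_pairs(enc, nb, sm$seqidx, params$l,
                      similarity_table(params$l),
                      threshold_k(params$l, params$f_threshold),
                      params$alpha, FALSE)
  w_norm <- lapply(sm$w, row_max_normalize)
  m2 <- lapply(seq_along(m2), function(i) {
    v <- row_max_normalize(as.numeric(m2[[i]]))
    v + w_norm[[i]][seq_along(v)]
  })
  list(m2 = m2, w_norm = w_norm)
}

cpp_neighborhood <- function(m1) {
  lapply(m1, function(v) cpp_window_max(as.numeric(v), 2L))
}

row_max_normalize <- function(v) {
  mx <- max(v)
  if (mx <= 0) return(numeric(length(v)))
  v / mx
}

#' Run the full two-stage alignment
#'
#' Convenience wrapper chaining [build_strand_matrix()], [first_pass()] and
#' [second_pass()].
#'
#' @param peaks a normalized `peak_set`.
#' @param params an [alignment_params()].
#' @return List with the strand matrix `sm`, support counts `m1`, combined
#'   weights `m2` and normalized coverage `w_norm`.
#' @export
alignment_matrices <- function(peaks, params = alignment_params()) {
  sm <- build_strand_matrix(peaks)
  m1 <- first_pass(sm, params)
  sp <- second_pass(sm, m1, params)
  list(sm = sm, m1 = m1, m2 = sp$m2, w_norm = sp$w_norm)
}
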