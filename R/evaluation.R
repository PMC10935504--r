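#' Classification score of a sequence against a motif
#'
#' The maximum plain PWM log-odds sum over every width-`l_x` window on both
#' strands. No coverage term enters: the score must be computable for
#' negative sequences, which carry none.
#'
#' @param seq DNA string (length at least the motif width).
#' @param model a `motif_model`.
#' @return The maximum log-odds window score.
#' @export
score_sequence <- function(seq, model) {
  seq <- toupper(seq)
  if (nchar(seq) < model$width) {
    stop("sequence shorter than the motif width ", model$width)
  }
  best <- -Inf
  ones <- function(n) rep(1, n)
  for (s in c(seq, reverse_complement(seq))) {
    enc <- encode_dna(s)[[1L]]
    # unit coverage and full-width window turn the match score into the
    # plain log-odds sum
    sc <- cpp_score_segments(enc, model$pwm, ones(nchar(s)), 0L, model$width)
    best <- max(best, sc)
  }
  best
}

#' Score many sequences against a motif
#'
#' @param seqs character vector of DNA sequences, or a `peak_set`.
#' @param model a `motif_model`.
#' @return Numeric vector of [score_sequence()] values.
#' @export
score_sequences <- function(seqs, model) {
  if (inherits(seqs, "peak_set")) seqs <- seqs$seq
  vapply(seqs, score_sequence, 0, model = model, USE.NAMES = FALSE)
}

#' Restricted-range partial AUC of a score-based classifier
#'
#' Builds the empirical ROC curve (threshold sweep; tied scores produce the
#' usual diagonal segments, equivalent to averaging) and reports two partial
#' areas: `pauc_specificity` integrates TPR over FPR in (0, 0.2);
#' `pauc_sensitivity` integrates 1 - FPR over TPR in (0.8, 1.0). Both are
#' standardized (McClish) to `[0, 1]` against the band's chance and perfect
#' areas, `0.5 (1 + (A - A_min) / (A_max - A_min))`, so a perfect
#' classifier scores 1 and an uninformative one 0.5 on either metric.
#'
#' @param pos_scores,neg_scores numeric score vectors for the positive and
#'   negative sequences (higher = more positive).
#' @param fpr_max upper FPR bound of the specificity band (default 0.2).
#' @param tpr_min lower TPR bound of the sensitivity band (default 0.8).
#' @return A list of class `roc_result` with `thresholds`, `fpr`, `tpr`,
#'   `pauc_sensitivity` and `pauc_specificity`.
#' @export
partial_auc <- function(pos_scores, neg_scores, fpr_max = 0.2, tpr_min = 0.8) {
  if (!length(pos_scores) || !length(neg_scores)) {
    stop("both score vectors must be nonempty")
  }
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), 0)
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  fpr <- fpr[keep]; tpr <- tpr[keep]

  # area under the piecewise-linear curve for x in [0, xmax]
  area_under <- function(x, y, xmax) {
    a <- 0
    for (k in seq_len(length(x) - 1L)) {
      x0 <- x[k]; x1 <- x[k + 1L]; y0 <- y[k]; y1 <- y[k + 1L]
      if (x0 >= xmax) break
      if (x1 > xmax) {   # clip the segment at xmax
        y1 <- y0 + (y1 - y0) * (xmax - x0) / (x1 - x0)
        x1 <- xmax
      }
      a <- a + (x1 - x0) * (y0 + y1) / 2
    }
    a
  }
  mcclish <- function(a, amin, amax) {
    0.5 * (1 + (max(a, amin) - amin) / (amax - amin))
  }
  a_spec <- area_under(fpr, tpr, fpr_max)
  pauc_spec <- mcclish(a_spec, fpr_max^2 / 2, fpr_max)
  # integrate (1 - FPR) dTPR over TPR in [tpr_min, 1]; the curve is monotone
  # nondecreasing in TPR, so swap the roles of the axes and clip from above
  a <- 0
  for (k in seq_len(length(tpr) - 1L)) {
    y0 <- tpr[k]; y1 <- tpr[k + 1L]; x0 <- fpr[k]; x1 <- fpr[k + 1L]
    if (y1 <= tpr_min) next
    if (y0 < tpr_min) {   # clip the segment at tpr_min
      x0 <- x0 + (x1 - x0) * (tpr_min - y0) / (y1 - y0)
      y0 <- tpr_min
    }
    a <- a + (y1 - y0) * (1 - (x0 + x1) / 2)
  }
  pauc_sens <- mcclish(a, (1 - tpr_min)^2 / 2, 1 - tpr_min)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr,
                 pauc_sensitivity = pauc_sens,
                 pauc_specificity = pauc_spec),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("pAUC(sensitivity) = %.4f   pAUC(specificity) = %.4f\n",
              x$pauc_sensitivity, x$pauc_specificity))
  invisible(x)
}

#' Sample negative sequences uniformly from a genome
#'
#' One uniformly placed interval per requested length; intervals with more
#' than 50% `N` are resampled (up to 100 tries each). Deterministic under
#' the seed.
#'
#' @param genome named character vector / `DNAStringSet` of contigs.
#' @param lengths integer vector of sequence lengths to draw.
#' @param seed integer RNG seed.
#' @return A basic-mode `peak_set` of sampled sequences.
#' @export
sample_negatives <- function(genome, lengths, seed = 1L) {
  genome <- as_genome(genome)
  clen <- nchar(genome)
  if (max(lengths) > max(clen)) {
    stop("requested length ", max(lengths), " exceeds the longest contig")
  }
  old <- .Random.seed_guard(seed)
  on.exit(old())
  ids <- seqs <- character(length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    ok_contigs <- which(clen >= L)
    for (try in seq_len(100L)) {
      ci <- ok_contigs[sample.int(length(ok_contigs), 1L)]
      start <- sample.int(clen[ci] - L + 1L, 1L)
      s <- substr(genome[ci], start, start + L - 1L)
      if (mean(strsplit(s, "")[[1L]] == "N") <= 0.5) break
      if (try == 100L) stop("could not place a negative after 100 tries")
    }
    ids[i] <- sprintf("neg_%d_%s:%d-%d", i, names(genome)[ci],
                      start - 1L, start - 1L + L)
    seqs[i] <- s
  }
  peak_set(ids, seqs)
}

# Seed the RNG locally; returns a restore function.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate motifs as sequence classifiers
#'
#' Scores positive and negative sets with each motif and reports the two
#' standardized partial AUCs per motif.
#'
#' @param fit an `exomotif` fit or list of `motif_model`s.
#' @param positives a `peak_set` or character vector of positive sequences.
#' @param negatives a `peak_set` or character vector of negative sequences.
#' @return Data frame with one row per motif: `motif`, `pauc_sensitivity`,
#'   `pauc_specificity`.
#' @export
evaluate_motifs <- function(fit, positives, negatives) {
  motifs <- if (inherits(fit, "exomotif")) fit$motifs else fit
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  if (!length(motifs)) stop("no motifs to evaluate")
  rows <- lapply(seq_along(motifs), function(i) {
    mm <- motifs[[i]]
    roc <- partial_auc(score_sequences(positives, mm),
                       score_sequences(negatives, mm))
    data.frame(motif = if (!is.null(mm$name)) mm$name else paste0("motif_", i),
               pauc_sensitivity = roc$pauc_sensitivity,
               pauc_specificity = roc$pauc_specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
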