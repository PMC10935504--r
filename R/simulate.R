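#' Specification of a synthetic planted-motif dataset
#'
#' Describes peak sequences with motif instances planted from a known PWM on
#' either strand, and triangular coverage bumps centered on the planted
#' sites, so every pipeline stage can be validated against ground truth.
#'
#' @param pwm 4 x w matrix of per-column nucleotide frequencies (rows
#'   A, C, G, T, columns summing to 1), or `NULL` for a random informative
#'   PWM of width `width` (see [random_pwm()]).
#' @param width motif width when `pwm` is `NULL` (default 14).
#' @param m number of peak sequences (default 20).
#' @param peak_len peak length in bp (default 200).
#' @param plant_rate fraction of sequences receiving one instance
#'   (default 0.9).
#' @param background length-4 background frequencies for non-motif bases
#'   (default uniform).
#' @param coverage_height peak height of the triangular coverage bump added
#'   to a baseline of 1 (default 9, i.e. a ~10x enrichment at the site).
#' @param coverage_halfwidth half-width of the bump in bp (default 30).
#' @param seed integer RNG seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(pwm = NULL, width = 14L, m = 20L, peak_len = 200L,
                       plant_rate = 0.9, background = rep(0.25, 4),
                       coverage_height = 9, coverage_halfwidth = 30L,
                       seed = 1L) {
  if (plant_rate < 0 || plant_rate > 1) stop("plant_rate must lie in [0, 1]")
  if (!is.null(pwm)) {
    if (nrow(pwm) != 4L) stop("pwm must have 4 rows (A, C, G, T)")
    if (any(abs(colSums(pwm) - 1) > 1e-8)) stop("pwm columns must sum to 1")
    width <- ncol(pwm)
  }
  if (width > peak_len) stop("motif width exceeds the peak length")
  stopifnot(abs(sum(background) - 1) < 1e-8)
  structure(list(pwm = pwm, width = as.integer(width), m = as.integer(m),
                 peak_len = as.integer(peak_len), plant_rate = plant_rate,
                 background = background,
                 coverage_height = coverage_height,
                 coverage_halfwidth = as.integer(coverage_halfwidth),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Random informative PWM
#'
#' Each column concentrates mass `1 - noise` on one uniformly chosen base
#' and spreads `noise` over the other three. With the default
#' `noise = 0.025` the information content is about 1.8 bits per column,
#' typical of a strong bacterial TF motif.
#'
#' @param width motif width.
#' @param noise total off-consensus probability per column.
#' @param seed integer RNG seed.
#' @return A 4 x width frequency matrix with rownames A, C, G, T.
#' @export
random_pwm <- function(width = 14L, noise = 0.025, seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old())
  pwm <- matrix(noise / 3, 4L, width, dimnames = list(DNA, NULL))
  cons <- sample.int(4L, width, replace = TRUE)
  for (j in seq_len(width)) pwm[cons[j], j] <- 1 - noise
  pwm
}

sample_from_pwm <- function(pwm) {
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    sample(DNA, 1L, prob = pwm[, j])
  }, ""), collapse = "")
}

#' Generate a planted-motif peak set with coverage
#'
#' Background bases are i.i.d. from the background distribution; each
#' selected sequence receives one instance sampled column-wise from the
#' planted PWM, on a uniformly chosen strand at a uniformly chosen
#' position. Raw coverage is a baseline of 1 plus a triangular bump of the
#' requested height and half-width centered on the planted site, then
#' log-normalized to `[0, 1]`. Deterministic under the spec's seed.
#'
#' @param spec a [plant_spec()].
#' @return List with `peaks` (a normalized `"cov"`-mode `peak_set`),
#'   `truth` (data frame `seq`, `pos`, `strand` of planted instances,
#'   1-based forward coordinates), and `pwm` (the planted matrix).
#' @export
generate_planted_dataset <- function(spec) {
  old <- .Random.seed_guard(spec$seed)
  on.exit(old())
  pwm <- if (is.null(spec$pwm)) {
    random_pwm(spec$width, seed = spec$seed + 1000L)
  } else {
    spec$pwm
  }
  w <- ncol(pwm)
  planted <- runif(spec$m) < spec$plant_rate
  seqs <- character(spec$m)
  cov <- vector("list", spec$m)
  truth <- NULL
  for (i in seq_len(spec$m)) {
    s <- sample(DNA, spec$peak_len, replace = TRUE, prob = spec$background)
    raw <- rep(1, spec$peak_len)
    if (planted[i]) {
      inst <- sample_from_pwm(pwm)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") inst <- reverse_complement(inst)
      pos <- sample.int(spec$peak_len - w + 1L, 1L)
      s[pos:(pos + w - 1L)] <- strsplit(inst, "")[[1L]]
      center <- pos + (w - 1) / 2
      bump <- pmax(0, spec$coverage_height *
                        (1 - abs(seq_len(spec$peak_len) - center) /
                           spec$coverage_halfwidth))
      raw <- raw + bump
      truth <- rbind(truth, data.frame(seq = i, pos = pos, strand = strand))
    }
    seqs[i] <- paste(s, collapse = "")
    cov[[i]] <- raw
  }
  peaks <- normalize_peaks(
    peak_set(sprintf("peak_%02d", seq_len(spec$m)), seqs, cov))
  list(peaks = peaks,
       truth = if (is.null(truth)) {
         data.frame(seq = integer(), pos = integer(), strand = character())
       } else truth,
       pwm = pwm)
}

#' Generate a split-motif dataset for width-recovery tests
#'
#' Plants one contiguous motif of `total_width` bases (wider than the
#' discovery segment length), so that two overlapping l-mers cover it and
#' the bookend merge should reconstruct the full width.
#'
#' @param spec a [plant_spec()]; its `pwm`/`width` are replaced.
#' @param total_width full planted width (default 22).
#' @param noise per-column off-consensus probability (default 0.05).
#' @return As [generate_planted_dataset()], with a `total_width`-wide PWM.
#' @export
generate_split_motif_dataset <- function(spec, total_width = 22L,
                                         noise = 0.05) {
  spec$pwm <- random_pwm(total_width, noise = noise, seed = spec$seed + 2000L)
  spec$width <- as.integer(total_width)
  generate_planted_dataset(spec)
}

#' Fraction of planted sites recovered by reported instances
#'
#' A truth site counts as recovered when some reported instance on the same
#' peak overlaps at least half of the planted width (strand ignored: a site
#' found on the opposite strand still covers the same bases).
#'
#' @param fit an `exomotif` fit or a single `motif_model`.
#' @param truth truth data frame from the generators.
#' @param peaks the `peak_set` analysed.
#' @param planted_width width of the planted motif.
#' @return Fraction in `[0, 1]` of truth sites recovered.
#' @export
site_recovery <- function(fit, truth, peaks, planted_width) {
  model <- if (inherits(fit, "exomotif")) fit$motifs[[1L]] else fit
  if (nrow(truth) == 0L) return(NA_real_)
  fw <- instances_forward(model$instances, nchar(peaks$seq))
  hit <- vapply(seq_len(nrow(truth)), function(k) {
    same <- fw$seqidx == truth$seq[k]
    if (!any(same)) return(FALSE)
    t0 <- truth$pos[k]; t1 <- t0 + planted_width - 1L
    ov <- pmin(fw$fend[same], t1) - pmax(fw$fstart[same], t0) + 1L
    any(ov >= planted_width / 2)
  }, TRUE)
  mean(hit)
}

#' Correlation between planted and recovered PWM columns
#'
#' Aligns the recovered PWM against the planted one over all offsets and
#' both orientations, and reports the best Pearson correlation between the
#' stacked overlapping frequency columns (at least 8 columns must overlap).
#'
#' @param recovered a `motif_model`.
#' @param planted 4 x w planted frequency matrix.
#' @return The best correlation in `[-1, 1]`.
#' @export
pwm_recovery_cor <- function(recovered, planted) {
  rec <- motif_frequencies(recovered)
  revcomp_pwm <- function(p) p[4:1, rev(seq_len(ncol(p))), drop = FALSE]
  best <- -1
  for (mat in list(rec, revcomp_pwm(rec))) {
    for (off in seq(-ncol(mat) + 1L, ncol(planted) - 1L)) {
      i1 <- max(1L, 1L - off); i2 <- min(ncol(mat), ncol(planted) - off)
      if (i2 - i1 + 1L < min(8L, ncol(planted))) next
      a <- as.vector(mat[, i1:i2])
      b <- as.vector(planted[, (i1 + off):(i2 + off)])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      best <- max(best, stats::cor(a, b))
    }
  }
  best
}

#' Site-level precision of reported instances
#'
#' The fraction of the top motif's instances that overlap a planted site on
#' their peak by at least half of the narrower of the two widths.
#'
#' @inheritParams site_recovery
#' @return Fraction in `[0, 1]`, or `NA` when the fit has no motifs.
#' @export
site_precision <- function(fit, truth, peaks, planted_width) {
  motifs <- if (inherits(fit, "exomotif")) fit$motifs else list(fit)
  if (!length(motifs)) return(NA_real_)
  model <- motifs[[1L]]
  fw <- instances_forward(model$instances, nchar(peaks$seq))
  ok <- vapply(seq_len(nrow(fw)), function(k) {
    tt <- truth[truth$seq == fw$seqidx[k], ]
    if (!nrow(tt)) return(FALSE)
    t1 <- tt$pos + planted_width - 1L
    ov <- pmin(fw$fend[k], t1) - pmax(fw$fstart[k], tt$pos) + 1L
    any(ov >= min(planted_width, model$width) / 2)
  }, TRUE)
  mean(ok)
}
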