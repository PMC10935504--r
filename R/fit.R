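#' Coverage-weighted de novo motif discovery
#'
#' Fits motif models to a set of narrow-peak sequences. The pipeline: (1)
#' per-peak log-normalization of coverage and expansion into a 2m-row
#' strand matrix; (2) a two-stage all-against-all segment alignment scored
#' by an upper-tail binomial statistic weighted first by coverage, then by
#' neighborhood-aggregated first-pass support; (3) a segment-similarity
#' graph whose top-ranked pairs per row pair become weighted edges; (4)
#' disjoint maximal cliques extracted greedily as potential motifs; (5) a
#' binomial "bookend" co-occurrence test that merges fragment pairs into
#' width-optimized seeds (`l_x = 2l - l_o`, `l_o` the modal overlap); (6)
#' PWM construction over the genomic background and match-score expansion
#' of the instance sets.
#'
#' @param x the peaks: a `peak_set`, a character vector of sequences, or a
#'   path to a FASTA or coverage-FASTA file.
#' @param coverage optional list of raw per-base coverage vectors (one per
#'   sequence); ignored when `x` already carries coverage.
#' @param mode `"auto"` (coverage-weighted when coverage is present),
#'   `"cov"`, or `"basic"` (discard coverage, all weights 1).
#' @param l segment length for the alignment (default 14).
#' @param l_range optional integer vector of segment lengths to iterate.
#' @param f_threshold similarity cutoff on the binomial statistic
#'   (default 3).
#' @param alpha per-row-pair rank cutoff in the alignment passes
#'   (default 5).
#' @param beta per-row-pair rank cutoff for graph edges (default 3).
#' @param d bookend co-occurrence window in bp (default 25).
#' @param p_cutoff bookend significance level (default 0.05).
#' @param t flank parameter of the match-score coverage window (default 2).
#' @param min_clique_size,max_motifs clique filtering (defaults 3 and 10).
#' @param genome optional genome (named character vector / `DNAStringSet`)
#'   for the background estimate; peaks are used otherwise.
#' @param expand run the match-score instance expansion (default `TRUE`).
#' @param expansion_iterations passes of the expansion (default 1).
#' @param verbose log pipeline progress.
#' @return An object of class `exomotif`: a list with `motifs` (list of
#'   `motif_model`, ranked), `peaks`, `params`, `mode`, `background` and
#'   the strand matrix / normalized coverage needed to score instances.
#' @examples
#' sim <- generate_planted_dataset(plant_spec(m = 8, peak_len = 80, seed = 7))
#' fit <- exomotif(sim$peaks)
#' fit
#' @export
exomotif <- function(x, coverage = NULL, mode = c("auto", "cov", "basic"),
                     l = 14L, l_range = NULL, f_threshold = 3, alpha = 5L,
                     beta = 3L, d = 25L, p_cutoff = 0.05, t = 2L,
                     min_clique_size = 3L, max_motifs = 10L, genome = NULL,
                     expand = TRUE, expansion_iterations = 1L,
                     verbose = FALSE) {
  mode <- match.arg(mode)
  peaks <- as_peak_set(x, coverage)
  if (mode == "basic" && !is.null(peaks$coverage)) {
    peaks <- peak_set(peaks$id, peaks$seq)
  }
  if (mode == "cov" && is.null(peaks$coverage)) {
    stop("mode 'cov' requested but no coverage available")
  }
  mode <- if (is.null(peaks$coverage)) "basic" else "cov"
  peaks <- normalize_peaks(peaks)

  ap <- alignment_params(l = l, f_threshold = f_threshold, alpha = alpha,
                         l_range = l_range)
  gp <- graph_params(beta = beta, min_clique_size = min_clique_size,
                     max_motifs = max_motifs)
  bp <- bookend_params(d = d, p_cutoff = p_cutoff)
  if (verbose) message("mode '", mode, "': ", length(peaks), " peak(s)")

  pot <- discover_potential_motifs(peaks, ap, gp)
  if (verbose) message(length(pot), " potential motif(s) from clique detection")
  seqlen <- nchar(peaks$seq)
  seeds <- if (length(pot)) {
    bookend_merge(pot, bp, seqlen, verbose = verbose)
  } else {
    list()
  }

  q <- estimate_background(peaks, genome)
  sm <- build_strand_matrix(peaks)
  w_norm <- lapply(sm$w, row_max_normalize)
  motifs <- list()
  for (i in seq_along(seeds)) {
    sd <- seeds[[i]]
    segs <- vapply(seq_len(nrow(sd$instances)), function(k) {
      segment_seq(sm, sd$instances$row[k], sd$instances$start[k],
                  sd$instances$width[k])
    }, "")
    mm <- build_pwm(segs, q, instances = sd$instances)
    mm$l <- sd$l
    mm$l_o <- sd$l_o
    mm$t <- as.integer(t)
    if (expand) {
      mm <- expand_instances(mm, sm, w_norm, q,
                             iterations = expansion_iterations)
    }
    if (is.null(mm$instances$score)) {
      mm$instances$score <- vapply(seq_len(nrow(mm$instances)), function(k) {
        match_score(mm, sm, w_norm, mm$instances$row[k], mm$instances$start[k])
      }, 0)
    }
    motifs[[i]] <- mm
  }
  if (length(motifs)) {
    # rank by total instance match score: rewards both site support and
    # informative width, so a merged full-width motif outranks its fragments
    ord <- order(-vapply(motifs, function(m) sum(m$instances$score), 0))
    motifs <- motifs[ord]
    motifs <- collapse_redundant(motifs, nchar(peaks$seq))
    motifs <- head(motifs, max(max_motifs, 1L))
    for (i in seq_along(motifs)) motifs[[i]]$name <- paste0("motif_", i)
  }
  structure(
    list(motifs = motifs, peaks = peaks, mode = mode, background = q,
         sm = sm, w_norm = w_norm,
         params = list(l = l, l_range = l_range, f_threshold = f_threshold,
                       alpha = alpha, beta = beta, d = d,
                       p_cutoff = p_cutoff, t = t,
                       min_clique_size = min_clique_size,
                       max_motifs = max_motifs, expand = expand)),
    class = "exomotif"
  )
}

as_peak_set <- function(x, coverage = NULL) {
  if (inherits(x, "peak_set")) return(x)
  if (is.character(x) && length(x) == 1L &&
      (file.exists(x) || grepl("[/\\\\]|\\.(fa|fasta|fna|cfa|txt)$", x,
                               ignore.case = TRUE))) {
    if (!file.exists(x)) stop("cannot interpret 'x': file not found: ", x)
    first <- readLines(x, n = 3L)
    return(if (length(first) >= 3L && startsWith(first[3L], "#")) {
      read_covfasta(x)
    } else {
      read_peak_fasta(x)
    })
  }
  if (is.character(x)) {
    ids <- if (!is.null(names(x))) names(x) else sprintf("seq_%d", seq_along(x))
    return(peak_set(ids, unname(x), coverage))
  }
  stop("cannot interpret 'x' as peaks (peak_set, sequences, or file path)")
}

#' @export
print.exomotif <- function(x, ...) {
  cat(sprintf("Coverage-weighted motif discovery fit (mode '%s')\n", x$mode))
  cat(sprintf("  %d peak(s), segment length %s\n", length(x$peaks),
              if (is.null(x$params$l_range)) x$params$l else
                paste(range(x$params$l_range), collapse = "-")))
  if (!length(x$motifs)) {
    cat("  no motifs found\n")
  } else {
    for (m in x$motifs) {
      cat(sprintf("  %s: width %d, %d sites, consensus %s\n",
                  m$name, m$width, m$nsites, m$consensus))
    }
  }
  invisible(x)
}

#' @export
summary.exomotif <- function(object, ...) {
  tab <- if (length(object$motifs)) {
    do.call(rbind, lapply(object$motifs, function(m) {
      ic <- information_content(m)
      data.frame(motif = m$name, width = m$width, nsites = m$nsites,
                 l_o = if (!is.null(m$l_o)) m$l_o else NA_integer_,
                 mean_ic_bits = round(mean(ic), 3),
                 consensus = m$consensus, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame()
  }
  structure(list(mode = object$mode, n_peaks = length(object$peaks),
                 params = object$params, motifs = tab),
            class = "summary.exomotif")
}

#' @export
print.summary.exomotif <- function(x, ...) {
  cat(sprintf("Motif discovery summary: %d peak(s), mode '%s'\n",
              x$n_peaks, x$mode))
  cat(sprintf("  l = %s, f threshold = %s, alpha = %d, beta = %d, d = %d, ",
              x$params$l, x$params$f_threshold, x$params$alpha,
              x$params$beta, x$params$d))
  cat(sprintf("P cutoff = %g, t = %d\n", x$params$p_cutoff, x$params$t))
  if (nrow(x$motifs)) print(x$motifs, row.names = FALSE) else
    cat("  no motifs found\n")
  invisible(x)
}

# Per-column information content (bits) of a motif's frequency matrix.
information_content <- function(mm) {
  freq <- motif_frequencies(mm)
  apply(freq, 2L, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
}

#' @export
coef.exomotif <- function(object, ...) {
  stats::setNames(lapply(object$motifs, `[[`, "pwm"),
                  vapply(object$motifs, `[[`, "", "name"))
}

#' Score new sequences with a fitted motif
#'
#' @param object an `exomotif` fit.
#' @param newdata a `peak_set` or character vector of sequences; defaults
#'   to the training peaks.
#' @param motif which motif to use (index or name, default the top-ranked).
#' @param ... unused.
#' @return Numeric vector of max log-odds window scores.
#' @export
predict.exomotif <- function(object, newdata = NULL, motif = 1L, ...) {
  if (!length(object$motifs)) stop("the fit contains no motifs")
  mm <- if (is.character(motif)) {
    object$motifs[[match(motif, vapply(object$motifs, `[[`, "", "name"))]]
  } else {
    object$motifs[[motif]]
  }
  if (is.null(newdata)) newdata <- object$peaks
  score_sequences(newdata, mm)
}

#' Plot per-column information content of discovered motifs
#'
#' A base-graphics profile of each motif's information content in bits per
#' column, with the consensus base lettered along the axis.
#'
#' @param x an `exomotif` fit.
#' @param motifs indices of motifs to draw (default all, up to 4).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.exomotif <- function(x, motifs = NULL, ...) {
  if (!length(x$motifs)) {
    warning("no motifs to plot")
    return(invisible(x))
  }
  if (is.null(motifs)) motifs <- seq_len(min(4L, length(x$motifs)))
  old <- graphics::par(mfrow = c(length(motifs), 1L),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in motifs) {
    mm <- x$motifs[[i]]
    ic <- information_content(mm)
    graphics::barplot(ic, names.arg = strsplit(mm$consensus, "")[[1L]],
                      ylim = c(0, 2), ylab = "bits",
                      main = sprintf("%s (%d sites)", mm$name, mm$nsites),
                      ...)
  }
  invisible(x)
}

# Drop a motif when a single higher-ranked motif of at least its width
# already covers most of its sites: narrower or equal-width duplicates of a
# reported motif carry no extra information, while a wider variant of the
# same sites is kept (it records the reassembled full span).
collapse_redundant <- function(motifs, seqlen, min_cover = 0.8) {
  kept <- list()
  for (m in motifs) {
    fm <- instances_forward(m$instances, seqlen)
    dup <- FALSE
    for (k in kept) {
      if (m$width > k$width) next
      fk <- instances_forward(k$instances, seqlen)
      covered <- vapply(seq_len(nrow(fm)), function(i) {
        same <- fk$seqidx == fm$seqidx[i]
        if (!any(same)) return(FALSE)
        ov <- pmin(fk$fend[same], fm$fend[i]) -
          pmax(fk$fstart[same], fm$fstart[i]) + 1L
        any(ov >= min(m$width, k$width) / 2)
      }, TRUE)
      if (mean(covered) >= min_cover) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- m
  }
  kept
}
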