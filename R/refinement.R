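DNA <- c("A", "C", "G", "T")

#' Background nucleotide frequencies
#'
#' Mononucleotide frequencies over the genome when one is supplied,
#' otherwise over the peak sequences (a message notes the fallback). `N`
#' bases are excluded; zero frequencies are lifted to 1e-6 and the vector
#' renormalized so PWM log-odds stay finite.
#'
#' @param peaks a `peak_set` (fallback source).
#' @param genome optional named character vector / `DNAStringSet` of contigs.
#' @return Named numeric 4-vector (A, C, G, T) summing to 1.
#' @export
estimate_background <- function(peaks = NULL, genome = NULL) {
  src <- if (!is.null(genome)) {
    unname(as_genome(genome))
  } else {
    if (is.null(peaks)) stop("supply peaks or a genome")
    message("no genome supplied; estimating background from peak sequences")
    peaks$seq
  }
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(src), DNA))
  if (sum(counts) == 0) stop("no usable (non-N) bases for the background")
  q <- counts / sum(counts)
  if (any(q == 0)) {
    q[q == 0] <- 1e-6
    q <- q / sum(q)
  }
  stats::setNames(as.numeric(q), DNA)
}

#' Build a position weight matrix from aligned instances
#'
#' Column frequencies use a Laplace pseudocount of 1 spread evenly over the
#' four bases: `p(i, j) = (count + 0.25) / (n + 1)`. An `N` base contributes
#' 0.25 to each base count at its position. The PWM entry is the log2-odds
#' `log2(p(i, j) / q(i))`.
#'
#' @param segments character vector of equal-length instance sequences, or a
#'   `potential_motif` plus `sm` to extract them.
#' @param q background frequencies from [estimate_background()].
#' @param instances optional instance data frame (`row`, `start`, `width`)
#'   recorded in the model.
#' @param name optional motif name.
#' @return An object of class `motif_model` with counts, frequencies
#'   implied, the log-odds `pwm`, `q`, width, site count and consensus.
#' @export
build_pwm <- function(segments, q, instances = NULL, name = NULL) {
  if (length(segments) < 2L) stop("need at least 2 instances to build a PWM")
  w <- unique(nchar(segments))
  if (length(w) != 1L) stop("instances must share one length")
  counts <- matrix(0, 4L, w, dimnames = list(DNA, NULL))
  for (s in segments) {
    ch <- strsplit(s, "")[[1L]]
    for (j in seq_len(w)) {
      if (ch[j] == "N") {
        counts[, j] <- counts[, j] + 0.25
      } else {
        counts[ch[j], j] <- counts[ch[j], j] + 1
      }
    }
  }
  n <- length(segments)
  freq <- (counts + 0.25) / (n + 1)
  pwm <- log2(freq / q)
  structure(
    list(counts = counts, pwm = pwm, q = q, width = w, nsites = n,
         instances = instances,
         consensus = paste(DNA[apply(counts, 2L, which.max)], collapse = ""),
         name = name),
    class = "motif_model"
  )
}

motif_frequencies <- function(mm) (mm$counts + 0.25) / (mm$nsites + 1)

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Motif%s: width %d, %d sites, consensus %s\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$width, x$nsites, x$consensus))
  invisible(x)
}

segment_seq <- function(sm, row, start, width) {
  substr(sm$seq[row], start, start + width - 1L)
}

#' Coverage-weighted motif match score
#'
#' Scores a width-`l_x` segment against a motif PWM, weighting the log-odds
#' sum by normalized coverage around the segment:
#' `S = 0.5 (max w[j'-t .. j'] + max w[j' .. j'+l_o+t]) * sum_j PWM[base_j, j]`,
#' with both coverage windows truncated at the row ends and `N` bases
#' contributing their column's mean PWM value. In basic mode (all weights 1)
#' this is exactly the plain log-odds sum.
#'
#' @param model a `motif_model` carrying `l_o` and `t` (see [exomotif()]);
#'   seeds that never merged use `l_o = l_x`.
#' @param sm the strand matrix.
#' @param w_norm row-max-normalized coverage rows from [second_pass()].
#' @param row,start segment coordinates (1-based).
#' @return The match score (finite real).
#' @export
match_score <- function(model, sm, w_norm, row, start) {
  lx <- model$width
  n <- sm$nbase[row]
  if (start < 1L || start + lx - 1L > n) stop("segment out of bounds")
  t <- if (!is.null(model$t)) model$t else 2L
  lo <- if (!is.null(model$l_o)) model$l_o else lx
  wrow <- w_norm[[row]]
  w1 <- max(wrow[max(1L, start - t):start])
  w2 <- max(wrow[start:min(n, start + lo + t)])
  ch <- strsplit(segment_seq(sm, row, start, lx), "")[[1L]]
  s <- 0
  for (j in seq_len(lx)) {
    s <- s + if (ch[j] == "N") mean(model$pwm[, j]) else model$pwm[ch[j], j]
  }
  unname(0.5 * (w1 + w2) * s)
}

score_all_segments <- function(model, sm, w_norm) {
  lx <- model$width
  out <- list()
  for (row in seq_along(sm$seq)) {
    nv <- sm$nbase[row] - lx + 1L
    if (nv < 1L) next
    sc <- cpp_score_segments(encode_dna(sm$seq[row])[[1L]], model$pwm,
                             w_norm[[row]],
                             if (!is.null(model$t)) model$t else 2L,
                             if (!is.null(model$l_o)) model$l_o else lx)
    out[[length(out) + 1L]] <- data.frame(row = row, start = seq_len(nv),
                                          score = sc)
  }
  do.call(rbind, out)
}

#' Expand a motif's instance set by match score
#'
#' Every width-`l_x` segment on every strand-matrix row scoring strictly
#' above the weakest current instance is admitted, except segments
#' overlapping an existing instance of the same row by more than half the
#' width (which would merely stack shifted copies). The PWM is rebuilt from
#' the expanded set; original instances are never removed. One pass by
#' default.
#'
#' @param model a `motif_model` with an `instances` data frame.
#' @param sm the strand matrix.
#' @param w_norm normalized coverage rows.
#' @param q background frequencies.
#' @param iterations number of expansion passes (default 1).
#' @return The expanded `motif_model` (instances gain a `score` column).
#' @export
expand_instances <- function(model, sm, w_norm, q, iterations = 1L) {
  for (it in seq_len(iterations)) {
    inst <- model$instances
    if (is.null(inst) || nrow(inst) < 2L) return(model)
    inst$score <- vapply(seq_len(nrow(inst)), function(k) {
      match_score(model, sm, w_norm, inst$row[k], inst$start[k])
    }, 0)
    thresh <- min(inst$score)
    allsc <- score_all_segments(model, sm, w_norm)
    cand <- allsc[allsc$score > thresh, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    lx <- model$width
    for (k in seq_len(nrow(cand))) {
      same <- inst$row == cand$row[k]
      if (any(same)) {
        ov <- pmin(inst$start[same] + lx - 1L, cand$start[k] + lx - 1L) -
          pmax(inst$start[same], cand$start[k]) + 1L
        if (any(ov > lx / 2)) keep[k] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      add <- data.frame(row = cand$row, start = cand$start, width = lx,
                        score = cand$score)
      new_inst <- rbind(inst, add)
    } else {
      new_inst <- inst
    }
    segs <- vapply(seq_len(nrow(new_inst)), function(k) {
      segment_seq(sm, new_inst$row[k], new_inst$start[k], lx)
    }, "")
    refit <- build_pwm(segs, q, instances = new_inst, name = model$name)
    refit$l_o <- model$l_o
    refit$t <- model$t
    refit$l <- model$l
    model <- refit
    if (!nrow(cand)) break   # fixed point
  }
  model
}
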