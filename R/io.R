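#' Peak records and peak sets
#'
#' A peak record holds one narrow-peak sequence (uppercase, alphabet
#' `A/C/G/T/N`) together with an optional per-base coverage vector of the
#' same length. A peak set is a list of records plus a mode flag: `"cov"`
#' when coverage is attached, `"basic"` when sequences alone are analysed.
#'
#' @param id character vector of record identifiers (must be unique).
#' @param seq character vector of DNA sequences.
#' @param coverage optional list of numeric per-base coverage vectors, one
#'   per record, or `NULL` for basic (sequence-only) mode.
#' @return An object of class `peak_set`.
#' @examples
#' ps <- peak_set(c("p1", "p2"), c("ACGTACGT", "TTGGCCAA"))
#' length(ps)
#' @export
peak_set <- function(id, seq, coverage = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L])
  }
  if (any(!nzchar(seq))) stop("empty sequence in record ", id[!nzchar(seq)][1L])
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    warning("mapping non-ACGTN ambiguity codes to N in ", sum(bad), " record(s)")
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  if (!is.null(coverage)) {
    if (!is.list(coverage) || length(coverage) != length(seq)) {
      stop("'coverage' must be a list with one vector per sequence")
    }
    for (i in seq_along(coverage)) {
      if (length(coverage[[i]]) != nchar(seq[i])) {
        stop("coverage length ", length(coverage[[i]]), " does not match ",
             "sequence length ", nchar(seq[i]), " for record ", id[i])
      }
      if (any(coverage[[i]] < 0)) stop("negative coverage in record ", id[i])
    }
  }
  structure(
    list(id = id, seq = seq, coverage = coverage,
         mode = if (is.null(coverage)) "basic" else "cov"),
    class = "peak_set"
  )
}

#' @export
length.peak_set <- function(x) length(x$id)

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d sequence(s), mode '%s', lengths %d-%d bp\n",
              length(x), x$mode,
              min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Read peak sequences from a FASTA file
#'
#' Multi-line records are concatenated and case is folded to upper. The
#' result is a basic-mode [peak_set()] (no coverage attached).
#'
#' @param path path to a FASTA file.
#' @return A `peak_set` without coverage.
#' @export
read_peak_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(dss))
  peak_set(ids, as.character(dss))
}

#' Write peak sequences to a FASTA file
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_fasta <- function(peaks, path) {
  dss <- Biostrings::DNAStringSet(peaks$seq)
  names(dss) <- peaks$id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Extract peak sequences from a genome given BED intervals
#'
#' Intervals are interpreted as 0-based half-open (standard BED), so an
#' interval `start=2, end=5` yields 3 bases. When a BED6 strand field is
#' `"-"` the reverse complement of the plus-strand sequence is returned.
#' Record ids come from the BED name field when present, otherwise
#' `"contig:start-end"`.
#'
#' @param genome a named character vector or `DNAStringSet` of contigs.
#' @param bed path to a BED3/BED6 file (tab or space separated).
#' @return A basic-mode `peak_set`.
#' @export
extract_peaks <- function(genome, bed) {
  genome <- as_genome(genome)
  if (!file.exists(bed)) stop("file not found: ", bed)
  lines <- readLines(bed)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("no intervals in BED file: ", bed)
  ids <- seqs <- character(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    if (length(f) < 3L) stop("malformed BED line ", k, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start) {
      stop("malformed BED line ", k, ": bad coordinates '", f[2L], " ", f[3L], "'")
    }
    contig <- f[1L]
    if (!contig %in% names(genome)) {
      stop("BED line ", k, ": contig '", contig, "' not in genome")
    }
    if (end > nchar(genome[[contig]])) {
      stop("BED line ", k, ": interval ", contig, ":", start, "-", end,
           " exceeds contig length ", nchar(genome[[contig]]))
    }
    s <- substr(genome[[contig]], start + 1L, end)
    strand <- if (length(f) >= 6L) f[6L] else "+"
    if (identical(strand, "-")) s <- reverse_complement(s)
    ids[k] <- if (length(f) >= 4L && nzchar(f[4L]) && f[4L] != ".") {
      f[4L]
    } else {
      paste0(contig, ":", start, "-", end)
    }
    seqs[k] <- s
  }
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  peak_set(ids, seqs)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- vapply(seq_along(genome), function(i) as.character(genome[[i]]), "")
    names(genome) <- NULL
  }
  g <- toupper(unlist(as.list(genome)))
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("genome contigs must be named")
  }
  bad <- grepl("[^ACGTN]", g)
  if (any(bad)) {
    warning("mapping non-ACGTN genome characters to N")
    g[bad] <- gsub("[^ACGTN]", "N", g[bad])
  }
  g
}

#' Attach per-base coverage tracks to peaks
#'
#' Coverage values are looked up per base over each peak's genomic interval;
#' positions missing from every track read as 0. Multiple tracks are summed
#' position-wise before attachment. Peaks must therefore carry interval ids
#' of the form `"contig:start-end"` (as produced by [extract_peaks()]) or an
#' explicit `intervals` data frame must be supplied.
#'
#' @param peaks a `peak_set`.
#' @param tracks one coverage track or a list of tracks. A track is either a
#'   path to a per-base text file with lines `contig pos value` (`pos`
#'   0-based), a path to a BigWig file (requires rtracklayer), or a named
#'   list of per-contig numeric vectors (value for base `i` at index `i`).
#' @param intervals optional data frame with columns `contig`, `start`,
#'   `end` (0-based half-open), one row per peak; parsed from ids otherwise.
#' @return A `peak_set` in `"cov"` mode carrying raw coverage.
#' @export
attach_coverage <- function(peaks, tracks, intervals = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!is.list(tracks) || !is.null(names(tracks)) && all(vapply(tracks, is.numeric, TRUE))) {
    tracks <- list(tracks)
  }
  if (is.character(tracks)) tracks <- as.list(tracks)
  if (is.null(intervals)) intervals <- parse_interval_ids(peaks$id)
  cov <- vector("list", length(peaks))
  for (i in seq_along(cov)) cov[[i]] <- numeric(nchar(peaks$seq[i]))
  n_missing <- 0L
  for (trk in tracks) {
    track <- read_coverage_track(trk)
    for (i in seq_along(cov)) {
      ctg <- intervals$contig[i]
      pos <- seq.int(intervals$start[i] + 1L, intervals$end[i])  # 1-based
      v <- numeric(length(pos))
      if (!is.null(track[[ctg]])) {
        idx <- pos[pos <= length(track[[ctg]])]
        v[seq_along(idx)] <- track[[ctg]][idx]
        v[is.na(v)] <- 0
      } else {
        n_missing <- n_missing + 1L
      }
      cov[[i]] <- cov[[i]] + v
    }
  }
  if (n_missing > 0L) {
    message("coverage missing for ", n_missing, " peak-track pair(s); read as 0")
  }
  peak_set(peaks$id, peaks$seq, coverage = cov)
}

parse_interval_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  ok <- lengths(m) == 4L
  if (!all(ok)) {
    stop("peak id '", ids[!ok][1L], "' is not of the form 'contig:start-end'; ",
         "supply 'intervals' explicitly")
  }
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Read a per-base coverage track
#'
#' Accepts a named list of per-contig numeric vectors (returned as is), a
#' path to a plain text per-base file with whitespace-separated lines
#' `contig pos value` (`pos` 0-based), or a path to a BigWig file, which is
#' delegated to rtracklayer when available.
#'
#' @param x track specification (list or file path).
#' @return A named list mapping contig to a numeric vector where element `i`
#'   is the coverage of base `i` (1-based).
#' @export
read_coverage_track <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    return(lapply(x, as.numeric))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("a coverage track is a named list or a file path")
  }
  if (!file.exists(x)) stop("file not found: ", x)
  if (grepl("\\.(bw|bigwig)$", x, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading BigWig requires the rtracklayer package")
    }
    gr <- rtracklayer::import(x, as = "GRanges")
    out <- list()
    for (ctg in unique(as.character(GenomicRanges::seqnames(gr)))) {
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
      v <- numeric(max(GenomicRanges::end(sub)))
      for (j in seq_along(sub)) {
        v[GenomicRanges::start(sub)[j]:GenomicRanges::end(sub)[j]] <- sub$score[j]
      }
      out[[ctg]] <- v
    }
    return(out)
  }
  tab <- utils::read.table(x, header = FALSE, col.names = c("contig", "pos", "value"),
                           colClasses = c("character", "integer", "numeric"))
  out <- list()
  for (ctg in unique(tab$contig)) {
    sub <- tab[tab$contig == ctg, ]
    v <- numeric(max(sub$pos) + 1L)
    v[sub$pos + 1L] <- sub$value   # pos is 0-based
    out[[ctg]] <- v
  }
  out
}

#' Read and write the combined coverage-FASTA format
#'
#' Each record occupies three lines: a `">id"` header, the sequence, and a
#' line starting with `#` holding space-separated per-base normalized
#' coverage values in `[0, 1]` (printed to 6 decimals). Round trips are
#' lossless at that precision.
#'
#' @param path file path.
#' @return `read_covfasta` returns a `peak_set` in `"cov"` mode.
#' @export
read_covfasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty coverage-FASTA file: ", path)
  if (length(lines) %% 3L != 0L) {
    stop("malformed coverage-FASTA: expected 3 lines per record, got ",
         length(lines), " lines")
  }
  hdr <- lines[seq(1L, length(lines), by = 3L)]
  seqs <- lines[seq(2L, length(lines), by = 3L)]
  covl <- lines[seq(3L, length(lines), by = 3L)]
  if (any(!startsWith(hdr, ">"))) stop("malformed header line in ", path)
  if (any(!startsWith(covl, "#"))) stop("malformed coverage line in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", hdr))
  cov <- lapply(covl, function(l) {
    as.numeric(strsplit(trimws(sub("^#", "", l)), "[ \t]+")[[1L]])
  })
  for (i in seq_along(cov)) {
    if (any(cov[[i]] < 0 | cov[[i]] > 1)) {
      stop("coverage outside [0,1] in record ", ids[i])
    }
  }
  out <- peak_set(ids, seqs, coverage = cov)
  out$normalized <- TRUE   # the format stores normalized values
  out
}

#' @param peaks a `peak_set` with normalized coverage in `[0, 1]`. A
#'   basic-mode set is written with all-1 coverage.
#' @rdname read_covfasta
#' @export
write_covfasta <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  cov <- peaks$coverage
  if (is.null(cov)) cov <- lapply(nchar(peaks$seq), function(n) rep(1, n))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(peaks$id)) {
    if (any(cov[[i]] < 0 | cov[[i]] > 1)) {
      stop("coverage outside [0,1] in record ", peaks$id[i],
           "; normalize before writing")
    }
    writeLines(c(
      paste0(">", peaks$id[i]),
      peaks$seq[i],
      paste0("# ", paste(sprintf("%.6f", cov[[i]]), collapse = " "))
    ), con)
  }
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Writes a MEME minimal motif file (version line, ACGT alphabet, background
#' frequencies, one letter-probability block per motif with its width and
#' site count). An empty motif list yields a valid header-only file.
#'
#' @param motifs a list of motif models (see [build_pwm()]) or an
#'   `exomotif` fit.
#' @param path output path.
#' @param background optional 4-vector of A/C/G/T background frequencies;
#'   defaults to the first motif's background, or uniform.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "exomotif")) motifs <- motifs$motifs
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  if (is.null(background)) {
    background <- if (length(motifs)) motifs[[1L]]$q else rep(0.25, 4)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", c("A", "C", "G", "T"), background), collapse = " "),
    ""
  ), con)
  for (i in seq_along(motifs)) {
    mm <- motifs[[i]]
    freq <- motif_frequencies(mm)
    writeLines(c(
      paste0("MOTIF ", if (!is.null(mm$name)) mm$name else paste0("motif_", i)),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
              ncol(freq), mm$nsites)
    ), con)
    for (j in seq_len(ncol(freq))) {
      writeLines(paste(sprintf("%.6f", freq[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write motif instances as BED6
#'
#' Coordinates are sequence-relative 0-based half-open; the name field is the
#' motif name, score the instance match score (0 when unscored), strand from
#' the instance's row parity.
#'
#' @param fit an `exomotif` fit or list of motif models.
#' @param peaks the `peak_set` the motifs were discovered in.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instance_bed <- function(fit, peaks, path) {
  motifs <- if (inherits(fit, "exomotif")) fit$motifs else fit
  rows <- list()
  for (i in seq_along(motifs)) {
    mm <- motifs[[i]]
    inst <- mm$instances
    name <- if (!is.null(mm$name)) mm$name else paste0("motif_", i)
    fw <- instances_forward(inst, nchar(peaks$seq))
    rows[[i]] <- data.frame(
      contig = peaks$id[fw$seqidx],
      start = fw$fstart - 1L,
      end = fw$fstart - 1L + inst$width,
      name = name,
      score = if (!is.null(inst$score)) round(inst$score, 3) else 0,
      strand = fw$strand,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs from a MEME minimal file
#'
#' Parses the subset of the MEME minimal format that [write_meme()] emits
#' (background frequencies and letter-probability blocks) back into motif
#' models usable for scoring.
#'
#' @param path a MEME minimal motif file.
#' @return List of `motif_model` objects.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path)
  bg <- rep(0.25, 4)
  bgline <- which(grepl("^Background letter frequencies", txt))
  if (length(bgline) && bgline[1] < length(txt)) {
    f <- strsplit(trimws(txt[bgline[1] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(f[seq(2, length(f), by = 2)]))
    if (length(vals) == 4L && !anyNA(vals)) bg <- vals
  }
  names(bg) <- c("A", "C", "G", "T")
  out <- list()
  starts <- which(grepl("^MOTIF ", txt))
  for (s in starts) {
    name <- strsplit(trimws(txt[s]), "\\s+")[[1L]][2L]
    hdr <- txt[s + 1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- suppressWarnings(as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)))
    if (is.na(nsites)) nsites <- 20L
    freq <- t(vapply(seq_len(w), function(j) {
      as.numeric(strsplit(trimws(txt[s + 1L + j]), "\\s+")[[1L]])
    }, numeric(4)))
    freq <- t(freq)               # 4 x w
    rownames(freq) <- c("A", "C", "G", "T")
    counts <- pmax(freq * (nsites + 1) - 0.25, 0)
    mm <- structure(
      list(counts = counts, pwm = log2(freq / bg), q = bg, width = w,
           nsites = nsites, instances = NULL,
           consensus = paste(c("A", "C", "G", "T")[apply(freq, 2L, which.max)],
                             collapse = ""),
           name = name),
      class = "motif_model")
    out[[length(out) + 1L]] <- mm
  }
  out
}
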