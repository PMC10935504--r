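#' Graph and clique parameters
#'
#' @param beta per-row-pair rank cutoff for edge admission (default 3).
#' @param min_clique_size smallest clique reported as a potential motif
#'   (default 3).
#' @param max_motifs maximum number of potential motifs kept per segment
#'   length (default 10).
#' @return A list of class `graph_params`.
#' @export
graph_params <- function(beta = 3L, min_clique_size = 3L, max_motifs = 10L) {
  if (beta < 1L) stop("beta must be at least 1")
  if (min_clique_size < 2L) stop("min_clique_size must be at least 2")
  structure(list(beta = as.integer(beta),
                 min_clique_size = as.integer(min_clique_size),
                 max_motifs = as.integer(max_motifs)),
            class = "graph_params")
}

#' Build the segment-similarity graph
#'
#' Vertices are l-segments (strand-matrix row, start); for every eligible
#' row pair the combined-weight score `f' = f * (M2[a, j] + M2[b, q])` is
#' ranked over all segment pairs and pairs in the top `beta` (ties included,
#' zero scores excluded) contribute an edge weighted by `f'`. Edge endpoints
#' always lie on rows of distinct peaks.
#'
#' @param sm a [build_strand_matrix()] result.
#' @param m2 combined weight rows from [second_pass()].
#' @param align_params an [alignment_params()].
#' @param params a [graph_params()].
#' @return A list of class `alignment_graph` with a vertex table, an edge
#'   table and the segment length `l`.
#' @export
build_graph <- function(sm, m2, align_params = alignment_params(),
                        params = graph_params()) {
  l <- align_params$l
  enc <- encode_dna(sm$seq)
  ed <- cpp_all_pairs(enc, m2, sm$seqidx, l,
                      similarity_table(l),
                      threshold_k(l, Inf),   # edges come from rank only
                      params$beta, TRUE)
  edges <- data.frame(row_a = ed$row_a, pos_a = ed$pos_a,
                      row_b = ed$row_b, pos_b = ed$pos_b,
                      weight = ed$weight)
  # canonical vertex keys; keep max weight on duplicate endpoint pairs
  if (nrow(edges)) {
    key <- paste(edges$row_a, edges$pos_a, edges$row_b, edges$pos_b)
    edges <- edges[order(key, -edges$weight), ]
    edges <- edges[!duplicated(paste(edges$row_a, edges$pos_a,
                                     edges$row_b, edges$pos_b)), ]
    rownames(edges) <- NULL
  }
  vkeys <- unique(c(paste(edges$row_a, edges$pos_a),
                    paste(edges$row_b, edges$pos_b)))
  verts <- if (length(vkeys)) {
    parts <- strsplit(vkeys, " ")
    data.frame(row = as.integer(vapply(parts, `[`, "", 1L)),
               start = as.integer(vapply(parts, `[`, "", 2L)))
  } else {
    data.frame(row = integer(), start = integer())
  }
  structure(list(vertices = verts, edges = edges, l = l,
                 seqidx = sm$seqidx),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("Segment-similarity graph: %d vertices, %d edges (l = %d)\n",
              nrow(x$vertices), nrow(x$edges), x$l))
  invisible(x)
}

#' Extract disjoint maximal cliques as potential motifs
#'
#' Greedy heuristic: seed with the unused vertex of highest degree (ties by
#' larger incident weight sum, then by row and start); repeatedly add the
#' unused vertex adjacent to every current member with the largest summed
#' edge weight into the clique, subject to one instance per peak (a vertex
#' may not join a clique that already holds a vertex of the same peak, on
#' either strand); stop when no candidate remains. Cliques of at least
#' `min_clique_size` vertices are accepted and their vertices retired, so
#' reported motifs are vertex-disjoint. The result is sorted by size then
#' mean edge weight and truncated to `max_motifs`.
#'
#' @param graph an [build_graph()] result.
#' @param params a [graph_params()].
#' @return List of `potential_motif` objects, each with an `instances` data
#'   frame (`row`, `start`, `width`), segment length `l` and a `score`
#'   (mean internal edge weight).
#' @export
find_disjoint_cliques <- function(graph, params = graph_params()) {
  verts <- graph$vertices
  nv <- nrow(verts)
  if (nv == 0L) return(list())
  vkey <- paste(verts$row, verts$start)
  eA <- match(paste(graph$edges$row_a, graph$edges$pos_a), vkey)
  eB <- match(paste(graph$edges$row_b, graph$edges$pos_b), vkey)
  ew <- graph$edges$weight
  adj <- vector("list", nv)          # adjacency: neighbor index -> weight
  for (k in seq_along(eA)) {
    adj[[eA[k]]] <- c(adj[[eA[k]]], stats::setNames(ew[k], eB[k]))
    adj[[eB[k]]] <- c(adj[[eB[k]]], stats::setNames(ew[k], eA[k]))
  }
  degree <- lengths(adj)
  wsum <- vapply(adj, function(a) if (length(a)) sum(a) else 0, 0)
  peak_of <- (verts$row + 1L) %/% 2L
  used <- rep(FALSE, nv)
  unseedable <- rep(FALSE, nv)   # failed seeds may still join later cliques
  ord <- order(-degree, -wsum, verts$row, verts$start)

  out <- list()
  repeat {
    seed_pool <- ord[!used[ord] & !unseedable[ord] & degree[ord] > 0L]
    if (!length(seed_pool)) break
    seed <- seed_pool[1L]
    members <- seed
    peaks_in <- peak_of[seed]
    repeat {
      # candidates adjacent to every member, unused, on a new peak
      cand <- as.integer(names(adj[[members[1L]]]))
      for (v in members[-1L]) {
        cand <- intersect(cand, as.integer(names(adj[[v]])))
        if (!length(cand)) break
      }
      cand <- cand[!used[cand] & !(peak_of[cand] %in% peaks_in)]
      if (!length(cand)) break
      gain <- vapply(cand, function(u) {
        sum(vapply(members, function(v) {
          a <- adj[[u]]
          a[[as.character(v)]]
        }, 0))
      }, 0)
      pick <- cand[order(-gain, verts$row[cand], verts$start[cand])][1L]
      members <- c(members, pick)
      peaks_in <- c(peaks_in, peak_of[pick])
    }
    if (length(members) >= params$min_clique_size) {
      inw <- unlist(lapply(members, function(v) {
        a <- adj[[v]]
        a[as.integer(names(a)) %in% members & as.integer(names(a)) > v]
      }))
      out[[length(out) + 1L]] <- structure(
        list(instances = data.frame(row = verts$row[members],
                                    start = verts$start[members],
                                    width = graph$l),
             l = graph$l,
             score = mean(inw)),
        class = "potential_motif")
      used[members] <- TRUE
    } else {
      # an unproductive seed leaves the pool but stays joinable
      unseedable[seed] <- TRUE
    }
  }
  sizes <- vapply(out, function(m) nrow(m$instances), 0L)
  scores <- vapply(out, function(m) m$score, 0)
  out <- out[order(-sizes, -scores)]
  head(out, params$max_motifs)
}

#' Discover potential motifs, optionally over a range of segment lengths
#'
#' Runs the two-stage alignment, graph construction and clique detection for
#' each requested segment length and pools the resulting potential motifs,
#' each tagged with its own length.
#'
#' @param peaks a normalized `peak_set`.
#' @param align_params an [alignment_params()] (its `l_range`, when set,
#'   supersedes `l`).
#' @param params a [graph_params()].
#' @return List of `potential_motif` objects.
#' @export
discover_potential_motifs <- function(peaks,
                                      align_params = alignment_params(),
                                      params = graph_params()) {
  ls <- if (!is.null(align_params$l_range)) align_params$l_range else align_params$l
  out <- list()
  for (l in ls) {
    ap <- alignment_params(l = l, f_threshold = align_params$f_threshold,
                           alpha = align_params$alpha)
    am <- alignment_matrices(peaks, ap)
    g <- build_graph(am$sm, am$m2, ap, params)
    out <- c(out, find_disjoint_cliques(g, params))
  }
  out
}
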