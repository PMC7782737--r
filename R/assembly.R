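#' Per-read coverage statistics from overlaps
#'
#' Computes each read's per-base overlap coverage (how many overlaps cover
#' each base) and its extremes `c_min`, `c_max`, `c_diff = c_max - c_min`.
#'
#' @param reads named character vector.
#' @param overlaps overlap table (see [compute_overlaps()]).
#' @return data.frame: `id`, `c_min`, `c_max`, `c_diff`.
#' @export
coverage_stats <- function(reads, overlaps) {
  lens <- nchar(reads)
  out <- data.frame(id = names(reads), c_min = 0L, c_max = 0L, c_diff = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    iv <- overlaps_for_read(overlaps, id, lens)
    n <- lens[[i]]
    d <- integer(n + 1L)
    if (nrow(iv)) {
      s <- pmax(0L, iv$start); e <- pmin(n, iv$end)
      ok <- e > s
      for (j in which(ok)) {
        d[s[j] + 1L] <- d[s[j] + 1L] + 1L
        d[e[j] + 1L] <- d[e[j] + 1L] - 1L
      }
    }
    cov <- cumsum(d[seq_len(n)])
    out$c_min[i] <- min(cov); out$c_max[i] <- max(cov)
  }
  out$c_diff <- out$c_max - out$c_min
  out
}

#' Coverage-based read and overlap filter
#'
#' Removes reads whose overlap coverage is locally too thin
#' (`c_min < min_coverage`), too deep (`c_max > max_coverage`, typical of
#' collapsed repeats) or too uneven (`c_diff > max_diff_coverage`),
#' together with all their overlaps.
#'
#' @param reads named character vector.
#' @param overlaps overlap table.
#' @param min_coverage,max_coverage,max_diff_coverage thresholds.
#' @return list(`reads`, `overlaps`, `removed` = ids).
#' @export
coverage_filter <- function(reads, overlaps, min_coverage = 2,
                            max_coverage = 200, max_diff_coverage = 150) {
  st <- coverage_stats(reads, overlaps)
  bad <- st$id[st$c_min < min_coverage | st$c_max > max_coverage |
                 st$c_diff > max_diff_coverage]
  keep <- setdiff(names(reads), bad)
  list(reads = reads[keep],
       overlaps = overlaps[!(overlaps$a %in% bad | overlaps$b %in% bad), ,
                           drop = FALSE],
       removed = bad)
}

overlap_overhang <- function(overlaps, lens) {
  alen <- lens[overlaps$a]; blen <- lens[overlaps$b]
  pmin(overlaps$a_start, overlaps$b_start) +
    pmin(alen - overlaps$a_end, blen - overlaps$b_end)
}

#' Adaptive (global + per-read) overlap quality filter
#'
#' For each read, the local identity cutoff is
#' `mean(identities) - alpha * sd` and the local overhang bound is
#' `mean(overhangs) + alpha * sd` over that read's overlaps; the effective
#' cutoffs are `max(global_identity, local)` and
#' `min(global_overhang, local)`.  An overlap is kept only if it passes
#' the effective cutoffs of *both* of its reads, so each read sheds its
#' relatively low-quality overlaps while the global floors keep overall
#' quality.
#'
#' @param overlaps overlap table.
#' @param reads named character vector (for lengths).
#' @param global_identity,global_overhang global floors.
#' @param alpha standard-deviation multiplier.
#' @param identity_margin,overhang_margin minimum width of the local band:
#'   at least this much identity (fraction) / overhang (bases) below/above
#'   the read's mean is always tolerated, so a razor-thin quality
#'   distribution cannot discard genuine dovetail neighbours.
#' @return Filtered overlap table.
#' @export
adaptive_overlap_filter <- function(overlaps, reads, global_identity = 0.90,
                                    global_overhang = 500, alpha = 2,
                                    identity_margin = 0.02,
                                    overhang_margin = 200) {
  if (nrow(overlaps) == 0) return(overlaps)
  lens <- nchar(reads)
  oh <- overlap_overhang(overlaps, lens)
  ids <- unique(c(overlaps$a, overlaps$b))
  ident_cut <- stats::setNames(rep(global_identity, length(ids)), ids)
  oh_cut <- stats::setNames(rep(global_overhang, length(ids)), ids)
  for (id in ids) {
    sel <- overlaps$a == id | overlaps$b == id
    iv <- overlaps$identity[sel]
    ov <- oh[sel]
    sd_i <- if (length(iv) > 1) sqrt(mean((iv - mean(iv))^2)) else 0
    sd_o <- if (length(ov) > 1) sqrt(mean((ov - mean(ov))^2)) else 0
    ident_cut[id] <- max(global_identity,
                         mean(iv) - max(alpha * sd_i, identity_margin))
    oh_cut[id] <- min(global_overhang,
                      mean(ov) + max(alpha * sd_o, overhang_margin))
  }
  keep <- overlaps$identity >= ident_cut[overlaps$a] &
    overlaps$identity >= ident_cut[overlaps$b] &
    oh <= oh_cut[overlaps$a] & oh <= oh_cut[overlaps$b]
  out <- overlaps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a directed string graph from dovetail overlaps
#'
#' Myers-style construction: contained reads are removed; every proper
#' dovetail overlap yields an extension edge and its dual on the reversed
#' orientations.  Nodes are oriented reads (`id:+` / `id:-`); an edge
#' `u -> v` carries the unaligned extension sequence of `v`, its length,
#' and the overlap length (alignment columns).
#'
#' @param reads named character vector.
#' @param overlaps filtered overlap table.
#' @param tol maximum unaligned overhang per read end for an overlap to
#'   count as a dovetail / containment (bases).
#' @return An object of class `string_graph`: list(`nodes`, `edges`,
#'   `contained`).
#' @export
build_string_graph <- function(reads, overlaps, tol = 500) {
  lens <- nchar(reads)
  la <- overlaps$a_start
  ra <- lens[overlaps$a] - overlaps$a_end
  lb <- overlaps$b_start
  rb <- lens[overlaps$b] - overlaps$b_end
  contained <- unique(c(overlaps$b[lb <= tol & rb <= tol],
                        overlaps$a[la <= tol & ra <= tol &
                                     !(lb <= tol & rb <= tol)]))
  keep <- !(overlaps$a %in% contained | overlaps$b %in% contained)
  ov <- overlaps[keep, , drop = FALSE]
  la <- la[keep]; ra <- ra[keep]; lb <- lb[keep]; rb <- rb[keep]
  edges <- list()
  add_edge <- function(from, to, ext, ovl_len, identity) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, ext = ext, ext_len = nchar(ext),
      ovl_len = ovl_len, identity = identity, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ov))) {
    o <- ov[i, ]
    ob <- o$strand
    bseq <- if (ob == "-") revcomp(reads[[o$b]]) else reads[[o$b]]
    oh_sp <- ra[i] + lb[i]            # suffix(a) -> prefix(oriented b)
    oh_ps <- la[i] + rb[i]            # prefix(a) <- suffix(oriented b)
    if (oh_sp <= oh_ps && ra[i] <= tol && lb[i] <= tol) {
      add_edge(node_id(o$a, "+"), node_id(o$b, ob),
               substr(bseq, o$b_end + 1L, nchar(bseq)), o$cols, o$identity)
      add_edge(node_id(o$b, flip(ob)), node_id(o$a, "-"),
               revcomp(substr(reads[[o$a]], 1L, o$a_start)),
               o$cols, o$identity)
    } else if (oh_ps < oh_sp && la[i] <= tol && rb[i] <= tol) {
      add_edge(node_id(o$b, ob), node_id(o$a, "+"),
               substr(reads[[o$a]], o$a_end + 1L, lens[o$a]),
               o$cols, o$identity)
      add_edge(node_id(o$a, "-"), node_id(o$b, flip(ob)),
               revcomp(substr(bseq, 1L, o$b_start)), o$cols, o$identity)
    }
    # otherwise: internal match, dropped
  }
  free <- setdiff(names(reads), contained)
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = c(node_id(free, "+"), node_id(free, "-")),
                 edges = edges, contained = contained),
            class = "string_graph")
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), ext = character(),
             ext_len = integer(), ovl_len = numeric(), identity = numeric(),
             stringsAsFactors = FALSE)
}

flip <- function(o) ifelse(o == "+", "-", "+")

#' @export
print.string_graph <- function(x, ...) {
  cat(sprintf("<string_graph> %d oriented nodes, %d edges (%d contained reads removed)\n",
              length(x$nodes), nrow(x$edges), length(x$contained)))
  invisible(x)
}

drop_edges <- function(g, drop) {
  if (!any(drop)) return(g)
  # keep duals consistent: removing u->v also removes flip(v)->flip(u)
  ed <- g$edges
  key <- paste(ed$from, ed$to)
  dual <- paste(node_flip(ed$to), node_flip(ed$from))
  drop <- drop | key %in% dual[drop]
  g$edges <- ed[!drop, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Transitive reduction of a string graph
#'
#' Removes every edge `v -> x` for which a two-edge path `v -> w -> x`
#' exists whose total extension length matches the direct edge within
#' `fuzz` bases (Myers' string-graph simplification).
#'
#' @param g a `string_graph`.
#' @param fuzz length tolerance in bases.
#' @return The reduced graph.
#' @export
transitive_reduction <- function(g, fuzz = 500) {
  ed <- g$edges
  if (nrow(ed) == 0) return(g)
  out_by <- split(seq_len(nrow(ed)), ed$from)
  reduced <- logical(nrow(ed))
  for (v in names(out_by)) {
    ei <- out_by[[v]]
    if (length(ei) < 2) next
    targets <- ed$to[ei]
    len_vx <- stats::setNames(ed$ext_len[ei], targets)
    for (k in seq_along(ei)) {
      w <- targets[k]
      wi <- out_by[[w]]
      if (is.null(wi)) next
      for (j in wi) {
        x <- ed$to[j]
        if (!x %in% targets || x == w) next
        tot <- ed$ext_len[ei[k]] + ed$ext_len[j]
        if (abs(len_vx[[x]] - tot) <= fuzz)
          reduced[ei[match(x, targets)]] <- TRUE
      }
    }
  }
  drop_edges(g, reduced)
}

#' Best-overlap pruning
#'
#' Marks, for every node, the out-edge and the in-edge with the largest
#' overlap length (ties broken by lexicographic target id); edges not
#' marked as anyone's best out-edge or best in-edge are removed (together
#' with their duals).
#'
#' @param g a `string_graph`.
#' @return The pruned graph.
#' @export
best_edge_prune <- function(g) {
  ed <- g$edges
  if (nrow(ed) == 0) return(g)
  best_of <- function(idx, other) {
    idx[order(-ed$ovl_len[idx], ed[[other]][idx])][1]
  }
  keep <- logical(nrow(ed))
  for (idx in split(seq_len(nrow(ed)), ed$from))
    keep[best_of(idx, "to")] <- TRUE
  for (idx in split(seq_len(nrow(ed)), ed$to))
    keep[best_of(idx, "from")] <- TRUE
  # protect duals of kept edges
  key <- paste(ed$from, ed$to)
  dual <- paste(node_flip(ed$to), node_flip(ed$from))
  keep <- keep | key %in% dual[keep]
  drop_edges(g, !keep)
}

out_edges <- function(ed, v) which(ed$from == v)
in_edges <- function(ed, v) which(ed$to == v)

#' Remove ambiguous edges: tips, bubbles, spurious links
#'
#' Dead-end paths of at most `tip_len` reads are removed; pairs of short
#' divergent-convergent paths (bubbles, branches up to `bubble_len` reads)
#' are collapsed onto the better-supported branch; edges whose overlap
#' length is below `spur_frac` of the best alternative at a branching node
#' are removed as spurious links.
#'
#' @param g a `string_graph`.
#' @param tip_len,bubble_len,spur_frac limits (see [pipeline_config()]).
#' @return The cleaned graph.
#' @export
clean_graph <- function(g, tip_len = 3, bubble_len = 5, spur_frac = 0.25) {
  repeat {
    n0 <- nrow(g$edges)
    g <- remove_spurious(g, spur_frac)
    g <- remove_tips(g, tip_len)
    g <- pop_bubbles(g, bubble_len)
    if (nrow(g$edges) == n0) break
  }
  g
}

remove_spurious <- function(g, frac) {
  ed <- g$edges
  if (nrow(ed) == 0) return(g)
  drop <- logical(nrow(ed))
  for (idx in split(seq_len(nrow(ed)), ed$from)) {
    if (length(idx) < 2) next
    best <- max(ed$ovl_len[idx])
    drop[idx[ed$ovl_len[idx] < frac * best]] <- TRUE
  }
  for (idx in split(seq_len(nrow(ed)), ed$to)) {
    if (length(idx) < 2) next
    best <- max(ed$ovl_len[idx])
    drop[idx[ed$ovl_len[idx] < frac * best]] <- TRUE
  }
  drop_edges(g, drop)
}

remove_tips <- function(g, tip_len) {
  repeat {
    ed <- g$edges
    if (nrow(ed) == 0) return(g)
    srcs <- setdiff(unique(ed$from), unique(ed$to))   # in-degree 0
    removed <- FALSE
    for (s in srcs) {
      path <- s
      v <- s
      ok <- FALSE
      enter <- NA_integer_
      for (step in seq_len(tip_len)) {
        oe <- out_edges(ed, v)
        if (length(oe) != 1) break
        nxt <- ed$to[oe]
        if (length(in_edges(ed, nxt)) > 1) { ok <- TRUE; enter <- oe; break }
        path <- c(path, nxt)
        v <- nxt
      }
      # only prune a tip whose branch node keeps a better-supported in-edge
      if (ok) {
        others <- setdiff(in_edges(ed, ed$to[enter]), enter)
        ok <- any(ed$ovl_len[others] >= ed$ovl_len[enter])
      }
      if (ok) {
        both <- c(path, node_flip(path))
        g <- drop_edges(g, ed2 <- (g$edges$from %in% both |
                                     g$edges$to %in% both))
        g$nodes <- setdiff(g$nodes, both)
        removed <- TRUE
        break
      }
    }
    if (!removed) return(g)
  }
}

pop_bubbles <- function(g, bubble_len) {
  ed <- g$edges
  if (nrow(ed) == 0) return(g)
  walk <- function(start_edge) {
    # follow unbranched internal nodes; return (end node, internal nodes,
    # support) or NULL
    v <- ed$to[start_edge]
    internal <- character(0)
    support <- ed$ovl_len[start_edge]
    for (step in seq_len(bubble_len)) {
      ie <- in_edges(ed, v); oe <- out_edges(ed, v)
      if (length(ie) > 1) return(list(end = v, internal = internal,
                                      support = support))
      if (length(oe) != 1) return(NULL)
      internal <- c(internal, v)
      support <- support + ed$ovl_len[oe]
      v <- ed$to[oe]
    }
    NULL
  }
  for (v in unique(ed$from)) {
    oe <- out_edges(ed, v)
    if (length(oe) != 2) next
    w1 <- walk(oe[1]); w2 <- walk(oe[2])
    if (is.null(w1) || is.null(w2)) next
    if (w1$end != w2$end) next
    lose <- if (w1$support >= w2$support) w2 else w1
    kill <- c(lose$internal, node_flip(lose$internal))
    first_edge <- if (w1$support >= w2$support) oe[2] else oe[1]
    drop <- seq_len(nrow(ed)) == first_edge |
      ed$from %in% kill | ed$to %in% kill
    g <- drop_edges(g, drop)
    g$nodes <- setdiff(g$nodes, kill)
    return(pop_bubbles(g, bubble_len))   # restart after a change
  }
  g
}

#' Extract contigs from a string graph
#'
#' Maximal unbranched paths become contigs (paths are broken at every
#' branch).  Each path's mirror (the reverse-complement traversal) is
#' emitted only once; cycle components (e.g. a circular genome) are broken
#' at their lexicographically smallest node.  A contig's sequence is its
#' first read spliced with every successor edge's extension sequence.
#'
#' @param g a `string_graph`.
#' @param reads named character vector of node sequences.
#' @return list(`contigs` = named character vector, `layout` = list of
#'   data.frames (`read`, `orient`, `offset`)).
#' @export
extract_contigs <- function(g, reads) {
  ed <- g$edges
  nodes <- g$nodes
  contigs <- character(0)
  layouts <- list()
  used <- character(0)
  emit <- function(path) {
    # the mirror traversal is blocked via `visited`, so each component is
    # emitted exactly once
    ns <- node_split(path)
    seq <- oriented_read(reads, ns$read[1], ns$orient[1])
    offs <- 0L
    if (length(path) > 1) {
      for (i in 2:length(path)) {
        ei <- which(ed$from == path[i - 1] & ed$to == path[i])[1]
        seq <- paste0(seq, ed$ext[ei])
        offs <- c(offs, nchar(seq) - nchar(reads[[ns$read[i]]]))
      }
    }
    cid <- sprintf("ctg%04d", length(contigs) + 1L)
    contigs[cid] <<- seq
    layouts[[cid]] <<- data.frame(read = ns$read, orient = ns$orient,
                                  offset = offs, stringsAsFactors = FALSE)
    used <<- c(used, ns$read)
  }
  is_start <- function(v) {
    ie <- in_edges(ed, v)
    if (length(ie) == 0) return(TRUE)
    if (length(ie) > 1) return(TRUE)
    u <- ed$from[ie]
    length(out_edges(ed, u)) != 1
  }
  visited <- character(0)
  for (v in nodes[vapply(nodes, is_start, TRUE)]) {
    if (v %in% visited) next
    path <- v
    visited <- c(visited, v, node_flip(v))
    cur <- v
    repeat {
      oe <- out_edges(ed, cur)
      if (length(oe) != 1) break
      nxt <- ed$to[oe]
      if (length(in_edges(ed, nxt)) != 1) break
      if (nxt %in% visited || nxt %in% path) break
      path <- c(path, nxt)
      visited <- c(visited, nxt, node_flip(nxt))
      cur <- nxt
    }
    emit(path)
  }
  # cycles: components with no start node
  remaining <- setdiff(nodes, visited)
  while (length(remaining) > 0) {
    v <- sort(remaining)[1]
    path <- v
    cur <- v
    repeat {
      oe <- out_edges(ed, cur)
      if (length(oe) != 1) break
      nxt <- ed$to[oe]
      if (nxt == v || nxt %in% path) break
      path <- c(path, nxt)
      cur <- nxt
    }
    emit(path)
    remaining <- setdiff(remaining, c(path, node_flip(path)))
  }
  list(contigs = contigs, layout = layouts)
}

oriented_read <- function(reads, id, orient) {
  if (orient == "-") revcomp(reads[[id]]) else reads[[id]]
}

#' Write contig layouts as TSV
#'
#' One row per layout read: contig id, read id, orientation, and the
#' read's approximate start offset within the contig.
#'
#' @param layout list of layout data.frames (see [extract_contigs()]).
#' @param path output file.
#' @export
write_layout_tsv <- function(layout, path) {
  rows <- lapply(names(layout), function(cid)
    cbind(contig = cid, layout[[cid]]))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), read = character(),
               orient = character(), offset = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble trimmed reads into contigs
#'
#' Runs the full contig stage: coverage filter, adaptive overlap filter,
#' string-graph construction, transitive reduction, best-overlap pruning,
#' graph cleaning, and contig extraction.
#'
#' @param reads trimmed read set.
#' @param overlaps overlap table from [trim_reads()].
#' @param cfg a [pipeline_config()].
#' @return list(`contigs`, `layout`, `graph` = final graph, `stages` =
#'   named edge counts after each stage).
#' @export
assemble_contigs <- function(reads, overlaps, cfg = pipeline_config()) {
  cf <- coverage_filter(reads, overlaps, cfg$min_coverage,
                        cfg$max_coverage, cfg$max_diff_coverage)
  ov <- adaptive_overlap_filter(cf$overlaps, cf$reads, cfg$global_identity,
                                cfg$global_overhang, cfg$identity_alpha)
  g <- build_string_graph(cf$reads, ov, cfg$global_overhang)
  stages <- c(raw = nrow(g$edges))
  g <- transitive_reduction(g, cfg$graph_fuzz)
  stages["transitive"] <- nrow(g$edges)
  g <- best_edge_prune(g)
  stages["best_edge"] <- nrow(g$edges)
  g <- clean_graph(g, cfg$tip_length, cfg$bubble_length, cfg$spur_frac)
  stages["clean"] <- nrow(g$edges)
  res <- extract_contigs(g, cf$reads)
  list(contigs = res$contigs, layout = res$layout, graph = g,
       reads = cf$reads, stages = stages)
}
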