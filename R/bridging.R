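#' Map raw reads onto contigs
#'
#' Anchor-chains each raw read against every contig in both orientations
#' and refines promising chains with the blockwise aligner (sensitive
#' fallback), so raw reads with high-error segments still map.  A read
#' crossing a former break point yields one hit per flanking contig.
#'
#' @param raw named character vector of raw reads.
#' @param contigs named character vector.
#' @param cfg a [pipeline_config()].
#' @param min_cols minimum alignment columns per hit.
#' @return data.frame: `read`, `contig`, `strand`, `r_start`, `r_end`
#'   (read forward coords), `c_start`, `c_end` (contig forward coords),
#'   `identity`, `cols`.
#' @export
map_raw_to_contigs <- function(raw, contigs, cfg = pipeline_config(),
                               min_cols = 1000) {
  idx <- kmer_index(contigs, cfg$kmer_size, cfg$kmer_stride,
                    max_occ = 0)
  rows <- list()
  for (id in names(raw)) {
    hits <- candidate_hits(idx, raw[[id]], epsilon = cfg$ddf_epsilon,
                           min_chain = cfg$min_chain)
    if (nrow(hits) == 0) next
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      ctg <- if (h$strand == "-") revcomp(contigs[[h$cand]]) else
        contigs[[h$cand]]
      a <- align_one(raw[[id]], ctg, h$seed_t, h$seed_c, cfg, pass = 2,
                     transcript = FALSE)
      if (a$cols < min_cols) next
      clen <- nchar(ctg)
      cs <- if (h$strand == "+") a$c_start else clen - a$c_end
      ce <- if (h$strand == "+") a$c_end else clen - a$c_start
      rows[[length(rows) + 1L]] <- data.frame(
        read = id, contig = h$cand, strand = h$strand,
        r_start = a$t_start, r_end = a$t_end, c_start = cs, c_end = ce,
        identity = 1 - a$diff, cols = a$cols, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(read = character(), contig = character(),
                      strand = character(), r_start = integer(),
                      r_end = integer(), c_start = integer(),
                      c_end = integer(), identity = numeric(),
                      cols = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # one best hit per (read, contig)
  out <- out[order(out$read, out$contig, -out$cols), , drop = FALSE]
  out <- out[!duplicated(paste(out$read, out$contig)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a raw read connecting two contigs
#'
#' Both hits must attach to a contig end (within `end_window` of a
#' terminus).  The gap length is the unaligned read distance between the
#' two hits minus the contigs' unaligned tails; a negative value means the
#' contig ends overlap (an "overlapped read"), a non-negative value a
#' "gap read".  The score is the sum of identity x length over the two
#' hits.
#'
#' @param hitA,hitB one-row hit data.frames for the same read on two
#'   different contigs.
#' @param contig_lens named lengths of the contigs.
#' @param end_window see [pipeline_config()]'s `bridge_end_window`.
#' @return A one-row link data.frame, or `NULL` for interior/same-contig
#'   pairs.
#' @export
classify_link <- function(hitA, hitB, contig_lens, end_window = 2000) {
  if (hitA$contig == hitB$contig) return(NULL)
  if (hitA$r_start > hitB$r_start) { tmp <- hitA; hitA <- hitB; hitB <- tmp }
  lenA <- contig_lens[[hitA$contig]]; lenB <- contig_lens[[hitB$contig]]
  # which end of each contig faces the junction (between the hits on the
  # read): for the first hit it is the end the read leaves, for the second
  # the end the read enters
  endA <- if (hitA$strand == "+") "R" else "L"
  endB <- if (hitB$strand == "+") "L" else "R"
  tailA <- if (endA == "R") lenA - hitA$c_end else hitA$c_start
  tailB <- if (endB == "L") hitB$c_start else lenB - hitB$c_end
  if (tailA > end_window || tailB > end_window) return(NULL)
  gap <- (hitB$r_start - hitA$r_end) - tailA - tailB
  data.frame(read = hitA$read, contig_a = hitA$contig,
             contig_b = hitB$contig, end_a = endA, end_b = endB,
             orientation = if (hitA$strand == hitB$strand) "same" else
               "different",
             kind = if (gap >= 0) "gap" else "overlapped",
             gap_len = gap,
             score = hitA$identity * hitA$cols + hitB$identity * hitB$cols,
             r_break_a = hitA$r_end, r_break_b = hitB$r_start,
             tail_a = tailA, tail_b = tailB,
             strand_a = hitA$strand, strand_b = hitB$strand,
             stringsAsFactors = FALSE)
}

#' Cluster link candidates by gap length
#'
#' Single-linkage clustering on the sorted gap/overlap lengths: two links
#' belong to the same cluster when their lengths differ by less than
#' `window` through a chain of such neighbours.
#'
#' @param links link rows for one contig pair and orientation.
#' @param window clustering window in bases (default 1000).
#' @return List of data.frames (one per cluster, sorted by gap length).
#' @export
cluster_links <- function(links, window = 1000) {
  if (nrow(links) == 0) return(list())
  links <- links[order(links$gap_len), , drop = FALSE]
  breaks <- which(diff(links$gap_len) >= window)
  idx <- cumsum(c(1, seq_len(nrow(links) - 1) %in% breaks))
  unname(split(links, idx))
}

#' Choose the winning link cluster
#'
#' The cluster with the largest score sum wins; ties break toward the
#' smaller median absolute gap length.  The representative read (used to
#' fill the gap) is the member with the largest individual score.
#'
#' @param clusters list from [cluster_links()].
#' @return list(`cluster`, `total_score`, `representative`), or `NULL`.
#' @export
choose_cluster <- function(clusters) {
  if (length(clusters) == 0) return(NULL)
  tot <- vapply(clusters, function(cl) sum(cl$score), 0)
  med <- vapply(clusters, function(cl) stats::median(abs(cl$gap_len)), 0)
  best <- order(-tot, med)[1]
  cl <- clusters[[best]]
  rep <- cl[which.max(cl$score), , drop = FALSE]
  list(cluster = cl, total_score = tot[best], representative = rep)
}

#' Bridge contigs with raw reads
#'
#' Maps raw reads to contigs, forms contig-pair link candidates from reads
#' whose two hits attach to contig ends, clusters them by gap length,
#' chooses the best cluster per contig pair and orientation, builds the
#' bridge graph (contig ends as nodes), resolves conflicts (an end with
#' several partners is a branch and is not merged), and emits the final
#' contigs with the representative read's sequence filling each gap.
#'
#' @param contigs named character vector.
#' @param raw named character vector of raw reads.
#' @param cfg a [pipeline_config()].
#' @param hits optional precomputed [map_raw_to_contigs()] table.
#' @return list(`contigs` = final contigs, `links` = chosen links table,
#'   `all_links` = every link candidate).
#' @export
bridge_contigs <- function(contigs, raw, cfg = pipeline_config(),
                           hits = NULL) {
  if (length(contigs) <= 1) {
    return(list(contigs = contigs,
                links = empty_links(), all_links = empty_links()))
  }
  if (is.null(hits)) hits <- map_raw_to_contigs(raw, contigs, cfg)
  lens <- nchar(contigs)
  cand <- list()
  for (id in unique(hits$read)) {
    hr <- hits[hits$read == id, , drop = FALSE]
    if (nrow(hr) < 2) next
    hr <- hr[order(hr$r_start), , drop = FALSE]
    for (i in seq_len(nrow(hr) - 1)) {
      lk <- classify_link(hr[i, ], hr[i + 1, ], lens,
                          cfg$bridge_end_window)
      if (!is.null(lk)) cand[[length(cand) + 1L]] <- lk
    }
  }
  all_links <- if (length(cand)) do.call(rbind, cand) else empty_links()
  chosen <- list()
  if (nrow(all_links) > 0) {
    grp_key <- paste(pmin(all_links$contig_a, all_links$contig_b),
                     pmax(all_links$contig_a, all_links$contig_b),
                     all_links$orientation)
    for (grp in split(all_links, grp_key)) {
      ch <- choose_cluster(cluster_links(grp, cfg$bridge_cluster_window))
      if (!is.null(ch)) {
        rep <- ch$representative
        rep$total_score <- ch$total_score
        rep$members <- nrow(ch$cluster)
        chosen[[length(chosen) + 1L]] <- rep
      }
    }
  }
  links <- if (length(chosen)) do.call(rbind, chosen) else empty_links()
  # remove transitive links: a direct A->C link implied by A->B plus B->C
  # (with B's length) within the clustering window
  if (nrow(links) > 1) {
    fwd_from <- node_id(links$contig_a, ifelse(links$end_a == "R", "+", "-"))
    fwd_to <- node_id(links$contig_b, ifelse(links$end_b == "L", "+", "-"))
    gl <- pmax(0, links$gap_len)
    ed <- data.frame(
      from = c(fwd_from, node_flip(fwd_to)),
      to = c(fwd_to, node_flip(fwd_from)),
      ext = "",
      ext_len = c(gl + nchar(contigs)[links$contig_b],
                  gl + nchar(contigs)[links$contig_a]),
      ovl_len = 0, identity = NA_real_, stringsAsFactors = FALSE)
    tg <- structure(list(nodes = unique(c(ed$from, ed$to)), edges = ed,
                         contained = character(0)), class = "string_graph")
    red <- transitive_reduction(tg, cfg$bridge_cluster_window)
    keep <- paste(fwd_from, fwd_to) %in% paste(red$edges$from, red$edges$to)
    links <- links[keep, , drop = FALSE]
  }
  # one link per contig end; competing partners at an end are a branch
  if (nrow(links) > 0) {
    ends <- c(paste(links$contig_a, links$end_a),
              paste(links$contig_b, links$end_b))
    conflicted <- unique(ends[duplicated(ends)])
    bad <- paste(links$contig_a, links$end_a) %in% conflicted |
      paste(links$contig_b, links$end_b) %in% conflicted
    links <- links[!bad, , drop = FALSE]
  }
  out <- splice_bridges(contigs, raw, links)
  list(contigs = out, links = links, all_links = all_links)
}

# Chosen links viewed as a (tiny) string graph over contigs, for GFA export.
bridge_graph <- function(contigs, links) {
  if (nrow(links) == 0) {
    g <- list(nodes = c(node_id(names(contigs), "+"),
                        node_id(names(contigs), "-")),
              edges = empty_edges(), contained = character(0))
    return(structure(g, class = "string_graph"))
  }
  edges <- data.frame(
    from = node_id(links$contig_a, ifelse(links$end_a == "R", "+", "-")),
    to = node_id(links$contig_b, ifelse(links$end_b == "L", "+", "-")),
    ext = "", ext_len = pmax(0, links$gap_len),
    ovl_len = pmax(0, -links$gap_len), identity = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(nodes = c(node_id(names(contigs), "+"),
                           node_id(names(contigs), "-")),
                 edges = edges, contained = character(0)),
            class = "string_graph")
}

empty_links <- function() {
  data.frame(read = character(), contig_a = character(),
             contig_b = character(), end_a = character(),
             end_b = character(), orientation = character(),
             kind = character(), gap_len = numeric(), score = numeric(),
             r_break_a = numeric(), r_break_b = numeric(),
             tail_a = numeric(), tail_b = numeric(),
             strand_a = character(), strand_b = character(),
             stringsAsFactors = FALSE)
}

# Walk chains of linked contigs and splice them.  Each link joins
# (contig_a, end_a) to (contig_b, end_b) through the representative
# read's junction segment.
splice_bridges <- function(contigs, raw, links) {
  if (nrow(links) == 0) return(contigs)
  merged <- character(0)
  used <- character(0)
  # adjacency: every link, viewed from both sides
  adj <- rbind(
    data.frame(ctg = links$contig_a, end = links$end_a, li = seq_len(nrow(links)),
               stringsAsFactors = FALSE),
    data.frame(ctg = links$contig_b, end = links$end_b, li = seq_len(nrow(links)),
               stringsAsFactors = FALSE))
  link_at <- function(ctg, end) {
    i <- which(adj$ctg == ctg & adj$end == end)
    if (length(i) == 0) NA_integer_ else adj$li[i[1]]
  }
  other_side <- function(li, ctg) {
    lk <- links[li, ]
    if (lk$contig_a == ctg) list(ctg = lk$contig_b, end = lk$end_b)
    else list(ctg = lk$contig_a, end = lk$end_a)
  }
  for (start in names(contigs)) {
    if (start %in% used) next
    # find a chain terminus: walk left from `start`
    cur <- start; in_end <- "L"; guard <- 0
    while (!is.na(li <- link_at(cur, in_end)) && guard < length(contigs)) {
      nb <- other_side(li, cur)
      if (nb$ctg %in% c(cur, start)) break     # cycle: break here
      cur <- nb$ctg
      in_end <- if (nb$end == "L") "R" else "L"   # entered via nb$end
      guard <- guard + 1
    }
    # now walk right from the terminus, splicing as we go
    chain_id <- cur
    orient <- if (in_end == "L") "+" else "-"
    seq <- if (orient == "+") contigs[[cur]] else revcomp(contigs[[cur]])
    used <- c(used, cur)
    out_end <- if (orient == "+") "R" else "L"
    repeat {
      li <- link_at(cur, out_end)
      if (is.na(li)) break
      lk <- links[li, ]
      nb <- other_side(li, cur)
      if (nb$ctg %in% used) break
      # junction sequence from the representative raw read
      jseq <- if (lk$kind == "gap" && lk$r_break_b > lk$r_break_a)
        substr(raw[[lk$read]], lk$r_break_a + 1L, lk$r_break_b) else ""
      # trim this contig's unaligned tail and splice
      tail_here <- if (lk$contig_a == cur) lk$tail_a else lk$tail_b
      tail_next <- if (lk$contig_a == cur) lk$tail_b else lk$tail_a
      strand_here <- if (lk$contig_a == cur) lk$strand_a else lk$strand_b
      strand_next <- if (lk$contig_a == cur) lk$strand_b else lk$strand_a
      if (strand_here != (if (orient == "+") "+" else "-")) {
        # the read runs along the other strand of the chain; its junction
        # segment must be reverse complemented
        jseq <- revcomp(jseq)
      }
      if (tail_here > 0) seq <- substr(seq, 1L, nchar(seq) - tail_here)
      nxt_orient <- if (nb$end == "L") "+" else "-"
      nxt_seq <- if (nxt_orient == "+") contigs[[nb$ctg]] else
        revcomp(contigs[[nb$ctg]])
      if (tail_next > 0) nxt_seq <- substr(nxt_seq, tail_next + 1L,
                                           nchar(nxt_seq))
      overlap_trim <- if (lk$kind == "overlapped")
        min(-lk$gap_len, nchar(nxt_seq) - 1L) else 0
      if (overlap_trim > 0) nxt_seq <- substr(nxt_seq, overlap_trim + 1L,
                                              nchar(nxt_seq))
      seq <- paste0(seq, jseq, nxt_seq)
      used <- c(used, nb$ctg)
      cur <- nb$ctg
      orient <- nxt_orient
      out_end <- if (orient == "+") "R" else "L"
    }
    merged[paste0(chain_id, "b")] <- seq
  }
  merged
}
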