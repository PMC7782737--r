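#' Select the longest reads up to a target coverage
#'
#' Sorts reads by length descending (ties by id) and keeps the smallest
#' prefix whose total length reaches `target * genome_size`; all reads are
#' kept (with a warning) when the set is too small.
#'
#' @param reads named character vector.
#' @param genome_size genome size estimate in bases.
#' @param target fold coverage to keep (default 40).
#' @return Subset of `reads`, in decreasing length order.
#' @export
select_longest_40x <- function(reads, genome_size, target = 40) {
  stopifnot(genome_size > 0)
  if (length(reads) == 0) return(reads)
  len <- nchar(reads)
  ord <- order(-len, names(reads))
  reads <- reads[ord]
  cum <- cumsum(nchar(reads))
  need <- target * genome_size
  if (cum[length(cum)] < need) {
    warning("only ", round(cum[length(cum)] / genome_size, 1),
            "X available; keeping all reads")
    return(reads)
  }
  reads[seq_len(which(cum >= need)[1])]
}

#' Pairwise overlaps within (or between) read sets
#'
#' Finds candidate pairs by k-mer chaining and aligns each pair once with
#' the blockwise aligner (sensitive realignment as a fallback when a block
#' stops the extension).  Records are reported from the template side
#' (`a`); coordinates on `b` refer to its oriented sequence with a strand
#' flag.
#'
#' @param reads named character vector (templates).
#' @param cfg a [pipeline_config()].
#' @param against optional second read set to overlap `reads` against
#'   (default: all-vs-all within `reads`, each unordered pair aligned
#'   once).
#' @param min_cols drop overlaps with fewer alignment columns.
#' @return data.frame: `a`, `b`, `strand`, `a_start`, `a_end`, `b_start`,
#'   `b_end` (oriented b), `identity`, `cols`.
#' @export
compute_overlaps <- function(reads, cfg = pipeline_config(), against = NULL,
                             min_cols = cfg$min_overlap_length) {
  self_mode <- is.null(against)
  targets <- if (self_mode) reads else against
  idx <- kmer_index(targets, cfg$kmer_size, cfg$kmer_stride,
                    cfg$kmer_max_occ)
  rows <- list()
  for (id in names(reads)) {
    hits <- candidate_hits(idx, reads[[id]], self = if (self_mode) id else NA,
                           epsilon = cfg$ddf_epsilon,
                           min_chain = cfg$min_chain)
    if (nrow(hits) == 0) next
    if (self_mode) hits <- hits[hits$cand > id, , drop = FALSE]  # one per pair
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      cand <- if (h$strand == "-") revcomp(targets[[h$cand]]) else
        targets[[h$cand]]
      a <- align_one(reads[[id]], cand, h$seed_t, h$seed_c, cfg, pass = 2,
                     transcript = FALSE)
      if (a$cols < min_cols) next
      rows[[length(rows) + 1L]] <- data.frame(
        a = id, b = h$cand, strand = h$strand,
        a_start = a$t_start, a_end = a$t_end,
        b_start = a$c_start, b_end = a$c_end,
        identity = 1 - a$diff, cols = a$cols, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(a = character(), b = character(), strand = character(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      identity = numeric(), cols = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# View an overlap table from the perspective of a single read: one row per
# overlap touching `id`, with this read's interval first.
overlaps_for_read <- function(overlaps, id, read_lens) {
  a_side <- overlaps[overlaps$a == id, , drop = FALSE]
  b_side <- overlaps[overlaps$b == id, , drop = FALSE]
  iv <- data.frame(start = integer(0), end = integer(0),
                   other = character(0), identity = numeric(0),
                   cols = numeric(0))
  if (nrow(a_side))
    iv <- rbind(iv, data.frame(start = a_side$a_start, end = a_side$a_end,
                               other = a_side$b, identity = a_side$identity,
                               cols = a_side$cols))
  if (nrow(b_side)) {
    # b-side coordinates are on the oriented b; map to forward coordinates
    len <- read_lens[[id]]
    s <- ifelse(b_side$strand == "+", b_side$b_start, len - b_side$b_end)
    e <- ifelse(b_side$strand == "+", b_side$b_end, len - b_side$b_start)
    iv <- rbind(iv, data.frame(start = s, end = e, other = b_side$a,
                               identity = b_side$identity,
                               cols = b_side$cols))
  }
  iv
}

#' Coverage intervals of a read from qualifying overlaps
#'
#' Unions the read-side intervals of all overlaps with identity strictly
#' greater than `min_identity`.
#'
#' @param read_len read length in bases.
#' @param intervals data.frame with `start`, `end`, `identity` (e.g. from
#'   the overlap table, read-side).
#' @param min_identity identity cutoff (strict).
#' @return data.frame of disjoint sorted intervals (`start`, `end`).
#' @export
coverage_from_overlaps <- function(read_len, intervals,
                                   min_identity = 0.90) {
  iv <- intervals[intervals$identity > min_identity, , drop = FALSE]
  union_intervals(iv$start, iv$end, read_len)
}

union_intervals <- function(start, end, limit = Inf) {
  if (length(start) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  start <- pmax(0L, as.integer(start)); end <- pmin(limit, as.integer(end))
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  os <- start[1]; oe <- end[1]
  rs <- integer(0); re <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= oe) oe <- max(oe, end[i])
    else { rs <- c(rs, os); re <- c(re, oe); os <- start[i]; oe <- end[i] }
  }
  data.frame(start = c(rs, os), end = c(re, oe))
}

#' Classify a read as complete or trimmed
#'
#' A read whose whole length is covered by qualifying overlaps is complete;
#' otherwise it is trimmed to its longest covered interval (leftmost on
#' ties).  Reads with no coverage are dropped (`NULL`).
#'
#' @param read sequence.
#' @param cov coverage intervals (from [coverage_from_overlaps()]).
#' @return list(`kind` = "complete"|"trimmed", `seq`, `start`, `end`), or
#'   `NULL`.
#' @export
classify_and_trim <- function(read, cov) {
  n <- nchar(read)
  if (nrow(cov) == 0) return(NULL)
  if (nrow(cov) == 1 && cov$start[1] <= 0 && cov$end[1] >= n)
    return(list(kind = "complete", seq = read, start = 0L, end = n))
  best <- which.max(cov$end - cov$start)     # leftmost maximum
  list(kind = "trimmed",
       seq = substr(read, cov$start[best] + 1L, cov$end[best]),
       start = cov$start[best], end = cov$end[best])
}

#' Second-round pairwise alignment schedule
#'
#' After trimming, pairwise alignments are repeated only where coordinates
#' changed: complete x trimmed and trimmed x trimmed.  Complete x complete
#' overlaps from the first round are reused.
#'
#' @param completes,trimmeds character vectors of read ids.
#' @return data.frame of unordered pairs (`a`, `b`).
#' @export
second_round_pairs <- function(completes, trimmeds) {
  pairs <- list()
  if (length(trimmeds) > 0 && length(completes) > 0)
    pairs[[1]] <- expand.grid(a = completes, b = trimmeds,
                              stringsAsFactors = FALSE)
  if (length(trimmeds) > 1) {
    cmb <- utils::combn(sort(trimmeds), 2)
    pairs[[length(pairs) + 1L]] <- data.frame(a = cmb[1, ], b = cmb[2, ],
                                              stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

#' Trim corrected reads by overlap coverage
#'
#' Selects the longest `target`X corrected reads, computes pairwise
#' overlaps, unions each read's high-identity overlap intervals, emits
#' complete reads unchanged and trimmed reads cut to their longest covered
#' interval, and re-aligns the pairs whose coordinates changed.  The
#' returned overlap table (first-round complete x complete records merged
#' with the second-round records) feeds the assembly stage.
#'
#' @param reads corrected reads (named character vector).
#' @param genome_size genome size estimate (bases).
#' @param cfg a [pipeline_config()].
#' @return list(`reads` = trimmed read set, `info` = data.frame (`id`,
#'   `kind`, `start`, `end`, `source`), `overlaps` = overlap table for
#'   assembly).
#' @export
trim_reads <- function(reads, genome_size, cfg = pipeline_config()) {
  sel <- select_longest_40x(reads, genome_size, cfg$trim_coverage_target)
  ovl <- compute_overlaps(sel, cfg)
  lens <- nchar(sel)
  info <- list()
  out <- character(0)
  for (id in names(sel)) {
    iv <- overlaps_for_read(ovl, id, lens)
    cov <- coverage_from_overlaps(lens[[id]], iv, cfg$trim_identity)
    cl <- classify_and_trim(sel[[id]], cov)
    if (is.null(cl)) {
      message("trimming: dropped uncovered read ", id)
      next
    }
    out[id] <- cl$seq
    info[[length(info) + 1L]] <- data.frame(
      id = id, kind = cl$kind, start = cl$start, end = cl$end,
      source = id, stringsAsFactors = FALSE)
  }
  info <- if (length(info)) do.call(rbind, info) else
    data.frame(id = character(), kind = character(), start = integer(),
               end = integer(), source = character())
  completes <- info$id[info$kind == "complete"]
  trimmeds <- info$id[info$kind == "trimmed"]
  keep_cc <- ovl$a %in% completes & ovl$b %in% completes
  first_round <- ovl[keep_cc, , drop = FALSE]
  second <- if (length(trimmeds) > 0)
    compute_overlaps(out[trimmeds], cfg, against = out) else
    data.frame()
  if (nrow(second) > 0) {
    second <- second[second$a != second$b, , drop = FALSE]
    # drop duplicate unordered pairs already present or mirrored
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    second <- second[!duplicated(key(second$a, second$b)), , drop = FALSE]
    second <- second[!(key(second$a, second$b) %in%
                         key(first_round$a, first_round$b)), , drop = FALSE]
    overlaps <- rbind(first_round, second)
  } else overlaps <- first_round
  rownames(overlaps) <- NULL
  list(reads = out, info = info, overlaps = overlaps)
}
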