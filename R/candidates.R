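#' Build a k-mer position index over a read set
#'
#' Indexes sampled canonical k-mers of every read.  K-mers occurring more
#' often than `max_occ` (likely repeats) are masked.  The index is an
#' external pointer bound to this session; rebuild it rather than
#' serializing it.
#'
#' @param reads named character vector.
#' @param k k-mer size (8--21).
#' @param stride sampling stride along each read.
#' @param max_occ occupancy cutoff; `0` disables masking.
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(reads, k = 13, stride = 5, max_occ = 500) {
  xp <- cpp_build_index(unname(reads), as.integer(k), as.integer(stride),
                        as.integer(max_occ))
  structure(list(ptr = xp, ids = names(reads), k = k, stride = stride),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<kmer_index> %d reads, k=%d stride=%d, %.0f k-mers / %.0f postings\n",
              info$n_reads, info$k, info$stride, info$n_kmers,
              info$n_postings))
  invisible(x)
}

#' Look up one k-mer in an index
#'
#' @param index a `kmer_index`.
#' @param kmer a k-length string.
#' @return data.frame with `read` (id), `pos` (0-based offset) and `strand`
#'   (`"+"` if the canonical form is the forward k-mer at that offset).
#' @export
index_lookup <- function(index, kmer) {
  df <- cpp_index_lookup(index$ptr, toupper(kmer))
  df$read <- index$ids[df$read]
  df
}

#' Find candidate hits for one template against an index
#'
#' For every indexed read sharing sampled k-mers with the template, the
#' distance-difference factor (DDF) selects a seed k-mer pair (the pair
#' supported by the most other pairs whose template/candidate offset
#' differences agree within `epsilon`); the supporting pairs plus the seed
#' are then reduced to the longest co-linear chain.  The chain size is the
#' hit's score, the first/last chain positions (extended by k) give the
#' approximate mapped intervals, and a mid-chain pair is reported as the
#' alignment seed.
#'
#' Candidate-side coordinates (`c_start`, `c_end`, `seed_c`) refer to the
#' oriented candidate: for `strand == "-"` they index the
#' reverse-complemented candidate sequence.  [write_paf()] converts back to
#' forward-strand coordinates.
#'
#' @param index a `kmer_index`.
#' @param template template sequence (character scalar).
#' @param self id (or `NA`) of the template inside the index, excluded from
#'   its own candidates.
#' @param epsilon distance-difference tolerance in bases.
#' @param min_chain minimum chain size to report a hit.
#' @return data.frame of hits: `cand`, `strand`, `score`, `t_start`,
#'   `t_end`, `c_start`, `c_end`, `seed_t`, `seed_c`.
#' @export
candidate_hits <- function(index, template, self = NA, epsilon = 32,
                           min_chain = 3) {
  self0 <- if (is.na(self)) -1L else match(self, index$ids) - 1L
  if (is.na(self0)) self0 <- -1L
  res <- cpp_scan_template(index$ptr, template, as.integer(self0),
                           as.integer(epsilon), as.integer(min_chain))
  hits <- res$hits
  hits$cand <- index$ids[hits$cand]
  hits
}

#' DDF seed selection and k-mer chaining for one read pair
#'
#' Convenience two-read version of [candidate_hits()]; optionally returns
#' the chained k-mer pairs.  Returns `NULL` when the pair shares no
#' sufficient chain.
#'
#' @param template,candidate sequences.
#' @param k,stride,epsilon,min_chain see [kmer_index()] /
#'   [candidate_hits()].
#' @param return_chain also return the chain's k-mer pair positions.
#' @return A one-row hits data.frame (strongest strand), with attribute
#'   `chain` when requested, or `NULL`.
#' @export
ddf_seed_and_chain <- function(template, candidate, k = 13, stride = 5,
                               epsilon = 32, min_chain = 3,
                               return_chain = FALSE) {
  res <- cpp_scan_pair(template, candidate, as.integer(k),
                       as.integer(stride), as.integer(epsilon),
                       as.integer(min_chain), TRUE)
  hits <- res$hits
  if (nrow(hits) == 0) return(NULL)
  best <- which.max(hits$score)
  out <- hits[best, , drop = FALSE]
  rownames(out) <- NULL
  if (return_chain) attr(out, "chain") <- res$chains[[best]]
  out
}

#' Keep the top-scoring candidate hits
#'
#' Sorts by DDF score descending, breaking ties by longer approximate
#' template interval and then lexicographic candidate id, and returns the
#' first `m` rows.
#'
#' @param hits hits data.frame.
#' @param m maximum number of hits to keep.
#' @return Sorted subset of `hits`.
#' @export
top_candidates <- function(hits, m) {
  stopifnot(m >= 1)
  if (nrow(hits) == 0) return(hits)
  span <- hits$t_end - hits$t_start
  ord <- order(-hits$score, -span, hits$cand)
  out <- hits[ord[seq_len(min(m, nrow(hits)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find candidate hits for every read in a set
#'
#' Builds the index once and scans each read as a template against all the
#' others, keeping at most `max_candidates` top hits per template.
#'
#' @param reads named character vector.
#' @param cfg a [pipeline_config()].
#' @param max_candidates per-template cap (default
#'   `cfg$max_aligned_candidates`).
#' @return Named list (one element per template id) of hits data.frames.
#' @export
find_candidates <- function(reads, cfg = pipeline_config(),
                            max_candidates = cfg$max_aligned_candidates) {
  idx <- kmer_index(reads, cfg$kmer_size, cfg$kmer_stride, cfg$kmer_max_occ)
  out <- vector("list", length(reads))
  names(out) <- names(reads)
  for (id in names(reads)) {
    h <- candidate_hits(idx, reads[[id]], self = id,
                        epsilon = cfg$ddf_epsilon,
                        min_chain = cfg$min_chain)
    out[[id]] <- top_candidates(h, max_candidates)
  }
  out
}

#' Export candidate hits as PAF
#'
#' Writes the approximate (k-mer-chain) hits of every template as 12-column
#' PAF records with the chain size in a `cm:i:` tag.
#'
#' @param hits_list named list of hits data.frames (see
#'   [find_candidates()]).
#' @param reads the read set the hits refer to.
#' @param path output file.
#' @export
write_hits_paf <- function(hits_list, reads, path) {
  rows <- lapply(names(hits_list), function(id) {
    h <- hits_list[[id]]
    if (is.null(h) || nrow(h) == 0) return(NULL)
    data.frame(a = id, b = h$cand, strand = h$strand, a_start = h$t_start,
               a_end = h$t_end, b_start = h$c_start, b_end = h$c_end,
               score = h$score, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- data.frame(a = character())
  write_paf(rows, reads, path)
}

# Oriented candidate sequence for a hit row.
oriented_candidate <- function(hit, reads) {
  s <- reads[[hit$cand]]
  if (hit$strand == "-") revcomp(s) else s
}
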