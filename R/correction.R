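#' Blockwise local alignment from a seed
#'
#' Extends an alignment outward from a seed k-mer pair in fixed-size blocks
#' (default 500 bp), aligning each template block against a banded window
#' of the candidate and stopping in a direction when a block pair exceeds
#' the per-block error ceiling (0.5) or a read end is reached.  This is the
#' pass-1 aligner: it deliberately refuses to cross high-error-rate
#' subsequences.
#'
#' @param template template sequence.
#' @param candidate candidate sequence, already oriented (reverse
#'   complemented for minus-strand hits).
#' @param seed_t,seed_c seed offsets (0-based) on template / oriented
#'   candidate.
#' @param cfg a [pipeline_config()].
#' @param transcript return an edit transcript (`M`/`X`/`I`/`D` over
#'   template columns) suitable for consensus.
#' @param max_block_err per-block error ceiling.
#' @return list with `t_start`, `t_end`, `c_start`, `c_end` (0-based
#'   half-open), `edits`, `cols`, `diff`, `stopped_left`, `stopped_right`
#'   and optionally `transcript`.
#' @export
blockwise_align <- function(template, candidate, seed_t, seed_c,
                            cfg = pipeline_config(), transcript = FALSE,
                            max_block_err = 0.5) {
  cpp_block_align(template, candidate, as.integer(seed_t),
                  as.integer(seed_c), as.integer(cfg$block_size),
                  block_slack(cfg), max_block_err,
                  if (transcript) "tb" else "dist")
}

#' Sensitive realignment for high-error pairs
#'
#' The pass-2 aligner: a gap-tolerant anchor chain locates the mapped
#' subsequences even across segments with up to ~50% local error, the
#' chained interval is realigned exactly (banded global alignment between
#' consecutive anchors), and the ends are extended blockwise.  Returns
#' `NULL` when no adequate chain exists or the overall difference exceeds
#' the global threshold.
#'
#' @inheritParams blockwise_align
#' @param max_diff drop the pair if the overall difference exceeds this.
#' @return As [blockwise_align()] (always with a transcript), or `NULL`.
#' @export
sensitive_align <- function(template, candidate, cfg = pipeline_config(),
                            max_diff = cfg$global_error_threshold) {
  cpp_sensitive_align(template, candidate, 11L, 2L, max_diff,
                      as.integer(cfg$block_size), block_slack(cfg), 4L)
}

align_one <- function(template, candidate, seed_t, seed_c, cfg, pass,
                      transcript) {
  a <- blockwise_align(template, candidate, seed_t, seed_c, cfg,
                       transcript = transcript)
  if (pass == 2 && (isTRUE(a$stopped_left) || isTRUE(a$stopped_right))) {
    s <- sensitive_align(template, candidate, cfg)
    if (!is.null(s) && s$cols > a$cols) return(s)
  }
  a
}

#' Estimate the individual alignment-quality threshold for a template
#'
#' Aligns the top-`n` candidates (default 50) and records the alignment
#' difference `d_i` of every alignment that spans more than `span_frac`
#' (60%) of the template or of the candidate.  The individual threshold is
#' `d = d0 - 5 D`, where `d0` is the mean recorded difference and `D` their
#' standard deviation, clamped into `[0, global]`; with no recorded
#' alignment the global threshold is returned as a fallback.
#'
#' @param template template sequence.
#' @param hits candidate hits for this template, strongest first (see
#'   [top_candidates()]); only the first
#'   `cfg$top_candidates_for_threshold` are used.
#' @param reads named character vector holding the candidate sequences.
#' @param cfg a [pipeline_config()].
#' @param pass 1 or 2 (selects the aligner used for the local alignments).
#' @return An object of class `threshold_estimate`: `n`, `d_i`, `d0`, `D`,
#'   `d`, plus attribute `alignments` (one result per aligned hit, reused
#'   by the support-selection stage).
#' @export
estimate_threshold <- function(template, hits, reads,
                               cfg = pipeline_config(), pass = 1) {
  n_align <- min(nrow(hits), cfg$top_candidates_for_threshold)
  tlen <- nchar(template)
  aligns <- vector("list", n_align)
  d_i <- numeric(0)
  for (i in seq_len(n_align)) {
    h <- hits[i, ]
    cand <- oriented_candidate(h, reads)
    # estimation is always blockwise and distance-only; the sensitive
    # realigner (which must produce transcripts) is reserved for the
    # support-selection stage
    a <- align_one(template, cand, h$seed_t, h$seed_c, cfg, pass = 1,
                   transcript = FALSE)
    aligns[[i]] <- a
    t_span <- a$t_end - a$t_start
    c_span <- a$c_end - a$c_start
    if (t_span > cfg$span_frac * tlen ||
        c_span > cfg$span_frac * nchar(cand))
      d_i <- c(d_i, a$diff)
  }
  out <- threshold_from_differences(d_i, cfg)
  attr(out, "alignments") <- aligns
  out
}

#' Compute the adaptive threshold from recorded differences
#'
#' The individual threshold is a lower bound on alignment *quality*:
#' supports must have identity of at least `mean identity - 5 sd`, i.e.
#' difference at most `d0 + 5 D` (clamped into `[0, global]`).  The
#' config switch `threshold_formula = "minus"` selects the literal
#' error-space subtraction `d0 - 5 D` instead; note that variant leaves
#' essentially no support below the threshold and is provided only for
#' comparison (see the methods vignette).
#'
#' @param d_i recorded alignment differences.
#' @param cfg a [pipeline_config()]; uses `global_error_threshold`,
#'   `threshold_sd_normalized` and `threshold_formula`.
#' @return A `threshold_estimate` (without alignments).
#' @export
threshold_from_differences <- function(d_i, cfg = pipeline_config()) {
  n <- length(d_i)
  if (n == 0) {
    return(structure(list(n = 0L, d_i = numeric(0), d0 = NA_real_,
                          D = NA_real_, d = cfg$global_error_threshold,
                          fallback = TRUE),
                     class = "threshold_estimate"))
  }
  d0 <- mean(d_i)
  ss <- sum((d_i - d0)^2)
  D <- if (cfg$threshold_sd_normalized) sqrt(ss / n) else sqrt(ss)
  sgn <- if (identical(cfg$threshold_formula, "minus")) -1 else 1
  d <- min(max(d0 + sgn * 5 * D, 0), cfg$global_error_threshold)
  structure(list(n = as.integer(n), d_i = d_i, d0 = d0, D = D, d = d,
                 fallback = FALSE),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> n=%d d0=%s D=%s d=%.4f%s\n", x$n,
              format(x$d0, digits = 4), format(x$D, digits = 4), x$d,
              if (isTRUE(x$fallback)) " (fallback to global)" else ""))
  invisible(x)
}

#' Filter support alignments by the two thresholds
#'
#' A support is kept iff its alignment difference is at most
#' `min(global, d)`.  Templates whose kept-support count falls below
#' `min_cov` are flagged uncorrectable (discarded without correction).
#'
#' @param diffs numeric vector of alignment differences.
#' @param d individual threshold (a number or a `threshold_estimate`).
#' @param global_threshold global overlapping-error-rate threshold.
#' @param min_cov minimum kept supports for the template to be correctable.
#' @return list(`keep` = logical vector, `uncorrectable` = flag).
#' @export
filter_supports <- function(diffs, d, global_threshold = 0.5, min_cov = 4) {
  if (inherits(d, "threshold_estimate")) d <- d$d
  keep <- diffs <= min(global_threshold, d)
  list(keep = keep, uncorrectable = sum(keep) < min_cov)
}

#' Coverage count array gate
#'
#' `cca_gate()` returns `FALSE` (skip the alignment) iff every count on the
#' candidate's approximate template interval is strictly greater than `C`;
#' `cca_update()` increments the counts of an accepted alignment's template
#' interval.
#'
#' @param counts integer vector (length of the template).
#' @param start,end 0-based half-open template interval.
#' @param C gate threshold.
#' @return `cca_gate`: logical (proceed?); `cca_update`: updated counts.
#' @export
cca_gate <- function(counts, start, end, C = 12) {
  start <- max(0L, as.integer(start)); end <- min(length(counts), as.integer(end))
  if (end <= start) return(TRUE)
  !all(counts[(start + 1L):end] > C)
}

#' @rdname cca_gate
#' @export
cca_update <- function(counts, start, end) {
  start <- max(0L, as.integer(start)); end <- min(length(counts), as.integer(end))
  if (end > start) {
    idx <- (start + 1L):end
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

#' Stream support alignments under the coverage-count-array gate
#'
#' Walks candidate hits in score order.  Before aligning a candidate the
#' CCA is examined on its approximate mapped template interval: if every
#' base there is already covered by more than `C` accepted supports the
#' alignment is skipped.  Executed alignments whose difference passes the
#' threshold are recorded as supports and update the CCA.
#'
#' @param template template sequence.
#' @param hits hits data.frame in score order.
#' @param threshold effective difference threshold
#'   (`min(global, individual)`).
#' @param reads named character vector of candidate sequences.
#' @param cfg a [pipeline_config()].
#' @param pass 1 or 2.
#' @param cca optional initial counts (default all zero).
#' @param gate apply the CCA gate (disable to measure the gate-free run).
#' @param prealigned optional list of distance-mode alignment results for
#'   the leading hits (from [estimate_threshold()]); reused to decide
#'   pass/fail before the transcript is computed.
#' @return list(`supports` = list of alignment records with transcripts and
#'   candidate ids, `cca` = final counts, `executed` = number of executed
#'   alignments).
#' @export
align_supports <- function(template, hits, threshold, reads,
                           cfg = pipeline_config(), pass = 1, cca = NULL,
                           gate = TRUE, prealigned = NULL) {
  tlen <- nchar(template)
  if (is.null(cca)) cca <- integer(tlen)
  C <- cfg$cca_threshold
  supports <- list()
  executed <- 0L
  max_sup <- if (is.null(cfg$max_supports)) Inf else cfg$max_supports
  for (i in seq_len(nrow(hits))) {
    if (length(supports) >= max_sup) break
    h <- hits[i, ]
    if (gate && !cca_gate(cca, h$t_start, h$t_end, C)) next
    pre <- if (!is.null(prealigned) && i <= length(prealigned))
      prealigned[[i]] else NULL
    # skip known failures, but never on the strength of an alignment that
    # stopped early (the sensitive realigner may still rescue it)
    if (!is.null(pre) && pre$diff > threshold &&
        !isTRUE(pre$stopped_left) && !isTRUE(pre$stopped_right)) next
    cand <- oriented_candidate(h, reads)
    a <- align_one(template, cand, h$seed_t, h$seed_c, cfg, pass,
                   transcript = TRUE)
    executed <- executed + 1L
    if (is.null(a$transcript) || a$diff > threshold) next
    a$cand <- h$cand
    a$strand <- h$strand
    a$csub <- substr(cand, a$c_start + 1L, a$c_end)
    supports[[length(supports) + 1L]] <- a
    cca <- cca_update(cca, a$t_start, a$t_end)
  }
  list(supports = supports, cca = cca, executed = executed)
}

#' Plurality consensus over support alignments
#'
#' Tallies, per template position, the aligned bases, deletions and
#' insertion strings of all supports and emits maximal runs of positions
#' with support count at least `min_cov` as corrected intervals with their
#' plurality sequence.  Base ties break lexicographically; a deletion must
#' strictly outnumber the best base; an insertion is emitted only on a
#' strict majority.
#'
#' @param template template sequence.
#' @param supports list of support alignments (from [align_supports()]).
#' @param min_cov minimum support count per corrected position.
#' @return data.frame with `start`, `end` (0-based half-open template
#'   interval) and `seq` (corrected sequence), plus attribute `coverage`.
#' @export
consensus <- function(template, supports, min_cov = 4) {
  if (length(supports) == 0) {
    out <- data.frame(start = integer(), end = integer(),
                      seq = character(), stringsAsFactors = FALSE)
    attr(out, "coverage") <- integer(nchar(template))
    return(out)
  }
  res <- cpp_consensus(template,
                       vapply(supports, function(s) as.integer(s$t_start), 1L),
                       vapply(supports, `[[`, "", "transcript"),
                       vapply(supports, `[[`, "", "csub"),
                       as.integer(min_cov))
  out <- data.frame(start = res$start, end = res$end, seq = res$seq,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- res$coverage
  out
}

# Shared per-template correction: candidates -> threshold -> gated supports
# -> consensus runs.
correct_template <- function(template, hits, reads, cfg, pass) {
  hits <- top_candidates(hits, cfg$max_aligned_candidates)
  est <- estimate_threshold(template, hits, reads, cfg, pass)
  thr <- min(cfg$global_error_threshold, est$d)
  res <- align_supports(template, hits, thr, reads, cfg, pass,
                        prealigned = attr(est, "alignments"))
  runs <- consensus(template, res$supports, cfg$consensus_min_coverage)
  list(est = est, runs = runs, supports = res$supports,
       executed = res$executed,
       uncorrectable = length(res$supports) < cfg$consensus_min_coverage)
}

splice_runs <- function(template, runs) {
  tlen <- nchar(template)
  mask <- logical(tlen)
  if (nrow(runs) == 0) return(list(seq = template, mask = mask))
  pieces <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (s > cur) pieces <- c(pieces, substr(template, cur + 1L, s))
    pieces <- c(pieces, runs$seq[i])
    mask[(s + 1L):e] <- TRUE
    cur <- e
  }
  if (cur < tlen) pieces <- c(pieces, substr(template, cur + 1L, tlen))
  list(seq = paste(pieces, collapse = ""), mask = mask)
}

#' Pass-1 correction of a read set
#'
#' For every template: candidate selection, adaptive threshold estimation,
#' CCA-gated support alignment with the blockwise aligner, and plurality
#' consensus.  Corrected intervals replace the template subsequence; the
#' rest of the template (including high-error subsequences, where blockwise
#' alignment stops) is passed through unchanged, so the output read is
#' full-length.
#'
#' @param reads named character vector.
#' @param cfg a [pipeline_config()].
#' @param hits_list optional precomputed [find_candidates()] result.
#' @param pool candidate read pool the hits refer to (defaults to `reads`;
#'   pass the full set when correcting a subset).
#' @param progress print a progress message every 100 templates.
#' @return list(`reads` = corrected reads (same ids and order), `mask` =
#'   list of per-base corrected flags, `stats` = per-template data.frame
#'   with `n`, `d0`, `D`, `d`, `supports`, `executed`, `uncorrectable`).
#' @export
correct_pass1 <- function(reads, cfg = pipeline_config(),
                          hits_list = NULL, pool = reads,
                          progress = FALSE) {
  if (is.null(hits_list)) hits_list <- find_candidates(pool, cfg)
  out <- reads
  mask <- vector("list", length(reads))
  names(mask) <- names(reads)
  stats <- template_stats_frame(names(reads))
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    r <- correct_template(reads[[i]], hits_list[[id]], pool, cfg, pass = 1)
    if (r$uncorrectable) {
      mask[[id]] <- logical(nchar(reads[[i]]))
    } else {
      sp <- splice_runs(reads[[i]], r$runs)
      out[[i]] <- sp$seq
      mask[[id]] <- sp$mask
    }
    stats[i, -1] <- template_stats_row(r)
    if (progress && i %% 100 == 0)
      message("pass 1: ", i, "/", length(reads), " templates")
  }
  list(reads = out, mask = mask, stats = stats)
}

#' Pass-2 correction: rescue high-error subsequences
#'
#' Re-runs the correction machinery on the pass-1 output, with the
#' sensitive realigner as a fallback wherever blockwise alignment
#' terminated early.  Only corrected subsequences are emitted, so a
#' template with an uncorrectable interior interval yields several
#' fragments (ids `template/2/start_end`); fragments shorter than
#' `min_len` are dropped.
#'
#' @param reads pass-1 corrected reads (named character vector).
#' @param cfg a [pipeline_config()].
#' @param hits_list optional precomputed candidates.
#' @param pool candidate pool the hits refer to (defaults to `reads`).
#' @param min_len minimum emitted fragment length (default
#'   `cfg$min_read_length`).
#' @param progress print progress.
#' @return list(`reads` = fragment sequences, `fragments` = data.frame
#'   (`id`, `template`, `start`, `end`), `stats` = per-template stats).
#' @export
correct_pass2 <- function(reads, cfg = pipeline_config(), hits_list = NULL,
                          pool = reads, min_len = cfg$min_read_length,
                          progress = FALSE) {
  if (is.null(hits_list)) hits_list <- find_candidates(pool, cfg)
  frag_seq <- character(0)
  frag_tab <- list()
  stats <- template_stats_frame(names(reads))
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    r <- correct_template(reads[[i]], hits_list[[id]], pool, cfg, pass = 2)
    runs <- if (r$uncorrectable)
      data.frame(start = integer(), end = integer(), seq = character())
      else r$runs
    keep <- which(nchar(runs$seq) >= min_len)
    for (j in keep) {
      fid <- sprintf("%s/2/%d_%d", id, runs$start[j], runs$end[j])
      frag_seq[fid] <- runs$seq[j]
      frag_tab[[length(frag_tab) + 1L]] <-
        data.frame(id = fid, template = id, start = runs$start[j],
                   end = runs$end[j], stringsAsFactors = FALSE)
    }
    stats[i, -1] <- template_stats_row(r)
    if (progress && i %% 100 == 0)
      message("pass 2: ", i, "/", length(reads), " templates")
  }
  fragments <- if (length(frag_tab)) do.call(rbind, frag_tab) else
    data.frame(id = character(), template = character(),
               start = integer(), end = integer())
  list(reads = frag_seq, fragments = fragments, stats = stats)
}

template_stats_frame <- function(ids) {
  data.frame(template = ids, n = NA_integer_, d0 = NA_real_, D = NA_real_,
             d = NA_real_, supports = NA_integer_, executed = NA_integer_,
             uncorrectable = NA, stringsAsFactors = FALSE)
}

template_stats_row <- function(r) {
  list(r$est$n, r$est$d0, r$est$D, r$est$d, length(r$supports),
       r$executed, r$uncorrectable)
}

#' Write per-template correction statistics
#'
#' @param stats stats data.frame from [correct_pass1()]/[correct_pass2()].
#' @param path output TSV.
#' @export
write_template_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
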