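#' Truth-aligned error profile of a read
#'
#' Aligns a read against its clean template (the oriented genome interval
#' it was sampled from) blockwise from the start and returns the overall
#' alignment difference plus per-window statistics.  Windows tile the read;
#' a final partial window shorter than half the window length is merged
#' into the previous one.
#'
#' @param read read sequence.
#' @param template oriented clean template (see the simulator's truth
#'   plans, or extract from a reference).
#' @param window window length in bases (default 500).
#' @return list(`error_rate` = edits / alignment columns, `windows` =
#'   data.frame (`start`, `len`, `edits`, `cols`, `rate`)); the window
#'   `rate` is edits over the shorter of the window and its aligned
#'   template span, so garbage windows score well above 0.5.
#' @export
truth_align_profile <- function(read, template, window = 500) {
  # anchor the alignment at a mid-chain exact match so reads that cover
  # only part of the template (pass-2 fragments) are profiled correctly
  ch <- cpp_anchor_chain(read, template, 13L, 2L, 2000L)
  seed <- if (nrow(ch) >= 3) ch[ceiling(nrow(ch) / 2), ] else c(0L, 0L)
  pr <- cpp_block_align(read, template, seed[1], seed[2],
                        as.integer(window),
                        as.integer(window / 2), 2.0, "tb")
  ops <- strsplit(pr$transcript, "")[[1]]
  if (length(ops) == 0)
    return(list(error_rate = NA_real_,
                windows = data.frame(start = integer(), len = integer(),
                                     edits = integer(), cols = integer(),
                                     rate = numeric())))
  consume_r <- ops != "I"                     # read base consumed
  # read coordinate of each alignment column (I columns sit on the next base)
  rpos <- pr$t_start + cumsum(consume_r) - as.integer(consume_r)
  widx <- rpos %/% window
  nwin <- max(widx) + 1L
  # merge a short final window (< window/2 read bases) into the previous one
  if (nwin > 1 && sum(consume_r & widx == nwin - 1L) < window / 2) {
    widx[widx == nwin - 1L] <- nwin - 2L
    nwin <- nwin - 1L
  }
  f <- factor(widx, levels = 0:(nwin - 1L))
  edits <- as.integer(tapply(ops %in% c("X", "I", "D"), f, sum,
                             default = 0L))
  cols <- as.integer(table(f))
  len <- as.integer(tapply(consume_r, f, sum, default = 0L))
  c_len <- as.integer(tapply(ops != "D", f, sum, default = 0L))
  rate <- edits / pmax(1L, pmin(len, c_len))
  list(error_rate = if (pr$cols > 0) pr$edits / pr$cols else NA_real_,
       windows = data.frame(start = (0:(nwin - 1L)) * window, len = len,
                            edits = edits, cols = cols, rate = rate))
}

#' Error rate of a read against its truth template
#'
#' Edit operations over alignment columns from a blockwise global
#' alignment of the read to its clean template.
#'
#' @inheritParams truth_align_profile
#' @return Fraction in `[0, 1]`.
#' @export
read_error_rate <- function(read, template) {
  truth_align_profile(read, template)$error_rate
}

#' Count high-error windows in a read
#'
#' Number of tiled windows whose truth-aligned error exceeds `cutoff`; a
#' read "has a HERS" iff the count is at least one.
#'
#' @inheritParams truth_align_profile
#' @param cutoff window error cutoff (default 0.5, strict).
#' @return Integer count.
#' @export
hers_windows <- function(read, template, window = 500, cutoff = 0.5) {
  pr <- truth_align_profile(read, template, window)
  sum(pr$windows$rate > cutoff)
}

#' Nx / NGx length statistic
#'
#' The smallest length L such that sequences of length >= L sum to at
#' least `x`% of the total length (Nx), or of `genome_size` (NGx) when a
#' genome size is supplied.  Returns 0 when the total never reaches the
#' target (possible for NGx).
#'
#' @param lengths sequence lengths.
#' @param x percentage (e.g. 50, 75).
#' @param genome_size optional reference size for NGx.
#' @return Length in bases.
#' @export
nx <- function(lengths, x = 50, genome_size = NULL) {
  if (length(lengths) == 0) return(0)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- if (is.null(genome_size)) sum(s) else genome_size
  cum <- cumsum(s)
  i <- which(cum >= x / 100 * total)
  if (length(i) == 0) 0 else s[i[1]]
}

#' Assembly consensus quality value
#'
#' `QV = 10 log10(100000 / (mismatches per 100 kbp + indels per 100
#' kbp))`, reported to one decimal; a perfect assembly (zero errors)
#' returns `Inf`.
#'
#' @param mismatches_per_100kbp,indels_per_100kbp error rates per 100 kbp.
#' @return QV (dimensionless, one decimal).
#' @export
qv <- function(mismatches_per_100kbp, indels_per_100kbp) {
  stopifnot(mismatches_per_100kbp >= 0, indels_per_100kbp >= 0)
  tot <- mismatches_per_100kbp + indels_per_100kbp
  if (tot == 0) return(Inf)
  round(10 * log10(1e5 / tot), 1)
}

#' Percentage of reads below an error cutoff
#'
#' @param error_rates per-read error rates.
#' @param cutoff rate cutoff (default 0.05, strict `<`).
#' @return Percentage in `[0, 100]`.
#' @export
percent_below <- function(error_rates, cutoff = 0.05) {
  if (length(error_rates) == 0) return(NA_real_)
  100 * mean(error_rates < cutoff, na.rm = TRUE)
}

#' Read-set statistics against simulator truth
#'
#' Computes, for a set of (raw or corrected) reads, the mean truth-aligned
#' error rate, the percentage below 5%, N50/N75, and the number of reads
#' containing at least one high-error window.  Corrected fragments named
#' `template/2/start_end` are measured against the matching slice of their
#' template's truth.
#'
#' @param reads named character vector.
#' @param truth truth data.frame with replay plans (from [sample_reads()]).
#' @param window,cutoff HERS window parameters.
#' @return list of scalar statistics plus per-read rates.
#' @export
read_set_stats <- function(reads, truth, window = 500, cutoff = 0.5) {
  plans <- attr(truth, "plans")
  rates <- numeric(length(reads))
  hers <- integer(length(reads))
  for (i in seq_along(reads)) {
    tpl <- template_for_id(names(reads)[i], plans)
    if (is.null(tpl)) { rates[i] <- NA; hers[i] <- NA; next }
    pr <- truth_align_profile(reads[[i]], tpl, window)
    rates[i] <- pr$error_rate
    hers[i] <- sum(pr$windows$rate > cutoff)
  }
  list(n = length(reads), total_bases = sum(nchar(reads)),
       mean_error = mean(rates, na.rm = TRUE),
       pct_below_5 = percent_below(rates),
       n50 = nx(nchar(reads), 50), n75 = nx(nchar(reads), 75),
       reads_with_hers = sum(hers >= 1, na.rm = TRUE),
       rates = rates, hers_windows = hers)
}

# Map a read id (possibly a pass-2 fragment "tpl/2/s_e") to its clean
# template sequence.
template_for_id <- function(id, plans) {
  if (id %in% names(plans)) return(plans[[id]]$template)
  m <- regmatches(id, regexec("^(.*)/2/\\d+_\\d+$", id))[[1]]
  if (length(m) == 2 && m[2] %in% names(plans))
    return(plans[[m[2]]]$template)
  NULL
}

#' Contig accuracy against the truth genome
#'
#' Maps each contig onto the genome (anchor chain plus blockwise
#' alignment, both strands) and reports genome coverage and identity.
#'
#' @param contigs named character vector.
#' @param genome genome sequence (`synthetic_genome` or character).
#' @param circular genome is circular (alignment may wrap).
#' @return list(`coverage` = covered fraction of the genome, `identity` =
#'   error-weighted mean identity, `per_contig` = data.frame).
#' @export
contig_accuracy <- function(contigs, genome, circular = TRUE) {
  g <- as.character(genome)
  G <- nchar(g)
  ref <- if (circular) paste0(g, substr(g, 1, min(G, 100000L))) else g
  rows <- list()
  cov <- data.frame(start = integer(), end = integer())
  for (id in names(contigs)) {
    best <- NULL
    for (strand in c("+", "-")) {
      ctg <- if (strand == "-") revcomp(contigs[[id]]) else contigs[[id]]
      ch <- cpp_anchor_chain(ctg, ref, 15L, 5L, 3000L)
      if (nrow(ch) < 5) next
      mid <- ceiling(nrow(ch) / 2)
      a <- cpp_block_align(ctg, ref, ch[mid, 1], ch[mid, 2], 500L, 250L,
                           0.9, "dist")
      if (is.null(best) || a$cols > best$cols) best <- c(a, strand = strand)
    }
    if (is.null(best)) next
    s <- best$c_start %% G; e <- s + (best$c_end - best$c_start)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = id, strand = best$strand, len = nchar(contigs[[id]]),
      g_start = s, g_end = e, identity = 1 - best$diff, cols = best$cols,
      stringsAsFactors = FALSE)
    cov <- rbind(cov, data.frame(start = s, end = min(e, G)))
    if (e > G) cov <- rbind(cov, data.frame(start = 0L, end = e - G))
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), strand = character(), len = integer(),
               g_start = integer(), g_end = integer(), identity = numeric(),
               cols = numeric())
  u <- union_intervals(cov$start, cov$end, G)
  covered <- sum(u$end - u$start) / G
  ident <- if (nrow(per)) sum(per$identity * per$cols) / sum(per$cols) else
    NA_real_
  list(coverage = covered, identity = ident, per_contig = per)
}

#' Assembly summary statistics
#'
#' @param contigs named character vector.
#' @param genome_size optional reference size for NG50.
#' @return list(`n_seqs`, `total`, `max`, `n50`, `n75`, `ng50`).
#' @export
assembly_stats <- function(contigs, genome_size = NULL) {
  len <- nchar(contigs)
  list(n_seqs = length(contigs), total = sum(len),
       max = if (length(len)) max(len) else 0,
       n50 = nx(len, 50), n75 = nx(len, 75),
       ng50 = if (is.null(genome_size)) NA_real_ else
         nx(len, 50, genome_size))
}
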