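#' Error model for simulated long reads
#'
#' Per-read target error rates are drawn from a Beta distribution rescaled
#' to `[min, max]`.  The defaults reproduce the error structure reported
#' for nanopore data: rates supported on roughly 7--50% with the mode near
#' 14% and mean near 15%.  `comp` fixes the substitution/deletion/insertion
#' composition of the realized errors.
#'
#' The *target* rate is the error rate an aligner should measure when the
#' read is realigned to its template.  Because independently drawn edits
#' partially cancel under optimal alignment, per-base edit events are
#' planted at an inflated rate `e(r) = r (1 + 0.9 r)` (calibrated once
#' against exact edit-distance realignment; see the methods vignette).
#'
#' @param min,max support of the rescaled Beta distribution.
#' @param mean target mean error rate.
#' @param concentration Beta concentration (shape1 + shape2).
#' @param comp named fractions `c(sub =, del =, ins =)` summing to 1.
#' @return An object of class `error_model`.
#' @export
nanopore_error_model <- function(min = 0.07, max = 0.50, mean = 0.15,
                                 concentration = 30,
                                 comp = c(sub = 0.4, del = 0.3, ins = 0.3)) {
  if (!(min <= mean && mean <= max)) stop("need min <= mean <= max")
  mu <- (mean - min) / (max - min)
  structure(list(type = "beta", min = min, max = max, mean = mean,
                 shape1 = mu * concentration,
                 shape2 = (1 - mu) * concentration,
                 comp = comp / sum(comp)),
            class = "error_model")
}

#' Constant-rate error model
#'
#' Every read receives the same target error rate; `rate = 0` yields exact
#' substrings of the genome.
#'
#' @param rate target per-read error rate.
#' @param comp error composition as in [nanopore_error_model()].
#' @return An object of class `error_model`.
#' @export
constant_error_model <- function(rate = 0,
                                 comp = c(sub = 0.4, del = 0.3, ins = 0.3)) {
  structure(list(type = "constant", rate = rate, comp = comp / sum(comp)),
            class = "error_model")
}

draw_error_rates <- function(model, n) {
  if (model$type == "constant") return(rep(model$rate, n))
  r <- model$min + (model$max - model$min) *
    stats::rbeta(n, model$shape1, model$shape2)
  while (any(bad <- r > 0.95))            # degenerate-read guard
    r[bad] <- model$min + (model$max - model$min) *
      stats::rbeta(sum(bad), model$shape1, model$shape2)
  r
}

#' High-error-rate subsequence (HERS) model
#'
#' Controls whether and where simulated reads carry a HERS: one contiguous
#' interval rewritten at a local error rate above 50%.  The probability of
#' carrying a HERS grows with read length: `"logistic"` uses
#' `p_max * plogis((L - midpoint) / scale)` (calibrated so that roughly
#' 3--23% of reads longer than 10 kb carry one); `"constant"` gives every
#' read longer than `min_len` the same probability `prob`; `"none"`
#' disables injection.  HERS intervals span 2--3 detection windows so that
#' at least one full alignment block falls entirely inside the rewritten
#' interval regardless of block phase.
#'
#' @param type `"logistic"`, `"constant"` or `"none"`.
#' @param local_rate target local alignment error rate (> 0.5).
#' @param prob,min_len constant-model probability for reads `> min_len`.
#' @param p_max,midpoint,scale logistic-model parameters (bases).
#' @param length_factor HERS length range in multiples of the detection
#'   window.
#' @param comp composition of HERS errors; insertion-heavy by default, as
#'   spurious basecalls dominate real high-error segments.
#' @return An object of class `hers_model`.
#' @export
hers_model <- function(type = c("logistic", "constant", "none"),
                       local_rate = 0.6, prob = 0.15, min_len = 10000,
                       p_max = 0.3, midpoint = 25000, scale = 8000,
                       length_factor = c(2, 3),
                       comp = c(sub = 0.25, del = 0.15, ins = 0.60)) {
  type <- match.arg(type)
  if (type != "none" && local_rate <= 0.5)
    stop("HERS local_rate must exceed 0.5")
  structure(list(type = type, local_rate = local_rate, prob = prob,
                 min_len = min_len, p_max = p_max, midpoint = midpoint,
                 scale = scale, length_factor = length_factor,
                 comp = comp / sum(comp)),
            class = "hers_model")
}

hers_prob <- function(model, len) {
  switch(model$type,
         none = rep(0, length(len)),
         constant = ifelse(len > model$min_len, model$prob, 0),
         logistic = model$p_max *
           stats::plogis((len - model$midpoint) / model$scale))
}

# Per-base edit events are planted at an inflated rate so the realized
# aligned error matches the target (optimal alignment cancels some edits).
event_rate <- function(target) pmin(0.97, target * (1 + 0.9 * target))

#' Generate a synthetic genome
#'
#' Uniform random DNA, optionally with near-identical repeat copies
#' inserted (a repeat unit is drawn once, then each copy is mutated down to
#' the requested identity and written over a random non-overlapping
#' interval).
#'
#' @param length genome length in bases.
#' @param repeat_spec `NULL` or `list(count =, unit_length =, identity =)`.
#' @param seed integer seed.
#' @return A character scalar of class `synthetic_genome` with attribute
#'   `repeat_features` (data.frame of source/inserted intervals and
#'   identity, 0-based half-open).
#' @export
make_genome <- function(length, repeat_spec = NULL, seed = 1) {
  set.seed(seed)
  feats <- data.frame(src_start = integer(), src_end = integer(),
                      ins_start = integer(), ins_end = integer(),
                      identity = numeric())
  if (!is.null(repeat_spec)) {
    count <- repeat_spec$count; unit <- repeat_spec$unit_length
    ident <- repeat_spec$identity
    if (count * unit * 2 > length)
      stop("repeat spec infeasible: copies exceed half the genome length")
    if (length < 10 * unit)
      stop("genome must be at least 10x the repeat unit length")
  }
  g <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
             collapse = "")
  if (!is.null(repeat_spec) && repeat_spec$count > 0) {
    count <- repeat_spec$count; unit <- repeat_spec$unit_length
    ident <- repeat_spec$identity
    src_start <- sample.int(length - unit, 1) - 1L
    unit_seq <- substr(g, src_start + 1, src_start + unit)
    taken <- list(c(src_start, src_start + unit))
    for (i in seq_len(count)) {
      repeat {
        s <- sample.int(length - unit, 1) - 1L
        ok <- all(vapply(taken, function(iv) s + unit <= iv[1] || s >= iv[2],
                         TRUE))
        if (ok) break
      }
      taken <- c(taken, list(c(s, s + unit)))
      # each copy diverges half the target from the unit, so two copies are
      # pairwise ~(1 - identity) apart
      copy <- if (ident >= 1) unit_seq else
        mutate_seq(unit_seq, event_rate((1 - ident) / 2),
                   c(sub = .4, del = .3, ins = .3))$seq
      copy <- substr(copy, 1, unit)                  # keep coordinates exact
      copy <- paste0(copy, substr(g, s + nchar(copy) + 1, s + unit))
      substr(g, s + 1, s + unit) <- copy
      feats <- rbind(feats, data.frame(
        src_start = src_start, src_end = src_start + unit,
        ins_start = s, ins_end = s + unit, identity = ident))
    }
  }
  structure(g, repeat_features = feats, class = "synthetic_genome")
}

# Apply per-base edit events to a sequence.  `rate` is a scalar or
# per-base vector of event probabilities; returns the mutated sequence,
# the realized edit plan, and the output coordinate of every input base.
mutate_seq <- function(s, rate, comp) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  u <- stats::runif(n)
  cs1 <- rate * comp[["sub"]]
  cs2 <- rate * (comp[["sub"]] + comp[["del"]])
  cs3 <- rate
  sub <- u < cs1
  del <- u >= cs1 & u < cs2
  ins <- u >= cs2 & u < cs3
  out <- ch
  if (any(sub)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3, sum(sub), replace = TRUE)
    out[sub] <- alt[cbind(match(ch[sub], rownames(alt)), pick)]
  }
  out[del] <- ""
  pre <- character(n)
  if (any(ins)) pre[ins] <- sample(c("A", "C", "G", "T"), sum(ins),
                                   replace = TRUE)
  pieces <- paste0(pre, out)
  offs <- cumsum(nchar(pieces))
  plan <- data.frame(
    pos = c(which(sub), which(del), which(ins)) - 1L,
    op = rep(c("S", "D", "I"), c(sum(sub), sum(del), sum(ins))),
    base = c(out[sub], rep(NA_character_, sum(del)), pre[ins]),
    stringsAsFactors = FALSE)
  plan <- plan[order(plan$pos), , drop = FALSE]
  rownames(plan) <- NULL
  list(seq = paste(pieces, collapse = ""), plan = plan,
       out_start = c(0L, offs[-n]))
}

#' Replay a recorded edit plan
#'
#' Deterministically re-applies the edit plan stored by the simulator to a
#' clean template, reproducing the emitted read byte for byte (the
#' conservation contract of the simulator).
#'
#' @param template clean template sequence (the oriented genome interval).
#' @param plan data.frame with columns `pos` (0-based template position),
#'   `op` (`"S"`, `"D"`, `"I"`) and `base`.
#' @return The corrupted sequence.
#' @export
apply_edit_plan <- function(template, plan) {
  ch <- strsplit(template, "")[[1]]
  pre <- character(length(ch))
  if (nrow(plan)) {
    s <- plan$op == "S"; d <- plan$op == "D"; i <- plan$op == "I"
    ch[plan$pos[s] + 1L] <- plan$base[s]
    ch[plan$pos[d] + 1L] <- ""
    pre[plan$pos[i] + 1L] <- plan$base[i]
  }
  paste(paste0(pre, ch), collapse = "")
}

#' Simulate nanopore-style reads with ground truth
#'
#' Draws reads of log-normal length uniformly in position and strand until
#' the requested coverage is reached, corrupts each read according to a
#' per-read error rate drawn from `error_model`, and injects a high-error
#' subsequence (HERS) with a probability that follows `hers_model`.  The
#' genome is treated as circular by default (reads may wrap), which keeps
#' coverage uniform; set `circular = FALSE` for strict substrings.
#'
#' @param genome a `synthetic_genome` or plain character scalar.
#' @param coverage fold coverage to target (total read bases within 5% of
#'   `coverage * genome length`).
#' @param length_model `list(mean =, min =, max =)` read-length model in
#'   bases (log-normal, truncated).
#' @param error_model see [nanopore_error_model()].
#' @param hers_model see [hers_model()].
#' @param seed integer seed.
#' @param circular sample across the origin (default `TRUE`).
#' @return `list(reads =, truth =)`: reads is a named character vector;
#'   truth is a data.frame (`read_id`, `start`, `end`, `strand`,
#'   `planned_error`, `hers_intervals`) with one row per read, 0-based
#'   half-open genome coordinates, plus attribute `plans` holding each
#'   read's realized edit plan and oriented template.
#' @export
sample_reads <- function(genome, coverage,
                         length_model = list(mean = 12000, min = 3000,
                                             max = 60000),
                         error_model = nanopore_error_model(),
                         hers_model = lorasm::hers_model(),
                         seed = 1, circular = TRUE) {
  stopifnot(coverage > 0,
            length_model$min <= length_model$mean,
            length_model$mean <= length_model$max)
  set.seed(seed)
  g <- as.character(genome)
  G <- nchar(g)
  g2 <- paste0(g, substr(g, 1, min(G, length_model$max + 1L)))
  sdlog <- 0.45
  meanlog <- log(length_model$mean) - sdlog^2 / 2
  target <- coverage * G
  lens <- integer(0); total <- 0
  while (total < target) {
    l <- as.integer(round(stats::rlnorm(64, meanlog, sdlog)))
    l <- l[l >= length_model$min & l <= length_model$max & l <= G]
    lens <- c(lens, l); total <- sum(lens)
  }
  lens <- lens[cumsum(lens) - lens < target]
  n <- length(lens)
  ids <- sprintf("read%05d", seq_len(n))
  starts <- if (circular) sample.int(G, n, replace = TRUE) - 1L else
    vapply(lens, function(l) sample.int(G - l + 1L, 1) - 1L, 1L)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rates <- draw_error_rates(error_model, n)
  p_hers <- hers_prob(hers_model, lens)
  has_hers <- stats::runif(n) < p_hers
  window <- 500
  reads <- character(n)
  hers_col <- character(n)
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- substr(g2, starts[i] + 1L, starts[i] + lens[i])
    if (strands[i] == "-") tpl <- revcomp(tpl)
    rate_vec <- rep(event_rate(rates[i]), lens[i])
    comp <- error_model$comp
    hrec <- NULL
    if (has_hers[i] && lens[i] > 2 * window + 400) {
      hl <- as.integer(round(stats::runif(
        1, hers_model$length_factor[1] * window,
        hers_model$length_factor[2] * window)))
      hl <- min(hl, lens[i] - 400L)
      hs <- sample.int(lens[i] - hl - 200L, 1) + 100L   # template coords
      hrec <- c(hs, hs + hl)
    }
    if (!is.null(hrec)) {
      # HERS events use their own, insertion-heavy composition; realize the
      # two regimes in a single pass with a blended per-base rate, using the
      # HERS composition only inside the interval
      m_fl <- mutate_seq(substr(tpl, 1, hrec[1]),
                         rep(event_rate(rates[i]), hrec[1]), comp)
      m_h <- mutate_seq(substr(tpl, hrec[1] + 1, hrec[2]),
                        event_rate(hers_model$local_rate), hers_model$comp)
      m_fr <- mutate_seq(substr(tpl, hrec[2] + 1, lens[i]),
                         rep(event_rate(rates[i]), lens[i] - hrec[2]), comp)
      reads[i] <- paste0(m_fl$seq, m_h$seq, m_fr$seq)
      plan <- rbind(m_fl$plan,
                    transform(m_h$plan, pos = pos + hrec[1]),
                    transform(m_fr$plan, pos = pos + hrec[2]))
      hs_read <- nchar(m_fl$seq)
      he_read <- hs_read + nchar(m_h$seq)
      hers_col[i] <- sprintf("%d-%d@%.2f", hs_read, he_read,
                             hers_model$local_rate)
      plans[[i]] <- list(template = tpl, plan = plan,
                         hers_template = hrec)
    } else {
      m <- mutate_seq(tpl, rate_vec, comp)
      reads[i] <- m$seq
      hers_col[i] <- ""
      plans[[i]] <- list(template = tpl, plan = m$plan,
                         hers_template = NULL)
    }
  }
  truth <- data.frame(read_id = ids, start = starts,
                      end = starts + lens, strand = strands,
                      planned_error = rates, hers_intervals = hers_col,
                      stringsAsFactors = FALSE)
  names(plans) <- ids
  attr(truth, "plans") <- plans
  attr(truth, "genome_length") <- G
  attr(truth, "circular") <- circular
  list(reads = stats::setNames(reads, ids), truth = truth)
}

#' Inject a high-error subsequence into an existing read
#'
#' Rewrites one contiguous interval of at least `window` bases at the given
#' local target error rate and records the interval in the truth row.
#' Reads shorter than the window are returned unchanged with a warning.
#'
#' @param read character scalar.
#' @param truth a one-row truth data.frame for this read (or `NULL`).
#' @param window minimum rewritten length (bases).
#' @param local_rate target local error rate (> 0.5).
#' @param seed integer seed.
#' @return `list(read =, truth =)` with the mutated sequence and updated
#'   `hers_intervals`.
#' @export
inject_hers <- function(read, truth = NULL, window = 500, local_rate = 0.6,
                        seed = 1) {
  if (local_rate <= 0.5) stop("HERS local_rate must exceed 0.5")
  n <- nchar(read)
  if (n < window) {
    warning("read shorter than the HERS window; returning it unchanged")
    return(list(read = read, truth = truth))
  }
  set.seed(seed)
  hl <- min(n, as.integer(round(stats::runif(1, 2 * window, 3 * window))))
  hs <- if (n - hl > 0) sample.int(n - hl, 1) else 0L   # 0-based
  hm <- hers_model(local_rate = local_rate)
  m <- mutate_seq(substr(read, hs + 1, hs + hl),
                  event_rate(local_rate), hm$comp)
  out <- paste0(substr(read, 1, hs), m$seq, substr(read, hs + hl + 1, n))
  iv <- sprintf("%d-%d@%.2f", hs, hs + nchar(m$seq), local_rate)
  if (!is.null(truth)) {
    old <- truth$hers_intervals[1]
    truth$hers_intervals[1] <- if (nzchar(old)) paste(old, iv, sep = ";")
      else iv
  }
  list(read = out, truth = truth)
}

#' Write simulated truth to TSV
#'
#' @param truth truth data.frame from [sample_reads()].
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth TSV
#'
#' @param path file written by [write_truth()].
#' @return Truth data.frame (without replay plans).
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character",
                                   hers_intervals = "character"))
}

# Oriented clean template for a read (the sequence its errors were applied
# to): genome interval, reverse-complemented for minus-strand reads.
truth_template <- function(truth_row, genome) {
  g <- as.character(genome)
  G <- nchar(g)
  s <- truth_row$start; e <- truth_row$end
  tpl <- if (e <= G) substr(g, s + 1, e) else
    paste0(substr(g, s + 1, G), substr(g, 1, e - G))
  if (truth_row$strand == "-") revcomp(tpl) else tpl
}
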