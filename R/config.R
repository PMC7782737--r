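#' Pipeline configuration
#'
#' Builds the configuration object used by every stage of the pipeline.
#' All thresholds can be overridden; the defaults encode the method's
#' standard constants (global overlapping-error-rate threshold 0.5, 50
#' top-scoring candidates for threshold estimation, at most 200 aligned
#' candidates, coverage-count-array gate C = 12, 500 bp alignment blocks
#' and error windows, 90% identity for trimming overlaps, the longest 40X
#' of corrected reads for assembly, and a 1000 bp gap-length clustering
#' window for contig bridging).  Constants the method leaves unstated
#' (k-mer size and stride, coverage filter triple, graph-cleaning limits)
#' are package defaults, documented here and in the methods vignette.
#'
#' @param global_error_threshold global overlapping-error-rate threshold
#'   applied to every support alignment (fraction in `[0, 1]`).
#' @param top_candidates_for_threshold number of top-DDF candidates aligned
#'   to estimate the individual threshold.
#' @param max_aligned_candidates cap on candidates considered per template.
#' @param cca_threshold gate `C` for the coverage count array: once every
#'   base of a candidate's mapped template interval is covered by more than
#'   `C` accepted supports, its alignment is skipped.
#' @param block_size alignment block length in bases (also the error-window
#'   length used for high-error-rate subsequence detection).
#' @param block_slack_frac band slack per block, as a fraction of
#'   `block_size`.
#' @param hers_window,hers_error_cutoff window length and error cutoff
#'   defining a high-error-rate subsequence (HERS).
#' @param span_frac minimum fraction of template or candidate length an
#'   alignment must span to be recorded for threshold estimation.
#' @param threshold_sd_normalized if `TRUE` (default) the spread `D` of the
#'   individual threshold is the population standard deviation
#'   `sqrt(sum((d_i - d0)^2) / n)`; if `FALSE` the unnormalised
#'   `sqrt(sum((d_i - d0)^2))` is used instead.
#' @param threshold_formula `"plus"` (default; the individual threshold is
#'   the quality lower bound `difference <= d0 + 5 D`) or `"minus"` (the
#'   literal error-space subtraction `d0 - 5 D`; see
#'   [threshold_from_differences()]).
#' @param consensus_min_coverage minimum support count for a template
#'   position to be eligible for consensus correction.
#' @param max_supports cap on recorded supports per template; once this
#'   many supports passed the threshold no further candidate is aligned
#'   (a dozen supports already saturate the consensus).
#' @param trim_identity minimum overlap identity (strictly greater than)
#'   for an overlap to contribute trimming coverage.
#' @param trim_coverage_target fold coverage of longest corrected reads kept
#'   for trimming and assembly.
#' @param min_read_length minimum raw read length retained by preprocessing.
#' @param min_coverage,max_coverage,max_diff_coverage per-read overlap
#'   coverage filter: reads with `c_min < min_coverage`, or
#'   `c_max > max_coverage`, or `c_max - c_min > max_diff_coverage` are
#'   dropped with their overlaps.
#' @param global_identity,global_overhang global floors for overlap identity
#'   and overhang filtering during assembly.
#' @param identity_alpha multiplier on the per-read identity standard
#'   deviation for the local (adaptive) identity cutoff.
#' @param min_overlap_length minimum alignment columns for an assembly
#'   overlap.
#' @param graph_fuzz length tolerance (bases) for transitive reduction.
#' @param tip_length,bubble_length maximum path length (in reads) removed as
#'   a tip / collapsed as a bubble branch.
#' @param spur_frac an edge whose overlap length is below this fraction of
#'   the best edge at a node is a spurious link.
#' @param bridge_cluster_window gap/overlap-length clustering window (bases)
#'   for contig bridging.
#' @param bridge_end_window a contig hit counts as an end hit if it is
#'   within this many bases of a contig terminus (or the read extends past
#'   the terminus).
#' @param kmer_size,kmer_stride,kmer_max_occ k-mer index parameters:
#'   k, sampling stride, and the occupancy cutoff above which repeat k-mers
#'   are masked.
#' @param ddf_epsilon distance-difference tolerance (bases) for DDF scoring.
#' @param min_chain minimum co-linear chain size to report a candidate hit.
#' @param rng_seed integer seed for every stochastic step.
#' @return An object of class `lorasm_config` (a named list).
#' @export
pipeline_config <- function(global_error_threshold = 0.5,
                            top_candidates_for_threshold = 50,
                            max_aligned_candidates = 200,
                            cca_threshold = 12,
                            block_size = 500,
                            block_slack_frac = 0.5,
                            hers_window = 500,
                            hers_error_cutoff = 0.5,
                            span_frac = 0.6,
                            threshold_sd_normalized = TRUE,
                            threshold_formula = "plus",
                            consensus_min_coverage = 4,
                            max_supports = 20,
                            trim_identity = 0.90,
                            trim_coverage_target = 40,
                            min_read_length = 1000,
                            min_coverage = 2,
                            max_coverage = 200,
                            max_diff_coverage = 150,
                            global_identity = 0.90,
                            global_overhang = 500,
                            identity_alpha = 2,
                            min_overlap_length = 2000,
                            graph_fuzz = 500,
                            tip_length = 3,
                            bubble_length = 5,
                            spur_frac = 0.25,
                            bridge_cluster_window = 1000,
                            bridge_end_window = 2000,
                            kmer_size = 13,
                            kmer_stride = 5,
                            kmer_max_occ = 500,
                            ddf_epsilon = 32,
                            min_chain = 3,
                            rng_seed = 1) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "lorasm_config")
}

validate_config <- function(cfg) {
  fracs <- c("global_error_threshold", "hers_error_cutoff", "span_frac",
             "trim_identity", "global_identity", "block_slack_frac",
             "spur_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("config field '", f, "' must be a fraction in [0, 1]")
  }
  counts <- c("top_candidates_for_threshold", "max_aligned_candidates",
              "cca_threshold", "block_size", "hers_window",
              "consensus_min_coverage", "trim_coverage_target",
              "min_read_length", "min_coverage", "max_coverage",
              "max_diff_coverage", "global_overhang", "min_overlap_length",
              "graph_fuzz", "tip_length", "bubble_length",
              "bridge_cluster_window", "bridge_end_window", "kmer_size",
              "kmer_stride", "kmer_max_occ", "ddf_epsilon", "min_chain")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("config field '", f, "' must be a non-negative number")
  }
  if (cfg$kmer_size < 8 || cfg$kmer_size > 21)
    stop("kmer_size must be in [8, 21]")
  invisible(TRUE)
}

#' Read a configuration file
#'
#' Parses a flat `key: value` file (YAML-style scalars only; `#` starts a
#' comment).  Unknown keys are an error so typos do not silently fall back
#' to defaults.
#'
#' @param path file to read.
#' @param base configuration the file overrides (default
#'   [pipeline_config()]).
#' @return A `lorasm_config` object.
#' @export
read_config <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(base)) stop("unknown config key: '", key, "'")
    base[[key]] <- if (val %in% c("TRUE", "true", "FALSE", "false")) {
      as.logical(toupper(val))
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }
  }
  validate_config(base)
  structure(base, class = "lorasm_config")
}

#' Write a configuration file
#'
#' @param cfg a `lorasm_config` object.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste0(names(cfg), ": ", vapply(cfg, format, "")), path)
  invisible(path)
}

#' @export
print.lorasm_config <- function(x, ...) {
  cat("<lorasm_config>\n")
  for (n in names(x)) cat(sprintf("  %-30s %s\n", n, format(x[[n]])))
  invisible(x)
}

block_slack <- function(cfg) as.integer(round(cfg$block_size * cfg$block_slack_frac))
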