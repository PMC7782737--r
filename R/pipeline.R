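#' Run the full pipeline
#'
#' Preprocesses raw reads, corrects them in two progressive passes, trims
#' the corrected reads, assembles string-graph contigs, and bridges the
#' contigs with the raw reads.  Every stage writes its artifacts under
#' `out_dir` and can also be run independently through the `stage_*`
#' functions.  The run is a pure function of (input reads, config): a rerun
#' with the same inputs produces identical outputs.
#'
#' @param raw path to a raw-read FASTA/FASTQ, or a named character vector.
#' @param out_dir output directory (created if missing).
#' @param cfg a [pipeline_config()].
#' @param genome_size genome size estimate in bases (defaults to total
#'   read bases / trim coverage target).
#' @return list with the final contigs and per-stage results (invisibly
#'   also written to `out_dir`).
#' @export
run_pipeline <- function(raw, out_dir, cfg = pipeline_config(),
                         genome_size = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- stage_logger(file.path(out_dir, "pipeline.log"))
  reads <- if (is.character(raw) && length(raw) == 1 && file.exists(raw))
    read_sequences(raw) else raw
  if (is.null(names(reads)) || length(reads) == 0)
    stop("pipeline stage 'input' failed: no named reads")
  set.seed(cfg$rng_seed)
  pre <- preprocess(reads, cfg$min_read_length)
  log("preprocess", sprintf("%d/%d reads kept", length(pre), length(reads)))
  if (is.null(genome_size))
    genome_size <- round(sum(nchar(pre)) / cfg$trim_coverage_target)

  p1 <- correct_pass1(pre, cfg)
  write_sequences(p1$reads, file.path(out_dir, "pass1.fasta"))
  write_template_stats(p1$stats, file.path(out_dir, "pass1_stats.tsv"))
  log("correct_pass1", sprintf("%d reads, %d uncorrectable",
                               length(p1$reads),
                               sum(p1$stats$uncorrectable, na.rm = TRUE)))

  p2 <- correct_pass2(p1$reads, cfg)
  write_sequences(p2$reads, file.path(out_dir, "pass2.fasta"))
  write_template_stats(p2$stats, file.path(out_dir, "pass2_stats.tsv"))
  log("correct_pass2", sprintf("%d fragments from %d templates",
                               length(p2$reads), length(p1$reads)))

  tr <- trim_reads(p2$reads, genome_size, cfg)
  write_sequences(trimmed_with_headers(tr),
                  file.path(out_dir, "trimmed.fasta"))
  write_paf(tr$overlaps, tr$reads, file.path(out_dir, "overlaps.paf"))
  write_overlaps_tsv(tr$overlaps, file.path(out_dir, "overlaps.tsv"))
  log("trim", sprintf("%d reads (%d trimmed), %d overlaps",
                      length(tr$reads), sum(tr$info$kind == "trimmed"),
                      nrow(tr$overlaps)))

  asm <- assemble_contigs(tr$reads, tr$overlaps, cfg)
  write_sequences(asm$contigs, file.path(out_dir, "contigs_prebridge.fasta"))
  write_gfa(asm$graph, asm$reads, file.path(out_dir, "string_graph.gfa"))
  write_layout_tsv(asm$layout, file.path(out_dir, "contigs_layout.tsv"))
  log("assemble", sprintf("%d contigs, graph edges %s", length(asm$contigs),
                          paste(names(asm$stages), asm$stages,
                                sep = "=", collapse = " ")))

  br <- bridge_contigs(asm$contigs, pre, cfg)
  write_sequences(br$contigs, file.path(out_dir, "contigs_final.fasta"))
  write_gfa(bridge_graph(asm$contigs, br$links), asm$contigs,
            file.path(out_dir, "bridge_graph.gfa"))
  if (nrow(br$links) > 0)
    utils::write.table(br$links, file.path(out_dir, "bridge_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  log("bridge", sprintf("%d -> %d contigs via %d links",
                        length(asm$contigs), length(br$contigs),
                        nrow(br$links)))

  stats <- list(
    pre_bridge = assembly_stats(asm$contigs, genome_size),
    final = assembly_stats(br$contigs, genome_size),
    genome_size = genome_size)
  jsonlite::write_json(stats, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reads = pre, pass1 = p1, pass2 = p2, trim = tr,
                 assembly = asm, bridge = br, stats = stats))
}

trimmed_with_headers <- function(tr) {
  ids <- names(tr$reads)
  kind <- tr$info$kind[match(ids, tr$info$id)]
  stats::setNames(tr$reads, paste0(ids, " kind=", kind))
}

stage_logger <- function(path) {
  t0 <- Sys.time()
  function(stage, msg) {
    line <- sprintf("[%s] %-14s %s (elapsed %.1fs)",
                    format(Sys.time(), "%H:%M:%S"), stage, msg,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")))
    cat(line, "\n", file = path, append = TRUE)
    message(line)
  }
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires missing artifact: ", path,
         call. = FALSE)
  path
}

#' Individual pipeline stages
#'
#' Each stage reads the artifacts of the previous one from `out_dir` and
#' writes its own; a missing upstream artifact is an error naming the
#' file.
#'
#' @param out_dir pipeline output directory.
#' @param raw raw reads path (stages that need them).
#' @param cfg a [pipeline_config()].
#' @param genome_size genome size in bases (see [run_pipeline()]).
#' @name stages
NULL

#' @rdname stages
#' @export
stage_correct <- function(raw, out_dir, cfg = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_sequences(require_artifact(raw, "correct"))
  set.seed(cfg$rng_seed)
  pre <- preprocess(reads, cfg$min_read_length)
  p1 <- correct_pass1(pre, cfg)
  write_sequences(p1$reads, file.path(out_dir, "pass1.fasta"))
  write_template_stats(p1$stats, file.path(out_dir, "pass1_stats.tsv"))
  p2 <- correct_pass2(p1$reads, cfg)
  write_sequences(p2$reads, file.path(out_dir, "pass2.fasta"))
  write_template_stats(p2$stats, file.path(out_dir, "pass2_stats.tsv"))
  invisible(p2)
}

#' @rdname stages
#' @export
stage_trim <- function(out_dir, cfg = pipeline_config(),
                       genome_size = NULL) {
  p2 <- read_sequences(require_artifact(file.path(out_dir, "pass2.fasta"),
                                        "trim"))
  if (is.null(genome_size))
    genome_size <- round(sum(nchar(p2)) / cfg$trim_coverage_target)
  tr <- trim_reads(p2, genome_size, cfg)
  write_sequences(trimmed_with_headers(tr),
                  file.path(out_dir, "trimmed.fasta"))
  write_paf(tr$overlaps, tr$reads, file.path(out_dir, "overlaps.paf"))
  write_overlaps_tsv(tr$overlaps, file.path(out_dir, "overlaps.tsv"))
  invisible(tr)
}

write_overlaps_tsv <- function(overlaps, path) {
  utils::write.table(overlaps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_overlaps_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(a = "character", b = "character",
                                   strand = "character"))
}

#' @rdname stages
#' @export
stage_assemble <- function(out_dir, cfg = pipeline_config()) {
  reads <- read_sequences(require_artifact(
    file.path(out_dir, "trimmed.fasta"), "assemble"))
  names(reads) <- sub("\\s.*$", "", names(reads))
  overlaps <- read_overlaps_tsv(require_artifact(
    file.path(out_dir, "overlaps.tsv"), "assemble"))
  asm <- assemble_contigs(reads, overlaps, cfg)
  write_sequences(asm$contigs, file.path(out_dir, "contigs_prebridge.fasta"))
  write_gfa(asm$graph, asm$reads, file.path(out_dir, "string_graph.gfa"))
  invisible(asm)
}

#' @rdname stages
#' @export
stage_bridge <- function(raw, out_dir, cfg = pipeline_config()) {
  contigs <- read_sequences(require_artifact(
    file.path(out_dir, "contigs_prebridge.fasta"), "bridge"))
  reads <- read_sequences(require_artifact(raw, "bridge"))
  reads <- preprocess(reads, cfg$min_read_length)
  br <- bridge_contigs(contigs, reads, cfg)
  write_sequences(br$contigs, file.path(out_dir, "contigs_final.fasta"))
  invisible(br)
}
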