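#' Read sequences from FASTA/FASTQ
#'
#' Reads a FASTA or FASTQ file into a named character vector of uppercase
#' sequences (one element per record, names are record ids, order
#' preserved).
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`; default guesses from the file
#'   extension (`.fq`/`.fastq` mean FASTQ).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate read id in ", path, ": ",
         ids[duplicated(ids)][1])
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param reads named character vector of sequences.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`; FASTQ records get constant dummy
#'   qualities (`"I"`).
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (format == "fasta") {
    out <- character(2L * length(reads))
    out[c(TRUE, FALSE)] <- paste0(">", names(reads))
    out[c(FALSE, TRUE)] <- unname(reads)
  } else {
    out <- character(4L * length(reads))
    out[seq(1, length(out), by = 4)] <- paste0("@", names(reads))
    out[seq(2, length(out), by = 4)] <- unname(reads)
    out[seq(3, length(out), by = 4)] <- "+"
    out[seq(4, length(out), by = 4)] <-
      vapply(nchar(reads), function(n) strrep("I", n), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Preprocess raw reads
#'
#' Drops reads shorter than `min_len` and maps ambiguity codes (N and other
#' IUPAC letters) to `"A"` deterministically, so downstream coordinates stay
#' stable while the read set becomes strictly ACGT.
#'
#' @param reads named character vector.
#' @param min_len minimum retained length in bases.
#' @return Filtered and normalized named character vector.
#' @export
preprocess <- function(reads, min_len = 1000) {
  if (min_len < 1) stop("min_len must be >= 1")
  if (length(reads) == 0) return(reads)
  keep <- nchar(reads) >= min_len
  dropped <- sum(!keep)
  out <- reads[keep]
  out <- chartr_ambiguity(out)
  if (length(out) == 0)
    warning("preprocessing removed every read (min_len = ", min_len, ")")
  if (dropped > 0)
    message("preprocess: removed ", dropped, " read(s) shorter than ",
            min_len, " bp")
  out
}

chartr_ambiguity <- function(x) {
  bad <- "NRYSWKMBDHVnryswkmbdhv"
  chartr(paste0(bad, "acgt"),
         paste0(strrep("A", nchar(bad)), "ACGT"), x)
}

revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "", USE.NAMES = FALSE)
}

#' Export candidate hits or overlaps as PAF
#'
#' Writes 12-column PAF.  Candidate hits (approximate, from k-mer chaining)
#' carry the chain size as a `cm:i:` tag; alignment-backed overlap records
#' carry the alignment difference as a `df:f:` tag.
#'
#' @param x a hits or overlaps data.frame (see [find_candidates()],
#'   [compute_overlaps()]).
#' @param reads named character vector the records refer to.
#' @param path output file.
#' @param targets optional second read set (for read-versus-contig
#'   records); defaults to `reads`.
#' @export
write_paf <- function(x, reads, path, targets = reads) {
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  qlen <- nchar(reads)[x$a]
  tlen <- nchar(targets)[x$b]
  # coordinates are stored on the oriented b; PAF wants forward-strand target
  bs <- ifelse(x$strand == "+", x$b_start, tlen - x$b_end)
  be <- ifelse(x$strand == "+", x$b_end, tlen - x$b_start)
  nmatch <- if ("identity" %in% names(x))
    as.integer(round(x$identity * x$cols)) else x$score
  alen <- if ("cols" %in% names(x)) x$cols else (x$a_end - x$a_start)
  tag <- if ("identity" %in% names(x))
    sprintf("df:f:%.4f", 1 - x$identity) else sprintf("cm:i:%d", x$score)
  lines <- paste(x$a, qlen, x$a_start, x$a_end, x$strand,
                 x$b, tlen, bs, be, nmatch, alen, 255L, tag, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export a string graph as GFA 1.0
#'
#' Segments are reads (or contigs); links are the graph's directed edges
#' with their overlap length as a CIGAR `<n>M` approximation.
#'
#' @param g a `string_graph` object.
#' @param reads named character vector of node sequences.
#' @param path output file.
#' @param write_sequences include sequences in S lines (default `FALSE`
#'   writes `*`).
#' @export
write_gfa <- function(g, reads, path, write_sequences = FALSE) {
  used <- unique(sub(":[+-]$", "", c(g$edges$from, g$edges$to, g$nodes)))
  used <- intersect(names(reads), used)
  slines <- paste("S", used,
                  if (write_sequences) unname(reads[used]) else "*",
                  paste0("LN:i:", nchar(reads[used])), sep = "\t")
  llines <- character(0)
  if (nrow(g$edges) > 0) {
    f <- node_split(g$edges$from); t <- node_split(g$edges$to)
    llines <- paste("L", f$read, f$orient, t$read, t$orient,
                    paste0(pmax(0, g$edges$ovl_len), "M"), sep = "\t")
  }
  writeLines(c("H\tVN:Z:1.0", slines, llines), path)
  invisible(path)
}

node_id <- function(read, orient) paste0(read, ":", orient)
node_split <- function(x) {
  n <- nchar(x)
  list(read = substr(x, 1, n - 2), orient = substr(x, n, n))
}
node_flip <- function(x) {
  n <- nchar(x)
  paste0(substr(x, 1, n - 2), ":", ifelse(substr(x, n, n) == "+", "-", "+"))
}
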