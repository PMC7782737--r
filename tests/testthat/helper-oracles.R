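# Shared fixtures and independent oracles used across test files.

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

rc_seq <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# independent mutator (subs/dels/ins at the given per-base event rate);
# deliberately separate from the package's own edit-plan machinery
mut_seq <- function(s, p, comp = c(.4, .3, .3)) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  u <- runif(n)
  cs <- cumsum(comp) * p
  sub <- u < cs[1]
  del <- u >= cs[1] & u < cs[2]
  ins <- u >= cs[2] & u < cs[3]
  out <- ch
  out[sub] <- vapply(out[sub], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  out[del] <- ""
  pre <- character(n)
  pre[ins] <- sample(c("A", "C", "G", "T"), sum(ins), TRUE)
  paste(paste0(pre, out), collapse = "")
}

# brute-force longest co-linear subset (strictly increasing in both
# coordinates), O(n^2) DP
lis_oracle <- function(t_pos, c_pos) {
  n <- length(t_pos)
  if (n == 0) return(0L)
  f <- rep(1L, n)
  ord <- order(t_pos, c_pos)
  t_pos <- t_pos[ord]; c_pos <- c_pos[ord]
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (t_pos[j] < t_pos[i] && c_pos[j] < c_pos[i] && f[j] + 1L > f[i])
        f[i] <- f[j] + 1L
    }
  }
  max(f)
}

# brute-force transitive reduction: drop every edge implied by a 2-path
# within the length tolerance
transitive_oracle <- function(edges, fuzz) {
  drop <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    v <- edges$from[k]; x <- edges$to[k]
    thr <- edges$ext_len[k]
    mid <- edges[edges$from == v & edges$to != x, , drop = FALSE]
    for (j in seq_len(nrow(mid))) {
      w <- mid$to[j]
      sec <- edges[edges$from == w & edges$to == x, , drop = FALSE]
      if (nrow(sec) && any(abs(thr - (mid$ext_len[j] + sec$ext_len)) <= fuzz))
        drop[k] <- TRUE
    }
  }
  edges[!drop, , drop = FALSE]
}

# transitive closure of |gap_i - gap_j| < window, as a partition
closure_clusters <- function(gaps, window) {
  n <- length(gaps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(gaps[i] - gaps[j]) < window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(gaps, roots))
}

# per-base coverage bitmap union oracle
bitmap_union <- function(start, end, len) {
  hit <- logical(len)
  for (i in seq_along(start)) {
    s <- max(0L, start[i]); e <- min(len, end[i])
    if (e > s) hit[(s + 1L):e] <- TRUE
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# a tiny cached clean-pipeline world shared across test files
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(42)
    g <- make_genome(60000, seed = 2)
    sim <- sample_reads(
      g, coverage = 25,
      length_model = list(mean = 8000, min = 3000, max = 20000),
      error_model = nanopore_error_model(mean = 0.12),
      hers_model = hers_model("none"), seed = 3)
    cache <<- list(genome = g, reads = sim$reads, truth = sim$truth)
    cache
  }
})
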