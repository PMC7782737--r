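test_that("k-mer index stores expected postings and canonical symmetry", {
  idx <- kmer_index(c(r1 = "ACGTACGTACGT"), k = 4, stride = 1, max_occ = 0)
  df <- index_lookup(idx, "ACGT")
  expect_setequal(df$pos[df$strand == "+"], c(0, 4, 8))

  s <- rnd_seq(300)
  idx2 <- kmer_index(c(f = s, r = rc_seq(s)), k = 13, stride = 1,
                     max_occ = 0)
  km <- substr(s, 101, 113)
  df2 <- index_lookup(idx2, km)
  expect_setequal(df2$read, c("f", "r"))
  expect_length(unique(df2$strand[match(c("f", "r"), df2$read)]), 2)
})

test_that("index postings re-extract correctly from their reads", {
  set.seed(21)
  reads <- setNames(replicate(30, rnd_seq(sample(200:500, 1))),
                    paste0("r", 1:30))
  idx <- kmer_index(reads, k = 11, stride = 3, max_occ = 0)
  # re-check a sample of k-mers through the lookup API
  for (id in sample(names(reads), 10)) {
    pos <- sample(0:(nchar(reads[[id]]) - 11), 1)
    pos <- pos - pos %% 3                     # a sampled offset
    km <- substr(reads[[id]], pos + 1, pos + 11)
    df <- index_lookup(idx, km)
    hit <- df[df$read == id & df$pos == pos, ]
    expect_equal(nrow(hit), 1)
    canon_fwd <- hit$strand == "+"
    got <- substr(reads[[id]], hit$pos + 1, hit$pos + 11)
    expect_identical(got, if (canon_fwd || km == rc_seq(km)) km else km)
  }
})

test_that("identical reads chain across their whole length", {
  set.seed(22)
  s <- rnd_seq(5000)
  h <- ddf_seed_and_chain(s, s, return_chain = TRUE)
  expect_identical(h$strand, "+")
  expect_gte((h$t_end - h$t_start) / 5000, 0.9)
  expect_gte((h$c_end - h$c_start) / 5000, 0.9)
  ch <- attr(h, "chain")
  expect_true(all(diff(ch$tpos) > 0) && all(diff(ch$cpos) > 0))
  # no shared k-mers: NULL
  expect_null(ddf_seed_and_chain(rnd_seq(500), rnd_seq(500)))
})

test_that("chaining matches the brute-force longest co-linear subset", {
  set.seed(23)
  for (rep in 1:40) {
    n_true <- sample(8:20, 1)
    base <- sort(sample(0:4000, n_true))
    t_pos <- base
    c_pos <- base + sample(-10:10, n_true, TRUE)     # near-diagonal
    n_out <- sample(0:3, 1)
    t_all <- c(t_pos, sample(0:4000, n_out))
    c_all <- c(c_pos, sample(4000:8000, n_out))      # off-diagonal outliers
    sup <- data.frame(t = t_all, c = c_all)
    chain <- lorasm:::cpp_lis_chain(sup$t, sup$c)
    expect_equal(chain, lis_oracle(sup$t, sup$c))
  }
})

test_that("minus-strand hits report oriented coordinates consistently", {
  set.seed(24)
  g <- rnd_seq(9000)
  a <- substr(g, 1, 6000)
  b <- rc_seq(substr(g, 3001, 9000))
  h <- ddf_seed_and_chain(a, b)
  expect_identical(h$strand, "-")
  # oriented candidate = revcomp(b) = substr(g, 3001, 9000): overlap region
  # is its first 3000 bases and a's last 3000
  expect_gt(h$t_start, 2500)
  expect_lt(h$c_start, 500)
})

test_that("top_candidates sorts, tie-breaks and truncates like a plain sort", {
  set.seed(25)
  hits <- data.frame(
    cand = sprintf("c%03d", 1:300),
    strand = "+",
    score = sample(1:50, 300, TRUE),
    t_start = 0L, t_end = sample(1000:9000, 300, TRUE),
    c_start = 0L, c_end = 0L, seed_t = 0L, seed_c = 0L,
    stringsAsFactors = FALSE)
  out <- top_candidates(hits, 200)
  ord <- order(-hits$score, -(hits$t_end - hits$t_start), hits$cand)
  expect_identical(out$cand, hits$cand[ord][1:200])
  # ties on score and span break by candidate id
  tie <- data.frame(cand = c("b", "a", "c"), strand = "+",
                    score = c(9, 9, 3), t_start = 0L, t_end = 100L,
                    c_start = 0L, c_end = 0L, seed_t = 0L, seed_c = 0L,
                    stringsAsFactors = FALSE)
  expect_identical(top_candidates(tie, 3)$cand, c("a", "b", "c"))
  expect_equal(nrow(top_candidates(hits[1:5, ], 200)), 5)
})

test_that("zero-error overlapping pairs are detected symmetrically", {
  g <- make_genome(40000, seed = 31)
  sim <- sample_reads(g, coverage = 6,
                      length_model = list(mean = 5000, min = 4000,
                                          max = 8000),
                      error_model = constant_error_model(0),
                      hers_model = hers_model("none"), seed = 32,
                      circular = FALSE)
  reads <- sim$reads
  tr <- sim$truth
  hl <- find_candidates(reads, pipeline_config())
  ov_truth <- function(i, j) {
    max(0, min(tr$end[i], tr$end[j]) - max(tr$start[i], tr$start[j]))
  }
  for (i in seq_along(reads)) for (j in seq_along(reads)) {
    if (i == j) next
    if (ov_truth(i, j) >= 2000) {
      hi <- hl[[tr$read_id[i]]]
      row <- hi[hi$cand == tr$read_id[j], , drop = FALSE]
      expect_gte(nrow(row), 1)
      # approximate template interval overlaps the truth overlap by >= 80%
      ts <- max(tr$start[i], tr$start[j]) - tr$start[i]
      te <- min(tr$end[i], tr$end[j]) - tr$start[i]
      if (tr$strand[i] == "-") {
        len <- tr$end[i] - tr$start[i]
        tmp <- ts; ts <- len - te; te <- len - tmp
      }
      inter <- min(te, row$t_end[1]) - max(ts, row$t_start[1])
      expect_gte(inter / (te - ts), 0.8)
      # symmetry of detection
      hj <- hl[[tr$read_id[j]]]
      expect_true(tr$read_id[i] %in% hj$cand)
    }
  }
})
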