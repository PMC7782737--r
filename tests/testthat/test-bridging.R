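# A fabricated two-contig world with known junction geometry -----------------

bridge_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(61)
    g <- rnd_seq(44000)
    # contigs cover [0, 20000) and [20800, 44000): an 800 bp gap
    contigs <- c(ctgA = substr(g, 1, 20000), ctgB = substr(g, 20801, 44000))
    # raw reads spanning the junction, plus interior and unrelated reads
    span <- lapply(1:5, function(i) {
      s <- 14000 + 800 * i
      mut_seq(substr(g, s + 1, s + 12000), 0.12)
    })
    names(span) <- paste0("gap", 1:5)
    interior <- c(int1 = mut_seq(substr(g, 5001, 13000), 0.12))
    junk <- c(junk1 = rnd_seq(8000))
    cache <<- list(genome = g, contigs = contigs,
                   raw = c(vapply(span, identity, ""), interior, junk))
    cache
  }
})

test_that("raw-to-contig mapping finds junction reads on both contigs", {
  w <- bridge_world()
  hits <- map_raw_to_contigs(w$raw, w$contigs, pipeline_config())
  gap_hits <- hits[hits$read == "gap3", ]
  expect_setequal(gap_hits$contig, c("ctgA", "ctgB"))
  expect_equal(nrow(hits[hits$read == "int1", ]), 1)
  expect_equal(nrow(hits[hits$read == "junk1", ]), 0)
})

test_that("classify_link measures gap length and orientation", {
  w <- bridge_world()
  hits <- map_raw_to_contigs(w$raw, w$contigs, pipeline_config())
  h <- hits[hits$read == "gap3", ]
  h <- h[order(h$r_start), ]
  lk <- classify_link(h[1, ], h[2, ], nchar(w$contigs), end_window = 2000)
  expect_identical(lk$kind, "gap")
  expect_identical(lk$orientation, "same")
  expect_equal(lk$gap_len, 800, tolerance = 0.4)
  expect_gt(lk$score, 0)
  # interior hits never form a link
  hi <- hits[hits$read == "int1", ]
  expect_null(classify_link(hi[1, ], hi[1, ], nchar(w$contigs), 2000))
})

test_that("overlapped contig ends give negative gap lengths", {
  set.seed(62)
  g <- rnd_seq(30000)
  contigs <- c(A = substr(g, 1, 15300), B = substr(g, 15001, 30000))  # 300 bp shared
  raw <- c(x = mut_seq(substr(g, 9001, 21000), 0.10))
  hits <- map_raw_to_contigs(raw, contigs, pipeline_config())
  expect_equal(nrow(hits), 2)
  hits <- hits[order(hits$r_start), ]
  lk <- classify_link(hits[1, ], hits[2, ], nchar(contigs), 2000)
  expect_identical(lk$kind, "overlapped")
  expect_lt(lk$gap_len, 0)
  expect_equal(lk$gap_len, -300, tolerance = 0.7)
})

test_that("link clustering equals the closure of the adjacency relation", {
  mk <- function(gaps) data.frame(read = paste0("r", seq_along(gaps)),
                                  contig_a = "A", contig_b = "B",
                                  end_a = "R", end_b = "L",
                                  orientation = "same", kind = "gap",
                                  gap_len = gaps, score = 1,
                                  stringsAsFactors = FALSE)
  cl <- cluster_links(mk(c(100, 900, 5000)), window = 1000)
  expect_equal(vapply(cl, nrow, 1L), c(2L, 1L))
  expect_setequal(cl[[1]]$gap_len, c(100, 900))
  expect_length(cluster_links(mk(42), 1000), 1)
  set.seed(63)
  for (i in 1:30) {
    gaps <- sample(-2000:8000, sample(2:20, 1))
    got <- lapply(cluster_links(mk(gaps), 1000), function(x) sort(x$gap_len))
    want <- lapply(closure_clusters(gaps, 1000), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("choose_cluster maximizes total score with a median tie-break", {
  mk <- function(gaps, scores) data.frame(gap_len = gaps, score = scores)
  c1 <- mk(c(100, 150), c(9000, 6000)); c2 <- mk(5000, 3000)
  ch <- choose_cluster(list(c1, c2))
  expect_equal(ch$total_score, 15000)
  expect_equal(ch$representative$score, 9000)  # max individual score
  expect_null(choose_cluster(list()))
  tie <- choose_cluster(list(mk(4000, 10), mk(100, 10)))
  expect_equal(tie$cluster$gap_len, 100)       # smaller median |gap|
})

test_that("bridging splices two contigs across a gap read", {
  w <- bridge_world()
  br <- bridge_contigs(w$contigs, w$raw, pipeline_config())
  expect_equal(length(br$contigs), 1)
  expect_equal(nrow(br$links), 1)
  expect_identical(br$links$kind, "gap")
  merged <- br$contigs[[1]]
  # the merged contig reconstructs the genome across the junction
  expect_equal(nchar(merged), nchar(w$genome), tolerance = 0.02)
  d <- lorasm:::cpp_edit_distance(merged, w$genome)
  expect_lt(d / nchar(w$genome), 0.02)         # junction is raw-read quality
  # every junction is supported by a spanning raw read
  expect_true(br$links$read %in% paste0("gap", 1:5))
})

test_that("a three-contig chain merges once, transitive link removed", {
  set.seed(66)
  g <- rnd_seq(50000)
  contigs <- c(A = substr(g, 1, 16000), B = substr(g, 16601, 32000),
               C = substr(g, 32601, 50000))              # two 600 bp gaps
  raw <- c(
    setNames(lapply(1:3, function(i)
      mut_seq(substr(g, 10001 + 600 * i, 22000 + 600 * i), 0.1)),
      paste0("ab", 1:3)),
    setNames(lapply(1:3, function(i)
      mut_seq(substr(g, 26001 + 600 * i, 38000 + 600 * i), 0.1)),
      paste0("bc", 1:3)),
    list(ac = mut_seq(substr(g, 12001, 36000), 0.1))     # spans A..C
  )
  raw <- vapply(raw, identity, "")
  br <- bridge_contigs(contigs, raw, pipeline_config())
  expect_equal(length(br$contigs), 1)
  # the chain uses the two adjacent links, not a direct A-C jump
  expect_setequal(paste(pmin(br$links$contig_a, br$links$contig_b),
                        pmax(br$links$contig_a, br$links$contig_b)),
                  c("A B", "B C"))
  d <- lorasm:::cpp_edit_distance(br$contigs[[1]], g)
  expect_lt(d / nchar(g), 0.02)
})

test_that("competing partners at one contig end block the merge", {
  set.seed(64)
  g <- rnd_seq(30000)
  contigs <- c(A = substr(g, 1, 12000),
               B = substr(g, 13001, 21000),
               C = rnd_seq(9000))
  # reads link A-R to both B-L and C-L (C link is fabricated via C's copy)
  raw <- c(ab = mut_seq(substr(g, 7001, 17000), 0.1),
           ac = mut_seq(paste0(substr(g, 7001, 12800),
                               substr(contigs[["C"]], 1, 5000)), 0.1))
  br <- bridge_contigs(contigs, raw, pipeline_config())
  expect_equal(length(br$contigs), 3)          # branch: nothing merged
  # without links contigs pass through unchanged
  br2 <- bridge_contigs(contigs, c(z = rnd_seq(5000)), pipeline_config())
  expect_identical(sort(unname(nchar(br2$contigs))),
                   sort(unname(nchar(contigs))))
})
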