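# helpers to fabricate overlap tables and graphs ----------------------------

mk_overlap <- function(a, b, strand, a_iv, b_iv, identity = 0.99,
                       cols = NULL) {
  data.frame(a = a, b = b, strand = strand, a_start = a_iv[1],
             a_end = a_iv[2], b_start = b_iv[1], b_end = b_iv[2],
             identity = identity,
             cols = if (is.null(cols)) a_iv[2] - a_iv[1] else cols,
             stringsAsFactors = FALSE)
}

mk_graph <- function(edges) {
  nodes <- unique(c(edges$from, edges$to, lorasm:::node_flip(edges$from),
                    lorasm:::node_flip(edges$to)))
  structure(list(nodes = nodes, edges = edges, contained = character(0)),
            class = "string_graph")
}

mk_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(from = r[[1]], to = r[[2]], ext = strrep("A", r[[3]]),
               ext_len = r[[3]], ovl_len = r[[4]],
               identity = 0.99, stringsAsFactors = FALSE)))
}

test_that("coverage stats match a per-base bitmap recount", {
  set.seed(51)
  for (rep in 1:10) {
    reads <- setNames(replicate(4, rnd_seq(1000)), paste0("r", 1:4))
    n <- sample(3:10, 1)
    ov <- do.call(rbind, lapply(seq_len(n), function(i) {
      ab <- sample(names(reads), 2)
      s1 <- sample(0:700, 1); s2 <- sample(0:700, 1)
      len <- sample(100:300, 1)
      mk_overlap(ab[1], ab[2], "+", c(s1, s1 + len), c(s2, s2 + len))
    }))
    st <- coverage_stats(reads, ov)
    for (id in names(reads)) {
      iv <- lorasm:::overlaps_for_read(ov, id, nchar(reads))
      cov <- integer(1000)
      for (j in seq_len(nrow(iv))) {
        s <- iv$start[j]; e <- iv$end[j]
        if (e > s) cov[(s + 1):e] <- cov[(s + 1):e] + 1L
      }
      expect_equal(st$c_min[st$id == id], min(cov))
      expect_equal(st$c_max[st$id == id], max(cov))
    }
  }
})

test_that("coverage filter removes thin, deep and uneven reads", {
  reads <- c(a = rnd_seq(3000), b = rnd_seq(3000), c = rnd_seq(3000))
  # a and b overlap fully; c has an uncovered tip
  ov <- rbind(mk_overlap("a", "b", "+", c(0, 3000), c(0, 3000)),
              mk_overlap("a", "c", "+", c(0, 1500), c(1500, 3000)))
  cf <- coverage_filter(reads, ov, min_coverage = 1, max_coverage = 100,
                        max_diff_coverage = 100)
  expect_true("c" %in% cf$removed)            # c_min 0 at its head
  expect_false("a" %in% cf$removed)
  expect_false(any(cf$overlaps$b == "c"))
})

test_that("adaptive overlap filter drops relatively low-quality overlaps", {
  reads <- setNames(replicate(12, rnd_seq(4000)), c("hub", paste0("n", 1:11)))
  ov <- do.call(rbind, lapply(1:10, function(i)
    mk_overlap("hub", paste0("n", i), "+", c(0, 3900), c(100, 4000),
               identity = if (i <= 9) 0.99 else 0.92)))
  kept <- adaptive_overlap_filter(ov, reads, 0.90, 500, alpha = 2)
  expect_equal(nrow(kept), 9)                  # the 0.92 outlier is dropped
  expect_false(any(kept$identity < 0.99))
  # a uniformly mediocre read keeps everything above the global floor
  ov2 <- do.call(rbind, lapply(1:8, function(i)
    mk_overlap("hub", paste0("n", i), "+", c(0, 3900), c(100, 4000),
               identity = 0.91)))
  expect_equal(nrow(adaptive_overlap_filter(ov2, reads, 0.90, 500, 2)), 8)
  # oversized overhang (an internal match) is dropped regardless of identity
  ov3 <- mk_overlap("hub", "n11", "+", c(800, 3900), c(700, 3800),
                    identity = 0.999)
  expect_equal(nrow(adaptive_overlap_filter(rbind(ov2, ov3), reads,
                                            0.90, 500, 2)), 8)
})

test_that("string graph construction: dovetail edges, duals, containment", {
  g <- rnd_seq(7000)
  reads <- c(a = substr(g, 1, 5000), b = substr(g, 3001, 7000),
             c = substr(g, 3500, 4500))
  ov <- rbind(mk_overlap("a", "b", "+", c(3000, 5000), c(0, 2000)),
              mk_overlap("a", "c", "+", c(3500, 4500), c(0, 1000)))
  sg <- build_string_graph(reads, ov, tol = 100)
  expect_identical(sg$contained, "c")
  expect_equal(nrow(sg$edges), 2)
  e1 <- sg$edges[sg$edges$from == "a:+", ]
  expect_identical(e1$to, "b:+")
  expect_equal(e1$ext_len, 2000)               # b extends a by 2 kb
  expect_identical(e1$ext, substr(g, 5001, 7000))
  dual <- sg$edges[sg$edges$from == "b:-", ]
  expect_identical(dual$to, "a:-")
  expect_equal(dual$ext_len, 3000)
})

test_that("a clean tiling assembles into one contig equal to the genome", {
  set.seed(52)
  g <- rnd_seq(26000)
  starts <- seq(0, 20000, by = 2000)
  reads <- setNames(lapply(starts, function(s) substr(g, s + 1, s + 6000)),
                    sprintf("t%02d", seq_along(starts)))
  reads <- vapply(reads, identity, "")
  # terminal reads of a linear tiling have uncovered outer ends; disable the
  # minimum-coverage filter so they survive
  cfg <- pipeline_config(min_coverage = 0)
  ov <- compute_overlaps(reads, cfg)
  asm <- assemble_contigs(reads, ov, cfg)
  expect_equal(length(asm$contigs), 1)
  expect_identical(unname(asm$contigs[[1]]), g)
  # layout conservation: first read + successive extensions re-splice
  lay <- asm$layout[[1]]
  expect_equal(nrow(lay), length(reads))
})

test_that("transitive reduction equals the brute-force 2-path oracle", {
  set.seed(53)
  tri <- mk_edges(list("a:+", "b:+", 100, 900), list("b:+", "c:+", 150, 850),
                  list("a:+", "c:+", 250, 700))
  red <- transitive_reduction(mk_graph(tri), fuzz = 10)
  expect_setequal(paste(red$edges$from, red$edges$to),
                  c("a:+ b:+", "b:+ c:+"))
  far <- mk_edges(list("a:+", "b:+", 100, 900), list("b:+", "c:+", 150, 850),
                  list("a:+", "c:+", 400, 700))
  expect_equal(nrow(transitive_reduction(mk_graph(far), 10)$edges), 3)
  for (rep in 1:60) {
    nn <- sample(4:12, 1)
    nodes <- paste0("n", seq_len(nn), ":+")
    pairs <- t(combn(seq_len(nn), 2))
    take <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    if (nrow(take) == 0) next
    ed <- do.call(rbind, lapply(seq_len(nrow(take)), function(i)
      mk_edges(list(nodes[take[i, 1]], nodes[take[i, 2]],
                    sample(50:500, 1), sample(100:1000, 1)))))
    fz <- sample(c(0, 50, 200), 1)
    got <- transitive_reduction(mk_graph(ed), fz)$edges
    want <- transitive_oracle(ed, fz)
    expect_setequal(paste(got$from, got$to), paste(want$from, want$to))
    # reachability is preserved
    reach <- function(edges, from, to, avoid = character(0)) {
      seen <- from
      repeat {
        nxt <- unique(edges$to[edges$from %in% seen])
        if (all(nxt %in% seen)) break
        seen <- union(seen, nxt)
      }
      to %in% seen
    }
    for (k in seq_len(nrow(ed)))
      expect_true(reach(got, ed$from[k], ed$to[k]))
  }
})

test_that("best-overlap pruning keeps each node's best in/out edges", {
  ed <- mk_edges(list("a:+", "b:+", 100, 3000), list("a:+", "c:+", 150, 1200),
                 list("d:+", "c:+", 120, 2000))
  pr <- best_edge_prune(mk_graph(ed))
  keys <- paste(pr$edges$from, pr$edges$to)
  expect_true("a:+ b:+" %in% keys)             # a's best out
  expect_true("d:+ c:+" %in% keys)             # c's best in
  expect_false("a:+ c:+" %in% keys)
  # a simple path is untouched
  path <- mk_edges(list("a:+", "b:+", 100, 900), list("b:+", "c:+", 100, 900))
  expect_equal(nrow(best_edge_prune(mk_graph(path))$edges), 2)
})

test_that("graph cleaning removes tips and pops bubbles", {
  # main path a->b->c->d with a 1-node spur b->x
  ed <- mk_edges(list("a:+", "b:+", 100, 900), list("b:+", "c:+", 100, 900),
                 list("c:+", "d:+", 100, 900), list("x:+", "b:+", 80, 300))
  cl <- clean_graph(mk_graph(ed), tip_len = 3, bubble_len = 5,
                    spur_frac = 0)
  expect_false(any(grepl("x", cl$edges$from) | grepl("x", cl$edges$to)))
  expect_equal(nrow(cl$edges), 3)
  # bubble: u -> (p1|q1) -> v, the weaker branch is removed
  bub <- mk_edges(list("u:+", "p:+", 100, 900), list("p:+", "v:+", 100, 900),
                  list("u:+", "q:+", 100, 400), list("q:+", "v:+", 100, 400),
                  list("v:+", "w:+", 100, 900), list("s:+", "u:+", 100, 900))
  cl2 <- clean_graph(mk_graph(bub), 3, 5, 0)
  expect_false(any(grepl("q", cl2$edges$from) | grepl("q", cl2$edges$to)))
  expect_true("u:+ p:+" %in% paste(cl2$edges$from, cl2$edges$to))
  # a clean linear path is unchanged
  lin <- mk_edges(list("a:+", "b:+", 100, 900), list("b:+", "c:+", 100, 900))
  expect_equal(nrow(clean_graph(mk_graph(lin), 3, 5, 0.25)$edges), 2)
})

test_that("contig extraction breaks at branches and handles singletons", {
  reads <- setNames(replicate(5, rnd_seq(1000)), c("a", "b", "c", "d", "e"))
  # Y shape: a -> b, c -> b (branch into b), b -> d
  ed <- rbind(
    data.frame(from = "a:+", to = "b:+", ext = substr(reads[["b"]], 501, 1000),
               ext_len = 500L, ovl_len = 500, identity = 0.99),
    data.frame(from = "c:+", to = "b:+", ext = substr(reads[["b"]], 501, 1000),
               ext_len = 500L, ovl_len = 500, identity = 0.99),
    data.frame(from = "b:+", to = "d:+", ext = substr(reads[["d"]], 501, 1000),
               ext_len = 500L, ovl_len = 500, identity = 0.99))
  g <- mk_graph(ed)
  g$nodes <- c(g$nodes, "e:+", "e:-")          # singleton read
  res <- extract_contigs(g, reads)
  expect_equal(length(res$contigs), 4)         # a, c, b+d, e
  reads_per <- vapply(res$layout, nrow, 1L)
  expect_setequal(reads_per, c(1, 1, 2, 1))
  expect_true(any(vapply(res$layout, function(l)
    identical(l$read, c("b", "d")), TRUE)))
  singleton <- res$contigs[vapply(res$layout, function(l)
    identical(l$read, "e"), TRUE)]
  expect_identical(unname(singleton), unname(reads["e"]))
})
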