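test_that("threshold arithmetic: zero variance, spread, fallback, clamp", {
  cfg <- pipeline_config()
  t1 <- threshold_from_differences(rep(0.10, 50), cfg)
  expect_equal(t1$d0, 0.10)
  expect_equal(t1$D, 0)
  expect_equal(t1$d, 0.10)

  # 25 at 0.14 and 25 at 0.16: d0 = 0.15, population sd D = 0.01; the
  # individual threshold is the quality lower bound d0 + 5 D = 0.20
  t2 <- threshold_from_differences(rep(c(0.14, 0.16), each = 25), cfg)
  expect_equal(t2$d0, 0.15)
  expect_equal(t2$D, 0.01)
  expect_equal(t2$d, 0.20)
  # literal printed subtraction, selectable for comparison
  cfgm <- pipeline_config(); cfgm$threshold_formula <- "minus"
  expect_equal(threshold_from_differences(rep(c(0.14, 0.16), each = 25),
                                          cfgm)$d, 0.10)
  # unnormalised spread variant
  cfgu <- pipeline_config(threshold_sd_normalized = FALSE)
  tu <- threshold_from_differences(rep(c(0.14, 0.16), each = 25), cfgu)
  expect_equal(tu$D, sqrt(sum((rep(c(0.14, 0.16), each = 25) - 0.15)^2)))

  t0 <- threshold_from_differences(numeric(0), cfg)
  expect_true(t0$fallback)
  expect_equal(t0$d, 0.5)                     # global fallback
  # clamped into [0, global]
  t3 <- threshold_from_differences(c(0.45, 0.55, 0.65), cfg)
  expect_lte(t3$d, 0.5)
})

test_that("filter_supports applies min(global, individual) exactly", {
  f <- filter_supports(c(0.08, 0.3, 0.55), d = 0.12,
                       global_threshold = 0.5, min_cov = 4)
  expect_identical(f$keep, c(TRUE, FALSE, FALSE))
  expect_true(f$uncorrectable)
  f2 <- filter_supports(c(0.45, 0.52), d = 0.5, global_threshold = 0.5,
                        min_cov = 1)
  expect_identical(f2$keep, c(TRUE, FALSE))   # global binds
  # predicate oracle on random differences
  set.seed(31)
  for (i in 1:20) {
    diffs <- runif(30, 0, 0.7)
    d <- runif(1, 0, 0.6)
    f3 <- filter_supports(diffs, d, 0.5, 4)
    expect_identical(f3$keep, diffs <= min(0.5, d))
  }
})

test_that("blockwise alignment: identity, HERS stop, agreement with edit distance", {
  set.seed(33)
  cfg <- pipeline_config()
  s <- rnd_seq(2000)
  a <- blockwise_align(s, s, 1000, 1000, cfg, transcript = TRUE)
  expect_equal(a$diff, 0)
  expect_equal(c(a$t_start, a$t_end, a$c_start, a$c_end), c(0, 2000, 0, 2000))
  expect_identical(a$transcript, strrep("M", 2000))

  # candidate whose sequence right of the seed turns into garbage:
  # extension stops at the garbage boundary
  g <- rnd_seq(6000)
  cand <- paste0(substr(g, 1, 3500), rnd_seq(2500))
  a2 <- blockwise_align(g, cand, 1000, 1000, cfg)
  expect_true(a2$stopped_right)
  expect_false(a2$stopped_left)
  expect_lte(a2$t_end, 4100)                  # stops within a block of 3500

  # 5%-error pairs: blockwise difference close to global edit-distance rate
  for (i in 1:8) {
    t <- rnd_seq(5000)
    c5 <- mut_seq(t, 0.05)
    bw <- blockwise_align(t, c5, 2500, 2500 +
                            (nchar(c5) - 5000) %/% 2, cfg)
    d <- lorasm:::cpp_edit_distance(t, c5)
    rate <- d / max(nchar(t), nchar(c5))
    expect_lt(abs(bw$diff - rate), 0.02)
  }
})

test_that("sensitive alignment spans inserts that stop blockwise alignment", {
  set.seed(34)
  cfg <- pipeline_config()
  g <- rnd_seq(12000)
  hers <- mut_seq(substr(g, 6001, 7200), 0.9, c(.25, .15, .6))
  tpl <- paste0(substr(g, 1, 6000), hers, substr(g, 7201, 12000))
  cand <- mut_seq(g, 0.05)
  bw <- blockwise_align(tpl, cand, 1000, 1000, cfg)
  expect_true(bw$stopped_right)
  sv <- sensitive_align(tpl, cand, cfg)
  expect_false(is.null(sv))
  expect_lt(sv$t_start, 500)
  expect_gt(sv$t_end, nchar(tpl) - 500)       # spans across the insert
  # clean pair: sensitive and blockwise agree within a block
  cl <- mut_seq(g, 0.05)
  sv2 <- sensitive_align(g, cl, cfg)
  bw2 <- blockwise_align(g, cl, 6000, 6000 + (nchar(cl) - 12000) %/% 2, cfg)
  expect_lt(abs((sv2$t_end - sv2$t_start) - (bw2$t_end - bw2$t_start)), 600)
  # unrelated reads: no chain
  expect_null(sensitive_align(rnd_seq(3000), rnd_seq(3000), cfg))
})

test_that("CCA gate and update follow the strict inequality", {
  counts <- rep(13L, 100)
  expect_false(cca_gate(counts, 0, 100, C = 12))   # all > C: skip
  counts[50] <- 12L
  expect_true(cca_gate(counts, 0, 100, C = 12))    # 12 is not > 12
  u <- cca_update(integer(10), 2, 5)
  expect_identical(u, c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("CCA gating bounds executed alignments and preserves output", {
  set.seed(35)
  cfg <- pipeline_config()
  cfg$max_supports <- Inf
  g <- rnd_seq(4000)
  tpl <- mut_seq(g, 0.12)
  # clean supports (the pass-2 regime): plurality votes are then effectively
  # unanimous, so the gated and gate-free consensus must agree exactly
  cands <- setNames(lapply(1:30, function(i) mut_seq(g, 0.03)),
                    sprintf("c%02d", 1:30))
  cands <- vapply(cands, identity, "")
  hits <- do.call(rbind, lapply(names(cands), function(id) {
    h <- ddf_seed_and_chain(tpl, cands[[id]])
    h$cand <- id
    h
  }))
  hits <- top_candidates(hits, 200)
  gated <- align_supports(tpl, hits, 0.5, cands, cfg, pass = 1)
  expect_lte(gated$executed, 13 + 4)   # full-span supports close the gate
  free <- align_supports(tpl, hits, 0.5, cands, cfg, pass = 1, gate = FALSE)
  expect_equal(free$executed, 30)
  # consensus computed from the gated supports matches the gate-free one
  cons_g <- consensus(tpl, gated$supports, 4)
  cons_f <- consensus(tpl, free$supports, 4)
  expect_gte(nrow(cons_g), 1)
  # with noisy supports the two consensuses may differ only at isolated
  # insertion-placement ambiguities
  d <- lorasm:::cpp_edit_distance(paste(cons_g$seq, collapse = ""),
                                  paste(cons_f$seq, collapse = ""))
  expect_lte(d / sum(nchar(cons_f$seq)), 0.002)
  # executed alignments never exceed the gate-free count
  expect_lte(gated$executed, free$executed)
})

test_that("consensus majority, threshold and tie-break rules", {
  set.seed(36)
  g <- rnd_seq(2000)
  tpl <- mut_seq(g, 0.15)
  mk <- function(seqs) lapply(seqs, function(s) {
    al <- lorasm:::cpp_global_align(tpl, s)
    list(t_start = 0L, transcript = al$transcript, csub = s)
  })
  cons <- consensus(tpl, mk(rep(list(g), 12)), 4)
  expect_equal(nrow(cons), 1)
  expect_identical(cons$seq, g)               # majority forced to truth
  # coverage below min_cov: empty
  expect_equal(nrow(consensus(tpl, mk(rep(list(g), 2)), 4)), 0)
  # 6/6 tie at one column resolves to the lexicographically smaller base
  tpl2 <- "AAAATAAAA"
  va <- "AAAACAAAA"; vb <- "AAAAGAAAA"
  sup <- lapply(c(rep(va, 6), rep(vb, 6)), function(s)
    list(t_start = 0L, transcript = paste0(strrep("M", 4), "X",
                                           strrep("M", 4)), csub = s))
  cons2 <- consensus(tpl2, sup, 4)
  expect_identical(cons2$seq, "AAAACAAAA")
})

test_that("pass-1 corrects a subset against the full candidate pool", {
  w <- small_world()
  cfg <- pipeline_config()
  hl <- find_candidates(w$reads, cfg)
  p1 <- correct_pass1(w$reads[1:8], cfg,
                      hits_list = hl[names(w$reads)[1:8]],
                      pool = w$reads)
  plans <- attr(w$truth, "plans")
  rates <- vapply(names(p1$reads), function(id)
    read_error_rate(p1$reads[[id]], plans[[id]]$template), 0)
  expect_lt(mean(rates), 0.06)
  expect_true(all(vapply(p1$mask, any, TRUE)))
  expect_lt(max(abs(nchar(p1$reads) / nchar(w$reads[1:8]) - 1)), 0.1)
})

test_that("pass-1 with zero supports passes the template through", {
  cfg <- pipeline_config()
  lone <- c(solo = rnd_seq(4000))
  p1 <- correct_pass1(lone, cfg,
                      hits_list = list(solo = data.frame(
                        cand = character(), strand = character(),
                        score = integer(), t_start = integer(),
                        t_end = integer(), c_start = integer(),
                        c_end = integer(), seed_t = integer(),
                        seed_c = integer(), stringsAsFactors = FALSE)))
  expect_identical(p1$reads[["solo"]], lone[["solo"]])
  expect_false(any(p1$mask$solo))
  expect_true(p1$stats$uncorrectable[1])
})

test_that("pass-2 splits templates at uncorrectable interior intervals", {
  set.seed(38)
  cfg <- pipeline_config()
  g <- rnd_seq(14000)
  # neighbours cover only the two flanks; the middle 2 kb has no support
  left <- substr(g, 1, 6000); right <- substr(g, 8001, 14000)
  reads <- c(tpl = g,
             setNames(lapply(1:6, function(i) mut_seq(left, 0.02)),
                      paste0("l", 1:6)),
             setNames(lapply(1:6, function(i) mut_seq(right, 0.02)),
                      paste0("r", 1:6)))
  reads <- vapply(reads, identity, "")
  p2 <- correct_pass2(reads["tpl"], cfg,
                      hits_list = list(tpl = top_candidates(do.call(rbind,
                        lapply(setdiff(names(reads), "tpl"), function(id) {
                          h <- ddf_seed_and_chain(reads[["tpl"]], reads[[id]])
                          if (is.null(h)) return(NULL)
                          h$cand <- id
                          h
                        })), 200)),
                      pool = reads, min_len = 1000)
  frs <- p2$fragments[p2$fragments$template == "tpl", ]
  expect_equal(nrow(frs), 2)
  expect_lt(frs$end[1], 8200)                 # first fragment ends pre-gap
  expect_gt(frs$start[2], 5800)
})
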