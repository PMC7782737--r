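test_that("make_genome is reproducible and honours repeat specs", {
  g1 <- make_genome(100000, seed = 1)
  g2 <- make_genome(100000, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(nchar(g1), 100000)

  g <- make_genome(100000, repeat_spec = list(count = 2, unit_length = 5000,
                                              identity = 1.0), seed = 5)
  f <- attr(g, "repeat_features")
  expect_equal(nrow(f), 2)
  copies <- substring(as.character(g), f$ins_start + 1, f$ins_end)
  expect_identical(copies[1], copies[2])       # identity 1 -> equal copies

  g95 <- make_genome(100000, repeat_spec = list(count = 2, unit_length = 5000,
                                                identity = 0.95), seed = 6)
  f95 <- attr(g95, "repeat_features")
  cp <- substring(as.character(g95), f95$ins_start + 1, f95$ins_end)
  d <- lorasm:::cpp_edit_distance(cp[1], cp[2])
  expect_gt(d / 5000, 0.03)                    # edit-distance oracle on pair
  expect_lt(d / 5000, 0.07)

  expect_error(make_genome(10000, repeat_spec = list(count = 10,
                                                     unit_length = 5000,
                                                     identity = 1)),
               "infeasible|10x")
})

test_that("zero-noise reads are exact oriented substrings", {
  g <- make_genome(50000, seed = 3)
  sim <- sample_reads(g, coverage = 3,
                      length_model = list(mean = 4000, min = 2000,
                                          max = 8000),
                      error_model = constant_error_model(0),
                      hers_model = hers_model("none"), seed = 4,
                      circular = FALSE)
  gs <- as.character(g)
  for (i in seq_along(sim$reads)) {
    tr <- sim$truth[i, ]
    sub <- substring(gs, tr$start + 1, tr$end)
    if (tr$strand == "-") sub <- rc_seq(sub)
    expect_identical(unname(sim$reads[[i]]), sub)
  }
})

test_that("realized error rates match the planned distribution", {
  g <- make_genome(150000, seed = 7)
  sim <- sample_reads(g, coverage = 8,
                      length_model = list(mean = 6000, min = 3000,
                                          max = 12000),
                      error_model = nanopore_error_model(mean = 0.15),
                      hers_model = hers_model("none"), seed = 7)
  expect_equal(sum(nchar(sim$reads)), 8 * 150000, tolerance = 0.05)
  st <- read_set_stats(sim$reads, sim$truth)
  expect_lt(abs(st$mean_error - 0.15), 0.02)
  # distribution support and mode (realized against the planned column)
  expect_true(all(sim$truth$planned_error >= 0.07 - 1e-9))
  expect_true(all(sim$truth$planned_error <= 0.50 + 1e-9))
  dens <- density(sim$truth$planned_error)
  expect_gt(dens$x[which.max(dens$y)], 0.10)
  expect_lt(dens$x[which.max(dens$y)], 0.20)
})

test_that("edit plans replay into the emitted reads (conservation)", {
  w <- small_world()
  plans <- attr(w$truth, "plans")
  for (i in sample(length(w$reads), 25)) {
    p <- plans[[names(w$reads)[i]]]
    expect_identical(apply_edit_plan(p$template, p$plan),
                     unname(w$reads[[i]]))
  }
})

test_that("HERS injection marks truth and is detectable; guards hold", {
  set.seed(9)
  tpl <- rnd_seq(8000)
  truth <- data.frame(read_id = "x", start = 0, end = 8000, strand = "+",
                      planned_error = 0, hers_intervals = "",
                      stringsAsFactors = FALSE)
  r1 <- inject_hers(tpl, truth, window = 500, local_rate = 0.6, seed = 5)
  expect_match(r1$truth$hers_intervals, "^\\d+-\\d+@0.60$")
  expect_gte(hers_windows(r1$read, tpl), 1)
  # determinism
  r2 <- inject_hers(tpl, truth, window = 500, local_rate = 0.6, seed = 5)
  expect_identical(r1$read, r2$read)
  # read shorter than window: unchanged with warning
  expect_warning(r3 <- inject_hers("ACGTACGT", NULL, window = 500,
                                   local_rate = 0.6), "shorter")
  expect_identical(r3$read, "ACGTACGT")
  expect_error(inject_hers(tpl, NULL, local_rate = 0.4), "exceed")
})

test_that("HERS injection probability follows the constant model", {
  g <- make_genome(120000, seed = 11)
  sim <- sample_reads(g, coverage = 15,
                      length_model = list(mean = 12000, min = 11000,
                                          max = 16000),
                      error_model = nanopore_error_model(mean = 0.12),
                      hers_model = hers_model("constant", prob = 0.2,
                                              min_len = 10000), seed = 12)
  long <- nchar(sim$reads) > 10000
  frac <- mean(nzchar(sim$truth$hers_intervals[long]))
  expect_lt(abs(frac - 0.20), 0.05 + 2 / sum(long))
})

test_that("truth TSV round-trips", {
  w <- small_world()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_truth(w$truth, p)
  tt <- read_truth(p)
  expect_equal(tt$start, w$truth$start)
  expect_identical(tt$read_id, w$truth$read_id)
  expect_identical(tt$strand, w$truth$strand)
})
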