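test_that("window tiling drops the trailing remainder", {
  t1 <- tile_windows(650, 200)
  expect_equal(nrow(t1), 3)
  expect_equal(c(t1$start[3], t1$end[3]), c(400, 600))
  expect_equal(nrow(tile_windows(199, 200)), 0)
  t2 <- tile_windows(400, 200)
  expect_equal(t2$start, c(0, 200))
  expect_equal(t2$end, c(200, 400))
})

test_that("window spectra localize an implanted period and average linearly", {
  g <- generate_genome(synthetic_spec(genome_length = 2000, coverage = 0.8,
                                      seed = 21))
  sp <- window_spectrum(g$genome, c(0, 200))
  expect_equal(sp$peak_period, 11, tolerance = 0.3)

  # avg4 over four identical windows reproduces the single-window spectrum
  block <- substr(g$genome$seq, 1, 200)
  g4 <- genome_sequence("rep", strrep(block, 4))
  s1 <- window_spectrum(g4, c(0, 200))
  s4 <- window_spectrum(g4, c(0, 200), avg4 = TRUE)
  expect_equal(s4$qstar, s1$qstar, tolerance = 1e-9)

  # averaging two disjoint single-period windows keeps both peaks
  mk_cos_win <- function(T0, seed) {
    gg <- generate_genome(synthetic_spec(genome_length = 200,
                                         implant_period = T0,
                                         tracts_per_array = 12,
                                         coverage = 0.8, seed = seed))
    gg$genome$seq
  }
  gmix <- genome_sequence("mix", paste0(mk_cos_win(10, 1), mk_cos_win(12.5, 2),
                                        mk_cos_win(10, 3), mk_cos_win(12.5, 4)))
  sm <- window_spectrum(gmix, c(0, 200), avg4 = TRUE)
  per <- sm$period
  q10 <- max(sm$qstar[per >= 9.6 & per <= 10.4])
  q125 <- max(sm$qstar[per >= 12.1 & per <= 12.9])
  trough <- min(sm$qstar[per >= 11 & per <= 11.6])
  expect_gt(q10, 2)
  expect_gt(q125, 2)
  expect_lt(trough, min(q10, q125))

  expect_error(window_spectrum(g$genome, c(1900, 2100)), "outside")
  expect_error(window_spectrum(g$genome, c(1400, 1600), avg4 = TRUE), "avg4")
})

test_that("degenerate windows are flagged and excluded from testing", {
  g <- genome_sequence("gc", strrep("GC", 300))
  sp <- window_spectrum(g, c(0, 200), motif = "AT2")
  expect_true(sp$degenerate)
  wr <- window_pvalues(g, c(0, 200), n_perm = 10, seed = 1)
  expect_true(wr$degenerate)
  expect_true(is.na(wr$p_min))
})

test_that("window p-values use the plus-one estimator over one ensemble", {
  g <- generate_genome(synthetic_spec(genome_length = 1000, seed = 3))
  wr <- window_pvalues(g$genome, c(0, 200), n_perm = 50, seed = 4)
  expect_true(all(wr$p_values >= 1 / 51 & wr$p_values <= 1))
  expect_equal(wr$p_min, min(wr$p_values))
  expect_true(wr$T_sig %in% default_test_periods())
  expect_gte(wr$p_window, wr$p_min)
  # reproducible given the seed
  wr2 <- window_pvalues(g$genome, c(0, 200), n_perm = 50, seed = 4)
  expect_identical(wr$p_values, wr2$p_values)
  expect_error(window_pvalues(g$genome, c(0, 200), n_perm = 0), "n_perm")
  expect_error(window_pvalues(g$genome, c(0, 200), n_perm = 5,
                              test_periods = c(8.05)), "subset")
})

test_that("R and C++ spectrum paths agree on shuffled windows", {
  g <- generate_genome(synthetic_spec(genome_length = 400, seed = 6))
  sub <- substr(g$genome$seq, 1, 200)
  periods <- default_period_grid()
  k <- 30:101
  ang <- outer(k, periods, function(k, T) 2 * pi * k / T)
  null_q <- periodscan:::with_seed(9,
    periodscan:::null_spectra_cpp(periodscan:::encode_seq(sub),
                                  periodscan:::motif_matrix("AT2"),
                                  5L, 30L, 101L, 3L, cos(ang), sin(ang)))
  shuffles <- periodscan:::with_seed(9, {
    codes <- periodscan:::encode_seq(sub)
    lapply(1:5, function(i)
      periodscan:::decode_seq(periodscan:::dinuc_shuffle_cpp(codes)))
  })
  for (i in 1:5) {
    r_spec <- periodscan:::one_window_spectrum(shuffles[[i]], "AT2", 30L,
                                               101L, periods, 3L, c(10, 12))
    expect_equal(unname(null_q[i, ]), r_spec$qstar, tolerance = 1e-10)
  }
})

test_that("segments concatenate adjacent significant windows by period range", {
  wf <- function(T_sig, p) data.frame(index = seq_along(T_sig),
                                      start = (seq_along(T_sig) - 1) * 200,
                                      end = seq_along(T_sig) * 200,
                                      T_sig = T_sig, p_min = p, p_window = p)
  seg <- build_segments(wf(c(11, 11.2, 13), c(0.001, 0.005, 0.5)))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(0, 400))
  expect_equal(seg$n_windows, 2)

  expect_equal(nrow(build_segments(wf(c(11, 11), c(0.5, 0.99)))), 0)

  seg2 <- build_segments(wf(c(11, 11, 11), c(0.001, 0.5, 0.001)))
  expect_equal(nrow(seg2), 2)
  expect_true(all(seg2$n_windows == 1))

  # different ranges separate even when adjacent
  seg3 <- build_segments(wf(c(10.0, 11.0), c(0.001, 0.001)))
  expect_equal(nrow(seg3), 2)
  expect_setequal(seg3$range_label, c("[9.6,10.3)", "[10.9,11.6)"))

  # segments never overlap within a range
  set.seed(31)
  for (r in 1:20) {
    n <- 30
    w <- wf(runif(n, 9, 13), runif(n)^3)
    seg <- build_segments(w)
    for (lab in unique(seg$range_label)) {
      s <- seg[seg$range_label == lab, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
  }
})

test_that("scanning a genome with a confined implant localizes it", {
  sp <- synthetic_spec(genome_length = 24000,
                       implant_regions = list(c(8000, 16000)), seed = 13)
  g <- generate_genome(sp)
  sc <- scan_genome(g$genome, n_perm = 300, seed = 5)
  expect_s3_class(sc, "genome_scan")
  expect_equal(nrow(sc$windows), 30)   # 120 windows of 200 bp in 30 avg4 units
  loc <- localization_scores(sc, g$truth)
  expect_gt(loc["precision"], 0.5)
  expect_gt(loc["recall"], 0.3)
  expect_output(print(sc), "avg4")
  expect_output(print(summary(sc)), "segments per period range")

  # per-window seeding makes the scan reproducible
  sc2 <- scan_genome(g$genome, n_perm = 300, seed = 5)
  expect_identical(sc$windows, sc2$windows)
})
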