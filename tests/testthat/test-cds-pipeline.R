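test_that("concatenated CDS spectra mask junctions and match single-CDS fits", {
  cds <- cds_record("g1", random_cds(80, seed = 1))
  single <- concatenated_cds_spectrum(list(cds))
  alone <- periodicity(cds$seq)
  expect_equal(single$spectrum$qstar, alone$spectrum$qstar, tolerance = 1e-12)

  # junction dinucleotides contribute nothing
  a <- cds_record("a", "AAAAAA")
  b <- cds_record("b", "AAAAAA")
  tr <- periodscan:::concat_cds_track(list(a, b), motif_set("AA"))
  expect_identical(tr$values,
                   c(rep(1L, 5), 0L, rep(1L, 5)))
  expect_error(concatenated_cds_spectrum(list()), "empty")
})

test_that("a position-encoded CDS set shows its implant period", {
  cs <- generate_cds_set(synthetic_spec(seed = 11, n_genes = 40))
  fit <- concatenated_cds_spectrum(cs$cds)
  expect_equal(fit$spectrum$peak_period, 11, tolerance = 0.3)
})

test_that("q_prime reports identity as exactly 1 and destroys phased signal", {
  cs <- generate_cds_set(synthetic_spec(seed = 8, n_genes = 30))
  qp <- q_prime(cs$cds, schemes = c("identity", "codon_order"),
                T_probe = 11.0, n_reps = 5, seed = 3)
  s <- setNames(qp$summary$mean, qp$summary$scheme)
  expect_equal(unname(s["identity"]), 1)
  expect_equal(qp$summary$min[1], 1)
  expect_equal(qp$summary$max[1], 1)
  expect_lt(s[["codon_order"]], 0.1)
  expect_equal(nrow(qp$reps), 10)
  expect_true(all(qp$reps$Q_prime >= 0))
  expect_output(print(qp), "codon_order")
  expect_error(q_prime(cs$cds, schemes = "bogus", n_reps = 2), "unknown")
})

test_that("q_prime on signal-free CDS shows no systematic attenuation", {
  # On signal-free sequence the pre-permutation band power is a single
  # noisy (~2 dof) draw exchangeable with the permuted draws, so the ratio
  # Q' is heavy-tailed and its mean is uninformative in any one set. The
  # robust reading of "no systematic attenuation" is that permuted powers
  # exceed the observed power half the time: across independent sets the
  # exceedance fraction P(Q' >= 1) averages 0.5.
  frac <- vapply(1:25, function(s) {
    cds <- lapply(1:8, function(i)
      cds_record(sprintf("r%02d", i), random_cds(100, seed = 100 * s + i)))
    qp <- q_prime(cds, schemes = "codon_order", T_probe = 11.0, n_reps = 8,
                  seed = s)
    mean(qp$reps$Q_prime >= 1)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.5), 0.2)
})

test_that("per-CDS spectra filter short CDS and match the core estimator", {
  short <- cds_record("short", random_cds(60, seed = 2))    # 180 bp
  long1 <- cds_record("long1", random_cds(150, seed = 3))
  long2 <- cds_record("long2", random_cds(200, seed = 4))
  m <- per_cds_spectra(list(short, long1, long2))
  expect_setequal(rownames(m$mat), c("long1", "long2"))
  expect_true(all(abs(rowMeans(m$mat) - 1) < 1e-9))
  expect_equal(unname(m$mat["long1", ]),
               periodicity(long1$seq)$spectrum$qstar, tolerance = 1e-12)
  expect_equal(m$T_max[["long1"]],
               periodicity(long1$seq)$spectrum$peak_period)
})

test_that("top-periodic selection ranks implanted CDS first, stably", {
  randoms <- lapply(1:40, function(i)
    cds_record(sprintf("r%02d", i), random_cds(500, seed = 100 + i)))
  wins <- 0L
  m1 <- NULL
  for (s in 1:10) {
    g <- generate_cds_set(synthetic_spec(seed = s, n_genes = 1,
                                         gene_length = c(1500, 1500)))
    implanted <- cds_record("implanted", g$cds[[1]]$seq)
    m <- per_cds_spectra(c(list(implanted), randoms))
    top <- select_top_periodic(m, n = 5, band = c(9.5, 13.5))
    if (identical(rownames(top$mat)[1], "implanted")) wins <- wins + 1L
    if (s == 1) m1 <- m
  }
  expect_gte(wins, 8)
  expect_equal(nrow(select_top_periodic(m1, n = 1000)$mat), nrow(m1$mat))

  # ranking invariant to row order
  implanted <- cds_record("implanted",
                          generate_cds_set(synthetic_spec(seed = 1,
                            n_genes = 1,
                            gene_length = c(1500, 1500)))$cds[[1]]$seq)
  mA <- per_cds_spectra(c(list(implanted), randoms))
  mB <- per_cds_spectra(c(randoms[21:40], list(implanted), randoms[1:20]))
  expect_identical(rownames(select_top_periodic(mA, 10)$mat),
                   rownames(select_top_periodic(mB, 10)$mat))
})

test_that("spectral clustering separates period-10 and period-11 CDS", {
  mk <- function(T0, n, seed0) lapply(seq_len(n), function(i) {
    cs <- generate_cds_set(synthetic_spec(seed = seed0 + i, n_genes = 1,
                                          implant_period = T0))
    cds_record(sprintf("T%g_%02d", T0, i), cs$cds[[1]]$seq)
  })
  cds <- c(mk(10, 15, 0), mk(12.5, 15, 400))
  m <- per_cds_spectra(cds)
  cl <- cluster_cds_spectra(m, k = 2)
  grp <- substr(rownames(cl$mat), 1, 3)
  agreement <- max(mean(cl$cluster[grp == "T10"] == 1),
                   mean(cl$cluster[grp == "T10"] == 2))
  expect_gte(agreement, 0.95)
  expect_equal(sort(cl$cluster_T_max$T_max), c(10, 12.5), tolerance = 0.4)

  one <- cluster_cds_spectra(m, k = 1)
  expect_equal(unique(unname(one$cluster)), 1)
  expect_equal(one$cluster_T_max$T_max,
               m$period[which.max(colMeans(m$mat))])
  # deterministic labels
  cl2 <- cluster_cds_spectra(m, k = 2)
  expect_identical(cl$cluster, cl2$cluster)
  expect_output(print(cl), "clustered into 2 groups")
})
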