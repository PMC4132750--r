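test_that("the spec constructor validates its fields", {
  expect_error(synthetic_spec(implant_period = 20), "2, 15")
  expect_error(synthetic_spec(coverage = 1.3), "0, 1")
  expect_error(synthetic_spec(implant_regions = list(c(-5, 100))), "region")
  expect_error(synthetic_spec(genome_length = 1000,
                              implant_regions = list(c(0, 2000))), "region")
  bad <- matrix(1, 4, 4)
  expect_error(synthetic_spec(background = bad), "sum to 1")
})

test_that("genome generation is deterministic and obeys coverage", {
  sp <- synthetic_spec(genome_length = 30000, seed = 14)
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$truth, g2$truth)

  covered <- sum(g1$truth$end - g1$truth$start)
  expect_equal(covered / 30000, 0.4, tolerance = 0.1)

  g0 <- generate_genome(synthetic_spec(genome_length = 30000, coverage = 0,
                                       seed = 2))
  expect_equal(nrow(g0$truth), 0)
})

test_that("background-only genomes match the Markov table composition", {
  # iid uniform: each dinucleotide expected at L/16 within 3 sigma
  g <- generate_genome(synthetic_spec(genome_length = 60000, coverage = 0,
                                      seed = 4))
  counts <- dinuc_counts(g$genome$seq)
  n <- sum(counts)
  p <- 1 / 16
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < 3.5 * sigma))

  # biased Markov chain: AT-rich stationary composition shows up
  at <- matrix(rep(c(0.35, 0.15, 0.15, 0.35), 4), 4, 4, byrow = TRUE)
  gb <- generate_genome(synthetic_spec(genome_length = 40000, coverage = 0,
                                       background = at, seed = 6))
  bc <- base_counts(gb$genome$seq)
  expect_equal(unname((bc[["A"]] + bc[["T"]]) / 40000), 0.7,
               tolerance = 0.02)
})

test_that("implanted genomes carry the target period only inside regions", {
  sp <- synthetic_spec(implant_regions = list(c(5000, 15000)),
                       genome_length = 30000, seed = 3)
  g <- generate_genome(sp)
  expect_true(all(g$truth$start >= 5000 & g$truth$end <= 15000))
  inside <- periodicity(substr(g$genome$seq, 5001, 15000))
  outside <- periodicity(substr(g$genome$seq, 15001, 30000))
  expect_equal(inside$spectrum$peak_period, 11, tolerance = 0.2)
  expect_gt(inside$spectrum$snr, outside$spectrum$snr)
})

test_that("generated CDS are translatable genes with coherent annotation", {
  cset <- generate_cds_set(synthetic_spec(n_genes = 20, seed = 5))
  expect_length(cset$cds, 20)
  for (cds in cset$cds) {
    expect_equal(cds$length %% 3, 0)
    aa <- translate_cds(cds)
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # genomic slices agree with the CDS records after strand resolution
  for (i in seq_len(nrow(cset$features))) {
    f <- cset$features[i, ]
    slice <- substr(cset$genome$seq, f$start + 1, f$end)
    if (f$strand == "-") slice <- revcomp(slice)
    expect_identical(slice, cset$cds[[f$id]]$seq)
  }
  # determinism
  cset2 <- generate_cds_set(synthetic_spec(n_genes = 20, seed = 5))
  expect_identical(cset$genome$seq, cset2$genome$seq)
})

test_that("unbiased CDS sets show no codon-order attenuation", {
  # exchangeability reading of "no attenuation" (see the q_prime tests):
  # permuted power exceeds the observed power about half the time
  frac <- vapply(1:20, function(s) {
    cs <- generate_cds_set(synthetic_spec(seed = 300 + s, n_genes = 6,
                                          positionIII_bias = 0,
                                          positionI_bias = 0,
                                          positionII_bias = 0))
    qp <- q_prime(cs$cds, schemes = "codon_order", T_probe = 11.0,
                  n_reps = 8, seed = s)
    mean(qp$reps$Q_prime >= 1)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.5), 0.2)
})

test_that("fixtures round trip through the package readers byte-identically", {
  sp <- synthetic_spec(genome_length = 5000, n_genes = 6, seed = 22)
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  p1 <- emit_fixture(sp, d1)
  p2 <- emit_fixture(sp, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))

  g <- read_fasta(p1[["genome"]])
  gen <- generate_genome(sp)
  expect_identical(g$synthetic$seq, gen$genome$seq)

  cg <- read_fasta(p1[["cds_genome"]])
  expect_no_warning(ann <- read_annotation(p1[["gff"]], "gff3", cg))
  cset <- generate_cds_set(sp)
  for (id in names(cset$cds))
    expect_identical(ann$cds[[id]]$seq, cset$cds[[id]]$seq)
})

test_that("truth-guided localization works end to end at reduced scale", {
  sp <- synthetic_spec(genome_length = 40000,
                       implant_regions = list(c(10000, 20000)), seed = 6)
  g <- generate_genome(sp)
  sc <- scan_genome(g$genome, n_perm = 400, seed = 3)
  # specificity: significant units under the calibrated per-window rule
  # stay inside the implanted region
  w <- sc$windows
  sig <- !is.na(w$p_window) & w$p_window < 0.01
  expect_gte(sum(sig), 2)
  expect_gte(mean(w$end[sig] > 10000 & w$start[sig] < 20000), 0.8)
})
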