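test_that("FASTA reading uppercases, masks ambiguity codes, keeps order", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y desc", "ACRGT"), f)
  got <- read_fasta(f)
  expect_identical(names(got), c("x", "y"))
  expect_identical(got$x$seq, "ACGT")
  expect_identical(got$x$length, 4L)
  expect_identical(got$y$seq, "ACNGT")   # R masked to N

  writeLines(c("not a header", "ACGT"), f)
  expect_error(read_fasta(f), "format error at line 1")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
})

test_that("short records are skipped under min_len with a warning", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">short", "ACGT", ">long", strrep("ACGT", 300)), f)
  expect_warning(got <- read_fasta(f, min_len = 1000), "skipping short")
  expect_identical(names(got), "long")
})

test_that("FASTA round trips through the writer", {
  seqs <- list(genome_sequence("a", random_seq(153, seed = 1)),
               genome_sequence("b", random_seq(70, seed = 2)))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back$a$seq, seqs[[1]]$seq)
  expect_identical(back$b$seq, seqs[[2]]$seq)
})

test_that("GFF3 coordinates convert to 0-based half-open and CDS strand-resolve", {
  fa <- tempfile(fileext = ".fa")
  genome_seq <- paste0("ATGAAA", random_seq(54, seed = 5))
  writeLines(c(">chr1", genome_seq), fa)
  g <- read_fasta(fa)
  gff <- tiny_gff3(tempfile(fileext = ".gff3"), c(
    "chr1\t.\tCDS\t1\t6\t.\t+\t0\tID=g1",
    "chr1\t.\tCDS\t1\t6\t.\t-\t0\tID=g2",
    "chr1\t.\tCDS\t10\t16\t.\t+\t0\tID=g3"))
  expect_warning(ann <- read_annotation(gff, "gff3", g), "not divisible by 3")
  f1 <- ann$features[ann$features$id == "g1", ]
  expect_equal(c(f1$start, f1$end), c(0, 6))
  expect_identical(ann$cds$g1$seq, "ATGAAA")
  expect_identical(ann$cds$g2$seq, periodscan::revcomp("ATGAAA"))
  expect_false("g3" %in% names(ann$cds))   # length 7 excluded
})

test_that("annotation coordinates outside the sequence are rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ATGAAATAG"), fa)
  g <- read_fasta(fa)
  gff <- tiny_gff3(tempfile(fileext = ".gff3"),
                   "chr1\t.\tCDS\t1\t300\t.\t+\t0\tID=far")
  expect_error(read_annotation(gff, "gff3", g), "out of bounds")
  expect_error(read_annotation(gff, "nonsense"), "arg")
})

test_that("intergenic complement partitions the genome", {
  feats <- periodscan:::feature_frame("s", 10, 20, "+", "CDS", "a")
  inter <- intergenic_complement(feats, 30)
  expect_equal(inter$start, c(0, 20))
  expect_equal(inter$end, c(10, 30))
  expect_true(all(inter$kind == "intergenic"))

  full <- periodscan:::feature_frame("s", 0, 30, "+", "CDS", "a")
  expect_equal(nrow(intergenic_complement(full, 30)), 0)

  olap <- periodscan:::feature_frame(c("s", "s"), c(0, 10), c(15, 20),
                                     c("+", "+"), c("CDS", "CDS"),
                                     c("a", "b"))
  inter2 <- intergenic_complement(olap, 25)
  expect_equal(c(inter2$start, inter2$end), c(20, 25))

  none <- intergenic_complement(periodscan:::feature_frame(), 40)
  expect_equal(c(none$start, none$end), c(0, 40))

  # partition property on random annotations
  for (s in 1:20) {
    set.seed(s)
    n <- sample(1:8, 1)
    st <- sort(sample(0:900, n))
    en <- pmin(st + sample(10:120, n, replace = TRUE), 1000)
    feats <- periodscan:::feature_frame(rep("s", n), st, en,
                                        rep("+", n), rep("CDS", n),
                                        paste0("f", 1:n))
    inter <- intergenic_complement(feats, 1000)
    covered <- sum(IRanges::width(periodscan:::as_iranges(feats))) +
      sum(inter$end - inter$start)
    expect_equal(covered, 1000)
    expect_equal(jaccard(feats, inter), 0)
  }
})

test_that("BED output round trips identically and carries a header", {
  feats <- periodscan:::feature_frame(rep("chr", 3), c(0, 50, 200),
                                      c(10, 150, 260), rep(".", 3),
                                      rep("other", 3), c("a", "b", "c"))
  f <- tempfile(fileext = ".bed")
  write_bed(feats, f, params = list(alpha = 0.01))
  expect_match(readLines(f, n = 1), "^# periodscan")
  back <- read_bed(f)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$id, feats$id)
})

test_that("GFF3 writer round trips through the reader", {
  cset <- generate_cds_set(synthetic_spec(n_genes = 5, seed = 2))
  f <- tempfile(fileext = ".gff3")
  write_gff3(cset$features, setNames(cset$genome$length, cset$genome$id), f)
  ann <- read_annotation(f, "gff3", setNames(list(cset$genome),
                                             cset$genome$id))
  cdsf <- ann$features[ann$features$kind == "CDS", ]
  expect_equal(cdsf$start, cset$features$start)
  expect_equal(cdsf$end, cset$features$end)
  expect_equal(cdsf$strand, cset$features$strand)
  for (id in names(cset$cds))
    expect_identical(ann$cds[[id]]$seq, cset$cds[[id]]$seq)
})

test_that("GenBank flat files parse locations, join and complement", {
  seq60 <- paste0("ATGAAATTTCCCGGGTAA", random_seq(42, seed = 7))
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC                 60 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..18",
    '                     /locus_tag="gbA"',
    "     CDS             complement(19..36)",
    '                     /locus_tag="gbB"',
    "     CDS             join(37..45,52..60)",
    '                     /locus_tag="gbC"',
    "ORIGIN",
    paste("        1", tolower(paste(substring(seq60, seq(1, 51, 10),
                                               seq(10, 60, 10)),
                                     collapse = " "))),
    "//"), gb)
  ann <- read_annotation(gb, "genbank")
  expect_identical(ann$genome$TESTREC$seq, seq60)
  expect_identical(ann$cds$gbA$seq, substr(seq60, 1, 18))
  expect_identical(ann$cds$gbB$seq,
                   periodscan::revcomp(substr(seq60, 19, 36)))
  expect_identical(ann$cds$gbC$seq,
                   paste0(substr(seq60, 37, 45), substr(seq60, 52, 60)))
  b <- ann$features[ann$features$id == "gbB", ]
  expect_identical(b$strand, "-")
})
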