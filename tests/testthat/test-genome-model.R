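test_that("the packaged organization table parses into the canonical 38-feature annotation", {
  a <- delia_annotation()
  expect_s3_class(a, "mito_annotation")
  expect_equal(nrow(a), 38L)
  expect_equal(genome_length(a), 16141L)
  expect_equal(sum(a$kind == "PCG"), 13L)
  expect_equal(sum(a$kind == "tRNA"), 22L)
  expect_equal(sum(a$kind == "rRNA"), 2L)
  expect_equal(sum(a$kind == "control_region"), 1L)
  # declared sizes all agree with the coordinate arithmetic
  expect_equal(feature_length(a$start, a$end, genome_length(a)), a$size_declared)
})

test_that("malformed organization tables are rejected with informative errors", {
  expect_error(parse_annotation_table(text = "Gene\tDirection\tLocation"),
               "no features")
  expect_error(parse_annotation_table(text = c("Gene\tDir\tLoc",
                                               "x\tF\tnot-a-range")),
               "malformed location")
  expect_error(parse_annotation_table(text = c("Gene\tDir\tLoc",
                                               "x\tZ\t1-10")),
               "direction")
})

test_that("parse and write round-trip on a small annotation", {
  a <- delia_annotation()
  lines <- write_annotation_table(a)[1:6]   # header + 5 rows
  b <- parse_annotation_table(text = lines)
  lines2 <- write_annotation_table(b)
  expect_identical(lines, lines2)
  expect_equal(b$gene, a$gene[1:5])
  expect_equal(b$start, a$start[1:5])
})

test_that("feature_length handles linear and origin-wrapping coordinates", {
  expect_equal(feature_length(1, 66, 16141), 66L)
  expect_equal(feature_length(1416, 2967, 16141), 1552L)
  expect_equal(feature_length(16140, 5, 16141), 7L)
})

test_that("intergenic_gap signs spacers, overlaps and abutments", {
  expect_equal(intergenic_gap(66, 64, 16141), -3L)
  expect_equal(intergenic_gap(6050, 6077, 16141), 26L)
  expect_equal(intergenic_gap(100, 101, 16141), 0L)
})

test_that("geometry summary recomputes the declared intergenic column", {
  a <- delia_annotation()
  g <- geometry_summary(a)
  # gap belongs to the following feature's row; closing pair comes last
  expect_equal(g$gaps$gap[-nrow(g$gaps)], a$intergenic_declared[-1])
  expect_equal(g$gaps$gap[nrow(g$gaps)], 0L)
})

test_that("a single feature covering the whole circle has no spacers or overlaps", {
  a <- mito_annotation(tibble::tibble(gene = "x", kind = "rRNA", strand = "J",
                                      start = 1L, end = 500L),
                       genome_length = 500L)
  g <- geometry_summary(a)
  expect_equal(g$n_spacers, 0L)
  expect_equal(g$n_overlaps, 0L)
})

test_that("strand tally counts genes per kind and excludes the control region", {
  a <- delia_annotation()
  st <- strand_tally(a)
  expect_equal(st$J[st$kind == "PCG"], 9L)
  expect_equal(st$J[st$kind == "tRNA"], 14L)
  expect_equal(st$N[st$kind == "PCG"], 4L)
  expect_equal(st$N[st$kind == "tRNA"], 8L)
  expect_equal(st$N[st$kind == "rRNA"], 2L)
  expect_equal(sum(st$J), 23L)
  expect_equal(sum(st$N), 14L)

  allj <- mito_annotation(tibble::tibble(
    gene = paste0("g", 1:5), kind = "tRNA", strand = "J",
    start = seq(1, 401, by = 100), end = seq(70, 470, by = 100)))
  expect_equal(sum(strand_tally(allj)$J), 5L)
  expect_equal(sum(strand_tally(allj)$N), 0L)

  set.seed(11)
  r <- random_annotation(10L)
  st <- strand_tally(r)
  expect_equal(sum(st$J) + sum(st$N), 10L)
  expect_equal(sum(st$J), sum(r$strand == "J"))
})

test_that("geometry agrees with the per-position coverage oracle", {
  set.seed(401)
  for (rep in 1:40) {
    a <- random_annotation(sample(5:20, 1))
    g <- geometry_summary(a)
    oracle <- coverage_gap_oracle(a)
    expect_equal(g$gaps$gap, oracle)
    expect_equal(g$spacer_bp, sum(oracle[oracle > 0]))
    expect_equal(g$overlap_bp, -sum(oracle[oracle < 0]))
  }
})

test_that("lengths and gaps are invariant under rotation of the origin", {
  set.seed(402)
  for (rep in 1:15) {
    a <- random_annotation(10L)
    L <- genome_length(a)
    k <- sample(L, 1)
    b <- rotate_annotation(a, k)
    expect_equal(feature_length(b$start, b$end, L),
                 feature_length(a$start, a$end, L))
    expect_equal(geometry_summary(b)$gaps$gap, geometry_summary(a)$gaps$gap)
  }
})

test_that("the GenBank flat-file reader maps sequence and features", {
  gbk <- c(
    "LOCUS       TESTREC  200 bp  DNA  circular",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "     CDS             10..60",
    "                     /gene=\"ND2\"",
    "     tRNA            complement(70..130)",
    "                     /product=\"tRNA-Gln\"",
    "     misc_feature    140..190",
    "                     /note=\"A+T rich region\"",
    "ORIGIN",
    paste("        1", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste("       61", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste("      121", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste("      181", "acgtacgtac acgtacgtac"),
    "//")
  path <- withr::local_tempfile(lines = gbk, fileext = ".gb")
  rec <- read_genbank(path)
  expect_equal(nchar(rec$sequence), 200L)
  expect_equal(substr(rec$sequence, 1, 8), "ACGTACGT")
  a <- rec$annotation
  expect_equal(nrow(a), 3L)
  expect_equal(a$gene[1:2], c("ND2", "tRNA-Gln"))
  expect_equal(a$kind, c("PCG", "tRNA", "control_region"))
  expect_equal(a$strand, c("J", "N", "J"))
  expect_equal(a$start, c(10L, 70L, 140L))
})
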