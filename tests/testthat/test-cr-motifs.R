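test_that("poly-T scanning reports maximal runs above threshold in order", {
  s <- paste0("AA", strrep("T", 37), "AA")
  h <- find_poly_t(s, min_run = 10)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$length, 37L)

  expect_equal(nrow(find_poly_t("TTT", min_run = 10)), 0L)

  s2 <- paste0("CC", strrep("T", 27), "CAC", strrep("T", 12), "G")
  h2 <- find_poly_t(s2, min_run = 10)
  expect_equal(h2$length, c(27L, 12L))
  expect_true(all(diff(h2$start) > 0))
})

test_that("N-strand poly-T hits are poly-A runs reported in J coordinates", {
  s <- paste0("GG", strrep("A", 15), "CCTT")
  h <- find_poly_t(s, min_run = 10, strand = "N")
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "N")
  expect_equal(h$start, 3L)
  expect_equal(h$end, 17L)
  # strand duality: same run found by a poly-A oracle on the J reading
  m <- gregexpr("A{10,}", s)[[1]]
  expect_equal(h$start, as.integer(m))
})

test_that("(TA)n scanning counts units phase-agnostically", {
  h <- find_ta_repeats("TATATATATA", min_units = 2)
  expect_equal(h$n, 5L)
  expect_equal(h$length, 10L)
  expect_equal(nrow(find_ta_repeats("TTTT", min_units = 2)), 0L)
  # AT-phase run: best TA frame starts one base in
  h <- find_ta_repeats("ATATATATA", min_units = 2)
  expect_equal(h$start, 2L)
  expect_equal(h$n, 4L)

  set.seed(51)
  flank1 <- random_dna(80, c(A = .3, C = .2, G = .3, T = .2))
  flank2 <- random_dna(80, c(A = .3, C = .2, G = .3, T = .2))
  s <- paste0(flank1, "C", strrep("TA", 98), "C", flank2)
  h <- find_ta_repeats(s, min_units = 10)
  expect_equal(h$n, 98L)
  expect_equal(h$start, 82L)
})

test_that("G(A)nT scanning finds every motif with its A-run count", {
  h <- find_gant("GAAAT")
  expect_equal(h$n, 3L)
  expect_equal(h$length, 5L)
  expect_equal(nrow(find_gant("GT")), 0L)

  set.seed(52)
  parts <- character(0)
  for (n in 1:5) parts <- c(parts, random_dna(20, c(A = .2, C = .4, G = .2, T = .2)),
                            "C", paste0("G", strrep("A", n), "T"), "C")
  s <- paste(parts, collapse = "")
  h <- find_gant(s, min_a = 1)
  expect_true(all(1:5 %in% h$n))
})

test_that("scanners agree with regular-expression oracles on random sequence", {
  set.seed(53)
  for (rep in 1:10) {
    s <- random_dna(2000, c(A = .35, C = .1, G = .1, T = .45))
    # poly-T oracle
    m <- gregexpr("T{6,}", s)[[1]]
    h <- find_poly_t(s, min_run = 6)
    expect_equal(h$start, if (m[1] == -1L) integer(0) else as.integer(m))
    expect_equal(h$length, if (m[1] == -1L) integer(0)
                 else as.integer(attr(m, "match.length")))
    # G(A)nT oracle
    m <- gregexpr("GA{2,}T", s)[[1]]
    h <- find_gant(s, min_a = 2)
    expect_equal(h$start, if (m[1] == -1L) integer(0) else as.integer(m))
    # (TA)n oracle: maximal TA-framed repeats
    m <- gregexpr("(?:TA){3,}", s)[[1]]
    h <- find_ta_repeats(s, min_units = 3)
    expect_equal(h$start, if (m[1] == -1L) integer(0) else as.integer(m))
    expect_equal(2L * h$n, if (m[1] == -1L) integer(0)
                 else as.integer(attr(m, "match.length")) %/% 2L * 2L)
  }
})

test_that("every reported hit is maximal", {
  set.seed(54)
  s <- random_dna(3000, c(A = .35, C = .1, G = .1, T = .45))
  chars <- strsplit(s, "")[[1]]
  h <- find_poly_t(s, min_run = 5)
  for (i in seq_len(nrow(h))) {
    if (h$start[i] > 1) expect_false(chars[h$start[i] - 1] == "T")
    if (h$end[i] < nchar(s)) expect_false(chars[h$end[i] + 1] == "T")
  }
  g <- find_gant(s, min_a = 1)
  for (i in seq_len(nrow(g))) {
    # the A-run inside G..T cannot extend: G and T delimit it by definition
    expect_equal(chars[g$start[i]], "G")
    expect_equal(chars[g$end[i]], "T")
    expect_true(all(chars[(g$start[i] + 1):(g$end[i] - 1)] == "A"))
  }
})

test_that("control-region scanning is strand-aware and needs a control region", {
  # one planted motif of each class in an otherwise C background
  cr <- paste0(strrep("C", 20), strrep("T", 14), strrep("C", 10),
               strrep("TA", 7), strrep("C", 10),
               revcomp("GAAAT"), strrep("C", 20))
  a <- cr_only_annotation(nchar(cr))
  hits <- scan_control_region(cr, a, min_polyt = 10, min_ta = 5, min_ga = 2)
  expect_equal(nrow(hits), 3L)
  expect_setequal(hits$motif, c("GAnT", "polyT", "TA_repeat"))
  expect_equal(hits$strand[hits$motif == "GAnT"], "N")
  expect_equal(hits$strand[hits$motif == "polyT"], "J")

  expect_equal(nrow(scan_control_region(strrep("C", 100),
                                        cr_only_annotation(100))), 0L)

  nocr <- mito_annotation(tibble::tibble(gene = "g", kind = "tRNA",
                                         strand = "J", start = 1L, end = 66L))
  expect_error(scan_control_region(strrep("A", 66), nocr), "no control region")

  # genomic offset: hits carry J-genome coordinates
  genome <- paste0(strrep("G", 50), cr)
  a2 <- cr_only_annotation(nchar(cr), offset = 50L)
  h2 <- scan_control_region(genome, a2, min_polyt = 10, min_ta = 5, min_ga = 2)
  expect_equal(h2$start[h2$motif == "polyT"], 50L + 21L)
})
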