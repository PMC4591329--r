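test_that("base counting tallies unambiguous and ambiguous bases", {
  bc <- base_counts("AATT")
  expect_equal(c(bc$a, bc$t, bc$c, bc$g), c(2L, 2L, 0L, 0L))
  bc <- base_counts("ACGTN")
  expect_equal(bc$ambiguous, 1L)
  expect_equal(bc$total, 4L)
  expect_error(base_counts(""), "empty")
  expect_error(base_counts("ACGX"), "invalid")

  set.seed(5)
  s <- random_dna(1000)
  chars <- strsplit(s, "")[[1]]
  bc <- base_counts(s)
  expect_equal(bc$a, sum(chars == "A"))
  expect_equal(bc$t, sum(chars == "T"))
  expect_equal(bc$g, sum(chars == "G"))
  expect_equal(bc$c, sum(chars == "C"))
})

test_that("skew formulas reproduce published whole-genome values at 3 decimals", {
  expect_equal(round_half_up(at_skew(39.6, 38.9), 3), 0.009)
  expect_equal(round_half_up(gc_skew(8.9, 12.6), 3), -0.172)
})

test_that("skews are symmetric, bounded and scale-invariant", {
  for (x in c(0.1, 1, 42)) expect_equal(at_skew(x, x), 0)
  expect_equal(at_skew(3, 0), 1)
  expect_equal(gc_skew(0, 5), -1)
  expect_true(is.na(at_skew(0, 0)))
  set.seed(6)
  for (rep in 1:50) {
    a <- runif(1, 0, 100); t <- runif(1, 0, 100); c <- runif(1, 1e-6, 1)
    expect_equal(at_skew(c * a, c * t), at_skew(a, t))
  }
})

test_that("composition summaries are internally consistent", {
  set.seed(7)
  s <- random_dna(500, c(A = .4, C = .1, G = .1, T = .4))
  cs <- composition_summary(s)
  expect_equal(cs$pct_a + cs$pct_c + cs$pct_g + cs$pct_t, 100)
  expect_equal(cs$at_skew * (cs$pct_a + cs$pct_t), cs$pct_a - cs$pct_t)
  f <- format_composition(cs)
  expect_lte(abs(f$pct_a + f$pct_c + f$pct_g + f$pct_t - 100), 0.2)
})

test_that("reverse complement negates both skews and preserves A+T", {
  set.seed(8)
  for (rep in 1:100) {
    s <- random_dna(sample(50:400, 1), c(A = .35, C = .1, G = .15, T = .4))
    cs <- composition_summary(s)
    cr <- composition_summary(revcomp(s))
    expect_equal(cr$at_skew, -cs$at_skew)
    expect_equal(cr$gc_skew, -cs$gc_skew)
    expect_equal(cr$pct_at, cs$pct_at)
  }
})

test_that("whole-genome counts equal the sum over a disjoint partition", {
  set.seed(9)
  s <- random_dna(997)
  cuts <- sort(sample(2:996, 7))
  bounds <- cbind(c(1, cuts), c(cuts - 1, 997))
  parts <- apply(bounds, 1, function(b) substr(s, b[1], b[2]))
  whole <- base_counts(s)
  acc <- lapply(parts, base_counts)
  expect_equal(whole$a, sum(vapply(acc, function(x) x$a, 0L)))
  expect_equal(whole$t, sum(vapply(acc, function(x) x$t, 0L)))
  expect_equal(whole$total, sum(vapply(acc, function(x) x$total, 0L)))
})

test_that("class composition uses the sense strand and errors on empty classes", {
  set.seed(10)
  g <- random_dna(300, c(A = .4, C = .1, G = .1, T = .4))
  a <- mito_annotation(tibble::tibble(
    gene = c("j1", "n1"), kind = c("tRNA", "tRNA"), strand = c("J", "N"),
    start = c(11L, 101L), end = c(80L, 180L)), genome_length = 300L)
  # single-feature class on J is just the raw subsequence
  expect_equal(class_composition(g, a, strand = "J"),
               composition_summary(substr(g, 11, 80)))
  # N-strand class is the reverse complement of its J-strand slice
  expect_equal(class_composition(g, a, strand = "N"),
               composition_summary(revcomp(substr(g, 101, 180))))
  expect_error(class_composition(g, a, kind = "PCG"), "no features match")
})

test_that("codon-position composition pools in-frame positions", {
  cp <- codon_position_composition("ATGATGATG")
  expect_equal(cp$pct_a, c(100, 0, 0))
  expect_equal(cp$pct_t, c(0, 100, 0))
  expect_equal(cp$pct_g, c(0, 0, 100))

  set.seed(12)
  seqs <- vapply(1:5, function(i) random_dna(3 * sample(10:40, 1)), "")
  cp <- codon_position_composition(seqs)
  # independent stride-3 oracle
  pooled <- lapply(1:3, function(k) {
    paste(vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      paste(chars[seq(k, length(chars), by = 3)], collapse = "")
    }, ""), collapse = "")
  })
  for (k in 1:3)
    expect_equal(cp[k, -1], composition_summary(pooled[[k]]), ignore_attr = TRUE)
  expect_warning(codon_position_composition(c("ATGATG", "AT")), "skipped")
})
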