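test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_codons(c("ATT", "TTA", "TAA")), c("I", "L", "*"))
  expect_equal(translate_codons("AGA"), "S")
  expect_equal(translate_codons("TGA"), "W")
  expect_equal(translate_codons("ATA"), "M")
  expect_equal(translate_codons("NNA"), "X")
  code <- mito_genetic_code()
  expect_length(code, 64L)
  expect_equal(sort(names(code)[code == "*"]), c("TAA", "TAG"))
})

test_that("codon extraction honours start and stop conventions", {
  expect_equal(extract_codons("ATGTTTTAA"), c("ATG", "TTT", "TAA"))

  # complete-stop gene: 3-nt start kept as a codon, stop kept as a codon
  set.seed(21)
  body <- replicate(337, random_dna(3))
  body <- ifelse(body %in% c("TAA", "TAG"), "AAA", body)
  cds <- paste0("ATT", paste(body, collapse = ""), "TAA")
  expect_equal(nchar(cds), 1017L)
  cod <- extract_codons(cds, "ATT", "TAA", gene = "ND2-like")
  expect_length(cod, 339L)
  expect_equal(cod[1], "ATT")
  expect_equal(cod[339], "TAA")

  # quadruplet start: consumed whole, excluded from the codon stream
  body4 <- replicate(515, random_dna(3))
  body4 <- ifelse(body4 %in% c("TAA", "TAG"), "AAA", body4)
  cds4 <- paste0("ATCA", paste(body4, collapse = ""), "TAA")
  expect_equal(nchar(cds4), 1552L)
  cod4 <- extract_codons(cds4, "ATCA", "TAA", gene = "COI-like")
  expect_length(cod4, 516L)
  expect_false(cod4[1] == "ATCA")

  # incomplete stop is stripped and excluded
  cds_t <- paste0("ATG", "TTTAAACCC", "T")
  expect_equal(extract_codons(cds_t, "ATG", "T"), c("ATG", "TTT", "AAA", "CCC"))
})

test_that("codon extraction errors and warnings name the offending gene", {
  expect_error(extract_codons("ATGAAA", "ATT", gene = "g1"), "g1.*not a prefix")
  expect_error(extract_codons("ATGAAA", "ATG", "TA", gene = "g2"),
               "g2.*does not terminate")
  # length not divisible by three after stop handling: truncated, not fatal
  expect_warning(out <- extract_codons(paste0("ATG", "AAAC", "TA"), "ATG", "TA",
                                       gene = "ND4-like"),
                 "ND4-like.*not divisible")
  expect_equal(out, c("ATG", "AAA"))
})

test_that("RSCU matches the definition and its family-sum identity", {
  counts <- codon_counts(character(0))
  counts[c("TTA", "TTG", "CTT")] <- c(8L, 2L, 2L)
  r <- rscu(counts)
  expect_equal(r$rscu[r$codon == "UUA"], 8 * 6 / 12)
  expect_equal(r$rscu[r$codon == "UUG"], 2 * 6 / 12)
  # never-observed families are undefined, not zero
  expect_true(all(is.na(r$rscu[r$aa == "C"])))

  # uniform usage within a family gives RSCU 1 everywhere in it
  counts <- codon_counts(character(0))
  counts[c("GGT", "GGC", "GGA", "GGG")] <- 5L
  r <- rscu(counts)
  expect_equal(r$rscu[r$aa == "G"], rep(1, 4))

  set.seed(22)
  for (rep in 1:20) {
    counts <- setNames(as.integer(rpois(64, 8)), names(codon_counts(character(0))))
    r <- rscu(counts)
    sums <- tapply(r$rscu, r$aa, sum)
    sizes <- tapply(r$rscu, r$aa, length)
    observed <- tapply(r$count, r$aa, sum) > 0
    expect_equal(unname(sums[observed]), unname(sizes[observed]))
    # scale invariance
    r3 <- rscu(counts * 3L)
    expect_equal(r3$rscu, r$rscu)
  }
})

test_that("amino-acid composition excludes stops and matches a direct tally", {
  aa <- aa_composition("TTA")
  expect_equal(aa$percent[aa$aa3 == "Leu"], 100)

  set.seed(23)
  codons <- sample(names(codon_counts(character(0))), 600, replace = TRUE)
  aa <- aa_composition(codons)
  res <- translate_codons(codons)
  res <- res[res != "*"]
  direct <- table(res)
  for (k in names(direct))
    expect_equal(aa$count[aa$aa == k], as.integer(direct[[k]]))
  expect_equal(sum(aa$percent), 100)
  expect_lte(abs(sum(round_half_up(aa$percent, 2)) - 100), 0.2)
  expect_error(aa_composition(c("TAA", "TAG")), "no non-stop")
})

test_that("translation of extracted codons recovers the residues a gene was built from", {
  set.seed(24)
  sense <- c("ATG", sample(setdiff(names(codon_counts(character(0))),
                                   c("TAA", "TAG")), 50, replace = TRUE), "TAA")
  cds <- paste(sense, collapse = "")
  out <- translate_codons(extract_codons(cds, "ATG", "TAA"))
  expect_equal(out, translate_codons(sense))
})
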