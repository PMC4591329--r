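# Codon extraction, invertebrate-mitochondrial translation, RSCU and
# amino-acid composition.

#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Differs from the standard code at AGA/AGG (Ser), AUA (Met) and UGA (Trp);
#' the stop family is UAA/UAG only.
#'
#' @return named character vector mapping the 64 DNA codons to one-letter
#'   amino acids (`"*"` for stop).
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("5")
  structure(as.character(code), names = names(code))
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

dna2rna <- function(x) gsub("T", "U", x, fixed = TRUE)

#' Split a coding sequence into codons under mitogenome conventions
#'
#' The declared start codon must be a prefix of the sequence.  A 4-nt start
#' (e.g. the quadruplet `ATCA` seen at dipteran COI) is consumed whole and
#' excluded from codon statistics; ordinary 3-nt starts are kept as the first
#' codon.  Incomplete terminal stops (`T` or `TA`, completed to UAA by
#' polyadenylation) are stripped and excluded; complete stops remain as the
#' final codon.  If the remaining length is not a multiple of three the final
#' partial codon is dropped with a warning naming the gene, so one
#' inconsistently annotated gene cannot stall a whole-genome run.
#'
#' @param cds sense-strand coding sequence (DNA or RNA alphabet).
#' @param start_codon declared start (3 or 4 nt); `NULL`/`NA` to skip the
#'   prefix check and read from position 1.
#' @param stop_codon declared stop (`"TAA"`, `"TAG"`, `"TA"`, `"T"`);
#'   `NULL`/`NA` for none.
#' @param gene gene name used in messages.
#' @return character vector of 3-nt DNA codons.
#' @export
extract_codons <- function(cds, start_codon = NULL, stop_codon = NULL,
                           gene = "cds") {
  s <- normalize_seq(cds)
  if (!is.null(start_codon) && !is.na(start_codon)) {
    sc <- normalize_seq(start_codon)
    if (substr(s, 1L, nchar(sc)) != sc)
      stop(sprintf("%s: declared start codon %s is not a prefix of the sequence",
                   gene, start_codon))
    if (nchar(sc) == 4L) s <- substr(s, 5L, nchar(s))
    else if (nchar(sc) != 3L)
      stop(sprintf("%s: start codon must have 3 or 4 nt", gene))
  }
  if (!is.null(stop_codon) && !is.na(stop_codon)) {
    tc <- normalize_seq(stop_codon)
    if (nchar(tc) %in% 1:2) {
      if (substr(s, nchar(s) - nchar(tc) + 1L, nchar(s)) != tc)
        stop(sprintf("%s: declared incomplete stop %s does not terminate the sequence",
                     gene, stop_codon))
      s <- substr(s, 1L, nchar(s) - nchar(tc))
    } else if (nchar(tc) == 3L) {
      if (substr(s, nchar(s) - 2L, nchar(s)) != tc)
        stop(sprintf("%s: declared stop %s does not terminate the sequence",
                     gene, stop_codon))
    } else stop(sprintf("%s: stop codon must have 1-3 nt", gene))
  }
  rem <- nchar(s) %% 3L
  if (rem != 0L) {
    warning(sprintf("%s: length %d not divisible by 3; final %d nt dropped",
                    gene, nchar(s), rem))
    s <- substr(s, 1L, nchar(s) - rem)
  }
  if (!nzchar(s)) return(character(0))
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Translate codons under the invertebrate mitochondrial code
#'
#' @param codons character vector of 3-nt codons (DNA or RNA).
#' @param code genetic code as from [mito_genetic_code()].
#' @return character vector of one-letter residues; `"*"` for stop, `"X"`
#'   for codons containing ambiguity codes.
#' @export
translate_codons <- function(codons, code = mito_genetic_code()) {
  codons <- normalize_seq(codons)
  out <- unname(code[codons])
  out[is.na(out)] <- "X"
  out
}

#' Tally codons over the full 64-codon table
#'
#' @param codons character vector of 3-nt codons (DNA or RNA alphabet);
#'   codons with ambiguity codes are dropped.
#' @return named integer vector of length 64 (DNA codon names).
#' @export
codon_counts <- function(codons) {
  codons <- normalize_seq(codons)
  codons <- codons[codons %in% ALL_CODONS]
  counts <- table(factor(codons, levels = ALL_CODONS))
  setNames(as.integer(counts), ALL_CODONS)
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * k / sum(family counts)` where `k` is the size of
#' the codon's synonymous family under the genetic code; the two stop codons
#' (UAA/UAG under table 5) form their own family.  Within every family with
#' at least one observation the RSCU values sum to the family size; families
#' never observed get `NA`, not 0.
#'
#' @param counts named per-codon counts as from [codon_counts()], or a
#'   character vector of codons which is tallied first.
#' @param code genetic code as from [mito_genetic_code()].
#' @return tibble: `codon` (RNA alphabet), `codon_dna`, `aa` (one-letter),
#'   `count`, `rscu`.
#' @export
rscu <- function(counts, code = mito_genetic_code()) {
  if (is.character(counts) && is.null(names(counts))) counts <- codon_counts(counts)
  counts <- counts[ALL_CODONS]
  if (any(is.na(counts))) stop("counts must cover all 64 codons (see codon_counts)")
  if (any(counts < 0)) stop("counts must be non-negative")
  aa <- unname(code[ALL_CODONS])
  fam_size <- ave(rep(1L, 64L), aa, FUN = sum)
  fam_sum <- ave(as.numeric(counts), aa, FUN = sum)
  val <- ifelse(fam_sum > 0, as.numeric(counts) * fam_size / fam_sum, NA_real_)
  tibble(codon = dna2rna(ALL_CODONS), codon_dna = ALL_CODONS, aa = aa,
         count = as.integer(counts), rscu = val)
}

#' Amino-acid composition of a codon set
#'
#' Stop codons are excluded from the denominator; codons with ambiguity
#' codes are dropped.
#'
#' @param codons character vector of codons, or named 64-codon counts.
#' @param code genetic code as from [mito_genetic_code()].
#' @return tibble: `aa` (one-letter), `aa3` (three-letter), `count`,
#'   `percent` (of all residues, summing to 100).
#' @export
aa_composition <- function(codons, code = mito_genetic_code()) {
  counts <- if (is.character(codons) && is.null(names(codons)))
    codon_counts(codons) else codons[ALL_CODONS]
  aa <- unname(code[ALL_CODONS])
  keep <- aa != "*"
  per_aa <- tapply(as.numeric(counts[keep]), aa[keep], sum)
  total <- sum(per_aa)
  if (total == 0) stop("no non-stop codons")
  aas <- names(AA3)
  tibble(aa = aas, aa3 = unname(AA3[aas]),
         count = as.integer(per_aa[aas]),
         percent = 100 * as.numeric(per_aa[aas]) / total)
}

#' Collect sense-strand coding sequences of the protein-coding genes
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()].
#' @param strand optional filter, `"J"` or `"N"`.
#' @return tibble: `gene`, `strand`, `cds` (sense strand), `start_codon`,
#'   `stop_codon`.
#' @export
pcg_set <- function(genome, a, strand = NULL) {
  stopifnot(inherits(a, "mito_annotation"))
  sel <- a$kind == "PCG"
  if (!is.null(strand)) sel <- sel & a$strand %in% strand
  if (!any(sel)) stop("no protein-coding genes match the filter")
  p <- a[sel, ]
  tibble(gene = p$gene, strand = p$strand,
         cds = mapply(feature_seq, start = p$start, end = p$end,
                      strand = p$strand, MoreArgs = list(genome = genome)),
         start_codon = p$start_codon, stop_codon = p$stop_codon)
}

#' Codon usage and amino-acid composition of a genome's PCGs
#'
#' Runs [pcg_set()], [extract_codons()], [rscu()] and [aa_composition()] in
#' one call.
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()].
#' @param strand optional strand filter for the PCG class.
#' @return list with `codons` (pooled codon vector), `rscu` and `aa`
#'   tibbles, and `n_codons`.
#' @export
codon_usage_table <- function(genome, a, strand = NULL) {
  codons <- pooled_codons(pcg_set(genome, a, strand = strand))
  list(codons = codons,
       rscu = rscu(codon_counts(codons)),
       aa = aa_composition(codons),
       n_codons = length(codons))
}
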