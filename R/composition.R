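# Nucleotide composition and strand-asymmetry (skew) statistics.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

normalize_seq <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

#' Count bases in a nucleotide sequence
#'
#' `U` is counted as `T`; IUPAC ambiguity codes are tallied separately and
#' excluded from every composition statistic.
#'
#' @param s a character string over the IUPAC nucleotide alphabet.
#' @return a `base_counts` list with elements `a`, `c`, `g`, `t`,
#'   `ambiguous` and `total` (unambiguous total).
#' @export
base_counts <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(normalize_seq(s), "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", IUPAC_AMBIG)
  if (any(bad))
    stop("invalid characters in sequence: ", paste(unique(chars[bad]), collapse = ""))
  structure(list(a = sum(chars == "A"), c = sum(chars == "C"),
                 g = sum(chars == "G"), t = sum(chars == "T"),
                 ambiguous = sum(chars %in% IUPAC_AMBIG),
                 total = sum(!chars %in% IUPAC_AMBIG)),
            class = "base_counts")
}

add_base_counts <- function(x, y) {
  structure(list(a = x$a + y$a, c = x$c + y$c, g = x$g + y$g, t = x$t + y$t,
                 ambiguous = x$ambiguous + y$ambiguous,
                 total = x$total + y$total), class = "base_counts")
}

#' AT and GC skew
#'
#' `at_skew(A, T) = (A - T) / (A + T)` and
#' `gc_skew(G, C) = (G - C) / (G + C)`; both are scale-invariant, so raw
#' counts and percentages give the same value.  When the denominator is zero
#' the skew is undefined and `NA` is returned.
#'
#' @param a,t,g,c counts or percentages of the respective bases (vectorized).
#' @return numeric skew values in `[-1, 1]`.
#' @export
at_skew <- function(a, t) {
  ifelse(a + t > 0, (a - t) / (a + t), NA_real_)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  ifelse(g + c > 0, (g - c) / (g + c), NA_real_)
}

#' Composition summary of a sequence or base counts
#'
#' @param x a nucleotide string or a [base_counts()] object.
#' @return one-row tibble: `n` (unambiguous bases), `pct_t`, `pct_c`,
#'   `pct_a`, `pct_g`, `pct_at`, `pct_gc`, `at_skew`, `gc_skew`.  Values are
#'   carried at full precision; see [format_composition()] for table-style
#'   rounding.
#' @export
composition_summary <- function(x) {
  bc <- if (inherits(x, "base_counts")) x else base_counts(x)
  if (bc$total == 0L) stop("no unambiguous bases")
  p <- function(n) 100 * n / bc$total
  tibble(n = bc$total,
         pct_t = p(bc$t), pct_c = p(bc$c), pct_a = p(bc$a), pct_g = p(bc$g),
         pct_at = p(bc$a + bc$t), pct_gc = p(bc$g + bc$c),
         at_skew = at_skew(bc$a, bc$t), gc_skew = gc_skew(bc$g, bc$c))
}

#' Round half away from zero
#'
#' Organization/composition tables round half-up (2.5 -> 2.6 at one
#' decimal), unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a composition summary at reporting precision
#'
#' Percentages at 1 decimal, skews at `skew_digits` decimals (2 in
#' class-composition tables, 3 in cross-genome skew tables), half-up.
#'
#' @param cs a tibble from [composition_summary()] (any number of rows).
#' @param skew_digits decimals for the skew columns.
#' @return the tibble with rounded values.
#' @export
format_composition <- function(cs, skew_digits = 2) {
  pct <- grep("^pct_", names(cs), value = TRUE)
  for (col in pct) cs[[col]] <- round_half_up(cs[[col]], 1)
  for (col in c("at_skew", "gc_skew"))
    if (col %in% names(cs)) cs[[col]] <- round_half_up(cs[[col]], skew_digits)
  cs
}

#' Reverse complement of a DNA string
#' @param s character string over the IUPAC alphabet (`U` accepted as `T`).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(normalize_seq(s))))
}

#' Extract a feature's sense-strand sequence
#'
#' Substring of the circular J-strand genome; features with `end < start`
#' wrap the origin.  `N`-strand features are reverse-complemented so the
#' returned string is the feature's reading (sense) strand.
#'
#' @param genome J-strand genome sequence (character string).
#' @param start,end 1-based inclusive J-strand coordinates.
#' @param strand `"J"` or `"N"`.
#' @return sense-strand sequence.
#' @export
feature_seq <- function(genome, start, end, strand = "J") {
  L <- nchar(genome)
  if (start > L || end > L) stop("feature coordinates exceed the genome")
  s <- if (end >= start) substr(genome, start, end)
       else paste0(substr(genome, start, L), substr(genome, 1L, end))
  if (strand == "N") revcomp(s) else toupper(s)
}

#' Composition of a feature class
#'
#' Concatenates the sense-strand sequence of every feature selected by
#' `kind`/`strand` and summarizes it.  This is the reading-strand convention:
#' it is what makes N-strand gene classes differ from J-strand classes even
#' though both live on one circular duplex.  Nucleotides inside overlapping
#' features are counted once per feature.
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()].
#' @param kind optional filter: one or more of `PCG`, `tRNA`, `rRNA`,
#'   `control_region`.
#' @param strand optional filter: `"J"` or `"N"`.
#' @return one-row tibble as [composition_summary()].
#' @export
class_composition <- function(genome, a, kind = NULL, strand = NULL) {
  stopifnot(inherits(a, "mito_annotation"))
  sel <- rep(TRUE, nrow(a))
  if (!is.null(kind)) sel <- sel & a$kind %in% kind
  if (!is.null(strand)) sel <- sel & a$strand %in% strand
  if (!any(sel))
    stop(sprintf("no features match filter kind=%s, strand=%s",
                 paste(kind %||% "*", collapse = "/"), strand %||% "*"))
  seqs <- mapply(feature_seq, start = a$start[sel], end = a$end[sel],
                 strand = a$strand[sel], MoreArgs = list(genome = genome))
  composition_summary(paste(seqs, collapse = ""))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Per-codon-position composition of protein-coding genes
#'
#' Pools the codons of all input genes (after start/stop handling by
#' [extract_codons()]) and summarizes each of the three codon positions.
#' Sequences shorter than one codon are skipped with a warning.
#'
#' @param pcgs a tibble as returned by [pcg_set()] (columns `gene`, `cds`,
#'   `start_codon`, `stop_codon`), or a plain character vector of in-frame
#'   coding sequences.
#' @return three-row tibble with a `position` column plus the
#'   [composition_summary()] columns.
#' @export
codon_position_composition <- function(pcgs) {
  codons <- pooled_codons(pcgs)
  if (length(codons) == 0L) stop("no codons in input")
  out <- lapply(1:3, function(pos) {
    cbind(tibble(position = pos),
          composition_summary(paste(substr(codons, pos, pos), collapse = "")))
  })
  as_tibble(do.call(rbind, out))
}

pooled_codons <- function(pcgs) {
  if (is.character(pcgs)) {
    pcgs <- tibble(gene = paste0("seq", seq_along(pcgs)), cds = pcgs,
                   start_codon = NA_character_, stop_codon = NA_character_)
  }
  codons <- character(0)
  for (i in seq_len(nrow(pcgs))) {
    if (nchar(pcgs$cds[i]) < 3L) {
      warning(sprintf("%s: sequence shorter than one codon, skipped", pcgs$gene[i]))
      next
    }
    codons <- c(codons,
                extract_codons(pcgs$cds[i],
                               start_codon = pcgs$start_codon[i],
                               stop_codon = pcgs$stop_codon[i],
                               gene = pcgs$gene[i]))
  }
  codons
}

#' Table-2 style composition table
#'
#' Assembles the classic feature-class composition table: whole genome,
#' protein-coding genes (pooled and per strand, each with first/second/third
#' codon-position rows), tRNA genes (pooled and per strand), rRNA genes, and
#' the control region.  Classes absent from the annotation are skipped.
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()].
#' @return tibble with a `feature` label column plus the
#'   [composition_summary()] columns (full precision; see
#'   [format_composition()]).
#' @export
composition_table <- function(genome, a) {
  rows <- list()
  push <- function(label, cs) {
    rows[[length(rows) + 1L]] <<- cbind(tibble(feature = label), cs)
  }
  push("Whole genome", composition_summary(genome))
  pcg_block <- function(label, strand) {
    cls <- try(class_composition(genome, a, kind = "PCG", strand = strand),
               silent = TRUE)
    if (inherits(cls, "try-error")) return(invisible(NULL))
    push(label, cls)
    pos <- codon_position_composition(pcg_set(genome, a, strand = strand))
    lab <- c("First codon position", "Second codon position", "Third codon position")
    for (k in 1:3) push(paste0(label, ": ", lab[k]), pos[k, -1])
  }
  pcg_block("Protein-coding genes", NULL)
  pcg_block("Protein-coding genes-J", "J")
  pcg_block("Protein-coding genes-N", "N")
  for (cls in list(list("tRNA genes", "tRNA", NULL),
                   list("tRNA genes-J", "tRNA", "J"),
                   list("tRNA genes-N", "tRNA", "N"),
                   list("rRNA genes", "rRNA", NULL),
                   list("Control region", "control_region", NULL))) {
    csum <- try(class_composition(genome, a, kind = cls[[2]], strand = cls[[3]]),
                silent = TRUE)
    if (!inherits(csum, "try-error")) push(cls[[1]], csum)
  }
  as_tibble(do.call(rbind, rows))
}
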