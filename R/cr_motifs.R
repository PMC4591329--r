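# Control-region structural-element scanners: poly-T stretches, (TA)n
# repeats and G(A)nT motifs, strand-aware.

motif_hits <- function(motif = character(0), strand = character(0),
                       start = integer(0), end = integer(0),
                       n = integer(0)) {
  tibble(motif = motif, strand = strand, start = as.integer(start),
         end = as.integer(end), length = as.integer(end - start + 1L),
         n = as.integer(n))
}

# map hit coordinates found on the reverse complement back to the forward
# frame of a sequence of length L
flip_coords <- function(start, end, L) {
  list(start = L - end + 1L, end = L - start + 1L)
}

regex_hits <- function(s, pattern) {
  m <- gregexpr(pattern, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(start = integer(0), end = integer(0)))
  list(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Find poly-T stretches
#'
#' Maximal runs of `T` of at least `min_run` bp, read on the requested
#' strand.  Hits found on the `N` strand (i.e. poly-A runs of the forward
#' string) are reported in forward (`J`) coordinates with a strand flag, so
#' all hits share one coordinate system.
#'
#' @param s nucleotide sequence (the J-strand reading).
#' @param min_run minimum run length in bp (>= 1).
#' @param strand `"J"` or `"N"`: which strand's reading to scan.
#' @return tibble of motif hits (`motif`, `strand`, `start`, `end`,
#'   `length`, `n`); for poly-T, `n` equals the run length.
#' @export
find_poly_t <- function(s, min_run = 10L, strand = "J") {
  stopifnot(min_run >= 1L, strand %in% c("J", "N"))
  s <- normalize_seq(s)
  scan <- if (strand == "N") revcomp(s) else s
  h <- regex_hits(scan, sprintf("T{%d,}", min_run))
  if (strand == "N" && length(h$start)) {
    fc <- flip_coords(h$start, h$end, nchar(s))
    h <- list(start = fc$start, end = fc$end)
  }
  o <- order(h$start)
  motif_hits(rep("polyT", length(h$start)), rep(strand, length(h$start)),
             h$start[o], h$end[o], (h$end - h$start + 1L)[o])
}

#' Find (TA)n tandem repeats
#'
#' Maximal TA-periodic runs with at least `min_units` TA units.  The scan is
#' phase-agnostic: a run entering in AT phase is reported with the TA frame
#' that maximizes the unit count, and `n = floor(run length / 2)` within
#' that frame (hit length is exactly `2n`).
#'
#' @param s nucleotide sequence.
#' @param min_units minimum number of TA units (>= 2).
#' @return tibble of motif hits with `n` = number of TA units.
#' @export
find_ta_repeats <- function(s, min_units = 5L) {
  stopifnot(min_units >= 2L)
  s <- normalize_seq(s)
  # maximal alternating A/T runs (no AA or TT inside), scanned directly:
  # phase handling is simpler than with a regex
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (chars[i] %in% c("A", "T")) {
      j <- i
      while (j < L && chars[j + 1L] %in% c("A", "T") && chars[j + 1L] != chars[j])
        j <- j + 1L
      if (j > i) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- motif_hits()
  for (r in runs) {
    a <- r[1]; b <- r[2]
    if (chars[a] == "A") a <- a + 1L            # enter TA frame
    n <- (b - a + 1L) %/% 2L
    if (n >= min_units)
      out <- rbind(out, motif_hits("TA_repeat", "J", a, a + 2L * n - 1L, n))
  }
  out[order(out$start), ]
}

#' Find G(A)nT motifs
#'
#' Every occurrence of `G` followed by a maximal run of at least `min_a`
#' `A`s followed by `T`; `n` is the number of `A`s (hit length `n + 2`).
#' Hits never overlap within their G..T span.
#'
#' @param s nucleotide sequence.
#' @param min_a minimum A-run length (>= 1).
#' @return tibble of motif hits with `n` = A-run length.
#' @export
find_gant <- function(s, min_a = 1L) {
  stopifnot(min_a >= 1L)
  s <- normalize_seq(s)
  h <- regex_hits(s, sprintf("GA{%d,}T", min_a))
  motif_hits(rep("GAnT", length(h$start)), rep("J", length(h$start)),
             h$start, h$end, (h$end - h$start + 1L) - 2L)
}

#' Scan the annotated control region for structural elements
#'
#' Extracts the control-region sequence and runs all three scanners.
#' Poly-T and G(A)nT are scanned on both strand readings; (TA)n runs are
#' their own reverse complement, so they are scanned once and reported on
#' `J`.  All hits are reported in J-strand genomic coordinates with a
#' strand flag.
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()] containing a `control_region` feature.
#' @param min_polyt,min_ta,min_ga detection thresholds (see the individual
#'   scanners); defaults 10 bp, 5 units and 1 A.
#' @return tibble of motif hits sorted by genomic start.
#' @export
scan_control_region <- function(genome, a, min_polyt = 10L, min_ta = 5L,
                                min_ga = 1L) {
  stopifnot(inherits(a, "mito_annotation"))
  cr <- a[a$kind == "control_region", ]
  if (nrow(cr) == 0L) stop("no control region annotated")
  cr <- cr[1L, ]
  s <- feature_seq(genome, cr$start, cr$end, "J")
  M <- nchar(s)
  Lg <- genome_length(a)
  rc <- revcomp(s)

  hits <- rbind(
    find_poly_t(s, min_polyt, strand = "J"),
    find_poly_t(s, min_polyt, strand = "N"),
    find_ta_repeats(s, min_ta),
    find_gant(s, min_ga),
    local({
      h <- find_gant(rc, min_ga)
      if (nrow(h)) {
        fc <- flip_coords(h$start, h$end, M)
        h$start <- fc$start; h$end <- fc$end; h$strand <- "N"
        h[order(h$start), ]
      } else h
    }))
  if (nrow(hits)) {
    # CR-local to circular genomic J coordinates
    hits$start <- as.integer((cr$start + hits$start - 2L) %% Lg + 1L)
    hits$end <- as.integer((cr$start + hits$end - 2L) %% Lg + 1L)
    hits <- hits[order(hits$start, hits$motif), ]
  }
  hits
}
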