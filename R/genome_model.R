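# Data model and geometry statistics for circular mitogenome annotations.

KINDS <- c("PCG", "tRNA", "rRNA", "control_region")

#' Construct a mitogenome annotation
#'
#' An annotation is a tibble of features in genomic (storage) order with one
#' row per feature and a `genome_length` attribute.  Coordinates are 1-based
#' inclusive on the J strand; a feature with `end < start` wraps the origin
#' of the circular molecule.
#'
#' @param features a data frame with columns `gene`, `kind` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control_region`), `strand` (`"J"` or `"N"`), `start`,
#'   `end`, and optionally `size_declared`, `anticodon_start`,
#'   `anticodon_end`, `anticodon`, `start_codon`, `stop_codon`,
#'   `intergenic_declared`.
#' @param genome_length total length of the circular molecule in bp; defaults
#'   to the maximum `end` coordinate (valid when the final feature abuts the
#'   origin, as in the canonical dipteran gene order).
#' @return a `mito_annotation` tibble.
#' @export
mito_annotation <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) stop("no features")
  req <- c("gene", "kind", "strand", "start", "end")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  opt <- c("size_declared", "anticodon_start", "anticodon_end", "anticodon",
           "start_codon", "stop_codon", "intergenic_declared")
  for (col in opt) {
    if (!col %in% names(features)) {
      features[[col]] <- if (col %in% c("anticodon", "start_codon", "stop_codon"))
        NA_character_ else NA_integer_
    }
  }
  features <- as_tibble(features[, c(req, opt)])
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- !features$kind %in% KINDS
  if (any(bad)) stop("unknown feature kind: ", paste(unique(features$kind[bad]), collapse = ", "))
  if (!all(features$strand %in% c("J", "N")))
    stop("strand must be 'J' or 'N'")
  if (any(features$start < 1L) || any(features$end < 1L))
    stop("coordinates must be >= 1")
  if (is.null(genome_length)) genome_length <- max(features$end)
  genome_length <- as.integer(genome_length)
  if (any(features$start > genome_length) || any(features$end > genome_length))
    stop("feature coordinates exceed genome_length")
  ac <- !is.na(features$anticodon_start)
  if (any(ac)) {
    inside <- mapply(function(s, e, a1, a2) {
      pos_in_feature(a1, s, e, genome_length) && pos_in_feature(a2, s, e, genome_length)
    }, features$start[ac], features$end[ac],
       features$anticodon_start[ac], features$anticodon_end[ac])
    if (!all(inside)) stop("anticodon span outside its feature")
  }
  structure(features,
            genome_length = genome_length,
            class = c("mito_annotation", class(features)))
}

pos_in_feature <- function(p, start, end, genome_length) {
  if (end >= start) p >= start && p <= end
  else p >= start || p <= end   # wraps the origin
}

#' Genome length of an annotation
#' @param a a `mito_annotation`.
#' @return integer length in bp.
#' @export
genome_length <- function(a) attr(a, "genome_length")

infer_kind <- function(gene) {
  ifelse(grepl("^tRNA", gene, ignore.case = TRUE), "tRNA",
  ifelse(grepl("rRNA|^12S|^16S", gene, ignore.case = TRUE), "rRNA",
  ifelse(grepl("control|D-?loop|A\\+T", gene, ignore.case = TRUE), "control_region",
         "PCG")))
}

#' Parse a gene-organization table
#'
#' Reads the tab-separated dialect used by mitogenome organization tables:
#' columns `Gene`, `Direction` (`F`/`R`, blank allowed for the control
#' region), `Location` (`"a-b"`, en dash accepted), `Size`, `Anticodon`
#' (`"p-qXXX"`), `Start`, `Stop`, `Intergenic`.  The `Size` and `Intergenic`
#' columns are retained for cross-validation but recomputed values (via
#' [feature_length()] and [geometry_summary()]) take precedence.
#'
#' @param file path to a TSV file, or a character vector of lines via `text`.
#' @param text optional character scalar/vector holding the table itself.
#' @return a [mito_annotation()].
#' @export
parse_annotation_table <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("no features: empty annotation table")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!grepl("gene", header[[1]], ignore.case = TRUE))
    stop("annotation table must have a header row starting with 'Gene'")
  body <- lines[-1]
  if (length(body) == 0L) stop("no features: annotation table has a header but no rows")
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    length(f) <- 8L          # pad short rows with NA
    f[is.na(f)] <- ""
    f <- trimws(f)
    gene <- f[[1]]
    dir <- f[[2]]
    if (!dir %in% c("F", "R", ""))
      stop(sprintf("row %d (%s): direction '%s' is not F or R", i, gene, dir))
    loc <- gsub("–", "-", f[[3]])
    m <- regmatches(loc, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", loc))[[1]]
    if (length(m) != 3L)
      stop(sprintf("row %d (%s): malformed location '%s'", i, gene, f[[3]]))
    acs <- ace <- NA_integer_; act <- NA_character_
    if (nzchar(f[[5]])) {
      am <- regmatches(gsub("–", "-", f[[5]]),
                       regexec("^([0-9]+)\\s*-\\s*([0-9]+)\\s*([ACGTUacgtu]+)$",
                               gsub("–", "-", f[[5]])))[[1]]
      if (length(am) != 4L)
        stop(sprintf("row %d (%s): malformed anticodon '%s'", i, gene, f[[5]]))
      acs <- as.integer(am[[2]]); ace <- as.integer(am[[3]]); act <- toupper(am[[4]])
    }
    tibble(
      gene = gene,
      kind = infer_kind(gene),
      strand = if (dir == "R") "N" else "J",
      start = as.integer(m[[2]]),
      end = as.integer(m[[3]]),
      size_declared = if (nzchar(f[[4]])) as.integer(f[[4]]) else NA_integer_,
      anticodon_start = acs, anticodon_end = ace, anticodon = act,
      start_codon = if (nzchar(f[[6]])) toupper(f[[6]]) else NA_character_,
      stop_codon = if (nzchar(f[[7]])) toupper(f[[7]]) else NA_character_,
      intergenic_declared = if (nzchar(f[[8]])) as.integer(f[[8]]) else NA_integer_)
  })
  mito_annotation(do.call(rbind, rows))
}

#' Serialize an annotation back to the organization-table dialect
#'
#' Inverse of [parse_annotation_table()] up to whitespace normalization.
#'
#' @param a a `mito_annotation`.
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @return character vector of TSV lines, invisibly when written to `file`.
#' @export
write_annotation_table <- function(a, file = NULL) {
  stopifnot(inherits(a, "mito_annotation"))
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  anti <- ifelse(is.na(a$anticodon_start), "",
                 paste0(a$anticodon_start, "-", a$anticodon_end, blank(a$anticodon)))
  lines <- c(
    "Gene\tDirection\tLocation\tSize\tAnticodon\tStart\tStop\tIntergenic",
    paste(a$gene,
          ifelse(a$kind == "control_region", "", ifelse(a$strand == "N", "R", "F")),
          paste0(a$start, "-", a$end),
          blank(a$size_declared),
          anti,
          blank(a$start_codon),
          blank(a$stop_codon),
          blank(a$intergenic_declared),
          sep = "\t"))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Length of a feature on a circular genome
#'
#' `end - start + 1` for ordinary features; features stored with
#' `end < start` wrap the origin and have length
#' `genome_length - start + 1 + end`.
#'
#' @param start,end 1-based inclusive J-strand coordinates (vectorized).
#' @param genome_length circle length in bp.
#' @return integer lengths in bp.
#' @export
feature_length <- function(start, end, genome_length) {
  as.integer(ifelse(end >= start, end - start + 1L,
                    genome_length - start + 1L + end))
}

#' Signed intergenic gap between consecutive features
#'
#' `next_start - prev_end - 1`, evaluated circularly: positive values are
#' intergenic spacers, negative values overlaps, zero means the features
#' abut.  On the circle the raw difference is reduced modulo
#' `genome_length` and centred into `(-L/2, L/2]`, so the result does not
#' depend on where the origin falls — the closing last-to-first pair and
#' pairs that straddle a rotated origin need no special casing.  Ties at
#' exactly `L/2` are reported as spacers.
#'
#' @param prev_end end coordinate of the preceding feature.
#' @param next_start start coordinate of the following feature.
#' @param genome_length circle length in bp; when `NULL` the raw linear
#'   difference is returned.
#' @return signed gap in bp (vectorized).
#' @export
intergenic_gap <- function(prev_end, next_start, genome_length = NULL) {
  g <- next_start - prev_end - 1L
  if (!is.null(genome_length)) {
    m <- g %% genome_length
    g <- ifelse(m <= genome_length %/% 2L, m, m - genome_length)
  }
  as.integer(g)
}

#' Spacer/overlap geometry of an annotation
#'
#' Applies [intergenic_gap()] to every consecutive feature pair in storage
#' order, including the circular last-to-first pair, and classifies each pair
#' as spacer (gap > 0), overlap (gap < 0) or abutting (gap = 0).  The gap is
#' attributed to the following feature's row, matching the usual organization
#' table convention.
#'
#' @param a a `mito_annotation`.
#' @return a `mito_geometry` list: `gaps` (tibble over all pairs), `spacers`,
#'   `overlaps`, their counts / bp totals / maxima, and the [strand_tally()].
#' @export
geometry_summary <- function(a) {
  stopifnot(inherits(a, "mito_annotation"), nrow(a) >= 1L)
  L <- genome_length(a)
  n <- nrow(a)
  idx_prev <- seq_len(n)
  idx_next <- c(seq_len(n)[-1L], 1L)
  gaps <- intergenic_gap(a$end[idx_prev], a$start[idx_next], L)
  tab <- tibble(prev_gene = a$gene[idx_prev], next_gene = a$gene[idx_next],
                gap = gaps)
  spacers <- tab[tab$gap > 0L, ]
  overlaps <- tab[tab$gap < 0L, ]
  overlaps$overlap <- -overlaps$gap
  structure(list(
    gaps = tab,
    spacers = spacers,
    overlaps = overlaps,
    n_spacers = nrow(spacers),
    spacer_bp = sum(spacers$gap),
    max_spacer = if (nrow(spacers)) max(spacers$gap) else 0L,
    n_overlaps = nrow(overlaps),
    overlap_bp = sum(overlaps$overlap),
    max_overlap = if (nrow(overlaps)) max(overlaps$overlap) else 0L,
    strand_tally = strand_tally(a),
    genome_length = L
  ), class = "mito_geometry")
}

#' @export
print.mito_geometry <- function(x, ...) {
  cat(sprintf("Circular annotation geometry (genome %d bp)\n", x$genome_length))
  cat(sprintf("  spacers : %d totaling %d bp (max %d)\n",
              x$n_spacers, x$spacer_bp, x$max_spacer))
  cat(sprintf("  overlaps: %d totaling %d bp (max %d)\n",
              x$n_overlaps, x$overlap_bp, x$max_overlap))
  st <- x$strand_tally
  cat(sprintf("  genes on J: %d, on N: %d (control region excluded)\n",
              sum(st$J), sum(st$N)))
  invisible(x)
}

#' Feature counts per kind and strand
#'
#' The control region is excluded from gene counts.
#'
#' @param a a `mito_annotation`.
#' @return tibble with columns `kind`, `J`, `N`.
#' @export
strand_tally <- function(a) {
  stopifnot(inherits(a, "mito_annotation"))
  genes <- a[a$kind != "control_region", ]
  kinds <- c("PCG", "tRNA", "rRNA")
  tibble(kind = kinds,
         J = vapply(kinds, function(k) sum(genes$kind == k & genes$strand == "J"),
                    0L, USE.NAMES = FALSE),
         N = vapply(kinds, function(k) sum(genes$kind == k & genes$strand == "N"),
                    0L, USE.NAMES = FALSE))
}

# ---- sequence input -------------------------------------------------------

#' Read a genome sequence from FASTA
#'
#' @param file path to a FASTA file; the first record is used.
#' @return an uppercase character string (J strand as deposited).
#' @export
read_fasta_genome <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  if (length(set) == 0L) stop("no sequences in ", file)
  toupper(as.character(set[[1L]]))
}

#' Read a GenBank flat file into a sequence and annotation
#'
#' A minimal reader for the classic flat-file format: the ORIGIN block gives
#' the sequence; `CDS`, `tRNA`, `rRNA` and `misc_feature`/`D-loop` features
#' with plain `a..b` or `complement(a..b)` locations are mapped to
#' annotation rows (joins and remote references are not supported).  Feature
#' names are taken from `/gene` or, failing that, `/product` qualifiers.
#'
#' @param file path to a GenBank flat file.
#' @return list with elements `sequence` (character string) and `annotation`
#'   (a [mito_annotation()]).
#' @export
read_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L) stop("no ORIGIN block in ", file)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence in ", file)

  fst <- grep("^FEATURES", lines)
  if (length(fst) != 1L) stop("no FEATURES block in ", file)
  feat_lines <- lines[(fst + 1L):(ori - 1L)]
  keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
            misc_feature = "control_region", D_loop = "control_region",
            `D-loop` = "control_region")
  rows <- list(); cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    tibble(gene = cur$name, kind = cur$kind, strand = cur$strand,
           start = cur$start, end = cur$end)
  }
  for (ln in feat_lines) {
    key_m <- regmatches(ln, regexec("^ {5}(\\S+) +(.+)$", ln))[[1]]
    if (length(key_m) == 3L && key_m[[2]] %in% names(keys)) {
      rows[[length(rows) + 1L]] <- flush(cur); cur <- NULL
      loc <- key_m[[3]]
      comp <- grepl("^complement\\(", loc)
      nums <- regmatches(loc, regexec("([0-9]+)\\.\\.[<>]?([0-9]+)", loc))[[1]]
      if (length(nums) != 3L) next  # unsupported location form; skip feature
      cur <- list(kind = unname(keys[[key_m[[2]]]]),
                  strand = if (comp) "N" else "J",
                  start = as.integer(nums[[2]]), end = as.integer(nums[[3]]),
                  name = key_m[[2]])
    } else if (!is.null(cur)) {
      q <- regmatches(ln, regexec("^ +/(gene|product)=\"?([^\"]+)\"?", ln))[[1]]
      if (length(q) == 3L) {
        # /gene wins; /product only fills in when no /gene was seen yet
        if (q[[2]] == "gene" || cur$name %in% names(keys)) cur$name <- q[[3]]
      }
    }
  }
  rows[[length(rows) + 1L]] <- flush(cur)
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no mappable features in ", file)
  ann <- do.call(rbind, rows)
  list(sequence = sequence,
       annotation = mito_annotation(ann, genome_length = nchar(sequence)))
}
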