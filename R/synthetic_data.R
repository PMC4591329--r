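# Synthetic circular mitogenome generator with a planted-truth record.
#
# The generator emulates the canonical dipteran mitogenome: 37 genes plus a
# control region in the classic gene order and strand assignment, ~78.5%
# A+T, protein-coding genes with ATN starts and complete or incomplete
# stops, tRNAs built as defect-free (or deliberately defective) clover
# leaves, and a control region carrying planted poly-T, (TA)n and G(A)nT
# elements.  Every planted quantity is stored in a truth record so analysis
# outputs can be checked for exact recovery.

#' Base probabilities from composition targets
#'
#' @param at target A+T fraction in `[0, 1]`.
#' @param at_sk,gc_sk target AT and GC skews in `[-1, 1]`.
#' @return named numeric vector over A, C, G, T summing to 1.
#' @export
base_probs <- function(at, at_sk, gc_sk) {
  stopifnot(at >= 0, at <= 1)
  c(A = at * (1 + at_sk) / 2, C = (1 - at) * (1 - gc_sk) / 2,
    G = (1 - at) * (1 + gc_sk) / 2, T = at * (1 - at_sk) / 2)
}

sample_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generator configuration
#'
#' Defaults mirror the conditions a dipteran mitogenome study reports:
#' whole-genome composition 78.5% A+T with AT skew 0.009 and GC skew
#' -0.172; a 93.7% A+T control region with two poly-T stretches (27 bp on
#' J near the upstream rRNA, 37 bp on N near the downstream tRNA), one
#' (TA)98 stretch and several G(A)nT elements on N; the classic 37-gene +
#' control-region gene order/strand template; and 7 planted U-U stem
#' defects spread over distinct tRNAs (matching the mismatch census such
#' genomes typically show).  All fields can be overridden.
#'
#' @param template a [mito_annotation()] giving gene order, strands, sizes,
#'   anticodons and start/stop codons; defaults to the organization table
#'   shipped with the package.
#' @param at_content,at_skew,gc_skew whole-genome composition targets.
#' @param cr_at_content,cr_at_skew,cr_gc_skew control-region targets.
#' @param n_uu_defects number of U-U stem defects planted in distinct tRNAs.
#' @param polyt_j,polyt_n lengths (bp) of the planted poly-T stretches on
#'   the J and N strand of the control region.
#' @param ta_units number of TA units in the planted (TA)n stretch.
#' @param gant_n integer vector of A-run lengths for planted G(A)nT
#'   elements on the N strand.
#' @param seed default random seed used by [generate_mitogenome()].
#' @return a `generator_config` list.
#' @export
generator_config <- function(template = NULL,
                             at_content = 0.785, at_skew = 0.009,
                             gc_skew = -0.172,
                             cr_at_content = 0.937, cr_at_skew = -0.02,
                             cr_gc_skew = -0.30,
                             n_uu_defects = 7L,
                             polyt_j = 27L, polyt_n = 37L,
                             ta_units = 98L, gant_n = 1:5,
                             seed = 1L) {
  if (is.null(template)) template <- delia_template()
  stopifnot(inherits(template, "mito_annotation"),
            at_content >= 0, at_content <= 1,
            cr_at_content >= 0, cr_at_content <= 1,
            n_uu_defects >= 0L, polyt_j >= 1L, polyt_n >= 1L,
            ta_units >= 2L, all(gant_n >= 1L))
  structure(list(template = template,
                 at_content = at_content, at_skew = at_skew, gc_skew = gc_skew,
                 cr_at_content = cr_at_content, cr_at_skew = cr_at_skew,
                 cr_gc_skew = cr_gc_skew,
                 n_uu_defects = as.integer(n_uu_defects),
                 polyt_j = as.integer(polyt_j), polyt_n = as.integer(polyt_n),
                 ta_units = as.integer(ta_units), gant_n = as.integer(gant_n),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' The packaged dipteran organization-table template
#'
#' @return the [mito_annotation()] parsed from the organization table
#'   shipped in `inst/extdata`.
#' @export
delia_template <- function() {
  parse_annotation_table(system.file("extdata", "delia_antiqua_mito.tsv",
                                     package = "mitoprofile", mustWork = TRUE))
}

# ---- protein-coding genes -------------------------------------------------

sample_codons <- function(n, probs) {
  if (n <= 0L) return(character(0))
  draw <- function(k) {
    m <- matrix(sample(names(probs), 3L * k, replace = TRUE, prob = probs),
                nrow = 3L)
    paste0(m[1, ], m[2, ], m[3, ])
  }
  out <- draw(n)
  bad <- out %in% c("TAA", "TAG")   # no internal stops
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out %in% c("TAA", "TAG")
  }
  out
}

# in-frame size nearest (not above) the template size for the start/stop
pcg_frame_size <- function(size, start_codon, stop_codon) {
  lead <- if (nchar(start_codon) == 4L) 4L else 0L
  tail <- if (nchar(stop_codon) < 3L) nchar(stop_codon) else 0L
  body <- size - lead - tail
  lead + (body %/% 3L) * 3L + tail
}

gen_pcg <- function(size, start_codon, stop_codon, probs) {
  lead4 <- nchar(start_codon) == 4L
  tailn <- if (nchar(stop_codon) < 3L) nchar(stop_codon) else 0L
  m <- (size - (if (lead4) 4L else 0L) - tailn) %/% 3L
  if (lead4) {
    body <- c(sample_codons(m - 1L, probs), "TAA")
    seq <- paste0(start_codon, paste(body, collapse = ""))
  } else if (tailn == 0L) {
    body <- c(start_codon, sample_codons(m - 2L, probs), stop_codon)
    seq <- paste(body, collapse = "")
  } else {
    body <- c(start_codon, sample_codons(m - 1L, probs))
    seq <- paste0(paste(body, collapse = ""), substr("TA", 1L, tailn))
  }
  stopifnot(nchar(seq) == size)
  seq
}

# ---- tRNAs ----------------------------------------------------------------

# sample one admissible Watson-Crick stem pair, AT-rich
sample_pair <- function(at) {
  r <- runif(1)
  if (r < at / 2) c("A", "T")
  else if (r < at) c("T", "A")
  else if (r < at + (1 - at) / 2) c("G", "C")
  else c("C", "G")
}

#' Generate one clover-leaf tRNA sequence with known layout
#'
#' Builds a tRNA from sampled arm sizes, threads complementary Watson-Crick
#' stems, places the given anticodon at the centre of its 7-nt loop, and
#' verifies by [fold_trna()] that the planted layout is recovered exactly
#' with zero mismatches (resampling deterministically otherwise).  When
#' `n_defects > 0`, that many stem pairs outside the DHU arm are mutated to
#' U-U and recovery of exactly those mismatches is verified.
#'
#' @param anticodon 3-nt sense-strand anticodon (DNA alphabet).
#' @param dhu_stem DHU stem size: 3, 4, or 0 for a DHU-less fold (as in
#'   mitochondrial tRNA-Ser(AGN)).
#' @param at A+T fraction used for stems and loops.
#' @param n_defects number of U-U defects to plant (in the acceptor,
#'   anticodon or T-psi-C stems).
#' @param max_tries resampling budget before giving up.
#' @return list with `seq`, `anticodon_span` (local), `layout`, `defects`
#'   (tibble `pos5`, `pos3`, `arm`, `type`) and the verified `fold`.
#' @export
generate_trna <- function(anticodon, dhu_stem = sample(3:4, 1L), at = 0.785,
                          n_defects = 0L, max_tries = 80L) {
  stopifnot(nchar(anticodon) == 3L, dhu_stem %in% c(0L, 3L, 4L))
  for (try in seq_len(max_tries)) {
    a <- sample(4:5, 1L)
    t <- sample(3:5, 1L)
    tl <- sample(5:8, 1L)
    v <- sample(2:9, 1L)
    # DHU-less tRNAs compensate the missing arm with a larger replacement
    # loop, as mitochondrial tRNA-Ser(AGN) does
    dl <- if (dhu_stem > 0L) sample(5:9, 1L) else sample(6:12, 1L)
    j1 <- 2L; j2 <- 1L; trail <- 0L
    R <- if (dhu_stem > 0L) 2L * dhu_stem + dl else dl
    L <- 7L + j1 + R + j2 + 2L * a + 7L + v + 2L * t + tl + 7L + trail
    if (L < 63L || L > 72L) next
    p <- 10L + j1 + R + j2 + a
    lay <- list(acceptor = 7L, j1 = j1, dhu_stem = dhu_stem,
                dhu_loop = if (dhu_stem > 0L) dl else NA_integer_,
                dhu_region = if (dhu_stem == 0L) dl else NA_integer_,
                j2 = j2, ac_stem = a, ac_loop = 7L, variable = v,
                tpsic_stem = t, tpsic_loop = tl, trail = trail)
    # loop, connector and variable-region positions are drawn from {A, C}
    # (weighted to keep the A+T target): no two such bases can form an
    # admissible pair, so stems cannot silently extend into loops and the
    # planted geometry stays the unique maximum-pairing assignment
    chars <- sample(c("A", "C"), L, replace = TRUE, prob = c(at, 1 - at))
    pr <- layout_pairs(lay, p, L)
    for (k in seq_along(pr$pos5)) {
      pair <- sample_pair(at)
      chars[pr$pos5[k]] <- pair[1]; chars[pr$pos3[k]] <- pair[2]
    }
    chars[p:(p + 2L)] <- strsplit(normalize_seq(anticodon), "")[[1]]
    defects <- tibble(pos5 = integer(0), pos3 = integer(0),
                      arm = character(0), type = character(0))
    if (n_defects > 0L) {
      # defects go where the census can identify them: anywhere in the
      # fixed-size acceptor stem, but only at interior pairs of the
      # flexible stems (a defect at a flexible stem's end pair would be
      # absorbed by the folder simply shrinking that stem); the DHU arm is
      # left defect-free
      idx <- stats::ave(seq_along(pr$arm), pr$arm, FUN = seq_along)
      len <- stats::ave(seq_along(pr$arm), pr$arm, FUN = length)
      eligible <- which(
        pr$arm == "acceptor" |
        (pr$arm == "anticodon" & idx > 1L) |
        (pr$arm == "TpsiC" & idx > 1L & idx < len))
      pick <- sample(eligible, n_defects)
      for (k in pick) {
        chars[pr$pos5[k]] <- "T"; chars[pr$pos3[k]] <- "T"
      }
      defects <- tibble(pos5 = pr$pos5[pick], pos3 = pr$pos3[pick],
                        arm = pr$arm[pick],
                        type = rep("U-U", n_defects))
    }
    seq <- paste(chars, collapse = "")
    fold <- fold_trna(seq, c(p, p + 2L))
    same_layout <- identical(fold$layout, lay)
    hits_ok <- fold$n_mismatches == n_defects &&
      (n_defects == 0L ||
       setequal(paste(fold$mismatches$pos5, fold$mismatches$pos3),
                paste(defects$pos5, defects$pos3)) &&
       all(fold$mismatches$type == "U-U"))
    if (same_layout && hits_ok)
      return(list(seq = seq, anticodon_span = c(p, p + 2L), layout = lay,
                  defects = defects, fold = fold))
  }
  stop("could not realize a clover-leaf tRNA within the resampling budget")
}

# ---- control region -------------------------------------------------------

gen_control_region <- function(cfg, cr_len) {
  probs <- base_probs(cfg$cr_at_content, cfg$cr_at_skew, cfg$cr_gc_skew)
  # planted elements in CR order: poly-T (J) near the upstream edge, the
  # (TA)n block, the G(A)nT cluster (N strand), poly-T (N, i.e. poly-A on
  # J) near the downstream edge; each flanked by single C guards that stop
  # any run from extending into the background
  elements <- list(
    list(motif = "polyT", strand = "J", n = cfg$polyt_j,
         seq = strrep("T", cfg$polyt_j)),
    list(motif = "TA_repeat", strand = "J", n = cfg$ta_units,
         seq = strrep("TA", cfg$ta_units)))
  for (n in cfg$gant_n)
    elements <- c(elements, list(list(motif = "GAnT", strand = "N", n = n,
                                      seq = revcomp(paste0("G", strrep("A", n), "T")))))
  elements <- c(elements, list(list(motif = "polyT", strand = "N",
                                    n = cfg$polyt_n,
                                    seq = strrep("A", cfg$polyt_n))))
  planted_bp <- sum(vapply(elements, function(e) nchar(e$seq) + 2L, 0L))
  n_bg <- length(elements) + 1L
  budget <- cr_len - planted_bp
  if (budget < 5L * n_bg)
    stop("planted motifs exceed the control region length")
  bg_len <- rep(budget %/% n_bg, n_bg)
  bg_len[n_bg] <- budget - sum(bg_len[-n_bg])
  parts <- character(0)
  pos <- 0L
  motifs <- motif_hits()
  for (k in seq_along(elements)) {
    bg <- sample_bases(bg_len[k], probs)
    parts <- c(parts, bg, "C")
    pos <- pos + bg_len[k] + 1L
    e <- elements[[k]]
    motifs <- rbind(motifs, motif_hits(e$motif, e$strand, pos + 1L,
                                       pos + nchar(e$seq), e$n))
    parts <- c(parts, e$seq, "C")
    pos <- pos + nchar(e$seq) + 1L
  }
  parts <- c(parts, sample_bases(bg_len[n_bg], probs))
  seq <- paste(parts, collapse = "")
  stopifnot(nchar(seq) == cr_len)
  list(seq = seq, motifs = motifs)   # motif coordinates are CR-local, J frame
}

# ---- whole genome ---------------------------------------------------------

#' Generate a synthetic circular mitogenome with planted truth
#'
#' Walks the template gene order, generating each feature on its sense
#' strand (reverse-complemented into the genome for N-strand genes):
#' protein-coding genes with the template's start/stop codons and in-frame
#' sizes, clover-leaf tRNAs with the template anticodons (DHU-less for
#' tRNA-Ser(AGN)), random rRNAs, template spacer lengths (template overlaps
#' are clamped to abutting so features stay independent), and a control
#' region with planted motifs.  U-U defects are planted in
#' `cfg$n_uu_defects` distinct tRNAs.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; defaults to `cfg$seed`.  The run is fully
#'   deterministic given (`cfg`, `seed`).
#' @return a `mito_sim` list: `sequence` (J strand), `annotation`
#'   (a [mito_annotation()]), `truth` (planted quantities: the annotation,
#'   per-tRNA layouts, `defects`, `motifs` in genomic coordinates, `gaps`,
#'   composition targets, and a `genome_id`).
#' @export
generate_mitogenome <- function(cfg = generator_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  tpl <- cfg$template
  probs <- base_probs(cfg$at_content, cfg$at_skew, cfg$gc_skew)

  # which tRNAs carry a planted defect
  trna_idx <- which(tpl$kind == "tRNA")
  if (cfg$n_uu_defects > length(trna_idx))
    stop("more defects requested than tRNAs in the template")
  defect_rows <- sort(sample(trna_idx, cfg$n_uu_defects))

  gaps <- ifelse(is.na(tpl$intergenic_declared), 0L,
                 pmax(0L, tpl$intergenic_declared))
  cr_row <- which(tpl$kind == "control_region")
  if (length(cr_row) != 1L) stop("template must contain exactly one control region")

  parts <- character(0)
  pos <- 0L
  rows <- list(); trna_truth <- list(); defects <- motifs <- NULL
  all_defects <- list()
  for (i in seq_len(nrow(tpl))) {
    f <- tpl[i, ]
    spacer <- gaps[i]
    if (spacer > 0L) {
      parts <- c(parts, sample_bases(spacer, probs))
      pos <- pos + spacer
    }
    anticodon_local <- NULL
    if (f$kind == "PCG") {
      size <- pcg_frame_size(f$size_declared, f$start_codon, f$stop_codon)
      sense <- gen_pcg(size, f$start_codon, f$stop_codon, probs)
    } else if (f$kind == "tRNA") {
      dhu <- if (grepl("Ser\\(AGN\\)", f$gene)) 0L else sample(3:4, 1L)
      tr <- generate_trna(f$anticodon, dhu_stem = dhu, at = cfg$at_content,
                          n_defects = if (i %in% defect_rows) 1L else 0L)
      sense <- tr$seq
      anticodon_local <- tr$anticodon_span
      trna_truth[[f$gene]] <- tr$layout
      if (nrow(tr$defects))
        all_defects[[f$gene]] <- cbind(tibble(gene = f$gene), tr$defects)
    } else if (f$kind == "rRNA") {
      sense <- sample_bases(f$size_declared, probs)
    } else {
      cr <- gen_control_region(cfg, f$size_declared)
      sense <- cr$seq
      motifs <- cr$motifs
      motifs$start <- motifs$start + pos   # genomic (CR never on N here)
      motifs$end <- motifs$end + pos
    }
    size <- nchar(sense)
    start <- pos + 1L; end <- pos + size
    acs <- ace <- NA_integer_
    if (!is.null(anticodon_local)) {
      if (f$strand == "J") {
        acs <- start + anticodon_local[1] - 1L
        ace <- start + anticodon_local[2] - 1L
      } else {
        acs <- end - anticodon_local[2] + 1L
        ace <- end - anticodon_local[1] + 1L
      }
    }
    rows[[i]] <- tibble(gene = f$gene, kind = f$kind, strand = f$strand,
                        start = start, end = end, size_declared = size,
                        anticodon_start = acs, anticodon_end = ace,
                        anticodon = f$anticodon,
                        start_codon = f$start_codon, stop_codon = f$stop_codon,
                        intergenic_declared = gaps[i])
    parts <- c(parts, if (f$strand == "N") revcomp(sense) else sense)
    pos <- pos + size
  }
  sequence <- paste(parts, collapse = "")
  ann <- mito_annotation(do.call(rbind, rows), genome_length = pos)
  defects <- if (length(all_defects)) as_tibble(do.call(rbind, all_defects))
             else tibble(gene = character(0), pos5 = integer(0),
                         pos3 = integer(0), arm = character(0),
                         type = character(0))
  truth <- list(
    seed = seed,
    genome_id = sprintf("mitosim-seed%d-len%d", seed, pos),
    seq_prefix = substr(sequence, 1L, 40L),
    annotation = ann,
    gaps = gaps,
    trna_layouts = trna_truth,
    defects = defects,
    motifs = motifs,
    targets = list(at_content = cfg$at_content, at_skew = cfg$at_skew,
                   gc_skew = cfg$gc_skew, cr_at_content = cfg$cr_at_content),
    config = cfg)
  structure(list(sequence = sequence, annotation = ann, truth = truth),
            class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  st <- strand_tally(x$annotation)
  cat(sprintf("Synthetic mitogenome %s: %d bp, %d features (%d J / %d N genes)\n",
              x$truth$genome_id, genome_length(x$annotation),
              nrow(x$annotation), sum(st$J), sum(st$N)))
  cat(sprintf("  planted: %d U-U tRNA defects, %d control-region motifs\n",
              nrow(x$truth$defects), nrow(x$truth$motifs)))
  invisible(x)
}

#' Check analysis outputs against the planted truth
#'
#' Re-runs the geometry, control-region and tRNA stages on the generated
#' genome and compares them with the truth record: gene order and strand
#' tally, feature lengths, recovery of every planted motif at its exact
#' coordinates with its exact repeat count, and recovery of exactly the
#' planted U-U defects.
#'
#' @param sim a `mito_sim` from [generate_mitogenome()], or its `truth`
#'   record (then `genome` and `annotation` must be supplied and are
#'   checked against the truth's genome identifier).
#' @param genome,annotation optional explicit analysis inputs.
#' @return tibble with columns `check`, `planted`, `recovered`, `ok`.
#' @export
truth_check <- function(sim, genome = NULL, annotation = NULL) {
  if (inherits(sim, "mito_sim")) {
    truth <- sim$truth
    genome <- genome %||% sim$sequence
    annotation <- annotation %||% sim$annotation
  } else truth <- sim
  if (is.null(genome) || is.null(annotation))
    stop("supply a mito_sim or an explicit genome and annotation")
  if (nchar(genome) != genome_length(truth$annotation) ||
      substr(genome, 1L, nchar(truth$seq_prefix)) != truth$seq_prefix)
    stop("mismatched genome identifiers: genome does not match the truth record")

  out <- list()
  note <- function(check, planted, recovered) {
    out[[length(out) + 1L]] <<- tibble(check = check,
                                       planted = as.character(planted),
                                       recovered = as.character(recovered),
                                       ok = identical(as.character(planted),
                                                      as.character(recovered)))
  }
  note("gene order", paste(truth$annotation$gene, collapse = ","),
       paste(annotation$gene, collapse = ","))
  st_t <- strand_tally(truth$annotation); st_r <- strand_tally(annotation)
  note("strand tally", paste(c(st_t$J, st_t$N), collapse = "/"),
       paste(c(st_r$J, st_r$N), collapse = "/"))
  L <- genome_length(annotation)
  note("feature lengths",
       paste(feature_length(truth$annotation$start, truth$annotation$end,
                            genome_length(truth$annotation)), collapse = ","),
       paste(feature_length(annotation$start, annotation$end, L), collapse = ","))
  geo <- geometry_summary(annotation)
  note("intergenic gaps", paste(truth$gaps[-1], collapse = ","),
       paste(geo$gaps$gap[-nrow(geo$gaps)], collapse = ","))

  hits <- scan_control_region(genome, annotation)
  key <- function(m) paste(m$motif, m$strand, m$start, m$end, m$n)
  found <- key(truth$motifs) %in% key(hits)
  note("planted CR motifs recovered", nrow(truth$motifs), sum(found))

  cen <- mismatch_census(annotation, genome)
  note("planted U-U defects: count", nrow(truth$defects), cen$n)
  note("planted U-U defects: all U-U", "TRUE",
       all(cen$hits$type == "U-U"))
  ck <- function(d) paste(d$gene, d$pos5, d$pos3)
  note("planted U-U defects: coordinates",
       paste(sort(ck(truth$defects)), collapse = ";"),
       paste(sort(ck(cen$hits)), collapse = ";"))
  as_tibble(do.call(rbind, out))
}
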