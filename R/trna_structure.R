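# Template-constrained clover-leaf folding for annotated mitochondrial tRNAs.
#
# Mitochondrial tRNA annotations supply the gene span and the anticodon
# position, so instead of free-energy folding we enumerate canonical
# clover-leaf geometries anchored at the anticodon and keep the assignment
# that maximizes admissible stem pairs.  This is deterministic and lets
# planted-truth tests verify exact parameter recovery.

# Admissible stem pairs (DNA alphabet, U == T): Watson-Crick plus G.U wobble.
ADMISSIBLE_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

# Arm-size bounds (bp / nt).  Stems follow the canonical metazoan
# mitochondrial ranges: acceptor 7, DHU 3-4 (or absent), anticodon 4-5,
# T-psi-C 3-5.  The anticodon loop is fixed at 7 nt with the anticodon at
# its center; other loops span 3-9 nt, the variable region 0-23 nt, the
# DHU replacement loop (when the arm is absent) 2-12 nt, the connector
# between acceptor stem and DHU arm 1-3 nt, the connector after the DHU
# arm 0-2 nt, and up to 4 unpaired nt may trail the acceptor stem.
TRNA_BOUNDS <- list(
  acceptor = 7L, dhu_stem = c(4L, 3L, 0L), dhu_loop = 3:9, dhu_absent = 2:12,
  j1 = c(2L, 1L, 3L), j2 = c(1L, 0L, 2L), ac_stem = c(5L, 4L), ac_loop = 7L,
  variable = 0:23, tpsic_stem = c(5L, 4L, 3L), tpsic_loop = 3:9, trail = 0:4)

rna_pair_type <- function(b5, b3) {
  r <- sort(c(gsub("T", "U", b5), gsub("T", "U", b3)))
  paste(r, collapse = "-")
}

layout_pairs <- function(lay, p, L) {
  # pair index table for one candidate geometry; positions are 1-based in
  # the gene, outermost stem pair first within each arm
  pos5 <- integer(0); pos3 <- integer(0); arm <- character(0)
  add <- function(a, i, j) {
    pos5 <<- c(pos5, i); pos3 <<- c(pos3, j); arm <<- c(arm, rep(a, length(i)))
  }
  i <- 1:7
  add("acceptor", i, L - lay$trail - (i - 1L))
  if (lay$dhu_stem > 0L) {
    b <- 7L + lay$j1
    k <- seq_len(lay$dhu_stem)
    add("DHU", b + k, b + 2L * lay$dhu_stem + lay$dhu_loop + 1L - k)
  }
  k <- seq_len(lay$ac_stem)
  add("anticodon", p - 3L - lay$ac_stem + k, p + 4L + lay$ac_stem + 1L - k)
  b <- p + 4L + lay$ac_stem + lay$variable
  k <- seq_len(lay$tpsic_stem)
  add("TpsiC", b + k, b + 2L * lay$tpsic_stem + lay$tpsic_loop + 1L - k)
  list(arm = arm, pos5 = pos5, pos3 = pos3)
}

#' Fold an annotated tRNA into a clover-leaf
#'
#' Enumerates clover-leaf geometries within canonical mitochondrial bounds
#' (acceptor stem 7 bp; DHU stem 3-4 bp or absent; anticodon stem 4-5 bp
#' with a fixed 7-nt loop centred on the given anticodon; T-psi-C stem
#' 3-5 bp; variable region 0-23 nt), anchored at the annotated anticodon,
#' and returns the geometry with the most admissible stem pairs
#' (Watson-Crick or G.U wobble).  Ties are broken by fewer mismatching stem
#' positions, then by the larger DHU arm, then by enumeration order, so the
#' result is deterministic.
#'
#' @param seq sense-strand tRNA sequence, 55-80 nt (DNA or RNA alphabet).
#' @param anticodon_span integer pair: 1-based inclusive positions of the
#'   anticodon within `seq`.
#' @return a `cloverleaf` object: `layout` (all arm/loop sizes), `pairs`
#'   (tibble with `arm`, `pos5`, `pos3`, `base5`, `base3`, `admissible`,
#'   `type`), `mismatches` (the non-admissible subset), `n_mismatches`,
#'   `score` and the anticodon.
#' @export
fold_trna <- function(seq, anticodon_span) {
  s <- normalize_seq(seq)
  L <- nchar(s)
  if (L < 55L || L > 80L)
    stop(sprintf("tRNA length %d outside the 55-80 nt clover-leaf range", L))
  anticodon_span <- as.integer(anticodon_span)
  p <- anticodon_span[[1]]
  if (anticodon_span[[2]] != p + 2L || p < 1L || p + 2L > L)
    stop("anticodon_span must be a 3-nt span inside the sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  left_budget <- p - 10L       # j1 + DHU region + j2 + ac_stem
  right_budget <- L - p - 4L   # ac_stem + variable + TpsiC arm + acceptor3 + trail
  B <- TRNA_BOUNDS
  best <- NULL
  for (a in B$ac_stem) {
    rights <- list()
    for (t in B$tpsic_stem) for (tl in B$tpsic_loop) for (tr in B$trail) {
      v <- right_budget - a - 2L * t - tl - 7L - tr
      if (v >= min(B$variable) && v <= max(B$variable))
        rights[[length(rights) + 1L]] <- list(t = t, tl = tl, trail = tr, v = v)
    }
    if (!length(rights)) next
    for (d in B$dhu_stem) {
      # without a DHU stem the connector/loop/connector split is not
      # identifiable (no pairs distinguish it), so it is canonicalized to
      # j1 = 2, j2 = 1 with the replacement loop taking the remainder
      dls <- if (d > 0L) B$dhu_loop else (left_budget - a - 3L)
      for (dl in dls) {
        if (d == 0L && !dl %in% B$dhu_absent) next
        R <- if (d > 0L) 2L * d + dl else dl
        j1s <- if (d > 0L) B$j1 else 2L
        for (j1 in j1s) {
          j2 <- left_budget - j1 - R - a
          if (!j2 %in% B$j2) next
          for (rt in rights) {
            lay <- list(acceptor = 7L, j1 = j1, dhu_stem = d,
                        dhu_loop = if (d > 0L) dl else NA_integer_,
                        dhu_region = if (d == 0L) dl else NA_integer_,
                        j2 = j2, ac_stem = a, ac_loop = 7L,
                        variable = rt$v, tpsic_stem = rt$t,
                        tpsic_loop = rt$tl, trail = rt$trail)
            pr <- layout_pairs(lay, p, L)
            ok <- paste0(chars[pr$pos5], chars[pr$pos3]) %in% ADMISSIBLE_PAIRS
            score <- sum(ok)
            mism <- length(ok) - score
            better <- is.null(best) || score > best$score ||
              (score == best$score && (mism < best$mism ||
                (mism == best$mism && d > best$lay$dhu_stem)))
            if (better)
              best <- list(lay = lay, pairs = pr, ok = ok,
                           score = score, mism = mism)
          }
        }
      }
    }
  }
  if (is.null(best))
    stop("no clover-leaf: no arm assignment satisfies the geometric bounds")
  pr <- best$pairs
  pairs <- tibble(arm = pr$arm, pos5 = pr$pos5, pos3 = pr$pos3,
                  base5 = chars[pr$pos5], base3 = chars[pr$pos3],
                  admissible = best$ok,
                  type = mapply(rna_pair_type, chars[pr$pos5], chars[pr$pos3],
                                USE.NAMES = FALSE))
  structure(list(
    seq = s, length = L,
    anticodon = list(start = p, end = p + 2L, seq = substr(s, p, p + 2L)),
    layout = best$lay,
    pairs = pairs,
    mismatches = pairs[!pairs$admissible, ],
    n_mismatches = best$mism,
    score = best$score
  ), class = "cloverleaf")
}

#' Does a clover-leaf have a DHU arm?
#' @param x a `cloverleaf`.
#' @return logical.
#' @export
has_dhu <- function(x) {
  stopifnot(inherits(x, "cloverleaf"))
  x$layout$dhu_stem > 0L
}

#' @export
print.cloverleaf <- function(x, ...) {
  l <- x$layout
  cat(sprintf("Clover-leaf, %d nt, anticodon %s at %d-%d\n",
              x$length, gsub("T", "U", x$anticodon$seq),
              x$anticodon$start, x$anticodon$end))
  cat(sprintf("  acceptor 7 bp | DHU %s | anticodon %d bp | TpsiC %d bp | variable %d nt\n",
              if (l$dhu_stem > 0L) paste0(l$dhu_stem, " bp") else "absent",
              l$ac_stem, l$tpsic_stem, l$variable))
  cat(sprintf("  %d stem pairs, %d mismatched\n", nrow(x$pairs), x$n_mismatches))
  if (x$n_mismatches > 0L)
    cat("  mismatches:", paste(sprintf("%s at %d:%d", x$mismatches$type,
                                       x$mismatches$pos5, x$mismatches$pos3),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Dot-bracket string of a clover-leaf
#'
#' Admissible (paired) stem positions become `(`/`)`; mismatched stem
#' positions and loops stay `.`.  The pairing is nested by construction, so
#' brackets are always balanced.
#'
#' @param x a `cloverleaf`.
#' @return character string of the same length as the sequence.
#' @export
to_dot_bracket <- function(x) {
  stopifnot(inherits(x, "cloverleaf"))
  db <- rep(".", x$length)
  pp <- x$pairs[x$pairs$admissible, ]
  db[pp$pos5] <- "("
  db[pp$pos3] <- ")"
  paste(db, collapse = "")
}

#' Parse a dot-bracket string into its pair set
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return tibble with `pos5`, `pos3`, sorted by `pos5`.
#' @export
parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  p5 <- integer(0); p3 <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      p5 <- c(p5, stack[length(stack)]); p3 <- c(p3, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  out <- tibble(pos5 = p5, pos3 = p3)
  out[order(out$pos5), ]
}

#' Mismatch census over all annotated tRNAs
#'
#' Folds every tRNA feature carrying an anticodon annotation and collects
#' all mismatching stem positions with gene attribution; tRNAs without an
#' anticodon span are skipped with a warning.
#'
#' @param a a [mito_annotation()].
#' @param genome J-strand genome sequence.
#' @return a `mismatch_census` list: `hits` (tibble `gene`, `arm`, `pos5`,
#'   `pos3`, `base5`, `base3`, `type` with positions local to the gene's
#'   sense strand), `n`, `by_type` (named counts), `folds` (named list of
#'   `cloverleaf` objects), `skipped`.
#' @export
mismatch_census <- function(a, genome) {
  stopifnot(inherits(a, "mito_annotation"))
  Lg <- genome_length(a)
  trnas <- a[a$kind == "tRNA", ]
  hits <- list(); folds <- list(); skipped <- character(0)
  for (i in seq_len(nrow(trnas))) {
    f <- trnas[i, ]
    if (is.na(f$anticodon_start)) {
      warning(sprintf("%s: no anticodon annotation, skipped", f$gene))
      skipped <- c(skipped, f$gene)
      next
    }
    s <- feature_seq(genome, f$start, f$end, f$strand)
    loc <- function(g) {
      if (f$strand == "J") ((g - f$start + Lg) %% Lg) + 1L
      else ((f$end - g + Lg) %% Lg) + 1L
    }
    span <- if (f$strand == "J") c(loc(f$anticodon_start), loc(f$anticodon_end))
            else c(loc(f$anticodon_end), loc(f$anticodon_start))
    cl <- fold_trna(s, span)
    folds[[f$gene]] <- cl
    if (nrow(cl$mismatches)) {
      hits[[length(hits) + 1L]] <-
        cbind(tibble(gene = f$gene), cl$mismatches[, c("arm", "pos5", "pos3",
                                                       "base5", "base3", "type")])
    }
  }
  hits <- if (length(hits)) as_tibble(do.call(rbind, hits))
          else tibble(gene = character(0), arm = character(0),
                      pos5 = integer(0), pos3 = integer(0),
                      base5 = character(0), base3 = character(0),
                      type = character(0))
  structure(list(hits = hits, n = nrow(hits),
                 by_type = if (nrow(hits)) table(hits$type) else table(character(0)),
                 folds = folds, skipped = skipped),
            class = "mismatch_census")
}

#' @export
print.mismatch_census <- function(x, ...) {
  cat(sprintf("tRNA mismatch census: %d mismatched stem pairs over %d folded tRNAs\n",
              x$n, length(x$folds)))
  if (x$n > 0L) {
    tb <- x$by_type
    cat("  by type:", paste(sprintf("%s x%d", names(tb), as.integer(tb)),
                            collapse = ", "), "\n")
  }
  if (length(x$skipped))
    cat("  skipped (no anticodon):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
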