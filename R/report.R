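# Orchestration: assemble the five classic descriptive tables and the
# cross-genome skew-scatter export.

#' Build the full descriptive report for one mitogenome
#'
#' Runs the geometry, composition, codon-usage, tRNA-structure and
#' control-region stages and collects their tables.  A failure in one stage
#' is recorded under `errors` and does not abort the others, so one
#' inconsistently annotated gene cannot block the rest of the report.
#'
#' @param genome J-strand genome sequence.
#' @param a a [mito_annotation()].
#' @param min_polyt,min_ta,min_ga control-region scanner thresholds.
#' @return a `mito_report` list: `organization` (recomputed sizes and gaps
#'   next to the declared columns), `geometry`, `composition`, `aa` (pooled
#'   and per strand), `rscu`, `trna` (per-tRNA arm summary), `census`,
#'   `cr_motifs`, `errors`, and a `provenance` block.
#' @export
build_report <- function(genome, a, min_polyt = 10L, min_ta = 5L, min_ga = 1L) {
  stopifnot(inherits(a, "mito_annotation"))
  genome <- normalize_seq(genome)
  if (nchar(genome) != genome_length(a))
    stop(sprintf("genome length (%d) and annotation genome_length (%d) disagree",
                 nchar(genome), genome_length(a)))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  L <- genome_length(a)
  geometry <- stage("geometry", geometry_summary(a))
  organization <- stage("organization", {
    gaps <- if (!is.null(geometry)) c(geometry$gaps$gap[nrow(geometry$gaps)],
                                      geometry$gaps$gap[-nrow(geometry$gaps)])
            else rep(NA_integer_, nrow(a))
    tibble(gene = a$gene, kind = a$kind, strand = a$strand,
           start = a$start, end = a$end,
           size = feature_length(a$start, a$end, L),
           size_declared = a$size_declared,
           start_codon = a$start_codon, stop_codon = a$stop_codon,
           gap = as.integer(gaps),
           intergenic_declared = a$intergenic_declared)
  })
  composition <- stage("composition", composition_table(genome, a))
  usage <- stage("codon_usage", codon_usage_table(genome, a))
  aa <- stage("aa", {
    pooled <- cbind(tibble(class = "all"), usage$aa)
    per_strand <- lapply(c("J", "N"), function(s) {
      u <- try(codon_usage_table(genome, a, strand = s), silent = TRUE)
      if (inherits(u, "try-error")) NULL else cbind(tibble(class = s), u$aa)
    })
    as_tibble(do.call(rbind, c(list(pooled), per_strand)))
  })
  census <- stage("trna", mismatch_census(a, genome))
  trna <- stage("trna_summary", {
    if (is.null(census)) stop("census unavailable")
    folds <- census$folds
    tibble(gene = names(folds),
           length = vapply(folds, function(f) f$length, 0L),
           dhu = vapply(folds, has_dhu, TRUE),
           dhu_stem = vapply(folds, function(f) f$layout$dhu_stem, 0L),
           ac_stem = vapply(folds, function(f) f$layout$ac_stem, 0L),
           tpsic_stem = vapply(folds, function(f) f$layout$tpsic_stem, 0L),
           variable = vapply(folds, function(f) f$layout$variable, 0L),
           anticodon = vapply(folds, function(f) gsub("T", "U", f$anticodon$seq), ""),
           mismatches = vapply(folds, function(f) f$n_mismatches, 0L))
  })
  cr <- stage("cr_motifs", scan_control_region(genome, a, min_polyt, min_ta, min_ga))
  structure(list(
    organization = organization,
    geometry = geometry,
    composition = composition,
    rscu = usage$rscu,
    n_codons = usage$n_codons,
    aa = aa,
    trna = trna,
    census = census,
    cr_motifs = cr,
    errors = errors,
    provenance = list(
      package = "mitoprofile",
      version = as.character(utils::packageVersion("mitoprofile")),
      genome_length = L,
      n_features = nrow(a),
      thresholds = list(min_polyt = min_polyt, min_ta = min_ta, min_ga = min_ga),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat(sprintf("Mitogenome report (%d bp, %d features)\n",
              x$provenance$genome_length, x$provenance$n_features))
  if (!is.null(x$geometry)) print(x$geometry)
  if (!is.null(x$n_codons))
    cat(sprintf("  codon usage over %d codons\n", x$n_codons))
  if (!is.null(x$census))
    cat(sprintf("  tRNA mismatches: %d\n", x$census$n))
  if (!is.null(x$cr_motifs))
    cat(sprintf("  control-region motif hits: %d\n", nrow(x$cr_motifs)))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Whole-genome skew scatter rows
#'
#' One row per genome with the whole-genome A+T%, AT skew, G+C% and GC
#' skew, the form used for cross-taxon strand-bias scatter plots.
#'
#' @param genomes named character vector (or named list) of J-strand genome
#'   sequences; names are the row labels.
#' @param groups optional named vector mapping labels to a grouping label.
#' @return tibble: `label`, `group`, `pct_at`, `at_skew`, `pct_gc`,
#'   `gc_skew`.
#' @export
skew_scatter <- function(genomes, groups = NULL) {
  genomes <- as.list(genomes)
  if (length(genomes) == 0L) stop("no genomes supplied")
  labels <- names(genomes) %||% paste0("genome", seq_along(genomes))
  rows <- lapply(seq_along(genomes), function(i) {
    cs <- composition_summary(genomes[[i]])
    tibble(label = labels[[i]],
           group = if (!is.null(groups)) unname(groups[labels[[i]]]) else NA_character_,
           pct_at = cs$pct_at, at_skew = cs$at_skew,
           pct_gc = cs$pct_gc, gc_skew = cs$gc_skew)
  })
  as_tibble(do.call(rbind, rows))
}
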