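# Shared fixtures and independent brute-force oracles.

delia_annotation <- function() {
  parse_annotation_table(system.file("extdata", "delia_antiqua_mito.tsv",
                                     package = "mitoprofile", mustWork = TRUE))
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# random circular annotation whose consecutive gaps span spacers, overlaps
# and abutments; features never wrap and overlaps stay small relative to
# feature sizes
random_annotation <- function(n = 12L) {
  sizes <- sample(30:120, n, replace = TRUE)
  gaps <- sample(-8:25, n - 1L, replace = TRUE)
  closing <- sample(0:25, 1L)
  start <- integer(n); end <- integer(n)
  start[1] <- 1L; end[1] <- sizes[1]
  for (i in seq_len(n - 1L)) {
    start[i + 1L] <- end[i] + gaps[i] + 1L
    end[i + 1L] <- start[i + 1L] + sizes[i + 1L] - 1L
  }
  mito_annotation(
    tibble::tibble(gene = paste0("f", seq_len(n)),
                   kind = sample(c("PCG", "tRNA", "rRNA"), n, replace = TRUE),
                   strand = sample(c("J", "N"), n, replace = TRUE),
                   start = start, end = end),
    genome_length = end[n] + closing)
}

# per-position coverage oracle: overlap of a consecutive pair is the size of
# the intersection of their position sets; the spacer is counted by walking
# the circle one position at a time from the first feature's end to the
# second feature's start
coverage_gap_oracle <- function(a) {
  L <- genome_length(a)
  pos_set <- function(i) {
    len <- feature_length(a$start[i], a$end[i], L)
    ((a$start[i] - 1L + seq_len(len) - 1L) %% L) + 1L
  }
  n <- nrow(a)
  nxt <- c(seq_len(n)[-1L], 1L)
  vapply(seq_len(n), function(i) {
    j <- nxt[i]
    ov <- length(intersect(pos_set(i), pos_set(j)))
    if (ov > 0L) return(-ov)
    d <- 0L; q <- a$end[i]
    repeat {
      q <- (q %% L) + 1L
      if (q == a$start[j]) break
      d <- d + 1L
      if (d > L) stop("oracle walked the whole circle")
    }
    d
  }, integer(1))
}

rotate_annotation <- function(a, k) {
  L <- genome_length(a)
  rot <- function(x) as.integer(((x - 1L + k) %% L) + 1L)
  f <- tibble::as_tibble(a)
  f$start <- rot(f$start); f$end <- rot(f$end)
  f$anticodon_start <- NA_integer_; f$anticodon_end <- NA_integer_
  mito_annotation(f, genome_length = L)
}

# one-feature annotation holding just a control region, for scanner tests
cr_only_annotation <- function(cr_seq_len, offset = 0L, total = cr_seq_len + offset) {
  mito_annotation(
    tibble::tibble(gene = "Control region", kind = "control_region",
                   strand = "J", start = offset + 1L, end = offset + cr_seq_len),
    genome_length = total)
}
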