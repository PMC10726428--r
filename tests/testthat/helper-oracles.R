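# Shared fixtures and independent brute-force oracles used across tests.

# per-base boolean union of intervals on one chromosome (0-based half-open)
bruteforce_merge <- function(starts, ends, max_bp = NULL) {
  max_bp <- max_bp %||% max(ends)
  covered <- logical(max_bp)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  starts_out <- c(0L, utils::head(stops, -1))[r$values]
  list(start = starts_out, end = stops[r$values])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_intervals <- function(n, span = 2000, max_width = 120) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = s, end = s + w)
}

# does each of a's intervals overlap any of b's (same chromosome, >= 1bp)
bruteforce_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# k-NN by exhaustive distance sort with the package's tie rule
oracle_knn <- function(train, labels, query, k) {
  apply(query, 1, function(qr) {
    d <- sqrt(colSums((t(train) - qr)^2))
    ord <- order(d)
    nn <- labels[ord[seq_len(k)]]
    tab <- table(nn)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else labels[ord[1]]
  })
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small NB count tibble with two groups and planted effects
tiny_cohort <- function(n_regions = 60, n_per_group = 6, delta = 0,
                        n_planted = 0, mu = 50, alpha = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("chr1:%d-%d", (seq_len(n_regions) - 1) * 1000,
                 (seq_len(n_regions) - 1) * 1000 + 500)
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("A", "B"), each = n_per_group)
  )
  lfc <- rep(0, n_regions)
  if (n_planted > 0) lfc[seq_len(n_planted)] <- delta
  m <- sapply(seq_len(nrow(samples)), function(j) {
    f <- if (samples$group[j] == "A") 2^lfc else rep(1, n_regions)
    rnbinom(n_regions, mu = mu * f, size = 1 / alpha)
  })
  rownames(m) <- ids
  colnames(m) <- samples$sample_id
  counts <- dplyr::bind_cols(tibble::tibble(region_id = ids),
                             tibble::as_tibble(m))
  list(counts = counts, samples = samples, planted = ids[lfc != 0])
}
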