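#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join distinct bind_rows bind_cols n row_number across
#'   rename pull slice anti_join semi_join
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 pmap imap
#' @importFrom stats median sd var setNames rnorm rpois rbinom rnbinom runif
#'   p.adjust pnorm pchisq pt qnorm binom.test ks.test lm coef dbinom
#'   complete.cases quantile prcomp cov rlnorm
#' @importFrom utils head tail
#' @importFrom mclust Mclust mclustBIC
NULL

# All genomic coordinates inside the package are 0-based half-open (BED
# convention); 1-based inputs (VCF POS, GRanges) are converted at the
# boundary.

make_region_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse "chrom:start-end" region identifiers
#'
#' Region ids encode a 0-based half-open interval, e.g. `"chr1:100-401"`
#' is the 301-bp interval starting at base 100.
#'
#' @param region_id Character vector of ids of the form `chrom:start-end`.
#' @return A tibble with columns `region_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' parse_region_id("chr1:100-401")
parse_region_id <- function(region_id) {
  m <- regexec("^(.+):([0-9]+)-([0-9]+)$", region_id)
  parts <- regmatches(region_id, m)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) {
    abort(sprintf("malformed region id(s): %s",
                  paste(utils::head(region_id[bad], 3), collapse = ", ")))
  }
  tibble(
    region_id = region_id,
    chrom = vapply(parts, `[[`, character(1), 2L),
    start = as.integer(vapply(parts, `[[`, character(1), 3L)),
    end   = as.integer(vapply(parts, `[[`, character(1), 4L))
  )
}

# Validate and canonicalise a region tibble: requires chrom/start/end,
# adds region_id when missing, sorts chrom (lexicographic) then start.
as_region_tbl <- function(x, provenance = "custom", sort = TRUE) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(paste0("region table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(x$start >= x$end)) abort("region intervals must satisfy start < end")
  if (any(x$start < 0)) abort("negative coordinates are not allowed")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (!"region_id" %in% names(x)) {
    x$region_id <- make_region_id(x$chrom, x$start, x$end)
  }
  if (sort) x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "provenance") <- provenance
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed), order preserved
regions_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_regions <- function(gr, provenance = "custom") {
  as_region_tbl(tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ), provenance = provenance)
}

# logical vector: does each interval of a overlap (>= 1 bp) any interval of b
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  # disjoint chromosome sets are an expected no-overlap case, not a warning
  suppressWarnings(
    GenomicRanges::countOverlaps(regions_to_granges(a),
                                 regions_to_granges(b)) > 0
  )
}

# Extract the numeric count matrix (regions x samples) from a wide count
# tibble whose first column is region_id.
count_matrix <- function(counts) {
  stopifnot(names(counts)[1] == "region_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$region_id
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(region_id = rownames(m)), out)
}

# samples x features matrix from a stabilized wide tibble (transposed view
# used by the classifiers)
signal_matrix <- function(stab) {
  m <- count_matrix(stab)
  t(m)
}

check_sample_alignment <- function(counts, samples) {
  ids <- names(counts)[-1]
  if (!setequal(ids, samples$sample_id)) {
    abort("count matrix columns and sample sheet sample_ids differ")
  }
  if (!identical(ids, samples$sample_id)) {
    # readers never reorder samples; align the sheet to the matrix here
    samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  }
  samples
}
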