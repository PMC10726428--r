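# Readers and writers for the standard formats the pipeline consumes.
# Dialects are strict: malformed lines raise errors naming the line, and
# every reader/writer pair is a round-trip identity on valid files.

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak dialect (BED6 + signalValue, pValue,
#' qValue, peak summit offset).  Coordinates are kept 0-based half-open.
#' Records failing the MACS2-style q-value filter are dropped: a peak is
#' kept when `10^-qvalue_neglog10 < max_qvalue`, i.e.
#' `qvalue_neglog10 > -log10(max_qvalue)`.
#'
#' @param path Path to a narrowPeak file.
#' @param max_qvalue Maximum Benjamini-Hochberg q-value for a peak to be
#'   kept (default 0.05, the conventional peak-calling cutoff).  `NULL`
#'   disables the filter.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue_neglog10`, `qvalue_neglog10`,
#'   `summit_offset`.  A `summit_offset` of -1 means "no summit recorded";
#'   consumers fall back to the interval midpoint.
#' @export
read_narrowpeak <- function(path, max_qvalue = 0.05) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = integer(), strand = character(),
      signal = double(), pvalue_neglog10 = double(),
      qvalue_neglog10 = double(), summit_offset = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    abort(sprintf("narrowPeak parse error at line %d: %d columns (expected 10)",
                  bad, nf[bad]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      abort(sprintf("narrowPeak parse error at line %d: non-numeric %s",
                    which(is.na(v))[1], what))
    }
    v
  }
  out <- tibble(
    chrom = col(1),
    start = as.integer(num(2, "start")),
    end = as.integer(num(3, "end")),
    name = col(4),
    score = as.integer(num(5, "score")),
    strand = col(6),
    signal = num(7, "signalValue"),
    pvalue_neglog10 = num(8, "pValue"),
    qvalue_neglog10 = num(9, "qValue"),
    summit_offset = as.integer(num(10, "summit"))
  )
  if (any(out$start >= out$end)) {
    abort(sprintf("narrowPeak parse error at line %d: start >= end",
                  which(out$start >= out$end)[1]))
  }
  if (!is.null(max_qvalue)) {
    out <- filter(out, .data$qvalue_neglog10 > -log10(max_qvalue))
  }
  out
}

#' Read chromatin loops from a BEDPE file
#'
#' Anchors are canonically ordered (anchor1 upstream of anchor2 for
#' intrachromosomal loops).  The loop span is the outer distance
#' `max(end1, end2) - min(start1, start2)`; loops spanning `max_span` or
#' more are dropped, matching the convention of keeping capture Hi-C
#' interactions spanning less than 2 Mb.
#'
#' @param path Path to a BEDPE file (>= 6 columns; optional name, score).
#' @param max_span Maximum allowed span in bp (default 2e6); `NULL`
#'   disables the filter.  Only applied to intrachromosomal loops.
#' @param same_chrom_only Drop interchromosomal records (default TRUE).
#' @param sample_id Optional label stored in the `sample_id` column.
#' @return Tibble with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `name`, `score`, `sample_id`.
#' @export
read_bedpe_loops <- function(path, max_span = 2e6, same_chrom_only = TRUE,
                             sample_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble(
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    name = character(), score = double(), sample_id = character()
  )
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 6L)) {
    abort(sprintf("BEDPE parse error at line %d: %d columns (expected >= 6)",
                  which(nf < 6L)[1], nf[which(nf < 6L)[1]]))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  num <- function(i) suppressWarnings(as.numeric(col(i)))
  out <- tibble(
    chrom1 = col(1), start1 = as.integer(num(2)), end1 = as.integer(num(3)),
    chrom2 = col(4), start2 = as.integer(num(5)), end2 = as.integer(num(6)),
    name = if (all(nf >= 7)) col(7) else NA_character_,
    score = if (all(nf >= 8)) num(8) else 1,
    sample_id = sample_id
  )
  out$score[is.na(out$score)] <- 1
  if (any(out$start1 < 0 | out$start2 < 0, na.rm = TRUE)) {
    abort("BEDPE parse error: negative coordinates")
  }
  # canonical anchor order
  swap <- out$chrom1 > out$chrom2 |
    (out$chrom1 == out$chrom2 & out$start1 > out$start2)
  if (any(swap)) {
    tmp <- out[swap, c("chrom1", "start1", "end1")]
    out[swap, c("chrom1", "start1", "end1")] <-
      out[swap, c("chrom2", "start2", "end2")]
    out[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  if (same_chrom_only) out <- filter(out, .data$chrom1 == .data$chrom2)
  if (!is.null(max_span)) {
    span <- pmax(out$end1, out$end2) - pmin(out$start1, out$start2)
    out <- out[out$chrom1 != out$chrom2 | span < max_span, , drop = FALSE]
  }
  out
}

#' Read genotypes from a minimal VCF
#'
#' Keeps biallelic single-nucleotide variants only; indels and
#' multiallelic records are skipped with a message reporting the counts.
#' GT fields (phased or unphased) are mapped to alt-allele dosages 0/1/2
#' (`NA` for missing genotypes).  The INFO `R2` imputation quality is
#' extracted when present; a missing `R2` is interpreted downstream as a
#' directly genotyped variant (quality 1).
#'
#' Positions are converted to the package's 0-based convention
#' (`pos = POS - 1`).
#'
#' @param path Path to an uncompressed or bgzipped VCF 4.x file.
#' @return Wide tibble: `variant_id`, `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `imputation_r2`, then one dosage column per sample.  Sample
#'   ids are recorded in the `"sample_ids"` attribute.
#' @export
read_vcf_minimal <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("VCF format error: ", conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  keep <- snv & !multi
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(sprintf("read_vcf_minimal: skipped %d non-biallelic-SNV record(s) (%d multiallelic)",
                   n_skip, sum(multi)))
  }
  pos1 <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- sprintf("%s:%d:%s:%s", fix[noid, "CHROM"], pos1[noid],
                      ref[noid], alt[noid])
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "R2")))
  if (length(r2) == 0) r2 <- rep(NA_real_, nrow(fix))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose_of <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
           vapply(strsplit(g, "/", fixed = TRUE),
                  function(a) sum(a == "1"), double(1)))
  }
  dos <- apply(gt, 2, dose_of)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  out <- tibble(
    variant_id = id[keep],
    chrom = fix[keep, "CHROM"],
    pos = pos1[keep] - 1L,
    ref = ref[keep],
    alt = alt[keep],
    imputation_r2 = r2[keep]
  )
  dos_tbl <- as_tibble(dos[keep, , drop = FALSE], .name_repair = "minimal")
  out <- bind_cols(out, dos_tbl)
  attr(out, "sample_ids") <- colnames(gt)
  out
}

#' Read and write region-by-sample count matrices
#'
#' The TSV dialect has a first column `region_id` holding
#' `chrom:start-end` ids (0-based half-open) and one non-negative integer
#' column per sample.  `write_counts()` followed by `read_counts()` is an
#' identity.
#'
#' @param path File path.
#' @return `read_counts()`: a wide count tibble.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(out)[1] <- "region_id"
  out$region_id <- as.character(out$region_id)
  if (!all(vapply(out[-1], is.numeric, logical(1)))) {
    abort("count matrix contains non-numeric cells")
  }
  m <- as.matrix(out[, -1, drop = FALSE])
  if (anyNA(m)) abort("count matrix contains missing cells")
  if (any(m < 0)) abort("count matrix contains negative counts")
  if (any(m != round(m))) abort("count matrix contains non-integer counts")
  if (anyDuplicated(out$region_id)) {
    abort(sprintf("duplicate region id: %s",
                  out$region_id[duplicated(out$region_id)][1]))
  }
  out
}

#' @rdname read_counts
#' @param counts Wide count tibble (first column `region_id`).
#' @export
write_counts <- function(counts, path) {
  stopifnot(names(counts)[1] == "region_id")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED3/BED6 with the usual 0-based half-open coordinates.  Extra columns
#' beyond the sixth are ignored on read.
#'
#' @param path File path.
#' @return `read_bed()`: region tibble (`chrom`, `start`, `end`,
#'   optionally `name`, `score`, `strand`, plus a derived `region_id`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(as_region_tbl(tibble(chrom = character(), start = integer(),
                                end = integer()), sort = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(vapply(fields, length, integer(1)))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(chrom = col(1),
                start = as.integer(col(2)),
                end = as.integer(col(3)))
  if (nf >= 4) out$name <- col(4)
  if (nf >= 5) out$score <- suppressWarnings(as.numeric(col(5)))
  if (nf >= 6) out$strand <- col(6)
  as_region_tbl(out, sort = FALSE)
}

#' @rdname read_bed
#' @param regions Region tibble.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(regions))
  # BED columns are positional: stop at the first absent one
  keep <- character(0)
  for (cn in c("chrom", "start", "end", "name", "score", "strand")) {
    if (cn %in% cols) keep <- c(keep, cn) else break
  }
  readr::write_tsv(regions[, keep, drop = FALSE], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' One transcript/gene per line.  The TSS is the leftmost base on the
#' plus strand and the rightmost base (end - 1, 0-based) on the minus
#' strand.  Exon blocks and the thick (CDS) interval are retained so that
#' annotation can distinguish UTRs from coding exons.
#'
#' @param path Path to a BED12 file.
#' @return Tibble: `gene_id`, `gene_name`, `chrom`, `strand`, `start`,
#'   `end`, `tss` (0-based position of the transcription start site),
#'   `thick_start`, `thick_end`, and `exons` (list-column of tibbles with
#'   `start`/`end`).
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (length(nf) > 0 && any(nf < 12L)) {
    abort(sprintf("BED12 parse error at line %d: %d columns (expected 12)",
                  which(nf < 12L)[1], nf[which(nf < 12L)[1]]))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- as.integer(f[2]); end <- as.integer(f[3])
    strand <- f[6]
    n_blk <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offs <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blk || length(offs) != n_blk) {
      abort(sprintf("BED12 parse error at line %d: blockCount mismatch", i))
    }
    ex <- tibble(start = start + offs, end = start + offs + sizes)
    tibble(
      gene_id = f[4], gene_name = f[4], chrom = f[1], strand = strand,
      start = start, end = end,
      tss = if (strand == "-") end - 1L else start,
      thick_start = as.integer(f[7]), thick_end = as.integer(f[8]),
      exons = list(ex)
    )
  })
  if (length(rows) == 0) {
    return(tibble(gene_id = character(), gene_name = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(), tss = integer(),
                  thick_start = integer(), thick_end = integer(),
                  exons = list()))
  }
  bind_rows(rows)
}

#' Read a sample sheet
#'
#' TSV with a `sample_id` column, a group label column (subtype or
#' progenitor stage) and any number of covariate columns.  Sample ids
#' must be unique; downstream stages align count-matrix columns to this
#' order and never silently reorder samples.
#'
#' @param path Path to the TSV.
#' @return Tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"sample_id" %in% names(out)) abort("sample sheet lacks a sample_id column")
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  out$sample_id[duplicated(out$sample_id)][1]))
  }
  out
}
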