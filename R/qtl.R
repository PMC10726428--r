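# Allele-specific chromatin-accessibility QTL scan: total-count
# association (OLS on stabilized signal) and allelic imbalance at
# heterozygotes (exact binomial, optional beta-binomial), combined by
# Fisher's method with a genome-wide BH FDR.

geno_sample_ids <- function(geno) {
  ids <- attr(geno, "sample_ids")
  if (is.null(ids)) {
    meta <- c("variant_id", "chrom", "pos", "ref", "alt", "imputation_r2",
              "region_id", "maf", "causal", "beta", "pi")
    ids <- setdiff(names(geno), meta)
  }
  ids
}

#' Filter variants to testable candidate (variant, region) pairs
#'
#' Keeps biallelic SNVs that (1) fall inside an open-chromatin region,
#' (2) have imputation quality `R2 >= min_r2` (a missing `R2` means the
#' variant was directly genotyped and passes), and (3) reach a sample
#' minor-allele frequency of `min_maf`.  Each surviving variant is
#' paired with its containing region.
#'
#' @param geno Wide genotype tibble from [read_vcf_minimal()] or
#'   [simulate_genotypes_allelic()] (variant metadata plus one dosage
#'   column per sample).
#' @param roi Region tibble of open-chromatin regions (non-overlapping).
#' @param min_r2 Imputation-quality threshold (default 0.80).
#' @param min_maf Sample MAF threshold (default 0.05).
#' @return Tibble of candidate pairs: variant metadata, `region_id`,
#'   `maf`, and the dosage columns; sample ids preserved in the
#'   attribute.
#' @export
filter_variants <- function(geno, roi, min_r2 = 0.80, min_maf = 0.05) {
  ids <- geno_sample_ids(geno)
  roi <- as_region_tbl(roi)
  dos <- as.matrix(geno[, ids, drop = FALSE])
  snv <- nchar(geno$ref) == 1 & nchar(geno$alt) == 1 & geno$ref != geno$alt
  r2 <- geno$imputation_r2
  r2[is.na(r2)] <- 1.0
  p_alt <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- snv & r2 >= min_r2 & maf >= min_maf
  g <- geno[keep, , drop = FALSE]
  g$maf <- maf[keep]
  # containing region (point containment; ROI regions are disjoint)
  gr_v <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_v, regions_to_granges(roi))
  region <- rep(NA_character_, nrow(g))
  region[S4Vectors::queryHits(hits)] <- roi$region_id[S4Vectors::subjectHits(hits)]
  g$region_id <- region
  g <- g[!is.na(g$region_id), , drop = FALSE]
  attr(g, "sample_ids") <- ids
  g
}

#' Total-count association: stabilized signal on alt dosage
#'
#' Per candidate pair, ordinary least squares of the region's stabilized
#' accessibility on the alt-allele dosage (plus optional sample-level
#' covariates, projected out exactly via residualization); two-sided
#' t-test p-value.  Pairs with constant dosage are skipped.
#'
#' @param stab Stabilized wide tibble from [stabilize()].
#' @param pairs Candidate pairs from [filter_variants()].
#' @param samples Optional sample sheet (required when `covariates` are
#'   requested).
#' @param covariates Character vector of covariate columns.
#' @return Tibble `variant_id`, `region_id`, `beta`, `se_beta`,
#'   `p_total`, `n` (beta in log2 accessibility units per alt dosage).
#' @export
total_assoc <- function(stab, pairs, samples = NULL, covariates = NULL) {
  ids <- geno_sample_ids(pairs)
  sm <- count_matrix(stab)
  if (!all(ids %in% colnames(sm))) {
    abort("stabilized matrix lacks some genotyped samples")
  }
  sm <- sm[, ids, drop = FALSE]
  miss_r <- setdiff(unique(pairs$region_id), rownames(sm))
  if (length(miss_r) > 0) abort("stabilized matrix lacks some candidate regions")
  Y <- t(sm[pairs$region_id, , drop = FALSE])            # n x P
  D <- t(as.matrix(pairs[, ids, drop = FALSE]))          # n x P
  n <- nrow(Y)
  q <- 1L
  if (length(covariates) > 0) {
    if (is.null(samples)) abort("covariates need a sample sheet")
    smp <- samples[match(ids, samples$sample_id), , drop = FALSE]
    Z <- stats::model.matrix(stats::reformulate(covariates), data = smp)
  } else {
    Z <- matrix(1, n, 1)
  }
  q <- ncol(Z)
  # residualize signal and dosage on covariates (Frisch-Waugh)
  qrz <- qr(Z)
  Yr <- Y - qr.fitted(qrz, Y)
  Dr <- D - qr.fitted(qrz, D)
  sxx <- colSums(Dr^2)
  sxy <- colSums(Dr * Yr)
  df <- n - q - 1L
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  rss <- colSums(Yr^2) - ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = df)
  out <- tibble(
    variant_id = pairs$variant_id, region_id = pairs$region_id,
    beta = unname(beta), se_beta = unname(se), p_total = unname(p),
    n = n
  )
  skipped <- sum(is.na(out$beta))
  if (skipped > 0) {
    inform(sprintf("total_assoc: %d pair(s) with constant dosage skipped", skipped))
  }
  filter(out, !is.na(.data$beta))
}

dbetabinom_ <- function(k, n, a, b) {
  exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Allelic-imbalance test at heterozygous samples
#'
#' Ref/alt ATAC reads are pooled across heterozygous carriers of each
#' variant; `pi = alt/(alt+ref)` and the two-sided exact binomial test
#' of `pi = 0.5` give the allelic evidence.  With
#' `method = "betabinomial"` and at least 5 heterozygotes, a
#' beta-binomial test with moment-estimated overdispersion is used
#' instead (robust to sample-to-sample variation in imbalance).
#' Variants with fewer than `min_het` heterozygotes or fewer than
#' `min_reads` pooled reads get missing results and degrade the
#' combined test to the total-count arm.
#'
#' @param allele_counts Tibble `variant_id`, `sample_id`, `ref_reads`,
#'   `alt_reads` (heterozygous samples only).
#' @param min_het,min_reads Testability gates (defaults 2 and 10).
#' @param method `"binomial"` (default) or `"betabinomial"`.
#' @return Tibble `variant_id`, `n_het`, `ref_reads`, `alt_reads`, `pi`,
#'   `p_allelic`.
#' @export
allelic_test <- function(allele_counts, min_het = 2, min_reads = 10,
                         method = c("binomial", "betabinomial")) {
  method <- match.arg(method)
  ac <- allele_counts |>
    group_by(.data$variant_id) |>
    summarise(n_het = n(),
              # per-het fractions must be computed before the pooled sums
              # shadow the read columns
              frac_list = list(.data$alt_reads /
                                 pmax(.data$alt_reads + .data$ref_reads, 1)),
              ref_reads = sum(.data$ref_reads),
              alt_reads = sum(.data$alt_reads),
              .groups = "drop")
  tot <- ac$ref_reads + ac$alt_reads
  testable <- ac$n_het >= min_het & tot >= min_reads
  pi <- ifelse(testable, ac$alt_reads / tot, NA_real_)
  pv <- rep(NA_real_, nrow(ac))
  for (i in which(testable)) {
    if (method == "betabinomial" && ac$n_het[i] >= 5) {
      # moment-match overdispersion from per-het alt fractions
      fr <- ac$frac_list[[i]]
      v <- var(fr)
      mu <- 0.5
      rho <- max(min((v - mu * (1 - mu) / (tot[i] / ac$n_het[i])) /
                       (mu * (1 - mu)), 0.9), 1e-6)
      s <- (1 - rho) / rho
      a <- mu * s; b <- (1 - mu) * s
      dens <- dbetabinom_(0:tot[i], tot[i], a, b)
      k <- ac$alt_reads[i]
      lo <- sum(dens[seq_len(k + 1)])
      hi <- sum(dens[(k + 1):(tot[i] + 1)])
      # tail doubling: monotone two-sided p even for U-shaped mixtures
      pv[i] <- min(1, 2 * min(lo, hi))
    } else {
      pv[i] <- binom.test(ac$alt_reads[i], tot[i], p = 0.5)$p.value
    }
  }
  tibble(variant_id = ac$variant_id, n_het = ac$n_het,
         ref_reads = ac$ref_reads, alt_reads = ac$alt_reads,
         pi = pi, p_allelic = pv)
}

#' Combine total and allelic evidence and apply genome-wide FDR
#'
#' Fisher's method combines `p_total` and `p_allelic` when both exist
#' (`X = -2(ln p_t + ln p_a) ~ chi^2_4`); otherwise the available
#' p-value is used.  Benjamini-Hochberg q-values are computed across all
#' pairs genome-wide; significant QTLs have `qvalue < fdr_level`
#' (default 10% FDR).  Per region, the lead variant is the smallest
#' combined p (position breaks ties).
#'
#' @param total Result of [total_assoc()].
#' @param allelic Result of [allelic_test()] (optional).
#' @param fdr_level FDR threshold (default 0.10).
#' @param positions Optional tibble `variant_id`, `pos` used for lead
#'   tie-breaking.
#' @return Tibble: per-pair effect records with `p_combined`, `qvalue`,
#'   `significant`, `lead`.
#' @export
combine_and_fdr <- function(total, allelic = NULL, fdr_level = 0.10,
                            positions = NULL) {
  out <- total
  if (!is.null(allelic)) {
    out <- left_join(out, allelic[, c("variant_id", "pi", "p_allelic")],
                     by = "variant_id")
  } else {
    out$pi <- NA_real_
    out$p_allelic <- NA_real_
  }
  if (nrow(out) == 0) abort("no testable pairs")
  both <- !is.na(out$p_total) & !is.na(out$p_allelic)
  pc <- ifelse(is.na(out$p_allelic), out$p_total,
               ifelse(is.na(out$p_total), out$p_allelic, NA_real_))
  if (any(both)) {
    x <- -2 * (log(pmax(out$p_total[both], 1e-300)) +
                 log(pmax(out$p_allelic[both], 1e-300)))
    pc[both] <- pchisq(x, df = 4, lower.tail = FALSE)
  }
  out$p_combined <- pc
  out$qvalue <- p.adjust(out$p_combined, method = "BH")
  out$significant <- out$qvalue < fdr_level
  if (!is.null(positions)) {
    out <- left_join(out, positions[, c("variant_id", "pos")], by = "variant_id")
  }
  if (!"pos" %in% names(out)) out$pos <- NA_integer_
  out <- out |>
    group_by(.data$region_id) |>
    arrange(.data$p_combined, .data$pos, .by_group = TRUE) |>
    mutate(lead = row_number() == 1) |>
    ungroup() |>
    arrange(.data$region_id, .data$pos)
  out
}

#' Overlap of significant QTLs with bound TF motif footprints
#'
#' A QTL overlaps a footprint when its position lies inside a bound
#' motif occurrence.  Returns the overlap fraction and a per-motif
#' abundance table ranked by descending count.
#'
#' @param qtls Significant QTL tibble with `chrom` and `pos` (0-based).
#' @param occurrences Tibble of motif occurrences with `chrom`, `start`,
#'   `end`, `motif_id`, `bound`.
#' @return List: `summary` (tibble `n_qtls`, `n_overlapping`,
#'   `fraction`) and `per_motif` (tibble `motif_id`, `n`, ranked).
#' @export
qtl_footprint_overlap <- function(qtls, occurrences) {
  occ <- filter(as_tibble(occurrences), .data$bound)
  n <- nrow(qtls)
  if (n == 0 || nrow(occ) == 0) {
    return(list(summary = tibble(n_qtls = n, n_overlapping = 0L, fraction = ifelse(n > 0, 0, NA_real_)),
                per_motif = tibble(motif_id = character(), n = integer())))
  }
  gr_q <- GenomicRanges::GRanges(qtls$chrom, IRanges::IRanges(qtls$pos + 1L, width = 1L))
  gr_o <- GenomicRanges::GRanges(occ$chrom, IRanges::IRanges(occ$start + 1L, occ$end))
  hits <- GenomicRanges::findOverlaps(gr_q, gr_o)
  n_over <- length(unique(S4Vectors::queryHits(hits)))
  per_motif <- tibble(motif_id = occ$motif_id[S4Vectors::subjectHits(hits)]) |>
    dplyr::count(.data$motif_id, sort = TRUE)
  list(summary = tibble(n_qtls = n, n_overlapping = n_over,
                        fraction = n_over / n),
       per_motif = per_motif)
}

#' Concordance of QTL effect directions with an external eQTL table
#'
#' Joins by variant id, harmonizes alleles (a ref/alt swap in the
#' external table flips its sign; allele mismatches are excluded and
#' counted), and reports the fraction of shared variants whose
#' accessibility effect sign matches the external effect sign.
#'
#' @param qtls QTL tibble with `variant_id`, `ref`, `alt`, `beta`.
#' @param external Tibble with `variant_id`, `ref`, `alt`, and `effect`
#'   (signed effect or sign).
#' @return Tibble `n_shared`, `n_concordant`, `concordant_fraction`,
#'   `n_unorientable`.
#' @export
eqtl_concordance <- function(qtls, external) {
  j <- inner_join(qtls[, c("variant_id", "ref", "alt", "beta")],
                  external[, c("variant_id", "ref", "alt", "effect")],
                  by = "variant_id", suffix = c("", "_ext"))
  same <- j$ref == j$ref_ext & j$alt == j$alt_ext
  swapped <- j$ref == j$alt_ext & j$alt == j$ref_ext
  orientable <- same | swapped
  n_bad <- sum(!orientable)
  if (n_bad > 0) {
    inform(sprintf("eqtl_concordance: %d unorientable record(s) excluded", n_bad))
  }
  eff <- ifelse(swapped, -j$effect, j$effect)
  conc <- sign(j$beta) == sign(eff)
  conc <- conc[orientable]
  tibble(n_shared = sum(orientable),
         n_concordant = sum(conc),
         concordant_fraction = if (sum(orientable) > 0) mean(conc) else NA_real_,
         n_unorientable = n_bad)
}
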