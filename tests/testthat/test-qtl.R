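# Variant filtering, the two-part QTL test, Fisher combination and
# downstream overlap/concordance reports.

test_that("filter_variants applies R2, ROI and MAF gates and pairs regions", {
  roi <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  dos <- function(...) rlang::set_names(list(...), sprintf("s%d", 1:4))
  geno <- tibble::tibble(
    variant_id = sprintf("v%d", 1:5),
    chrom = "chr1",
    pos = c(100L, 1200L, 700L, 300L, 1300L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G"),
    imputation_r2 = c(NA, 0.9, NA, 0.5, 0.95),
    s1 = c(1, 0, 1, 1, 0), s2 = c(1, 1, 0, 1, 0),
    s3 = c(0, 2, 1, 0, 0), s4 = c(2, 1, 2, 2, 0)
  )
  attr(geno, "sample_ids") <- sprintf("s%d", 1:4)
  got <- filter_variants(geno, roi, min_r2 = 0.80, min_maf = 0.05)
  # v1: in ROI1, genotyped (R2 NA -> 1), MAF .5 -> kept
  # v2: in ROI2, R2 .9 -> kept; v3: outside ROIs; v4: R2 .5 < .8;
  # v5: monomorphic (MAF 0)
  expect_equal(got$variant_id, c("v1", "v2"))
  expect_equal(got$region_id, c("chr1:0-500", "chr1:1000-1500"))
})

test_that("total association equals lm, with and without covariates", {
  set.seed(51)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  dosage <- rbinom(n, 2, 0.4)
  covar <- rnorm(n)
  y1 <- 0.4 * dosage + 0.8 * covar + rnorm(n)
  y2 <- rnorm(n)
  ym <- rbind(y1, y2)
  colnames(ym) <- ids
  stab <- dplyr::bind_cols(
    tibble::tibble(region_id = c("chr1:0-500", "chr1:1000-1500")),
    tibble::as_tibble(ym))
  pairs <- tibble::tibble(variant_id = c("v1", "v2"),
                          region_id = c("chr1:0-500", "chr1:1000-1500"))
  dm <- rbind(dosage, dosage)
  colnames(dm) <- ids
  pairs <- dplyr::bind_cols(pairs, tibble::as_tibble(dm))
  attr(pairs, "sample_ids") <- ids
  samples <- tibble::tibble(sample_id = ids, covar = covar)

  got <- total_assoc(stab, pairs, samples, covariates = "covar")
  for (i in 1:2) {
    y <- as.numeric(stab[i, -1])
    ref <- summary(lm(y ~ dosage + covar))$coefficients["dosage", ]
    expect_equal(got$beta[i], unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(got$se_beta[i], unname(ref["Std. Error"]), tolerance = 1e-10)
    expect_equal(got$p_total[i], unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  }
  plain <- total_assoc(stab, pairs)
  ref0 <- summary(lm(as.numeric(stab[1, -1]) ~ dosage))$coefficients["dosage", ]
  expect_equal(plain$beta[1], unname(ref0["Estimate"]), tolerance = 1e-10)
  expect_equal(plain$p_total[1], unname(ref0["Pr(>|t|)"]), tolerance = 1e-10)

  # constant dosage is skipped
  const <- pairs
  for (id in ids) const[[id]] <- 1
  expect_equal(nrow(suppressMessages(total_assoc(stab, const))), 0)
})

test_that("allelic test: pooled pi, exact binomial tails, gates", {
  even <- tibble::tibble(variant_id = "v", sample_id = sprintf("h%d", 1:5),
                         ref_reads = 5, alt_reads = 5)
  r <- allelic_test(even)
  expect_equal(r$pi, 0.5)
  expect_equal(r$p_allelic, 1)

  skew <- tibble::tibble(variant_id = "v", sample_id = sprintf("h%d", 1:5),
                         ref_reads = 2, alt_reads = 8)
  r2 <- allelic_test(skew)
  expect_equal(r2$pi, 0.8)
  # symmetric null: two-sided tail is 2 * P(X <= 10) for X ~ Bin(50, 1/2)
  expect_equal(r2$p_allelic, 2 * pbinom(10, 50, 0.5), tolerance = 1e-12)

  gated <- tibble::tibble(variant_id = "v", sample_id = "h1",
                          ref_reads = 2, alt_reads = 2)
  r3 <- allelic_test(gated)  # 1 het, 4 reads: below both gates
  expect_true(is.na(r3$pi) && is.na(r3$p_allelic))

  # beta-binomial variant stays valid and is more conservative under
  # sample-to-sample heterogeneity
  set.seed(52)
  het <- tibble::tibble(variant_id = "v", sample_id = sprintf("h%d", 1:8),
                        ref_reads = c(30, 2, 25, 3, 28, 1, 26, 4),
                        alt_reads = c(2, 29, 3, 27, 2, 30, 3, 28))
  pbb <- allelic_test(het, method = "betabinomial")$p_allelic
  expect_true(pbb >= 0 && pbb <= 1)
  expect_gt(pbb, 0.05)  # balanced pooled counts: no imbalance call
})

test_that("Fisher combination matches the chi-square df 4 closed form", {
  total <- tibble::tibble(variant_id = c("v1", "v2"),
                          region_id = c("r1", "r2"),
                          beta = c(0.3, 0), se_beta = 0.1,
                          p_total = c(0.01, 1), n = 50)
  allelic <- tibble::tibble(variant_id = c("v1", "v2"), n_het = 5,
                            ref_reads = 20, alt_reads = 30,
                            pi = c(0.6, 0.5), p_allelic = c(0.04, 1))
  got <- combine_and_fdr(total, allelic, fdr_level = 0.10)
  # closed form for chi2 with 4 df: P(X > x) = exp(-x/2) * (1 + x/2)
  x <- -2 * (log(0.01) + log(0.04))
  expect_equal(got$p_combined[got$variant_id == "v1"],
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(got$p_combined[got$variant_id == "v2"], 1)
  expect_equal(got$qvalue, p.adjust(got$p_combined, "BH"))

  # a missing allelic arm degrades to the total p-value
  solo <- combine_and_fdr(total[1, ], NULL)
  expect_equal(solo$p_combined, 0.01)
  expect_true(solo$lead)
})

test_that("ref/alt relabeling negates beta, reflects pi, keeps p-values", {
  coh <- simulate_cohort(n_subtypes = 1, n_per_subtype = 40, n_regions = 300,
                         enriched_frac = 0.01, delta = 0,
                         correlated_pair = NULL, seed = 53)
  g <- simulate_genotypes_allelic(coh, frac_regions = 0.2, frac_causal = 0.5,
                                  seed = 53)
  stab <- stabilize(g$counts)
  pairs <- filter_variants(g$geno, coh$truth$regions)
  ta <- suppressMessages(total_assoc(stab, pairs))
  al <- allelic_test(g$allele_counts)

  ids <- attr(pairs, "sample_ids")
  flipped <- pairs
  for (id in ids) flipped[[id]] <- 2 - flipped[[id]]
  ta2 <- suppressMessages(total_assoc(stab, flipped))
  expect_equal(ta2$beta, -ta$beta, tolerance = 1e-10)
  expect_equal(ta2$p_total, ta$p_total, tolerance = 1e-10)

  swapped <- g$allele_counts
  swapped$tmp <- swapped$ref_reads
  swapped$ref_reads <- swapped$alt_reads
  swapped$alt_reads <- swapped$tmp
  al2 <- allelic_test(swapped[, names(g$allele_counts)])
  expect_equal(al2$pi, 1 - al$pi, tolerance = 1e-12)
  expect_equal(al2$p_allelic, al$p_allelic, tolerance = 1e-12)
})

test_that("QTL-footprint overlap counts bound occurrences only", {
  qtls <- tibble::tibble(variant_id = sprintf("v%d", 1:4),
                         chrom = "chr1", pos = c(105L, 205L, 305L, 405L))
  occ <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 200L, 300L),
                        end = c(110L, 210L, 310L),
                        motif_id = c("Ma", "Mb", "Ma"),
                        bound = c(TRUE, FALSE, TRUE))
  ov <- qtl_footprint_overlap(qtls, occ)
  expect_equal(ov$summary$n_overlapping, 2L)  # v1 and v3; v2 unbound; v4 outside
  expect_equal(ov$summary$fraction, 0.5)
  expect_equal(ov$per_motif$motif_id, "Ma")
  expect_equal(ov$per_motif$n, 2L)
})

test_that("eQTL concordance harmonizes alleles before comparing signs", {
  qtls <- tibble::tibble(variant_id = c("v1", "v2", "v3", "v4"),
                         ref = c("A", "C", "G", "T"),
                         alt = c("G", "T", "A", "A"),
                         beta = c(0.5, -0.3, 0.2, 0.4))
  ext_same <- qtls
  ext_same$effect <- ext_same$beta
  expect_equal(eqtl_concordance(qtls, ext_same)$concordant_fraction, 1.0)

  ext_flip <- ext_same
  ext_flip$effect <- -ext_flip$effect
  expect_equal(eqtl_concordance(qtls, ext_flip)$concordant_fraction, 0.0)

  # one allele-swapped record flips its sign; one unorientable is dropped
  ext <- ext_same
  ext$ref[3] <- "A"; ext$alt[3] <- "G"       # swap: effect must be negated
  ext$effect[3] <- -qtls$beta[3]             # so harmonized sign matches
  ext$ref[4] <- "C"; ext$alt[4] <- "G"       # mismatched alleles
  r <- suppressMessages(eqtl_concordance(qtls, ext))
  expect_equal(r$n_shared, 3L)
  expect_equal(r$n_unorientable, 1L)
  expect_equal(r$concordant_fraction, 1.0)
})

test_that("planted QTLs are recovered and nulls stay quiet at desk scale", {
  coh <- simulate_cohort(n_subtypes = 1, n_per_subtype = 60, n_regions = 600,
                         enriched_frac = 0.01, delta = 0,
                         correlated_pair = NULL, seed = 54)
  g <- simulate_genotypes_allelic(coh, frac_regions = 0.3, frac_causal = 0.5,
                                  beta = 0.5, pi = 0.7, seed = 54)
  stab <- stabilize(g$counts)
  pairs <- filter_variants(g$geno, coh$truth$regions)
  q <- combine_and_fdr(suppressMessages(total_assoc(stab, pairs)),
                       allelic_test(g$allele_counts),
                       positions = g$truth)
  causal <- g$truth$variant_id[g$truth$causal]
  sens <- mean(causal %in% q$variant_id[q$significant])
  expect_gte(sens, 0.8)
  fdr <- mean(!q$variant_id[q$significant] %in% causal)
  expect_lte(fdr, 0.15)
})
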