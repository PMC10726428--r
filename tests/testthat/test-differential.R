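# Normalization, dispersion, NB Wald testing and the DAS selection rules.

test_that("size factors are median-of-ratios", {
  counts <- tibble::tibble(region_id = c("r1", "r2", "r3"),
                           a = c(2, 3, 5), b = c(4, 6, 10), c = c(8, 12, 20))
  sf <- size_factors(counts)
  expect_equal(sf$size_factor, c(0.5, 1, 2))  # hand-computed ratios

  same <- tibble::tibble(region_id = c("r1", "r2"), a = c(5, 9), b = c(5, 9))
  expect_equal(size_factors(same)$size_factor, c(1, 1))

  zero <- tibble::tibble(region_id = c("r1", "r2"), a = c(0, 5), b = c(3, 0))
  expect_error(size_factors(zero), "all-positive")
})

test_that("stabilize is log2(normalized + 1) with optional row Z-scores", {
  counts <- tibble::tibble(region_id = c("r1", "r2"),
                           a = c(0, 7), b = c(0, 31))
  v <- stabilize(counts, sf = tibble::tibble(sample_id = c("a", "b"),
                                             size_factor = c(1, 1)))
  expect_equal(v$a, c(0, 3))        # log2(7 + 1) = 3
  expect_equal(v$b, c(0, 5))
  z <- stabilize(counts, sf = tibble::tibble(sample_id = c("a", "b"),
                                             size_factor = c(1, 1)),
                 z_score = TRUE)
  zm <- as.matrix(z[2, -1])
  expect_equal(mean(zm), 0)
  expect_equal(sd(zm), 1)
})

test_that("dispersion: zero-variance floors, Poisson rows stay small, NB recovered", {
  set.seed(5)
  n <- 50
  pois <- t(sapply(1:100, function(i) rpois(n, 60)))
  nb <- t(sapply(1:100, function(i) rnbinom(n, mu = 60, size = 1 / 0.5)))
  m <- rbind(pois, nb, matrix(7, 1, n))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  counts <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("r%03d", seq_len(nrow(m)))),
    tibble::as_tibble(as.data.frame(m))
  )
  disp <- estimate_dispersion(counts)
  expect_equal(disp$alpha_mom[201], 1e-8)             # constant row
  expect_lt(mean(disp$alpha_mom[1:100]), 0.05)        # Poisson-like
  expect_lt(abs(mean(disp$alpha_mom[101:200]) - 0.5), 0.15)  # alpha = 0.5 +- 30%
})

test_that("nb_wald: exact null rows, antisymmetry, planted effect recovery", {
  cc <- tiny_cohort(n_regions = 300, n_per_group = 10, delta = 2,
                    n_planted = 50, seed = 2)
  res <- suppressMessages(
    nb_wald(cc$counts, cc$samples, group = "group", contrast = c("A", "B")))
  # identical counts in the two groups give log2FC 0 and p 1
  flat <- cc$counts
  for (j in seq(2, ncol(flat))) flat[[j]] <- flat[[2]]
  res_flat <- suppressMessages(
    nb_wald(flat, cc$samples, group = "group", contrast = c("A", "B")))
  expect_lt(max(abs(res_flat$log2FC)), 1e-6)
  expect_gt(min(res_flat$pvalue), 1 - 1e-6)

  # swapping the contrast negates log2FC and keeps p
  swp <- suppressMessages(
    nb_wald(cc$counts, cc$samples, group = "group", contrast = c("B", "A")))
  expect_equal(swp$log2FC, -res$log2FC, tolerance = 1e-8)
  expect_equal(swp$pvalue, res$pvalue, tolerance = 1e-8)

  # planted log2FC = 2 (fold change 4) at n = 10 + 10
  planted <- res$region_id %in% cc$planted
  expect_gt(median(res$log2FC[planted]), 1.6)
  expect_lt(median(res$log2FC[planted]), 2.4)
  expect_equal(res$stat, res$log2FC / res$lfcSE, tolerance = 1e-12)
  # BH keeps padj >= pvalue
  expect_true(all(res$padj >= res$pvalue - 1e-12, na.rm = TRUE))
})

test_that("nb_wald agrees with DESeq2 on a small matrix", {
  skip_if_not_installed("DESeq2")
  cc <- tiny_cohort(n_regions = 150, n_per_group = 6, delta = 1.5,
                    n_planted = 30, seed = 4)
  res <- suppressMessages(
    nb_wald(cc$counts, cc$samples, group = "group", contrast = c("A", "B")))
  m <- as.matrix(cc$counts[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- cc$counts$region_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(group = factor(cc$samples$group, levels = c("B", "A"))),
    ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("group", "A", "B"))
  expect_gt(cor(res$log2FC, ref$log2FoldChange), 0.97)
  expect_gt(cor(res$stat, ref$stat), 0.95)
  sig_ref <- which(ref$padj < 1e-4)
  expect_true(all(res$padj[sig_ref] < 0.1, na.rm = TRUE))
})

test_that("covariates enter the design and a confounder is adjusted away", {
  set.seed(8)
  n <- 24
  batch <- rep(c("u", "v"), each = n / 2)
  grp <- rep(c("A", "B"), times = n / 2)  # balanced across batch
  mu <- ifelse(batch == "u", 40, 120)     # strong batch effect, no group effect
  m <- t(sapply(1:120, function(i) rnbinom(n, mu = mu, size = 1 / 0.1)))
  colnames(m) <- sprintf("s%02d", 1:n)
  counts <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("r%03d", 1:120)),
    tibble::as_tibble(as.data.frame(m)))
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                            group = grp, batch = batch)
  res <- suppressMessages(nb_wald(counts, samples, group = "group",
                                  contrast = c("A", "B"),
                                  covariates = "batch"))
  expect_equal(sum(res$padj < 0.05, na.rm = TRUE), 0)
  expect_true(all(res$converged))
})

test_that("exclusivity filter keeps regions significant in exactly one subtype", {
  ovr <- tidyr::crossing(subtype = c("X", "Y", "Z"),
                         region_id = sprintf("r%d", 1:8))
  ovr$log2FC <- 1.5
  ovr$padj <- 0.5
  ovr$significant <- FALSE
  mark <- function(d, r, s, lfc = 1.5) {
    i <- d$region_id == r & d$subtype == s
    d$significant[i] <- TRUE
    d$padj[i] <- 0.01
    d$log2FC[i] <- lfc
    d
  }
  ovr <- mark(ovr, "r1", "X")              # exclusive -> kept
  ovr <- mark(ovr, "r2", "Y", lfc = -2)    # exclusive, depleted
  ovr <- mark(ovr, "r3", "X")              # significant in two -> dropped
  ovr <- mark(ovr, "r3", "Z")
  ovr <- mark(ovr, "r4", "X")              # in all three -> dropped
  ovr <- mark(ovr, "r4", "Y")
  ovr <- mark(ovr, "r4", "Z")
  cat_ <- exclusivity_filter(ovr)
  expect_setequal(cat_$region_id, c("r1", "r2"))
  expect_equal(cat_$direction[cat_$region_id == "r2"], "depleted")
  expect_equal(cat_$subtype[cat_$region_id == "r1"], "X")
})

test_that("one_vs_rest applies the padj and |lfc| gates and skips singletons", {
  coh <- simulate_cohort(n_subtypes = 3, n_per_subtype = 5, n_regions = 400,
                         enriched_frac = 0.02, delta = 2,
                         correlated_pair = NULL, seed = 21)
  # add a singleton subtype
  counts <- coh$counts
  counts$lonely <- counts[[2]]
  samples <- dplyr::bind_rows(coh$samples,
                              tibble::tibble(sample_id = "lonely",
                                             subtype = "S99"))
  ovr <- suppressMessages(one_vs_rest(counts, samples))
  expect_false("S99" %in% ovr$subtype)
  expect_true(all(ovr$padj[ovr$significant] < 0.05))
  expect_true(all(abs(ovr$log2FC[ovr$significant]) >= 1))
  # planted regions recovered for their own subtype
  truth <- coh$truth$enriched
  sig <- ovr[ovr$significant, ]
  hit <- merge(sig, truth, by = c("region_id", "subtype"))
  expect_gt(nrow(hit) / nrow(truth), 0.8)
})

test_that("progenitor identity loci take the union across stage contrasts", {
  sim <- simulate_progenitors(stages = c("HSC", "CLP", "ProB"),
                              n_per_stage = 10, n_windows = 1500,
                              loci_per_stage = 30, delta = 2,
                              n_ball_like = 0, seed = 31)
  prog <- sim$samples[sim$samples$stage != "B-ALL", ]
  pc <- sim$counts[, c("region_id", prog$sample_id)]
  loci <- suppressMessages(progenitor_identity_loci(pc, prog))
  planted <- unlist(sim$truth$loci)
  expect_gt(mean(planted %in% loci$region_id), 0.85)
  expect_equal(anyDuplicated(loci$region_id), 0)  # union keeps each window once

  # null staircase: essentially no loci at padj < 0.005
  null <- simulate_progenitors(stages = c("HSC", "CLP", "ProB"),
                               n_per_stage = 10, n_windows = 1500,
                               loci_per_stage = 30, delta = 0,
                               n_ball_like = 0, seed = 32)
  nl <- suppressMessages(progenitor_identity_loci(null$counts[, c("region_id", prog$sample_id)],
                                                  prog))
  expect_lte(nrow(nl), 2)
})

test_that("ball_vs_prob splits significant regions by direction", {
  cc <- tiny_cohort(n_regions = 300, n_per_group = 8, delta = 2,
                    n_planted = 40, seed = 6)
  samples <- cc$samples
  samples$group <- ifelse(samples$group == "A", "B-ALL", "Pro-B")
  res <- suppressMessages(ball_vs_prob(cc$counts, samples))
  sig <- res[!is.na(res$enriched_in), ]
  expect_true(all(sig$log2FC[sig$enriched_in == "B-ALL"] > 0))
  expect_true(all(sig$log2FC[sig$enriched_in == "Pro-B"] < 0))
  expect_gt(sum(sig$enriched_in == "B-ALL"), 20)
})

test_that("deg_proximity_ks matches the ECDF-supremum definition", {
  das <- tibble::tibble(chrom = "chr1", start = c(1000L, 5000L),
                        end = c(1300L, 5300L))
  same <- c(900, 1400, 5200)
  r0 <- deg_proximity_ks(das, same, same)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$pvalue, 1)

  near <- rep(1150, 5)         # all at distance 0 from a midpoint
  far <- rep(10^6, 5)
  r1 <- deg_proximity_ks(das, near, far)
  expect_equal(unname(r1$statistic), 1)

  set.seed(12)
  deg <- runif(20, 0, 20000)
  bg <- runif(20, 0, 20000)
  got <- deg_proximity_ks(das, deg, bg)
  mids <- c(1150, 5150)
  d1 <- sapply(deg, function(p) min(abs(mids - p)))
  d2 <- sapply(bg, function(p) min(abs(mids - p)))
  grid <- sort(unique(c(d1, d2)))
  D <- max(abs(ecdf(d1)(grid) - ecdf(d2)(grid)))
  expect_equal(unname(got$statistic), D)
  expect_error(deg_proximity_ks(das[0, ], deg, bg), "empty")
})
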