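# Count normalization, negative-binomial Wald testing with covariates,
# and the DAS / identity-locus selection rules.
#
# The model is the standard NB log-link GLM with fixed per-region
# dispersion, fit by iteratively reweighted least squares; p-values come
# from the normal approximation to the Wald statistic and are BH-adjusted
# within each contrast.  There is no LFC shrinkage, independent filtering
# or outlier replacement.

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over all-positive regions of
#' `count_ij / geomean_i`.  Factors are reported on the natural scale
#' (their geometric mean over the reference rows is approximately 1).
#'
#' @param counts Wide count tibble (first column `region_id`).
#' @return Tibble `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  pos <- rowSums(m <= 0) == 0
  if (!any(pos)) {
    abort(paste0("no region has all-positive counts; median-of-ratios is ",
                 "undefined (consider a pseudo-reference fallback)"))
  }
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(median(col - ref)))
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Stabilized accessibility signal
#'
#' `v_ij = log2(count_ij / s_j + 1)`, a monotone, parameter-free
#' variance-stabilizing transform of the normalized counts.  With
#' `z_score = TRUE` each region row is additionally centred and scaled
#' (mean 0, sd 1), the form used for heatmaps and classifiers.
#'
#' @param counts Wide count tibble.
#' @param sf Size-factor tibble from [size_factors()]; computed when
#'   `NULL`.
#' @param z_score Per-region Z-scoring flag (default `FALSE`).
#' @return Wide tibble of the same shape with real-valued signal.
#' @export
stabilize <- function(counts, sf = NULL, z_score = FALSE) {
  m <- count_matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  if (anyNA(s)) abort("size factors missing for some samples")
  v <- log2(sweep(m, 2, s, "/") + 1)
  if (z_score) {
    mu <- rowMeans(v)
    sdv <- apply(v, 1, sd)
    sdv[sdv == 0] <- 1
    v <- (v - mu) / sdv
  }
  matrix_to_counts(v)
}

#' Per-region NB dispersion estimates
#'
#' Method-of-moments estimate on normalized counts,
#' `alpha_mom = max((s2 - mean)/mean^2, alpha_min)`, followed by a robust
#' log-log linear mean-dispersion trend and geometric-mean shrinkage
#' toward the trend: `alpha = exp((log alpha_mom + log alpha_trend)/2)`.
#'
#' @param counts Wide count tibble (>= 3 samples).
#' @param sf Size-factor tibble; computed when `NULL`.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @return Tibble `region_id`, `mean_norm`, `alpha_mom`, `alpha_trend`,
#'   `alpha`.
#' @export
estimate_dispersion <- function(counts, sf = NULL, alpha_min = 1e-8) {
  m <- count_matrix(counts)
  if (ncol(m) < 3) abort("dispersion estimation needs >= 3 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  nm <- sweep(m, 2, s, "/")
  mu <- rowMeans(nm)
  v <- rowSums((nm - mu)^2) / (ncol(nm) - 1)
  a_mom <- pmax((v - mu) / mu^2, alpha_min)
  a_mom[!is.finite(a_mom)] <- alpha_min
  # trend fit on informative rows only (floored rows carry no signal)
  use <- mu > 0 & a_mom > alpha_min * 10
  if (sum(use) >= 10) {
    fit <- tryCatch(
      MASS::rlm(y ~ x, data = data.frame(x = log(mu[use]), y = log(a_mom[use])),
                maxit = 50),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      a_tr <- rep(exp(mean(log(a_mom[use]))), length(mu))
    } else {
      cf <- coef(fit)
      a_tr <- exp(cf[1] + cf[2] * log(pmax(mu, 1e-8)))
    }
  } else {
    a_tr <- rep(exp(mean(log(a_mom))), length(mu))
  }
  a_tr <- pmax(a_tr, alpha_min)
  alpha <- exp(0.5 * (log(a_mom) + log(a_tr)))
  tibble(region_id = rownames(m), mean_norm = mu,
         alpha_mom = unname(a_mom), alpha_trend = unname(a_tr),
         alpha = unname(alpha))
}

# Vectorized IRLS for the NB log-link GLM with fixed dispersion.
# Y: regions x samples counts; X: samples x p design; offset log size
# factors; alpha: per-region dispersion.  Returns coefficient, SE for
# column `j_int`, and a convergence flag per region.
nb_irls <- function(Y, X, offset, alpha, j_int, max_iter = 50, tol = 1e-6) {
  n <- ncol(Y); R <- nrow(Y); p <- ncol(X)
  Yt <- t(Y)                                    # n x R
  eta0 <- log(pmax(Yt, 0.5)) - offset
  P0 <- solve(crossprod(X), t(X))
  B <- P0 %*% eta0                              # p x R
  conv <- rep(FALSE, R)
  two_col <- p == 2
  if (two_col) x2 <- X[, 2]
  a11 <- a12 <- a22 <- b1 <- b2 <- NULL
  for (iter in seq_len(max_iter)) {
    ETA <- X %*% B + offset
    ETA[ETA > 30] <- 30; ETA[ETA < -30] <- -30
    MU <- exp(ETA)
    W <- MU / (1 + sweep(MU, 2, alpha, "*"))
    Z <- (ETA - offset) + (Yt - MU) / MU
    if (two_col) {
      wz <- W * Z
      a11 <- colSums(W); a12 <- colSums(W * x2); a22 <- colSums(W * x2 * x2)
      b1 <- colSums(wz); b2 <- colSums(wz * x2)
      det <- a11 * a22 - a12 * a12
      det[det <= 0 | !is.finite(det)] <- NA
      Bn <- rbind((a22 * b1 - a12 * b2) / det,
                  (a11 * b2 - a12 * b1) / det)
    } else {
      Bn <- B
      for (r in seq_len(R)) {
        xw <- X * W[, r]
        M <- crossprod(xw, X)
        rhs <- crossprod(xw, Z[, r])
        br <- tryCatch(solve(M, rhs), error = function(e) rep(NA_real_, p))
        Bn[, r] <- br
      }
    }
    bad <- colSums(!is.finite(Bn)) > 0
    Bn[, bad] <- B[, bad]
    delta <- apply(abs(Bn - B), 2, max)
    conv <- !bad & delta < tol
    B <- Bn
    if (all(conv | bad)) break
  }
  # SE at the final fit
  ETA <- X %*% B + offset
  ETA[ETA > 30] <- 30; ETA[ETA < -30] <- -30
  MU <- exp(ETA)
  W <- MU / (1 + sweep(MU, 2, alpha, "*"))
  se <- rep(NA_real_, R)
  if (two_col) {
    a11 <- colSums(W); a12 <- colSums(W * x2); a22 <- colSums(W * x2 * x2)
    det <- a11 * a22 - a12 * a12
    se <- sqrt(ifelse(det > 0, a11 / det, NA_real_))
  } else {
    for (r in seq_len(R)) {
      xw <- X * W[, r]
      M <- crossprod(xw, X)
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (!is.null(Minv)) se[r] <- sqrt(Minv[j_int, j_int])
    }
  }
  list(beta = B[j_int, ], se = se, converged = conv & is.finite(se))
}

build_design <- function(samples, grp, contrast, covariates) {
  df <- data.frame(.grp = factor(grp, levels = c(contrast[2], contrast[1])))
  if (length(covariates) > 0) {
    miss <- setdiff(covariates, names(samples))
    if (length(miss) > 0) {
      abort(paste0("covariate(s) absent from sample sheet: ",
                   paste(miss, collapse = ", ")))
    }
    for (cv in covariates) {
      v <- samples[[cv]]
      df[[cv]] <- if (is.character(v) || is.logical(v)) factor(v) else v
    }
  }
  X <- stats::model.matrix(stats::reformulate(c(".grp", covariates)), data = df)
  if (qr(X)$rank < ncol(X)) abort("design matrix is not full rank")
  # move the group column to position 2 for the fast path
  j <- which(colnames(X) == paste0(".grp", contrast[1]))
  X[, c(1, j, setdiff(seq_len(ncol(X)), c(1, j))), drop = FALSE]
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits, per region, an NB GLM of counts on a two-level group indicator
#' plus optional covariates, with log size factors as offsets and fixed
#' per-region dispersion, and reports the Wald test of the group
#' coefficient (contrast\[1\] relative to contrast\[2\]).  Regions whose
#' IRLS fit does not converge get a missing p-value and are excluded from
#' the BH adjustment.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet aligned to the count columns.
#' @param group Name of the sample-sheet column holding the group label.
#' @param contrast Character vector `c(groupA, groupB)`; positive
#'   `log2FC` means higher accessibility in `groupA`.
#' @param covariates Character vector of sample-sheet covariate columns
#'   (categorical covariates are one-hot coded against a reference
#'   level).  Default none.
#' @param sf,dispersions Optional precomputed [size_factors()] /
#'   [estimate_dispersion()] results (computed from `counts` when
#'   `NULL`); pass them explicitly to share normalization across several
#'   contrasts.
#' @param max_iter,tol IRLS controls.
#' @return Tibble: `region_id`, `baseMean`, `log2FC`, `lfcSE`, `stat`,
#'   `pvalue`, `padj`, `converged`.
#' @export
nb_wald <- function(counts, samples, group, contrast, covariates = NULL,
                    sf = NULL, dispersions = NULL,
                    max_iter = 50, tol = 1e-6) {
  samples <- check_sample_alignment(counts, samples)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf)
  grp_all <- samples[[group]]
  use <- grp_all %in% contrast
  if (sum(grp_all == contrast[1]) == 0 || sum(grp_all == contrast[2]) == 0) {
    abort("both contrast groups must be non-empty")
  }
  m <- count_matrix(counts)[, use, drop = FALSE]
  smp <- samples[use, , drop = FALSE]
  s <- sf$size_factor[match(colnames(m), sf$sample_id)]
  alpha <- dispersions$alpha[match(rownames(m), dispersions$region_id)]
  X <- build_design(smp, grp_all[use], contrast, covariates)
  fit <- nb_irls(m, X, log(s), alpha, j_int = 2L,
                 max_iter = max_iter, tol = tol)
  ln2 <- log(2)
  log2fc <- fit$beta / ln2
  lfcse <- fit$se / ln2
  stat <- fit$beta / fit$se
  pv <- 2 * pnorm(-abs(stat))
  pv[!fit$converged] <- NA_real_
  n_fail <- sum(!fit$converged)
  if (n_fail > 0) {
    inform(sprintf("nb_wald: %d region(s) did not converge; excluded from BH", n_fail))
  }
  padj <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  padj[ok] <- p.adjust(pv[ok], method = "BH")
  tibble(
    region_id = rownames(m),
    baseMean = rowMeans(sweep(m, 2, s, "/")),
    log2FC = unname(log2fc), lfcSE = unname(lfcse), stat = unname(stat),
    pvalue = unname(pv), padj = unname(padj),
    converged = unname(fit$converged)
  )
}

#' One-vs-rest differential accessibility across subtypes
#'
#' Each subtype with at least two samples is contrasted against the
#' pooled remainder of the cohort.  A region is flagged significant for a
#' subtype when `padj < padj_max` and `|log2FC| >= min_abs_lfc`
#' (defaults 0.05 and 1).  Size factors and dispersions are computed
#' once on the full matrix and shared across contrasts; BH adjustment is
#' within contrast.
#'
#' @inheritParams nb_wald
#' @param group Sample-sheet column with subtype labels (default
#'   `"subtype"`).
#' @param padj_max,min_abs_lfc Significance gates.
#' @return Long tibble: one [nb_wald()] row per region and subtype, plus
#'   `subtype` and `significant` columns.
#' @export
one_vs_rest <- function(counts, samples, group = "subtype",
                        covariates = NULL, padj_max = 0.05,
                        min_abs_lfc = 1, sf = NULL, dispersions = NULL) {
  samples <- check_sample_alignment(counts, samples)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf)
  labs <- samples[[group]]
  tab <- table(labs)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    inform(paste0("one_vs_rest: skipping singleton subtype(s): ",
                  paste(singletons, collapse = ", ")))
  }
  subtypes <- sort(names(tab)[tab >= 2])
  res <- map(subtypes, function(st) {
    s2 <- samples
    s2$.ovr <- ifelse(labs == st, st, ".rest")
    out <- nb_wald(counts, s2, group = ".ovr", contrast = c(st, ".rest"),
                   covariates = covariates, sf = sf,
                   dispersions = dispersions)
    out$subtype <- st
    out
  })
  res <- bind_rows(res)
  res$significant <- !is.na(res$padj) & res$padj < padj_max &
    abs(res$log2FC) >= min_abs_lfc
  res[, c("subtype", setdiff(names(res), "subtype"))]
}

#' Exclusivity filter: subtype-enriched DAS catalog
#'
#' Keeps the regions significant in exactly one subtype's one-vs-rest
#' contrast; regions differential in two or more subtypes are excluded.
#' Direction is `"enriched"` when accessibility is higher in the subtype
#' (`log2FC > 0`) and `"depleted"` otherwise.
#'
#' @param ovr Result of [one_vs_rest()].
#' @return Tibble (DAS catalog): `region_id`, `subtype`, `direction`,
#'   `log2FC`, `padj`; each region maps to exactly one subtype.
#' @export
exclusivity_filter <- function(ovr) {
  sig <- filter(ovr, .data$significant)
  counts_per_region <- dplyr::count(sig, .data$region_id)
  uniq <- counts_per_region$region_id[counts_per_region$n == 1]
  out <- filter(sig, .data$region_id %in% uniq)
  tibble(
    region_id = out$region_id,
    subtype = out$subtype,
    direction = ifelse(out$log2FC > 0, "enriched", "depleted"),
    log2FC = out$log2FC,
    padj = out$padj
  )
}

#' One-vs-rest testing plus exclusivity in one call
#'
#' Convenience wrapper running [one_vs_rest()] followed by
#' [exclusivity_filter()].
#'
#' @inheritParams one_vs_rest
#' @return List with elements `one_vs_rest` (long result tibble) and
#'   `catalog` (the exclusive DAS catalog).
#' @export
enrich_subtypes <- function(counts, samples, group = "subtype",
                            covariates = NULL, padj_max = 0.05,
                            min_abs_lfc = 1) {
  ovr <- one_vs_rest(counts, samples, group = group,
                     covariates = covariates, padj_max = padj_max,
                     min_abs_lfc = min_abs_lfc)
  list(one_vs_rest = ovr, catalog = exclusivity_filter(ovr))
}

#' B cell progenitor identity loci
#'
#' One-vs-rest contrasts among progenitor stages on a windowed (250-bp)
#' count matrix with the stricter `padj < 0.005` gate.  Unlike the
#' subtype catalog, exclusivity is NOT required: a window differential in
#' several stage contrasts is kept once.
#'
#' @inheritParams one_vs_rest
#' @param group Sample-sheet column with stage labels (default
#'   `"stage"`).
#' @param padj_max,min_abs_lfc Gates (defaults 0.005 and 1).
#' @return Region tibble of identity loci (provenance `"das"`); region
#'   ids must be `chrom:start-end` window ids.
#' @export
progenitor_identity_loci <- function(counts, samples, group = "stage",
                                     covariates = NULL, padj_max = 0.005,
                                     min_abs_lfc = 1) {
  ovr <- one_vs_rest(counts, samples, group = group,
                     covariates = covariates, padj_max = padj_max,
                     min_abs_lfc = min_abs_lfc)
  ids <- sort(unique(ovr$region_id[ovr$significant]))
  if (length(ids) == 0) {
    return(as_region_tbl(tibble(chrom = character(), start = integer(),
                                end = integer()), provenance = "das"))
  }
  as_region_tbl(parse_region_id(ids), provenance = "das")
}

#' B-ALL versus Pro-B differential accessibility
#'
#' Single two-group contrast splitting significant regions into
#' case-enriched and control-enriched sets by the sign of `log2FC`.
#'
#' @inheritParams nb_wald
#' @param case,control The two group labels (defaults `"B-ALL"`,
#'   `"Pro-B"`).
#' @param padj_max,min_abs_lfc Gates (defaults 0.05 and 1).
#' @return [nb_wald()] tibble plus an `enriched_in` column (`case`
#'   label, `control` label, or `NA` when not significant).
#' @export
ball_vs_prob <- function(counts, samples, group = "group",
                         case = "B-ALL", control = "Pro-B",
                         covariates = NULL, padj_max = 0.05,
                         min_abs_lfc = 1) {
  res <- nb_wald(counts, samples, group = group,
                 contrast = c(case, control), covariates = covariates)
  sig <- !is.na(res$padj) & res$padj < padj_max & abs(res$log2FC) >= min_abs_lfc
  res$enriched_in <- ifelse(sig & res$log2FC > 0, case,
                            ifelse(sig, control, NA_character_))
  res
}

#' Kolmogorov-Smirnov test of DAS proximity to gene sets
#'
#' For every TSS in each list, the distance to the nearest DAS midpoint
#' is computed; the two distance samples are compared with a two-sample
#' KS test.  `alternative = "deg_nearer"` tests one-sidedly whether the
#' first list (e.g. upregulated DEGs) lies closer to DASs than the
#' background.
#'
#' @param das Region tibble of DASs.
#' @param deg_tss,background_tss Tibbles with `chrom`, `pos`, or bare
#'   numeric position vectors (single implicit chromosome).
#' @param alternative `"two.sided"` (default) or `"deg_nearer"`.
#' @return Tibble `statistic`, `pvalue`, `alternative`.
#' @export
deg_proximity_ks <- function(das, deg_tss, background_tss,
                             alternative = c("two.sided", "deg_nearer")) {
  alternative <- match.arg(alternative)
  das <- as_region_tbl(das)
  if (nrow(das) == 0) abort("deg_proximity_ks: empty DAS set")
  as_pos_tbl <- function(x) {
    if (is.numeric(x)) tibble(chrom = ".", pos = x) else as_tibble(x)
  }
  deg <- as_pos_tbl(deg_tss); bg <- as_pos_tbl(background_tss)
  if (nrow(deg) == 0 || nrow(bg) == 0) abort("TSS lists must be non-empty")
  mids <- tibble(chrom = if (all(deg$chrom == ".")) "." else das$chrom,
                 pos = (das$start + das$end) %/% 2L)
  nearest_dist <- function(tss) {
    vapply(seq_len(nrow(tss)), function(i) {
      m <- mids$pos[mids$chrom == tss$chrom[i]]
      if (length(m) == 0) return(Inf)
      min(abs(m - tss$pos[i]))
    }, double(1))
  }
  d1 <- nearest_dist(deg); d2 <- nearest_dist(bg)
  alt <- if (alternative == "deg_nearer") "greater" else "two.sided"
  kt <- suppressWarnings(ks.test(d1, d2, alternative = alt))
  tibble(statistic = unname(kt$statistic), pvalue = kt$p.value,
         alternative = alternative)
}
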