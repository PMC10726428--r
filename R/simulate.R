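# Synthetic cohorts with known ground truth, emulating every statistical
# structure the pipeline assumes: negative-binomial counts with
# subtype-enriched effect loci and a deliberately correlated subtype
# pair, progenitor staircase loci, bound/unbound insertion profiles,
# genotype-linked total and allelic count effects, and annotation
# fixtures (genes, histone marks, loops, blacklist).
#
# Every generator takes an explicit seed and is fully deterministic
# given it.

subtype_names <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate a multi-subtype B-ALL-like ATAC count cohort
#'
#' Counts follow `NB(mean = s_j * mu_i * 2^(delta * e_ij), dispersion
#' alpha_i)` where `e_ij = 1` when region i is planted as enriched for
#' sample j's subtype.  Region baselines `mu_i` and sample size factors
#' `s_j` are log-normal; dispersions are log-normal around 0.2.  One
#' designated subtype pair shares a fraction of its enriched block (plus
#' smaller private blocks), emulating molecularly related subtypes that
#' classifiers confuse.
#'
#' @param n_subtypes,n_per_subtype Cohort design (defaults 10 and 8).
#' @param n_regions Number of regions (default 20000).
#' @param enriched_frac Fraction of regions planted per subtype
#'   (default 0.01).
#' @param delta Planted log2 effect size (default 2).
#' @param depth Target mean count (default 50).
#' @param alpha_meanlog,alpha_sdlog Log-normal dispersion parameters
#'   (defaults `log(0.2)` and 0.5).
#' @param mu_sdlog Log-normal spread of region baselines (default 1).
#' @param sf_sdlog Log-normal spread of sample size factors
#'   (default 0.15).
#' @param correlated_pair Indices of the correlated subtype pair
#'   (default `c(1, 2)`); `NULL` disables it.
#' @param pair_shared_frac Fraction of the pair's enriched block that is
#'   shared (default 0.6).
#' @param seed RNG seed (required).
#' @return List: `counts` (wide tibble), `samples` (sample sheet with
#'   `subtype`), `truth` (region catalog, per-subtype enriched regions
#'   with `shared` flags, `mu`, `alpha`, `size_factor`, and the
#'   correlated pair labels).
#' @export
simulate_cohort <- function(n_subtypes = 10, n_per_subtype = 8,
                            n_regions = 20000, enriched_frac = 0.01,
                            delta = 2, depth = 50,
                            alpha_meanlog = log(0.2), alpha_sdlog = 0.5,
                            mu_sdlog = 1, sf_sdlog = 0.15,
                            correlated_pair = c(1, 2),
                            pair_shared_frac = 0.6, seed) {
  if (missing(seed)) abort("simulate_cohort requires a seed")
  n_enr <- round(enriched_frac * n_regions)
  if (n_enr < 1) abort("enriched_frac * n_regions must be >= 1 per subtype")
  set.seed(seed)
  subtypes <- subtype_names(n_subtypes)
  regions <- tibble(
    chrom = "chr1",
    start = as.integer((seq_len(n_regions) - 1L) * 1000L),
    end = as.integer((seq_len(n_regions) - 1L) * 1000L + 500L)
  )
  regions <- as_region_tbl(regions, provenance = "roi", sort = FALSE)
  mu <- rlnorm(n_regions, meanlog = log(depth) - mu_sdlog^2 / 2,
               sdlog = mu_sdlog)
  alpha <- rlnorm(n_regions, meanlog = alpha_meanlog, sdlog = alpha_sdlog)

  pool <- sample.int(n_regions)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  enriched <- list()
  pair <- if (!is.null(correlated_pair)) subtypes[correlated_pair] else character(0)
  if (length(pair) == 2) {
    n_shared <- round(pair_shared_frac * n_enr)
    shared_idx <- take(n_shared)
    for (st in pair) {
      priv <- take(n_enr - n_shared)
      enriched[[st]] <- tibble(
        region_idx = c(shared_idx, priv),
        subtype = st, delta = delta,
        shared = c(rep(TRUE, n_shared), rep(FALSE, length(priv)))
      )
    }
  }
  for (st in setdiff(subtypes, pair)) {
    enriched[[st]] <- tibble(region_idx = take(n_enr), subtype = st,
                             delta = delta, shared = FALSE)
  }
  enriched <- bind_rows(enriched)
  enriched$region_id <- regions$region_id[enriched$region_idx]

  sample_ids <- as.vector(vapply(subtypes, function(st)
    sprintf("%s_%02d", st, seq_len(n_per_subtype)), character(n_per_subtype)))
  samples <- tibble(sample_id = sample_ids,
                    subtype = rep(subtypes, each = n_per_subtype))
  s <- rlnorm(length(sample_ids), 0, sf_sdlog)
  s <- s / exp(mean(log(s)))

  lfc <- matrix(0, n_regions, n_subtypes, dimnames = list(NULL, subtypes))
  lfc[cbind(enriched$region_idx, match(enriched$subtype, subtypes))] <-
    enriched$delta
  counts <- matrix(0L, n_regions, length(sample_ids),
                   dimnames = list(regions$region_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    mean_j <- s[j] * mu * 2^lfc[, samples$subtype[j]]
    counts[, j] <- rnbinom(n_regions, mu = mean_j, size = 1 / alpha)
  }
  list(
    counts = matrix_to_counts(counts),
    samples = samples,
    truth = list(
      regions = regions,
      enriched = enriched[, c("region_id", "region_idx", "subtype",
                              "delta", "shared")],
      mu = mu, alpha = alpha,
      size_factor = tibble(sample_id = sample_ids, size_factor = s),
      correlated_pair = pair,
      delta = delta, depth = depth
    )
  )
}

#' Simulate additional samples from an existing cohort truth
#'
#' Draws a new, independent cohort (new size factors, new NB noise) from
#' the same generative truth — same regions, baselines, dispersions and
#' enriched blocks — for validation-projection experiments.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param subtypes Subtype labels to draw (must be present in the
#'   truth).
#' @param n_per_subtype Samples per subtype.
#' @param sf_sdlog Log-normal spread of the new cohort's size factors
#'   (default 0.15).
#' @param seed RNG seed (required).
#' @return List `counts`, `samples` as in [simulate_cohort()].
#' @export
simulate_cohort_samples <- function(truth, subtypes, n_per_subtype,
                                    sf_sdlog = 0.15, seed) {
  if (missing(seed)) abort("simulate_cohort_samples requires a seed")
  bad <- setdiff(subtypes, unique(truth$enriched$subtype))
  if (length(bad) > 0) {
    abort(paste0("unknown subtype(s): ", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  n_regions <- nrow(truth$regions)
  sample_ids <- as.vector(vapply(subtypes, function(st)
    sprintf("V_%s_%02d", st, seq_len(n_per_subtype)), character(n_per_subtype)))
  samples <- tibble(sample_id = sample_ids,
                    subtype = rep(subtypes, each = n_per_subtype))
  s <- rlnorm(length(sample_ids), 0, sf_sdlog)
  s <- s / exp(mean(log(s)))
  lfc <- matrix(0, n_regions, length(subtypes),
                dimnames = list(NULL, subtypes))
  enr <- truth$enriched[truth$enriched$subtype %in% subtypes, , drop = FALSE]
  lfc[cbind(enr$region_idx, match(enr$subtype, subtypes))] <- enr$delta
  counts <- matrix(0L, n_regions, length(sample_ids),
                   dimnames = list(truth$regions$region_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    mean_j <- s[j] * truth$mu * 2^lfc[, samples$subtype[j]]
    counts[, j] <- rnbinom(n_regions, mu = mean_j, size = 1 / truth$alpha)
  }
  list(counts = matrix_to_counts(counts), samples = samples)
}

#' Simulate per-sample peaks and subtype summits around true regions
#'
#' Each true region emits one subtype-level summit at its (jittered)
#' midpoint, and per-sample peaks containing the summit with independent
#' dropout, so that ROI recovery by [select_roi()] is measurable against
#' the known regions.
#'
#' @param regions Region tibble of true accessible regions.
#' @param samples Sample sheet with `sample_id`, `subtype`.
#' @param dropout_prob Per-sample peak dropout probability (default
#'   0.2).
#' @param jitter_sd Summit jitter sd in bp (default 10).
#' @param peak_half_width Per-sample peak half-width (default 200).
#' @param seed RNG seed (required).
#' @return List: `summits` (`subtype`, `chrom`, `pos`), `peaks`
#'   (`sample_id`, `chrom`, `start`, `end`), `truth` (per-region summit
#'   positions).
#' @export
simulate_peaks <- function(regions, samples, dropout_prob = 0.2,
                           jitter_sd = 10, peak_half_width = 200, seed) {
  if (missing(seed)) abort("simulate_peaks requires a seed")
  set.seed(seed)
  x <- as_region_tbl(regions)
  mid <- (x$start + x$end) %/% 2L
  subtypes <- unique(samples$subtype)
  summits <- bind_rows(lapply(subtypes, function(st) {
    tibble(subtype = st, chrom = x$chrom,
           pos = as.integer(mid + round(rnorm(nrow(x), 0, jitter_sd))),
           region_id = x$region_id)
  }))
  summits$pos <- pmax(summits$pos, 0L)
  peaks <- bind_rows(lapply(seq_len(nrow(samples)), function(j) {
    st <- samples$subtype[j]
    sm <- summits[summits$subtype == st, , drop = FALSE]
    keep <- runif(nrow(sm)) >= dropout_prob
    tibble(sample_id = samples$sample_id[j],
           chrom = sm$chrom[keep],
           start = pmax(0L, as.integer(sm$pos[keep] - peak_half_width)),
           end = as.integer(sm$pos[keep] + peak_half_width + 1L))
  }))
  list(summits = summits[, c("subtype", "chrom", "pos")],
       peaks = peaks,
       truth = summits)
}

#' Simulate a progenitor staircase cohort with a B-ALL-like group
#'
#' Windows (250 bp) carry stage-specific identity loci: each stage's
#' loci are elevated by `delta` in that stage only.  An optional
#' B-ALL-like sample group shares the Pro-B profile, so a k-NN
#' cell-of-origin classifier trained on the progenitors should assign it
#' to Pro-B.
#'
#' @param stages Ordered stage labels (default a five-stage B-lineage
#'   staircase ending in Pro-B/Pre-B).
#' @param n_per_stage Samples per stage (default 4).
#' @param n_windows Number of 250-bp windows (default 5000).
#' @param loci_per_stage Identity loci per stage (default 2% of
#'   windows).
#' @param delta Planted log2 effect (default 2).
#' @param n_ball_like B-ALL-like samples sharing the Pro-B profile
#'   (default 6; 0 disables).
#' @param ball_stage Which stage the B-ALL-like group mirrors (default
#'   `"ProB"`).
#' @param depth,alpha_meanlog,alpha_sdlog,sf_sdlog As in
#'   [simulate_cohort()].
#' @param seed RNG seed (required).
#' @return List: `counts` (windowed wide tibble), `samples` (`stage`
#'   column; B-ALL-like samples labeled `"B-ALL"`), `truth` (loci per
#'   stage).
#' @export
simulate_progenitors <- function(stages = c("HSC", "MPP", "CLP", "ProB", "PreB"),
                                 n_per_stage = 4, n_windows = 5000,
                                 loci_per_stage = round(0.02 * n_windows),
                                 delta = 2, n_ball_like = 6,
                                 ball_stage = "ProB", depth = 50,
                                 alpha_meanlog = log(0.2), alpha_sdlog = 0.5,
                                 sf_sdlog = 0.15, seed) {
  if (missing(seed)) abort("simulate_progenitors requires a seed")
  set.seed(seed)
  windows <- as_region_tbl(tibble(
    chrom = "chr1",
    start = as.integer((seq_len(n_windows) - 1L) * 250L),
    end = as.integer(seq_len(n_windows) * 250L)
  ), provenance = "windowed", sort = FALSE)
  mu <- rlnorm(n_windows, log(depth) - 0.5, 1)
  alpha <- rlnorm(n_windows, alpha_meanlog, alpha_sdlog)
  pool <- sample.int(n_windows)
  loci <- list()
  for (k in seq_along(stages)) {
    loci[[stages[k]]] <- pool[seq_len(loci_per_stage) + (k - 1) * loci_per_stage]
  }
  groups <- c(rep(stages, each = n_per_stage),
              rep("B-ALL", n_ball_like))
  profile_of <- c(stages, "B-ALL")
  sample_ids <- sprintf("%s_%02d", groups,
                        unlist(lapply(table(factor(groups, levels = unique(groups))), seq_len)))
  samples <- tibble(sample_id = sample_ids, stage = groups)
  s <- rlnorm(length(sample_ids), 0, sf_sdlog)
  s <- s / exp(mean(log(s)))
  counts <- matrix(0L, n_windows, length(sample_ids),
                   dimnames = list(windows$region_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    st <- groups[j]
    eff_stage <- if (st == "B-ALL") ball_stage else st
    lfc <- rep(0, n_windows)
    lfc[loci[[eff_stage]]] <- delta
    counts[, j] <- rnbinom(n_windows, mu = s[j] * mu * 2^lfc,
                           size = 1 / alpha)
  }
  list(counts = matrix_to_counts(counts), samples = samples,
       truth = list(windows = windows,
                    loci = lapply(loci, function(i) windows$region_id[i]),
                    delta = delta, ball_stage = ball_stage))
}

#' Simulate Tn5 insertion profiles around motif occurrences
#'
#' Per-base counts are Poisson with rate `flank_rate` outside the motif
#' core and `flank_rate * (1 - d)` inside it for bound occurrences
#' (depletion depth `d`); unbound occurrences use `d = 0`.  Bound flags
#' are drawn once per occurrence and shared across groups;
#' `group_depths` plants group-specific depletion (differential
#' binding).
#'
#' @param n_motifs Number of motifs (ids `M001`, ...; default 20).
#' @param n_occurrences Occurrences per motif (default 200).
#' @param groups Group ids to emit pooled profiles for (default
#'   `c("A", "B")`).
#' @param motif_len,w_out Window geometry in bp (defaults 10 and 50).
#' @param flank_rate Poisson insertion rate per base (default 5).
#' @param depth Depletion depth `d` in `[0, 1]` for bound occurrences
#'   (default 0.5).
#' @param bound_prob Probability an occurrence is bound (default 0.5).
#' @param group_depths Optional named list `motif_id -> named numeric of
#'   per-group depths` overriding `depth`.
#' @param region_ids Optional region ids cycled over occurrences (so
#'   occurrences can be subset by DAS membership).
#' @param seed RNG seed (required).
#' @return List: `profiles` (tibble with `counts` list-column, ready for
#'   [footprint_score()]) and `truth` (per-occurrence bound flags and
#'   per-motif group depths).
#' @export
simulate_insertions <- function(n_motifs = 20, n_occurrences = 200,
                                groups = c("A", "B"), motif_len = 10,
                                w_out = 50, flank_rate = 5, depth = 0.5,
                                bound_prob = 0.5, group_depths = NULL,
                                region_ids = NULL, seed) {
  if (missing(seed)) abort("simulate_insertions requires a seed")
  if (depth < 0 || depth > 1) abort("depth must be in [0, 1]")
  set.seed(seed)
  motifs <- sprintf("M%03d", seq_len(n_motifs))
  L <- motif_len + 2L * w_out
  core <- (w_out + 1L):(w_out + motif_len)
  rows <- vector("list", n_motifs * length(groups))
  truth_rows <- vector("list", n_motifs)
  k <- 0
  for (mi in seq_along(motifs)) {
    mt <- motifs[mi]
    occ_ids <- sprintf("%s_occ%04d", mt, seq_len(n_occurrences))
    bound <- runif(n_occurrences) < bound_prob
    rid <- if (is.null(region_ids)) NA_character_ else
      rep(region_ids, length.out = n_occurrences)
    truth_rows[[mi]] <- tibble(motif_id = mt, occurrence_id = occ_ids,
                               bound = bound, region_id = rid)
    for (g in groups) {
      d_g <- depth
      if (!is.null(group_depths) && !is.null(group_depths[[mt]])) {
        d_g <- group_depths[[mt]][[g]]
      }
      rate <- matrix(flank_rate, n_occurrences, L)
      rate[bound, core] <- flank_rate * (1 - d_g)
      cnt <- matrix(rpois(n_occurrences * L, rate), n_occurrences, L)
      k <- k + 1
      rows[[k]] <- tibble(
        occurrence_id = occ_ids, motif_id = mt, group_id = g,
        motif_len = motif_len, w_out = w_out,
        region_id = rid,
        counts = lapply(seq_len(n_occurrences), function(o) cnt[o, ])
      )
    }
  }
  depths <- tidyr::crossing(motif_id = motifs, group_id = groups)
  depths$depth <- vapply(seq_len(nrow(depths)), function(i) {
    gd <- group_depths[[depths$motif_id[i]]]
    if (is.null(gd)) depth else gd[[depths$group_id[i]]]
  }, double(1))
  list(profiles = bind_rows(rows),
       truth = list(occurrences = bind_rows(truth_rows), depths = depths,
                    flank_rate = flank_rate))
}

#' Simulate genotypes and allele-specific counts for a cohort
#'
#' Places one biallelic SNV at the midpoint of a fraction of the
#' cohort's regions; dosages follow Hardy-Weinberg at the given MAF.
#' Causal variants scale their region's NB mean by
#' `2^(beta * dosage / 2)` (so `beta` is the homozygote-homozygote log2
#' difference) and the counts of those regions are redrawn from the
#' cohort truth.  For each heterozygote, reads at the variant are a
#' binomial thinning of the region count (`read_frac`), and alt reads
#' are binomial with success `pi` (causal) or 0.5 (non-causal).
#'
#' @param cohort A [simulate_cohort()] result (its `truth` supplies
#'   `mu`, `alpha` and size factors for the redraw).
#' @param frac_regions Fraction of regions receiving a variant
#'   (default 0.3).
#' @param frac_causal Fraction of variants that are causal
#'   (default 0.5).
#' @param beta Causal total-count effect, log2 between homozygotes
#'   (default 0.5).
#' @param pi Causal het alt-allele fraction (default 0.7).
#' @param maf Population alt-allele frequency (default 0.3).
#' @param read_frac Fraction of region reads overlapping the variant
#'   (default 0.2).
#' @param imputed_frac Fraction of variants flagged as imputed with an
#'   `R2` drawn from `r2_range`; the rest have missing `R2`
#'   (genotyped).  Defaults 0.3 and `c(0.85, 1)`.
#' @param r2_range Range of imputation quality for imputed variants.
#' @param seed RNG seed (required).
#' @return List: `geno` (wide genotype tibble for [filter_variants()]),
#'   `allele_counts` (het-only `variant_id`, `sample_id`, `ref_reads`,
#'   `alt_reads`), `counts` (the modified count tibble), `truth`
#'   (per-variant `causal`, `beta`, `pi`, `region_id`).
#' @export
simulate_genotypes_allelic <- function(cohort, frac_regions = 0.3,
                                       frac_causal = 0.5, beta = 0.5,
                                       pi = 0.7, maf = 0.3,
                                       read_frac = 0.2, imputed_frac = 0.3,
                                       r2_range = c(0.85, 1), seed) {
  if (missing(seed)) abort("simulate_genotypes_allelic requires a seed")
  set.seed(seed)
  truth <- cohort$truth
  regions <- truth$regions
  counts <- count_matrix(cohort$counts)
  sample_ids <- colnames(counts)
  n <- length(sample_ids)
  n_var <- max(1L, round(frac_regions * nrow(regions)))
  vidx <- sort(sample.int(nrow(regions), n_var))
  causal <- rep(FALSE, n_var)
  causal[sample.int(n_var, round(frac_causal * n_var))] <- TRUE
  pos <- (regions$start[vidx] + regions$end[vidx]) %/% 2L
  variant_id <- sprintf("rs%06d", vidx)
  dos <- matrix(rbinom(n_var * n, 2, maf), n_var, n,
                dimnames = list(variant_id, sample_ids))
  sfac <- truth$size_factor$size_factor[match(sample_ids,
                                              truth$size_factor$sample_id)]
  # redraw counts for variant regions with the dosage effect on the mean
  for (v in seq_len(n_var)) {
    i <- vidx[v]
    b <- if (causal[v]) beta else 0
    mean_v <- sfac * truth$mu[i] * 2^(b * dos[v, ] / 2)
    counts[i, ] <- rnbinom(n, mu = mean_v, size = 1 / truth$alpha[i])
  }
  imputed <- runif(n_var) < imputed_frac
  r2 <- ifelse(imputed, runif(n_var, r2_range[1], r2_range[2]), NA_real_)
  geno <- bind_cols(
    tibble(variant_id = variant_id, chrom = regions$chrom[vidx],
           pos = as.integer(pos), ref = "A", alt = "G",
           imputation_r2 = r2),
    as_tibble(dos, .name_repair = "minimal")
  )
  attr(geno, "sample_ids") <- sample_ids
  het <- which(dos == 1, arr.ind = TRUE)
  ac <- tibble(
    variant_id = variant_id[het[, 1]],
    sample_id = sample_ids[het[, 2]],
    region_idx = vidx[het[, 1]],
    pi_eff = ifelse(causal[het[, 1]], pi, 0.5)
  )
  reads <- rbinom(nrow(ac), counts[cbind(ac$region_idx, het[, 2])], read_frac)
  alt <- rbinom(nrow(ac), reads, ac$pi_eff)
  ac$alt_reads <- alt
  ac$ref_reads <- reads - alt
  list(
    geno = geno,
    allele_counts = ac[, c("variant_id", "sample_id", "ref_reads", "alt_reads")],
    counts = matrix_to_counts(counts),
    truth = tibble(variant_id = variant_id,
                   region_id = regions$region_id[vidx],
                   pos = as.integer(pos), causal = causal,
                   beta = ifelse(causal, beta, 0),
                   pi = ifelse(causal, pi, 0.5), maf = maf)
  )
}

#' Simulate annotation fixtures: genes, histone marks, loops, blacklist
#'
#' Builds a toy annotation layer over an existing region catalog: gene
#' models with promoters downstream of a subset of regions, histone-mark
#' interval sets realizing a planted chromatin state per region, loops
#' connecting a sample of regions to gene promoters, a blacklist
#' overlapping a few chosen regions, and a random gene set.
#'
#' @param regions Region tibble to annotate.
#' @param n_genes Number of genes (default 20).
#' @param n_loops Number of region-promoter loops (default 15).
#' @param n_blacklist Regions overlapped by the blacklist (default 2).
#' @param seed RNG seed (required).
#' @return List: `genes`, `k27ac`, `k4me1`, `k27me3`, `loops`,
#'   `blacklist`, `gene_set`, and `truth` (planted states and looped
#'   pairs).
#' @export
simulate_annotations <- function(regions, n_genes = 20, n_loops = 15,
                                 n_blacklist = 2, seed) {
  if (missing(seed)) abort("simulate_annotations requires a seed")
  set.seed(seed)
  x <- as_region_tbl(regions)
  n <- nrow(x)
  gidx <- sort(sample.int(n, min(n_genes, n)))
  strand <- rep(c("+", "-"), length.out = length(gidx))
  tss <- as.integer(x$end[gidx] + 200L)
  gstart <- ifelse(strand == "+", tss, tss - 4999L)
  gend <- ifelse(strand == "+", tss + 5000L, tss + 1L)
  genes <- tibble(
    gene_id = sprintf("G%03d", seq_along(gidx)),
    gene_name = sprintf("G%03d", seq_along(gidx)),
    chrom = x$chrom[gidx], strand = strand,
    start = as.integer(pmax(0, gstart)), end = as.integer(gend),
    tss = tss,
    thick_start = as.integer(pmax(0, gstart) + 600L),
    thick_end = as.integer(gend - 600L),
    exons = lapply(seq_along(gidx), function(i) {
      s0 <- max(0, gstart[i])
      tibble(start = as.integer(s0 + c(0L, 2000L, 4000L)),
             end = as.integer(s0 + c(1000L, 3000L, 5000L)))
    })
  )
  states <- sample(c("active", "bivalent_poised", "repressed", "unmarked"),
                   n, replace = TRUE)
  mark_rows <- function(want) x[want, c("chrom", "start", "end")]
  has_ac <- states == "active" | states == "bivalent_poised"
  # active/bivalent regions carry K27ac, K4me1 or both
  which_mark <- sample(c("ac", "me1", "both"), n, replace = TRUE)
  k27ac <- mark_rows(has_ac & which_mark %in% c("ac", "both"))
  k4me1 <- mark_rows(has_ac & which_mark %in% c("me1", "both"))
  k27me3 <- mark_rows(states %in% c("bivalent_poised", "repressed"))
  loop_idx <- sample.int(n, min(n_loops, n))
  loop_gene <- sample(seq_along(gidx), length(loop_idx), replace = TRUE)
  prom_start <- ifelse(genes$strand[loop_gene] == "+",
                       genes$tss[loop_gene] - 2000L,
                       genes$tss[loop_gene] - 500L)
  prom_end <- ifelse(genes$strand[loop_gene] == "+",
                     genes$tss[loop_gene] + 501L,
                     genes$tss[loop_gene] + 2001L)
  loops <- tibble(
    chrom1 = x$chrom[loop_idx], start1 = x$start[loop_idx],
    end1 = x$end[loop_idx],
    chrom2 = x$chrom[loop_idx],
    start2 = as.integer(pmax(0, prom_start)),
    end2 = as.integer(prom_end),
    name = sprintf("loop%03d", seq_along(loop_idx)),
    score = round(runif(length(loop_idx), 5, 50)),
    sample_id = "synthetic"
  )
  swap <- loops$start1 > loops$start2
  if (any(swap)) {
    tmp <- loops[swap, c("start1", "end1")]
    loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
    loops[swap, c("start2", "end2")] <- tmp
  }
  bl_idx <- sample.int(n, min(n_blacklist, n))
  blacklist <- as_region_tbl(x[bl_idx, c("chrom", "start", "end")],
                             provenance = "custom")
  gene_set <- sort(sample(genes$gene_id, max(1, length(gidx) %/% 3)))
  list(
    genes = genes, k27ac = as_region_tbl(k27ac), k4me1 = as_region_tbl(k4me1),
    k27me3 = as_region_tbl(k27me3), loops = loops, blacklist = blacklist,
    gene_set = gene_set,
    truth = list(
      states = tibble(region_id = x$region_id, state = states),
      looped = tibble(region_id = x$region_id[loop_idx],
                      gene_id = genes$gene_id[loop_gene]),
      blacklisted = x$region_id[bl_idx]
    )
  )
}
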