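# Interval algebra and the region-of-interest, annotation,
# chromatin-state and loop-overlap procedures.  GenomicRanges/IRanges do
# the heavy lifting behind tibble-in / tibble-out surfaces.

#' Merge overlapping genomic intervals
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param provenance Provenance tag stored on the result.
#' @return Region tibble of sorted, pairwise non-overlapping intervals
#'   covering exactly the same bases as the input union.
#' @export
merge_intervals <- function(intervals, provenance = "custom") {
  x <- as_region_tbl(intervals, sort = TRUE)
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(regions_to_granges(x))
  granges_to_regions(gr, provenance = provenance)
}

#' Select reproducible open-chromatin regions of interest
#'
#' Implements summit-anchored ROI selection: (1) keep each subtype-level
#' peak summit that lies inside peaks from at least `min_support`
#' distinct samples of that subtype; (2) extend each surviving summit
#' symmetrically to a `2*half_width + 1` bp interval (default 301 bp);
#' (3) merge overlapping intervals; (4) eliminate any merged interval
#' overlapping the blacklist by one or more bases.
#'
#' @param subtype_summits Tibble with `subtype`, `chrom`, `pos`
#'   (0-based summit positions of subtype-merged peaks).
#' @param per_sample_peaks Tibble with `sample_id`, `chrom`, `start`,
#'   `end` (peak intervals per patient sample, e.g. from
#'   [read_narrowpeak()]).
#' @param sample_sheet Tibble mapping `sample_id` to `subtype`.
#' @param blacklist Region tibble of excluded intervals (may be empty).
#' @param min_support Minimum number of distinct same-subtype samples
#'   whose peaks must contain a summit (default 2: "reproducible among
#'   multiple samples").
#' @param half_width Summit extension half-width in bp (default 150,
#'   giving 301-bp intervals).
#' @return Region tibble with provenance `"roi"`.
#' @export
select_roi <- function(subtype_summits, per_sample_peaks, sample_sheet,
                       blacklist = NULL, min_support = 2, half_width = 150) {
  if (min_support < 1) abort("min_support must be >= 1")
  summits <- as_tibble(subtype_summits)
  peaks <- as_tibble(per_sample_peaks)
  peaks <- left_join(peaks, sample_sheet[, c("sample_id", "subtype")],
                     by = "sample_id")
  if (anyNA(peaks$subtype)) {
    abort("per_sample_peaks contains sample_ids absent from the sample sheet")
  }
  known_chrom <- unique(peaks$chrom)
  if (any(!summits$chrom %in% known_chrom)) {
    warn("summit(s) on chromosome(s) with no peaks; kept, but cannot gain support")
  }
  keep <- logical(nrow(summits))
  for (st in unique(summits$subtype)) {
    si <- which(summits$subtype == st)
    pk <- peaks[peaks$subtype == st, , drop = FALSE]
    if (nrow(pk) == 0) next
    sgr <- GenomicRanges::GRanges(summits$chrom[si],
                                  IRanges::IRanges(summits$pos[si] + 1L, width = 1L))
    pgr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
    hits <- GenomicRanges::findOverlaps(sgr, pgr)
    support <- tapply(pk$sample_id[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits),
                      function(s) length(unique(s)))
    ok <- as.integer(names(support))[support >= min_support]
    keep[si[ok]] <- TRUE
  }
  kept <- summits[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(as_region_tbl(tibble(chrom = character(), start = integer(),
                                end = integer()), provenance = "roi"))
  }
  ext <- tibble(chrom = kept$chrom,
                start = pmax(0L, as.integer(kept$pos - half_width)),
                end = as.integer(kept$pos + half_width + 1L))
  merged <- merge_intervals(ext, provenance = "roi")
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    merged <- merged[!overlaps_any(merged, as_region_tbl(blacklist)), , drop = FALSE]
  }
  as_region_tbl(merged, provenance = "roi")
}

#' Tile regions into fixed-width windows
#'
#' Each region is tiled left to right into consecutive `width`-bp
#' windows.  A final partial window is kept when it is at least half the
#' window width; otherwise it is absorbed into the preceding window
#' (regions shorter than `width/2` with no preceding window are kept
#' whole).  Total covered bases are conserved.
#'
#' @param regions Region tibble.
#' @param width Window width in bp (default 250).
#' @return Region tibble with provenance `"windowed"`; window ids carry
#'   the parent id plus a `_w<k>` suffix in the `parent_id`/`region_id`
#'   columns.
#' @export
window_regions <- function(regions, width = 250) {
  if (width < 1) abort("width must be >= 1")
  x <- as_region_tbl(regions)
  out <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]; e <- x$end[i]
    len <- e - s
    n_full <- len %/% width
    rem <- len %% width
    if (n_full == 0) {
      starts <- s; ends <- e
    } else {
      starts <- s + width * (0:(n_full - 1))
      ends <- starts + width
      if (rem >= width / 2) {
        starts <- c(starts, s + width * n_full)
        ends <- c(ends, e)
      } else if (rem > 0) {
        ends[n_full] <- e
      }
    }
    out[[i]] <- tibble(
      chrom = x$chrom[i], start = as.integer(starts), end = as.integer(ends),
      parent_id = x$region_id[i],
      region_id = paste0(x$region_id[i], "_w", seq_along(starts))
    )
  }
  res <- bind_rows(out)
  res <- res[, c("chrom", "start", "end", "region_id", "parent_id")]
  attr(res, "provenance") <- "windowed"
  res
}

#' Annotate regions against a gene model
#'
#' Assigns each region, by its midpoint, to exactly one category with the
#' precedence promoter > 5' UTR > 3' UTR > exon > intron >
#' distal intergenic, and reports the nearest TSS with a strand-signed
#' distance (negative upstream of the TSS).
#'
#' @param regions Region tibble.
#' @param genes Gene model tibble from [read_gene_model()] (or the
#'   synthetic generator).
#' @param promoter_window Length-2 numeric `(upstream, downstream)` bp
#'   around the TSS defining promoters (default `c(2000, 500)`).
#' @return Tibble: `region_id`, `category`, `gene_id`, `distance_to_tss`.
#' @export
annotate_regions <- function(regions, genes, promoter_window = c(2000, 500)) {
  if (nrow(genes) == 0) abort("gene model is empty")
  x <- as_region_tbl(regions)
  mid <- (x$start + x$end) %/% 2L
  up <- promoter_window[1]; down <- promoter_window[2]
  plus <- genes$strand != "-"
  prom_start <- ifelse(plus, genes$tss - up, genes$tss - down)
  prom_end <- ifelse(plus, genes$tss + down + 1, genes$tss + up + 1)

  in_iv <- function(p, chrom, iv_chrom, iv_start, iv_end) {
    # any interval (same chromosome) containing point p
    gr_p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p + 1L, width = 1L))
    gr_iv <- GenomicRanges::GRanges(iv_chrom,
                                    IRanges::IRanges(pmax(0, iv_start) + 1L, iv_end))
    suppressWarnings(GenomicRanges::countOverlaps(gr_p, gr_iv) > 0)
  }

  is_prom <- in_iv(mid, x$chrom, genes$chrom, prom_start, prom_end)

  # exon blocks split into 5' UTR / 3' UTR / coding-or-plain exon
  ex <- tidyr::unnest(genes[, c("gene_id", "chrom", "strand",
                                "thick_start", "thick_end", "exons")],
                      "exons")
  has_cds <- !is.na(ex$thick_start) & ex$thick_start < ex$thick_end
  # portions of exons before thick_start / after thick_end
  left_u <- ex[has_cds & ex$start < ex$thick_start, , drop = FALSE]
  left_u$end <- pmin(left_u$end, left_u$thick_start)
  right_u <- ex[has_cds & ex$end > ex$thick_end, , drop = FALSE]
  right_u$start <- pmax(right_u$start, right_u$thick_end)
  utr5 <- bind_rows(left_u[left_u$strand != "-", ], right_u[right_u$strand == "-", ])
  utr3 <- bind_rows(right_u[right_u$strand != "-", ], left_u[left_u$strand == "-", ])

  is_utr5 <- if (nrow(utr5)) in_iv(mid, x$chrom, utr5$chrom, utr5$start, utr5$end) else rep(FALSE, nrow(x))
  is_utr3 <- if (nrow(utr3)) in_iv(mid, x$chrom, utr3$chrom, utr3$start, utr3$end) else rep(FALSE, nrow(x))
  is_exon <- in_iv(mid, x$chrom, ex$chrom, ex$start, ex$end)
  is_gene <- in_iv(mid, x$chrom, genes$chrom, genes$start, genes$end)

  category <- rep("distal_intergenic", nrow(x))
  category[is_gene] <- "intron"
  category[is_exon] <- "exon"
  category[is_utr3] <- "3'UTR"
  category[is_utr5] <- "5'UTR"
  category[is_prom] <- "promoter"

  # nearest TSS per region, distance signed by gene strand
  gene_id <- rep(NA_character_, nrow(x))
  dist <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    g <- which(genes$chrom == x$chrom[i])
    if (length(g) == 0) { category[i] <- "distal_intergenic"; next }
    d_signed <- ifelse(genes$strand[g] != "-",
                       mid[i] - genes$tss[g],
                       genes$tss[g] - mid[i])
    j <- which.min(abs(d_signed))
    gene_id[i] <- genes$gene_id[g[j]]
    dist[i] <- d_signed[j]
  }
  tibble(region_id = x$region_id, category = category,
         gene_id = gene_id, distance_to_tss = dist)
}

#' Classify regions by histone-mark chromatin state
#'
#' A region "has" a mark when it overlaps the mark's interval set by at
#' least one base.  States: active (H3K27ac or H3K4me1, without
#' H3K27me3), bivalent/poised (H3K27me3 together with H3K27ac or
#' H3K4me1), repressed (H3K27me3 alone), unmarked otherwise.  The four
#' states partition the input.
#'
#' @param regions Region tibble.
#' @param k27ac,k4me1,k27me3 Region tibbles of merged mark intervals.
#' @return Tibble `region_id`, `state`.
#' @export
classify_chromatin_state <- function(regions, k27ac, k4me1, k27me3) {
  x <- as_region_tbl(regions)
  a <- overlaps_any(x, as_region_tbl(k27ac))
  m1 <- overlaps_any(x, as_region_tbl(k4me1))
  p <- overlaps_any(x, as_region_tbl(k27me3))
  act <- a | m1
  state <- dplyr::case_when(
    act & !p ~ "active",
    act & p ~ "bivalent_poised",
    p ~ "repressed",
    TRUE ~ "unmarked"
  )
  tibble(region_id = x$region_id, state = state)
}

#' Overlap regions with chromatin loops and looped genes
#'
#' A region is "in a loop" when it overlaps either anchor.  For each
#' region, the genes whose promoter window overlaps the opposite anchor
#' are collected, and `in_gene_set` reports whether any of them belongs
#' to `gene_set` (e.g. a cancer-implicated gene list).
#'
#' @param regions Region tibble.
#' @param loops Loop tibble from [read_bedpe_loops()].
#' @param genes Gene model tibble.
#' @param gene_set Character vector of gene ids (optional).
#' @param promoter_window Promoter definition as in [annotate_regions()].
#' @return Tibble: `region_id`, `in_loop`, `looped_genes` (list-column),
#'   `in_gene_set`.
#' @export
overlap_loops <- function(regions, loops, genes, gene_set = character(0),
                          promoter_window = c(2000, 500)) {
  x <- as_region_tbl(regions)
  n <- nrow(x)
  looped <- vector("list", n)
  in_loop <- logical(n)
  if (nrow(loops) > 0) {
    gr_x <- regions_to_granges(x)
    gr_a1 <- GenomicRanges::GRanges(loops$chrom1,
                                    IRanges::IRanges(loops$start1 + 1L, loops$end1))
    gr_a2 <- GenomicRanges::GRanges(loops$chrom2,
                                    IRanges::IRanges(loops$start2 + 1L, loops$end2))
    plus <- genes$strand != "-"
    prom <- tibble(
      chrom = genes$chrom,
      start = as.integer(ifelse(plus, genes$tss - promoter_window[1],
                                genes$tss - promoter_window[2])),
      end = as.integer(ifelse(plus, genes$tss + promoter_window[2] + 1,
                              genes$tss + promoter_window[1] + 1)),
      gene_id = genes$gene_id
    )
    prom$start <- pmax(0L, prom$start)
    gr_p <- GenomicRanges::GRanges(prom$chrom,
                                   IRanges::IRanges(prom$start + 1L, prom$end))
    h1 <- GenomicRanges::findOverlaps(gr_x, gr_a1)
    h2 <- GenomicRanges::findOverlaps(gr_x, gr_a2)
    pa1 <- GenomicRanges::findOverlaps(gr_a1, gr_p)  # promoters at anchor1
    pa2 <- GenomicRanges::findOverlaps(gr_a2, gr_p)  # promoters at anchor2
    genes_at <- function(hits, anchor_hits) {
      # region -> loops via one anchor; genes at the opposite anchor
      out <- rep(list(character(0)), n)
      if (length(hits) == 0) return(out)
      loop_of <- S4Vectors::subjectHits(hits)
      reg_of <- S4Vectors::queryHits(hits)
      gmap <- split(prom$gene_id[S4Vectors::subjectHits(anchor_hits)],
                    S4Vectors::queryHits(anchor_hits))
      for (k in seq_along(reg_of)) {
        g <- gmap[[as.character(loop_of[k])]]
        if (!is.null(g)) {
          out[[reg_of[k]]] <- union(out[[reg_of[k]]], g)
        }
      }
      out
    }
    g_via_a1 <- genes_at(h1, pa2)
    g_via_a2 <- genes_at(h2, pa1)
    in_loop <- seq_len(n) %in% S4Vectors::queryHits(h1) |
      seq_len(n) %in% S4Vectors::queryHits(h2)
    looped <- map2(g_via_a1, g_via_a2, union)
  } else {
    looped <- rep(list(character(0)), n)
  }
  tibble(
    region_id = x$region_id,
    in_loop = in_loop,
    looped_genes = looped,
    in_gene_set = map_lgl(looped, ~ any(.x %in% gene_set))
  )
}

#' Fraction of regions overlapping another interval set
#'
#' @param a,b Region tibbles.
#' @return Fraction of `a`'s regions with >= 1 bp overlap of any `b`
#'   interval.
#' @export
overlap_fraction <- function(a, b) {
  a <- as_region_tbl(a)
  if (nrow(a) == 0) abort("overlap_fraction: empty query set (undefined fraction)")
  mean(overlaps_any(a, as_region_tbl(b)))
}
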