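# Activity-by-contact element-to-gene scoring and TF-to-target-gene
# network assembly over subtype-enriched DASs.

#' Element activity: geometric mean of ATAC and H3K27ac signal
#'
#' `A = sqrt((atac + pc) * (k27ac + pc))`, symmetric in its two inputs.
#'
#' @param data Tibble with columns `region_id`, `atac`, `k27ac`
#'   (non-negative signals).
#' @param pseudocount Added to both signals before the geometric mean
#'   (default 0).
#' @return Input tibble with an `activity` column appended.
#' @export
region_activity <- function(data, pseudocount = 0) {
  if (any(data$atac < 0) || any(data$k27ac < 0)) {
    abort("activity inputs must be non-negative")
  }
  mutate(data, activity = sqrt((.data$atac + pseudocount) *
                                 (.data$k27ac + pseudocount)))
}

#' Activity-by-contact element-to-gene scores
#'
#' Candidate elements for a gene are those within `max_dist` of its TSS.
#' The contact `C` is the strongest loop score linking the element to
#' the gene's promoter window (0 with no loop).  With
#' `include_promoter`, an element overlapping the promoter window is
#' treated as the gene's promoter candidate and its contact is raised to
#' the maximum observed contact for that gene (standard ABC practice).
#' The ABC score is `A*C` normalized over the gene's candidates, so
#' scores for each gene sum to 1; predictions with
#' `abc_score >= threshold` are flagged retained.
#'
#' @param elements Region tibble of candidate elements carrying an
#'   `activity` column (see [region_activity()]).
#' @param genes Gene model tibble (needs `gene_id`, `chrom`, `strand`,
#'   `tss`).
#' @param loops Loop tibble from [read_bedpe_loops()].
#' @param max_dist Maximum element-TSS distance in bp (default 2e6, the
#'   loop-span rule).
#' @param include_promoter Promoter max-contact convention flag
#'   (default TRUE).
#' @param threshold Retention threshold on the ABC score (default 0.04).
#' @param promoter_window As in [annotate_regions()].
#' @return Tibble `region_id`, `gene_id`, `activity`, `contact`,
#'   `abc_score`, `retained`.
#' @export
abc_scores <- function(elements, genes, loops, max_dist = 2e6,
                       include_promoter = TRUE, threshold = 0.04,
                       promoter_window = c(2000, 500)) {
  el <- as_region_tbl(elements)
  if (!"activity" %in% names(el)) abort("elements need an activity column")
  plus <- genes$strand != "-"
  prom <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(0L, as.integer(ifelse(plus, genes$tss - promoter_window[1],
                                       genes$tss - promoter_window[2]))),
    end = as.integer(ifelse(plus, genes$tss + promoter_window[2] + 1,
                            genes$tss + promoter_window[1] + 1))
  )
  # candidate pairs within max_dist of the TSS
  mid <- (el$start + el$end) / 2
  cand <- tidyr::crossing(ei = seq_len(nrow(el)), gi = seq_len(nrow(genes)))
  cand <- cand[el$chrom[cand$ei] == genes$chrom[cand$gi], , drop = FALSE]
  cand <- cand[abs(mid[cand$ei] - genes$tss[cand$gi]) <= max_dist, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(region_id = character(), gene_id = character(),
                  activity = double(), contact = double(),
                  abc_score = double(), retained = logical()))
  }
  # contact: strongest loop with one anchor on the element and the other
  # on the gene promoter
  contact <- numeric(nrow(cand))
  if (nrow(loops) > 0) {
    gr_el <- regions_to_granges(el)
    gr_pr <- GenomicRanges::GRanges(prom$chrom,
                                    IRanges::IRanges(prom$start + 1L, prom$end))
    gr_a1 <- GenomicRanges::GRanges(loops$chrom1,
                                    IRanges::IRanges(loops$start1 + 1L, loops$end1))
    gr_a2 <- GenomicRanges::GRanges(loops$chrom2,
                                    IRanges::IRanges(loops$start2 + 1L, loops$end2))
    ov <- function(gr, anchors) {
      h <- GenomicRanges::findOverlaps(gr, anchors)
      split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    }
    e_a1 <- ov(gr_el, gr_a1); e_a2 <- ov(gr_el, gr_a2)
    p_a1 <- ov(gr_pr, gr_a1); p_a2 <- ov(gr_pr, gr_a2)
    for (k in seq_len(nrow(cand))) {
      ei <- as.character(cand$ei[k]); gi <- as.character(cand$gi[k])
      l1 <- intersect(e_a1[[ei]] %||% integer(0), p_a2[[gi]] %||% integer(0))
      l2 <- intersect(e_a2[[ei]] %||% integer(0), p_a1[[gi]] %||% integer(0))
      ll <- union(l1, l2)
      if (length(ll) > 0) contact[k] <- max(loops$score[ll])
    }
  }
  out <- tibble(
    region_id = el$region_id[cand$ei],
    gene_id = genes$gene_id[cand$gi],
    activity = el$activity[cand$ei],
    contact = contact
  )
  if (include_promoter) {
    # element overlapping the promoter window gets the gene's max contact
    gr_el <- regions_to_granges(el)
    gr_pr <- GenomicRanges::GRanges(prom$chrom,
                                    IRanges::IRanges(prom$start + 1L, prom$end))
    hp <- GenomicRanges::findOverlaps(gr_el, gr_pr)
    prom_pair <- tibble(region_id = el$region_id[S4Vectors::queryHits(hp)],
                        gene_id = prom$gene_id[S4Vectors::subjectHits(hp)],
                        is_prom = TRUE)
    out <- left_join(out, prom_pair, by = c("region_id", "gene_id"))
    out <- out |>
      group_by(.data$gene_id) |>
      mutate(contact = ifelse(!is.na(.data$is_prom) & .data$is_prom,
                              pmax(.data$contact, max(.data$contact)),
                              .data$contact)) |>
      ungroup() |>
      select(-"is_prom")
  }
  out <- out |>
    group_by(.data$gene_id) |>
    mutate(.tot = sum(.data$activity * .data$contact)) |>
    ungroup()
  zero <- unique(out$gene_id[out$.tot == 0])
  if (length(zero) > 0) {
    inform(sprintf("abc_scores: %d gene(s) with zero total A*C dropped", length(zero)))
  }
  out <- filter(out, .data$.tot > 0)
  out$abc_score <- out$activity * out$contact / out$.tot
  out$.tot <- NULL
  out$retained <- out$abc_score >= threshold
  arrange(out, .data$gene_id, dplyr::desc(.data$abc_score))
}

#' Assemble the TF-to-target-gene network
#'
#' Edges connect a TF motif to a gene whenever a bound occurrence of the
#' motif lies in a subtype-enriched DAS that carries a retained ABC link
#' to the gene, and the gene belongs to the supplied gene set.  TFs are
#' ranked by mean differential footprint signal and genes by
#' expression; the network is truncated to the top `top_tf_n` TFs and
#' `top_gene_n` genes.
#'
#' @param das DAS catalog subset (tibble with `region_id`; e.g. the
#'   enriched rows of [exclusivity_filter()] output).
#' @param bound_occurrences Tibble with `motif_id`, `region_id`,
#'   `bound`.
#' @param abc Retained predictions from [abc_scores()].
#' @param gene_set Character vector of eligible gene ids (e.g.
#'   cancer-implicated genes).
#' @param tf_scores Tibble `motif_id`, `delta_fps` (differential
#'   footprint signal used for TF ranking).
#' @param gene_expression Tibble `gene_id`, `tpm`.
#' @param top_tf_n,top_gene_n Truncation sizes (defaults 10).
#' @return Edge tibble: `motif_id`, `gene_id`, `supporting_regions`
#'   (list-column), `tf_rank_score`, `gene_rank_score`.
#' @export
build_tf_target_network <- function(das, bound_occurrences, abc, gene_set,
                                    tf_scores, gene_expression,
                                    top_tf_n = 10, top_gene_n = 10) {
  occ <- filter(as_tibble(bound_occurrences), .data$bound,
                .data$region_id %in% das$region_id)
  links <- filter(abc, .data$retained, .data$gene_id %in% gene_set,
                  .data$region_id %in% das$region_id)
  edges <- inner_join(occ[, c("motif_id", "region_id")],
                      links[, c("region_id", "gene_id")],
                      by = "region_id", relationship = "many-to-many") |>
    distinct()
  if (nrow(edges) == 0) {
    inform("build_tf_target_network: empty TF/DAS/ABC intersection")
    return(tibble(motif_id = character(), gene_id = character(),
                  supporting_regions = list(), tf_rank_score = double(),
                  gene_rank_score = double()))
  }
  tfr <- tf_scores |>
    group_by(.data$motif_id) |>
    summarise(tf_rank_score = mean(.data$delta_fps), .groups = "drop")
  ger <- gene_expression[, c("gene_id", "tpm")]
  edges <- edges |>
    group_by(.data$motif_id, .data$gene_id) |>
    summarise(supporting_regions = list(sort(unique(.data$region_id))),
              .groups = "drop") |>
    left_join(tfr, by = "motif_id") |>
    left_join(ger, by = "gene_id") |>
    rename(gene_rank_score = "tpm")
  top_tfs <- edges |>
    distinct(.data$motif_id, .data$tf_rank_score) |>
    arrange(dplyr::desc(.data$tf_rank_score), .data$motif_id) |>
    head(top_tf_n) |>
    pull("motif_id")
  top_genes <- edges |>
    distinct(.data$gene_id, .data$gene_rank_score) |>
    arrange(dplyr::desc(.data$gene_rank_score), .data$gene_id) |>
    head(top_gene_n) |>
    pull("gene_id")
  edges |>
    filter(.data$motif_id %in% top_tfs, .data$gene_id %in% top_genes) |>
    arrange(dplyr::desc(.data$tf_rank_score), dplyr::desc(.data$gene_rank_score))
}
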