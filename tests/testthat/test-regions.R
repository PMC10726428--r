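# Interval algebra and ROI/annotation/state/loop procedures against
# brute-force per-base oracles.

test_that("merge_intervals equals the per-base union oracle", {
  m <- merge_intervals(tibble::tibble(chrom = "chr1",
                                      start = c(100L, 150L),
                                      end = c(200L, 300L)))
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)

  disjoint <- tibble::tibble(chrom = "chr1", start = c(0L, 500L),
                             end = c(100L, 600L))
  expect_equal(merge_intervals(disjoint)[, c("start", "end")],
               disjoint[, c("start", "end")], ignore_attr = TRUE)

  set.seed(42)
  for (rep in 1:5) {
    iv <- random_intervals(7)
    got <- merge_intervals(iv)
    want <- bruteforce_merge(iv$start, iv$end)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("select_roi implements summit support, 301-bp extension, merge, blacklist", {
  sheet <- tibble::tibble(sample_id = c("a1", "a2", "a3"),
                          subtype = "X")
  # summit at 1000 covered by 2 samples -> kept, extended to [850, 1151)
  summits <- tibble::tibble(subtype = "X", chrom = "chr1",
                            pos = c(1000L, 5000L))
  peaks <- tibble::tibble(
    sample_id = c("a1", "a2", "a3"),
    chrom = "chr1",
    start = c(900L, 950L, 4990L),
    end = c(1100L, 1050L, 5010L)
  )
  roi <- select_roi(summits, peaks, sheet, min_support = 2)
  expect_equal(nrow(roi), 1)  # summit 5000 has support 1 only
  expect_equal(roi$start, 850L)
  expect_equal(roi$end, 1151L)
  expect_equal(roi$end - roi$start, 301L)

  # blacklist removal at >= 1 bp overlap
  bl <- tibble::tibble(chrom = "chr1", start = 1150L, end = 1160L)
  expect_equal(nrow(select_roi(summits, peaks, sheet, blacklist = bl,
                               min_support = 2)), 0)
  expect_error(select_roi(summits, peaks, sheet, min_support = 0),
               "min_support")
})

test_that("select_roi matches an exhaustive manual pipeline on a toy case", {
  set.seed(11)
  sheet <- tibble::tibble(sample_id = sprintf("s%d", 1:3), subtype = "X")
  summits <- tibble::tibble(subtype = "X", chrom = "chr1",
                            pos = c(500L, 700L, 2000L, 4000L, 6000L))
  peaks <- dplyr::bind_rows(lapply(1:3, function(j) {
    keep <- c(TRUE, TRUE, j <= 1, j <= 2, FALSE)
    tibble::tibble(sample_id = sprintf("s%d", j), chrom = "chr1",
                   start = summits$pos[keep] - 50L,
                   end = summits$pos[keep] + 50L)
  }))
  bl <- tibble::tibble(chrom = "chr1", start = 3900L, end = 3950L)
  got <- select_roi(summits, peaks, sheet, blacklist = bl,
                    min_support = 2, half_width = 150)
  # manual: support = {3,3,1,2,0}; kept summits 500, 700, 4000;
  # extend -> [350,651), [550,851), [3850,4151); first two merge;
  # [3850,4151) hits the blacklist
  expect_equal(got$start, 350L)
  expect_equal(got$end, 851L)
  # deterministic
  expect_identical(got, select_roi(summits, peaks, sheet, blacklist = bl,
                                   min_support = 2, half_width = 150))
})

test_that("window_regions tiles, keeps >= half-width remainders, conserves bases", {
  r1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L)
  w1 <- window_regions(r1, 250)
  expect_equal(w1$start, c(0L, 250L))
  expect_equal(w1$end, c(250L, 500L))

  w2 <- window_regions(tibble::tibble(chrom = "chr1", start = 0L, end = 625L), 250)
  expect_equal(w2$start, c(0L, 250L, 500L))   # 125 >= 125: partial kept
  expect_equal(w2$end, c(250L, 500L, 625L))

  w3 <- window_regions(tibble::tibble(chrom = "chr1", start = 0L, end = 600L), 250)
  expect_equal(w3$end, c(250L, 600L))         # 100 < 125: merged into previous

  set.seed(7)
  regs <- merge_intervals(random_intervals(10, span = 5000, max_width = 900))
  ww <- window_regions(regs, 250)
  expect_equal(sum(ww$end - ww$start), sum(regs$end - regs$start))
  # re-merging the windows reconstructs the parent set
  back <- merge_intervals(ww)
  expect_equal(back$start, regs$start)
  expect_equal(back$end, regs$end)
})

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gplus", "gminus"), gene_name = c("gplus", "gminus"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(10000L, 40000L), end = c(20000L, 50000L),
    tss = c(10000L, 49999L),
    thick_start = c(11500L, 41500L), thick_end = c(18500L, 48500L),
    exons = list(
      tibble::tibble(start = c(10000L, 14000L, 18000L),
                     end = c(12000L, 15000L, 20000L)),
      tibble::tibble(start = c(40000L, 44000L, 48000L),
                     end = c(42000L, 45000L, 50000L))
    )
  )
}

test_that("annotate_regions applies category precedence by midpoint", {
  genes <- toy_genes()
  mk <- function(mid) {
    tibble::tibble(chrom = "chr1", start = mid - 50L, end = mid + 50L,
                   region_id = sprintf("chr1:%d-%d", mid - 50L, mid + 50L))
  }
  regions <- dplyr::bind_rows(
    mk(9500L),    # 500 bp upstream of + TSS -> promoter
    mk(11000L),   # exonic but before thick_start -> 5'UTR (+)
    mk(14500L),   # coding exon
    mk(13000L),   # intron
    mk(19000L),   # exon after thick_end -> 3'UTR (+)
    mk(49000L),   # exon after thick_end on minus strand -> 5'UTR
    mk(30000L)    # between genes -> distal
  )
  ann <- annotate_regions(regions, genes, promoter_window = c(2000, 500))
  got <- ann$category[match(regions$region_id, ann$region_id)]
  expect_equal(got, c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                      "5'UTR", "distal_intergenic"))
  # distance signed by strand: 500 bp upstream of the + TSS is negative
  expect_equal(ann$distance_to_tss[match(regions$region_id[1], ann$region_id)],
               -500)
  expect_equal(ann$gene_id[match(regions$region_id[6], ann$region_id)],
               "gminus")
  # a chromosome absent from the gene model falls back to distal
  far <- annotate_regions(tibble::tibble(chrom = "chrZ", start = 0L, end = 100L),
                          genes)
  expect_equal(far$category, "distal_intergenic")
})

test_that("chromatin states follow the mark logic and partition regions", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 100L, 200L, 300L, 400L),
                            end = c(50L, 150L, 250L, 350L, 450L))
  regions$region_id <- sprintf("chr1:%d-%d", regions$start, regions$end)
  iv <- function(starts) tibble::tibble(chrom = "chr1", start = starts,
                                        end = starts + 50L)
  st <- classify_chromatin_state(
    regions,
    k27ac = iv(0L),              # region 1: K27ac only
    k4me1 = iv(c(0L, 100L, 200L)),  # regions 1-3
    k27me3 = iv(c(200L, 300L))      # regions 3-4
  )
  expect_equal(st$state, c("active", "active", "bivalent_poised",
                           "repressed", "unmarked"))
  expect_equal(sort(unique(st$region_id)), sort(regions$region_id))
  expect_equal(nrow(st), nrow(regions))
})

test_that("overlap_loops matches an exhaustive anchor-overlap oracle", {
  genes <- toy_genes()
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(1000L, 3000L, 70000L, 8000L, 52000L, 60000L),
                            end = c(1500L, 3500L, 70500L, 8500L, 52500L, 60500L))
  regions$region_id <- sprintf("chr1:%d-%d", regions$start, regions$end)
  # loops: region1 <-> promoter of gplus; region5 <-> promoter of gminus;
  # region2 <-> nothing genic; region3 untouched
  loops <- tibble::tibble(
    chrom1 = "chr1", start1 = c(1000L, 3000L, 50500L),
    end1 = c(1400L, 3400L, 51500L),
    chrom2 = "chr1", start2 = c(9500L, 25000L, 52000L),
    end2 = c(10000L, 25500L, 52400L),
    name = c("l1", "l2", "l3"), score = 1, sample_id = "t"
  )
  ov <- overlap_loops(regions, loops, genes, gene_set = "gplus")
  byid <- function(col) ov[[col]][match(regions$region_id, ov$region_id)]
  expect_equal(byid("in_loop"), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(byid("looped_genes")[[1]], "gplus")
  expect_equal(byid("looped_genes")[[5]], "gminus")
  expect_equal(byid("in_gene_set"), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("overlap_fraction counts >=1 bp overlaps and rejects empty input", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L))
  expect_equal(overlap_fraction(a, a), 1.0)
  b <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  expect_equal(overlap_fraction(a, b), 0.0)
  expect_error(overlap_fraction(a[0, ], b), "empty")

  set.seed(3)
  aa <- random_intervals(10)
  bb <- random_intervals(6)
  expect_equal(overlap_fraction(aa, bb),
               mean(bruteforce_overlap_any(dplyr::arrange(aa, start), bb)))
})
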