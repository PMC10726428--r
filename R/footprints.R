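# Tn5-insertion footprint scoring, bound/unbound calling, differential
# footprint statistics and the pairwise-subtype top-median TF selection.
#
# An insertion profile covers [-w_out, motif, +w_out] around a motif
# occurrence.  The footprint score (FPS) is computed on the profile
# normalized to mean 1 over the window: mean insertion rate over the
# flank bases (flank_width bases immediately adjacent to the core on
# each side) minus the mean over the core (motif) bases.  Factor binding
# protects the core from transposition, so bound occurrences have
# positive FPS.

profile_tbl_check <- function(profiles) {
  req <- c("occurrence_id", "motif_id", "group_id", "motif_len", "w_out",
           "counts")
  miss <- setdiff(req, names(profiles))
  if (length(miss) > 0) {
    abort(paste0("insertion profile table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  profiles
}

#' Footprint score per motif occurrence
#'
#' @param profiles Insertion-profile tibble with columns
#'   `occurrence_id`, `motif_id`, `group_id`, `motif_len`, `w_out`, and
#'   a `counts` list-column of per-base insertion counts over the window
#'   (length `motif_len + 2*w_out`); see [simulate_insertions()].
#' @param flank_width Flank width in bp on each side of the core
#'   (default 30; must not exceed `w_out`).
#' @param min_cov Minimum total insertions in the window for the score
#'   to be defined (default 20); lower-coverage occurrences get `NA`.
#' @return Tibble `occurrence_id`, `motif_id`, `group_id`, `coverage`,
#'   `fps` (plus `region_id` if present in the input).
#' @export
footprint_score <- function(profiles, flank_width = 30, min_cov = 20) {
  profile_tbl_check(profiles)
  if (any(flank_width > profiles$w_out)) {
    abort("flank_width exceeds the available flank (w_out)")
  }
  fps_one <- function(counts, m, w_out) {
    L <- m + 2L * w_out
    if (length(counts) != L) abort("profile length does not match motif_len + 2*w_out")
    tot <- sum(counts)
    if (tot < min_cov) return(c(tot, NA_real_))
    norm <- counts / mean(counts)
    core <- (w_out + 1L):(w_out + m)
    flank <- c((w_out - flank_width + 1L):w_out,
               (w_out + m + 1L):(w_out + m + flank_width))
    c(tot, mean(norm[flank]) - mean(norm[core]))
  }
  res <- t(mapply(fps_one, profiles$counts, profiles$motif_len, profiles$w_out))
  out <- tibble(
    occurrence_id = profiles$occurrence_id,
    motif_id = profiles$motif_id,
    group_id = profiles$group_id,
    coverage = res[, 1],
    fps = res[, 2]
  )
  if ("region_id" %in% names(profiles)) out$region_id <- profiles$region_id
  out
}

#' Bound/unbound calls from footprint scores
#'
#' Fits a two-component Gaussian mixture (EM, deterministic
#' initialization) to the footprint scores of one motif in one group;
#' occurrences with posterior probability > 0.5 for the upper-mean
#' component are called bound.  When the fitted components are closer
#' than 0.1 pooled standard deviations (or the fit fails), a fallback
#' threshold of mean + 1 sd is used.  Fewer than 20 scored occurrences
#' yield all-unbound calls with a warning.
#'
#' @param scores Tibble from [footprint_score()] restricted to one
#'   motif/group (or any tibble with `occurrence_id` and `fps`).
#' @param seed RNG seed for the mixture fit (default 1).
#' @return Input tibble plus `bound` and `posterior` columns; the
#'   decision threshold is stored in the `"threshold"` attribute.
#' @export
bound_call <- function(scores, seed = 1) {
  x <- scores$fps
  ok <- which(!is.na(x))
  bound <- rep(FALSE, nrow(scores))
  post <- rep(NA_real_, nrow(scores))
  thr <- NA_real_
  if (length(ok) < 20) {
    warn("bound_call: fewer than 20 scored occurrences; all called unbound")
  } else {
    xs <- x[ok]
    if (sd(xs) < 1e-12) {
      # constant scores: nothing exceeds mean + 1 sd, none bound
      attr(scores, "threshold") <- mean(xs)
      scores$bound <- bound
      scores$posterior <- post
      return(scores)
    }
    fit <- tryCatch({
      withr_seed <- function(expr) { set.seed(seed); expr }
      withr_seed(suppressWarnings(
        mclust::Mclust(xs, G = 2, modelNames = "V", verbose = FALSE)
      ))
    }, error = function(e) NULL)
    degenerate <- TRUE
    if (!is.null(fit) && !is.null(fit$parameters)) {
      mu <- fit$parameters$mean
      sig <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sig) == 1) sig <- rep(sig, 2)
      pooled <- sqrt(mean(sig^2))
      degenerate <- pooled == 0 || abs(diff(mu)) < 0.1 * pooled
    }
    if (!degenerate) {
      upper <- which.max(fit$parameters$mean)
      post[ok] <- fit$z[, upper]
      bound[ok] <- post[ok] > 0.5
      # implied decision boundary (for reporting): midpoint crossing
      thr <- min(xs[bound[ok]], na.rm = TRUE)
      if (!is.finite(thr)) thr <- NA_real_
    } else {
      thr <- mean(xs) + sd(xs)
      bound[ok] <- xs > thr
      post[ok] <- as.numeric(bound[ok])
    }
  }
  out <- scores
  out$bound <- bound
  out$posterior <- post
  attr(out, "threshold") <- thr
  out
}

#' Differential TF footprinting between two groups
#'
#' For every motif, per-occurrence footprint scores of the two groups
#' are paired (same occurrence set, per-group pooled insertion
#' profiles); `delta_fps` is the mean of per-occurrence score
#' differences, `z` the standardized mean difference, and the two-sided
#' p-value comes from a seeded sign-flip permutation of the group labels
#' within occurrence.  Motifs with fewer than 10 jointly scored
#' occurrences are flagged unreliable.
#'
#' @param profiles Insertion-profile tibble covering both groups.
#' @param group_a,group_b Group ids to compare; positive `delta_fps`
#'   means deeper footprints (more binding) in `group_a`.
#' @param flank_width,min_cov Passed to [footprint_score()].
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param seed Permutation seed (default 1).
#' @return Tibble, one row per motif: `motif_id`, `group_a`, `group_b`,
#'   `delta_fps`, `z`, `pvalue`, `n_occurrences`, `reliable`.
#' @export
differential_footprint <- function(profiles, group_a, group_b,
                                   flank_width = 30, min_cov = 20,
                                   n_perm = 1000, seed = 1) {
  sc <- footprint_score(profiles, flank_width = flank_width,
                        min_cov = min_cov)
  sa <- filter(sc, .data$group_id == group_a)
  sb <- filter(sc, .data$group_id == group_b)
  joined <- inner_join(sa[, c("occurrence_id", "motif_id", "fps")],
                       sb[, c("occurrence_id", "motif_id", "fps")],
                       by = c("occurrence_id", "motif_id"),
                       suffix = c("_a", "_b"))
  joined <- filter(joined, !is.na(.data$fps_a) & !is.na(.data$fps_b))
  motifs <- sort(unique(sc$motif_id))
  set.seed(seed)
  res <- map(motifs, function(mt) {
    d <- joined$fps_a[joined$motif_id == mt] -
      joined$fps_b[joined$motif_id == mt]
    n <- length(d)
    if (n == 0) {
      return(tibble(motif_id = mt, group_a = group_a, group_b = group_b,
                    delta_fps = NA_real_, z = NA_real_, pvalue = NA_real_,
                    n_occurrences = 0L, reliable = FALSE))
    }
    dbar <- mean(d)
    sdd <- sd(d)
    z <- if (n > 1 && sdd > 0) dbar / (sdd / sqrt(n)) else NA_real_
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    perm <- as.numeric(crossprod(d, signs)) / n
    pv <- (1 + sum(abs(perm) >= abs(dbar))) / (n_perm + 1)
    tibble(motif_id = mt, group_a = group_a, group_b = group_b,
           delta_fps = dbar, z = z, pvalue = pv,
           n_occurrences = n, reliable = n >= 10)
  })
  bind_rows(res)
}

#' Per-subtype median pairwise differential footprint matrix
#'
#' For each motif and subtype s, the median over all other subtypes t of
#' `delta_fps(s, t)` — the signature used to find TF footprints that are
#' consistently enriched in one subtype across every pairwise
#' comparison, rather than global trends.
#'
#' @param profiles Insertion-profile tibble covering all subtypes
#'   (group ids are subtype labels; profiles pooled per subtype).
#' @param flank_width,min_cov Passed to [footprint_score()].
#' @return Long tibble `motif_id`, `subtype`, `median_delta_fps`.
#' @export
pairwise_subtype_matrix <- function(profiles, flank_width = 30,
                                    min_cov = 20) {
  sc <- footprint_score(profiles, flank_width = flank_width,
                        min_cov = min_cov)
  subtypes <- sort(unique(sc$group_id))
  if (length(subtypes) < 2) abort("need >= 2 subtypes")
  motifs <- sort(unique(sc$motif_id))
  # per-occurrence scores in wide form: one column per subtype
  wide <- tidyr::pivot_wider(sc[, c("occurrence_id", "motif_id", "group_id", "fps")],
                             names_from = "group_id", values_from = "fps")
  out <- vector("list", length(motifs) * length(subtypes))
  k <- 0
  for (mt in motifs) {
    w <- wide[wide$motif_id == mt, , drop = FALSE]
    for (s in subtypes) {
      deltas <- vapply(setdiff(subtypes, s), function(t) {
        d <- w[[s]] - w[[t]]
        d <- d[!is.na(d)]
        if (length(d) == 0) NA_real_ else mean(d)
      }, double(1))
      k <- k + 1
      out[[k]] <- tibble(motif_id = mt, subtype = s,
                         median_delta_fps = median(deltas, na.rm = TRUE))
    }
  }
  bind_rows(out)
}

#' Select top-median subtype-enriched TF footprints
#'
#' Per subtype, motifs are ranked by descending median pairwise
#' differential footprint score (ties broken by motif id, lexicographic)
#' and the top `top_n` are kept.
#'
#' @param matrix_tbl Long tibble from [pairwise_subtype_matrix()].
#' @param top_n Motifs retained per subtype (default 5).
#' @return Tibble `subtype`, `motif_id`, `median_delta_fps`, `rank`.
#' @export
top_median_selection <- function(matrix_tbl, top_n = 5) {
  if (top_n < 1) abort("top_n must be >= 1")
  matrix_tbl |>
    group_by(.data$subtype) |>
    arrange(dplyr::desc(.data$median_delta_fps), .data$motif_id,
            .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= top_n) |>
    ungroup() |>
    select("subtype", "motif_id", "median_delta_fps", "rank")
}

#' Differential footprints restricted to a region set
#'
#' Filters occurrences to those inside the supplied regions (matched by
#' `region_id`) before running [differential_footprint()] — e.g. top TF
#' footprints at enriched or depleted DASs.
#'
#' @param profiles Insertion-profile tibble carrying a `region_id`
#'   column.
#' @param das Region tibble (or anything with a `region_id` column).
#' @inheritParams differential_footprint
#' @return As [differential_footprint()].
#' @export
footprints_at_regions <- function(profiles, das, group_a, group_b,
                                  flank_width = 30, min_cov = 20,
                                  n_perm = 1000, seed = 1) {
  if (!"region_id" %in% names(profiles)) {
    abort("profiles lack a region_id column")
  }
  sub <- filter(profiles, .data$region_id %in% das$region_id)
  if (nrow(sub) == 0) {
    return(tibble(motif_id = character(), group_a = character(),
                  group_b = character(), delta_fps = double(), z = double(),
                  pvalue = double(), n_occurrences = integer(),
                  reliable = logical()))
  }
  differential_footprint(sub, group_a, group_b, flank_width = flank_width,
                         min_cov = min_cov, n_perm = n_perm, seed = seed)
}
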