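#' Remove SNPs within 3 bp of another variant
#'
#' Drops every site whose nearest other variant on the same chromosome is
#' within `min_dist` bp (inclusive); both members of a close pair are removed.
#'
#' @param sites tibble with `chrom` and `pos`, sorted by (chrom, pos).
#' @param min_dist distance threshold in bp; sites with a neighbour at
#'   distance `<= min_dist` are removed (default 3).
#' @return Integer index of surviving sites (rows of `sites`).
#' @export
#' @examples
#' proximity_filter(tibble::tibble(chrom = "c", pos = c(100L, 103L, 200L)))
proximity_filter <- function(sites, min_dist = 3) {
  n <- nrow(sites)
  if (n == 0L) return(integer(0))
  if (!identical(order(sites$chrom, sites$pos), seq_len(n))) {
    abort("`sites` must be sorted by (chrom, pos)")
  }
  same_prev <- c(FALSE, sites$chrom[-1] == sites$chrom[-n])
  d_prev <- c(Inf, diff(sites$pos))
  d_prev[!same_prev] <- Inf
  d_next <- c(d_prev[-1], Inf)
  which(d_prev > min_dist & d_next > min_dist)
}

#' Genotype- and site-level reference-panel filters
#'
#' Applies the panel curation rules on a genotype matrix with per-genotype
#' depth and quality annotations: genotypes failing depth or genotype-quality
#' thresholds are set missing; sites failing site quality, the singleton rule
#' (exactly one alternate allele copy observed), or per-site missingness above
#' `max_missing` are removed. An optional repetitive-region mask (0-based
#' half-open intervals) removes all sites it covers.
#'
#' @param gt integer matrix (individuals x sites) of genotypes 0/1/2, NA for
#'   missing.
#' @param depth,gq numeric matrices of the same shape: per-genotype depth and
#'   genotype quality.
#' @param site_qual numeric vector of per-site quality scores.
#' @param mean_depth per-individual mean genomic depth (recycled if scalar).
#' @param sites optional tibble with `chrom`, `pos` for mask subtraction.
#' @param mask optional tibble of repetitive intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param min_gt_depth,max_gt_depth_mult,min_site_qual,min_gq,max_missing,drop_singletons
#'   filter parameters (defaults 6, 3, 25, 20, 0.20, TRUE).
#' @return A `site_filter_report` list: `genotypes` (filtered matrix),
#'   `surviving` (site index), `removed` (named per-filter counts, applied in
#'   order), `n_input`.
#' @export
genotype_and_site_filters <- function(gt, depth, gq, site_qual,
                                      mean_depth,
                                      sites = NULL, mask = NULL,
                                      min_gt_depth = 6, max_gt_depth_mult = 3,
                                      min_site_qual = 25, min_gq = 20,
                                      max_missing = 0.20,
                                      drop_singletons = TRUE) {
  if (is.null(depth) || is.null(gq) || is.null(site_qual)) {
    abort("depth, gq and site_qual annotations are required")
  }
  if (!all(dim(depth) == dim(gt)) || !all(dim(gq) == dim(gt))) {
    abort("annotation matrices must match the genotype matrix shape")
  }
  n_sites <- ncol(gt)
  mean_depth <- rep_len(mean_depth, nrow(gt))

  # genotype-level: set missing on depth / GQ failure
  max_dp <- max_gt_depth_mult * mean_depth
  bad_gt <- depth < min_gt_depth | depth > max_dp | gq < min_gq
  gt[bad_gt & !is.na(gt)] <- NA_integer_

  removed <- c(site_qual = 0L, mask = 0L, singleton = 0L, missingness = 0L)
  keep <- rep(TRUE, n_sites)

  fail_qual <- site_qual < min_site_qual
  removed["site_qual"] <- sum(keep & fail_qual)
  keep <- keep & !fail_qual

  if (!is.null(mask) && nrow(mask) > 0) {
    if (is.null(sites)) abort("`sites` required when a mask is supplied")
    hits <- GenomicRanges::findOverlaps(
      sites_to_gr(sites$chrom, sites$pos), regions_to_gr(mask)
    )
    in_mask <- seq_len(n_sites) %in% S4Vectors::queryHits(hits)
    removed["mask"] <- sum(keep & in_mask)
    keep <- keep & !in_mask
  }

  if (drop_singletons) {
    alt_copies <- colSums(gt, na.rm = TRUE)
    singleton <- alt_copies == 1L
    removed["singleton"] <- sum(keep & singleton)
    keep <- keep & !singleton
  }

  miss_frac <- colMeans(is.na(gt))
  fail_miss <- miss_frac > max_missing
  removed["missingness"] <- sum(keep & fail_miss)
  keep <- keep & !fail_miss

  structure(
    list(genotypes = gt, surviving = which(keep), removed = removed,
         n_input = n_sites),
    class = "site_filter_report"
  )
}

#' @export
print.site_filter_report <- function(x, ...) {
  cat(sprintf("<site_filter_report> %d sites in, %d surviving\n",
              x$n_input, length(x$surviving)))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-12s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  invisible(x)
}

#' KING-robust pairwise kinship
#'
#' The between-family robust estimator:
#' `phi = (N_het,het - 2 * N_opposite_hom) / (N_het_i + N_het_j)`, computed
#' over sites where both genotypes are non-missing. Duplicates/MZ twins score
#' ~0.5, parent-offspring ~0.25, second-degree ~0.125.
#'
#' @param gt integer matrix (individuals x sites) of genotypes 0/1/2, NA
#'   allowed.
#' @return Tibble of pairs: `id1`, `id2`, `kinship`.
#' @export
king_kinship <- function(gt) {
  n <- nrow(gt)
  ids <- rownames(gt) %||% paste0("ind", seq_len(n))
  pairs <- utils::combn(n, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- !is.na(gt[i, ]) & !is.na(gt[j, ])
    gi <- gt[i, ok]; gj <- gt[j, ok]
    n_hh <- sum(gi == 1L & gj == 1L)
    n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
    n_het_i <- sum(gi == 1L); n_het_j <- sum(gj == 1L)
    denom <- n_het_i + n_het_j
    tibble(id1 = ids[i], id2 = ids[j],
           kinship = if (denom > 0) (n_hh - 2 * n_opp) / denom else NA_real_)
  })
  res
}

#' Remove individuals with close relatives
#'
#' Computes KING-robust kinship for all pairs and removes individuals greedily
#' — the individual in the largest number of above-threshold pairs first, ties
#' broken by id order — until no pair exceeds the threshold.
#'
#' @param gt integer matrix (individuals x sites), rownames as ids.
#' @param threshold kinship above which a pair is flagged (default 0.0885,
#'   the second-degree cutoff).
#' @return Character vector of retained individual ids.
#' @export
kinship_filter <- function(gt, threshold = 0.0885) {
  n <- nrow(gt)
  ids <- rownames(gt) %||% paste0("ind", seq_len(n))
  rownames(gt) <- ids
  if (n < 2) return(ids)
  kin <- king_kinship(gt)
  flagged <- kin[!is.na(kin$kinship) & kin$kinship > threshold, , drop = FALSE]
  retained <- ids
  while (nrow(flagged) > 0) {
    counts <- table(factor(c(flagged$id1, flagged$id2), levels = retained))
    worst <- names(counts)[counts == max(counts)]
    drop_id <- sort(worst)[1]
    retained <- setdiff(retained, drop_id)
    flagged <- flagged[flagged$id1 != drop_id & flagged$id2 != drop_id, ,
                       drop = FALSE]
  }
  if (length(retained) == 0) abort("kinship filtering removed every individual")
  retained
}

#' MAF and transversion site filter
#'
#' Removes sites whose minor allele frequency is below `min_maf` and,
#' optionally, transition sites (ref/alt pair A/G or C/T in either order),
#' which are confounded by post-mortem C-to-T deamination in ancient DNA.
#'
#' @param sites tibble with `ref`, `alt`, and `alt_freq`.
#' @param min_maf minimum minor allele frequency (default 0.025).
#' @param transversions_only drop transitions (default TRUE).
#' @return Integer index of surviving sites.
#' @export
maf_transversion_filter <- function(sites, min_maf = 0.025,
                                    transversions_only = TRUE) {
  maf <- pmin(sites$alt_freq, 1 - sites$alt_freq)
  keep <- maf >= min_maf
  if (transversions_only) {
    keep <- keep & !is_transition_pair(sites$ref, sites$alt)
  }
  which(keep)
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style `indep-pairwise`: within sliding windows of `window_snps`
#' SNPs advanced by `step_snps`, each pair with genotype-count r-squared above
#' `r2_max` has its later-indexed SNP removed (greedy, first to last);
#' removals persist across windows. Missing genotypes are handled by
#' pairwise-complete correlation.
#'
#' @param gt integer matrix (individuals x sites).
#' @param window_snps,step_snps,r2_max pruning parameters (defaults 50, 5,
#'   0.5).
#' @return Integer index of surviving sites.
#' @export
ld_prune <- function(gt, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  n_sites <- ncol(gt)
  keep <- rep(TRUE, n_sites)
  starts <- seq(1L, max(1L, n_sites), by = step_snps)
  for (s in starts) {
    e <- min(s + window_snps - 1L, n_sites)
    idx <- s:e
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r <- suppressWarnings(cor(gt[, idx, drop = FALSE],
                              use = "pairwise.complete.obs"))
    r2 <- r^2
    for (a in seq_len(length(idx) - 1)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1):length(idx)) {
        if (!keep[idx[b]]) next
        if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[idx[b]] <- FALSE
      }
    }
    if (e >= n_sites) break
  }
  which(keep)
}
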