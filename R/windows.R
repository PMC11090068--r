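#' Sliding genomic windows
#'
#' Windows `[k * step, k * step + window)` per chromosome, clipped at the
#' chromosome end; trailing truncated windows are included. Coordinates are
#' 0-based half-open.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window_bp,step_bp window and step size (defaults 500 kb / 100 kb);
#'   `step_bp` must not exceed `window_bp`.
#' @return Tibble: `chrom`, `start`, `end`.
#' @export
#' @examples
#' make_windows(c(chr1 = 1.2e6))
make_windows <- function(chrom_lengths, window_bp = 5e5, step_bp = 1e5) {
  if (step_bp > window_bp) abort("`step_bp` must not exceed `window_bp`")
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chrom) {
    starts <- seq(0, max(0, len - 1), by = step_bp)
    starts <- starts[starts < len]
    tibble(chrom = chrom, start = starts, end = pmin(starts + window_bp, len))
  })
}

#' Per-window imputation accuracy and recovery
#'
#' For each window: accuracy is the number of correctly imputed genotypes
#' (all three classes) over the genotypes evaluable in the window (truth and
#' call both non-missing); recovery is the number of called genotypes present
#' in the truth over the number of panel variants in the window. Windows with
#' no evaluable sites are flagged `NaN`.
#'
#' @param truth,called call-set tibbles on the panel site index.
#' @param panel the `haplotype_panel`.
#' @param windows tibble from [make_windows()].
#' @return `windows` with `n_panel_sites`, `n_evaluated`, `accuracy`,
#'   `recovery` added.
#' @export
window_metrics <- function(truth, called, panel, windows) {
  site_gr <- sites_to_gr(panel$sites$chrom, panel$sites$pos)
  win_gr <- regions_to_gr(windows)
  hits <- GenomicRanges::findOverlaps(site_gr, win_gr)
  site_of <- S4Vectors::queryHits(hits)
  win_of <- S4Vectors::subjectHits(hits)

  t_gt <- truth$gt[match(seq_len(nrow(panel$sites)), truth$site_index)]
  c_gt <- called$gt[match(seq_len(nrow(panel$sites)), called$site_index)]

  eval_ok <- !is.na(t_gt[site_of]) & !is.na(c_gt[site_of])
  correct <- eval_ok & t_gt[site_of] == c_gt[site_of]
  in_truth_called <- !is.na(t_gt[site_of]) & !is.na(c_gt[site_of])

  n_win <- nrow(windows)
  n_panel <- tabulate(win_of, nbins = n_win)
  n_eval <- tabulate(win_of[eval_ok], nbins = n_win)
  n_correct <- tabulate(win_of[correct], nbins = n_win)
  n_called <- tabulate(win_of[in_truth_called], nbins = n_win)

  windows |>
    mutate(
      n_panel_sites = n_panel,
      n_evaluated = n_eval,
      accuracy = ifelse(n_eval > 0, n_correct / n_eval, NaN),
      recovery = ifelse(n_panel > 0, n_called / n_panel, NaN)
    )
}

#' Bottom-percentile outlier regions
#'
#' Selects windows at or below the `percentile / 100` quantile of the chosen
#' metric (the default 0.01 reads "bottom 0.01 percentile" literally as the
#' 1e-4 quantile) and merges overlapping or book-ended selections into
#' regions.
#'
#' @param windowed tibble from [window_metrics()].
#' @param percentile percentile (not quantile) defining the cutoff.
#' @param metric `"accuracy"` or `"recovery"`.
#' @return Merged region tibble (`chrom`, `start`, `end`).
#' @export
outlier_regions <- function(windowed, percentile = 0.01,
                            metric = c("accuracy", "recovery")) {
  metric <- match.arg(metric)
  vals <- windowed[[metric]]
  if (all(is.nan(vals))) abort("all windows are NaN; nothing to rank")
  thr <- quantile(vals, probs = percentile / 100, na.rm = TRUE, names = FALSE)
  sel <- windowed[!is.nan(vals) & vals <= thr, c("chrom", "start", "end")]
  merge_regions(sel)
}

#' Merge overlapping or book-ended regions
#' @param regions tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @return Merged, sorted region tibble.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(tibble(chrom = character(), start = integer(),
                                        end = integer()))
  gr_to_regions(GenomicRanges::reduce(regions_to_gr(regions)))
}

#' Regions shared across samples
#'
#' Pools per-sample region sets, merges them, annotates each merged region
#' with the number of distinct samples contributing at least 1 bp of overlap,
#' and keeps regions supported by at least `min_samples` samples.
#'
#' @param region_sets list of per-sample region tibbles.
#' @param min_samples minimum supporting samples (default 4).
#' @return Region tibble with a `support` column.
#' @export
shared_regions <- function(region_sets, min_samples = 4) {
  if (length(region_sets) < min_samples) {
    abort("fewer region sets supplied than `min_samples`")
  }
  pooled <- merge_regions(bind_rows(region_sets))
  if (nrow(pooled) == 0) return(pooled |> mutate(support = integer()))
  pooled_gr <- regions_to_gr(pooled)
  support <- rep(0L, nrow(pooled))
  for (rs in region_sets) {
    if (nrow(rs) == 0) next
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pooled_gr, regions_to_gr(merge_regions(rs)))
    ))
    support[hit] <- support[hit] + 1L
  }
  out <- pooled |> mutate(support = support)
  out[out$support >= min_samples, , drop = FALSE]
}

#' Base-pair subtraction of region sets
#'
#' Removes every base covered by any of `others` from `target`
#' (BEDTools-subtract semantics).
#'
#' @param target region tibble.
#' @param others a region tibble or list of them.
#' @return Region tibble of the remaining spans of `target`.
#' @export
unique_regions <- function(target, others) {
  if (is.data.frame(others)) others <- list(others)
  other_all <- bind_rows(others)
  if (nrow(target) == 0) return(target)
  if (nrow(other_all) == 0) return(merge_regions(target))
  tgt <- regions_to_gr(merge_regions(target))
  oth <- regions_to_gr(merge_regions(other_all))
  # align seqlevels so disjoint chromosome sets do not warn
  lv <- union(GenomicRanges::seqnames(GenomicRanges::seqinfo(tgt)),
              GenomicRanges::seqnames(GenomicRanges::seqinfo(oth)))
  GenomeInfoDb::seqlevels(tgt) <- lv
  GenomeInfoDb::seqlevels(oth) <- lv
  gr_to_regions(GenomicRanges::setdiff(tgt, oth))
}
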