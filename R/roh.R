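#' Windowed scan for runs of homozygosity
#'
#' Re-implementation of the PLINK `--homozyg` windowed algorithm with the
#' standard ancient-genome parameter set. Sliding windows of `window_snp`
#' consecutive SNPs are flagged homozygous when they contain at most
#' `window_het` heterozygous calls; each SNP's homozygosity proportion is the
#' fraction of flagged windows among the windows containing it; SNPs whose
#' proportion exceeds `window_threshold` form candidate runs, which are split
#' at inter-SNP gaps above `gap_kb`. Emitted runs must contain at least
#' `min_snp` SNPs, span at least `min_kb` kb, and keep a density of at least
#' one SNP per `density_kb_per_snp` kb. Windows are truncated at chromosome
#' ends, not wrapped.
#'
#' Input calls must have no missing genotypes (filter and subset first, as a
#' gold-standard ROH input would be).
#'
#' @param calls call-set tibble with complete `gt`.
#' @param density_kb_per_snp,gap_kb,min_kb,min_snp,window_het,window_snp,window_threshold
#'   scan parameters (defaults 50, 100, 500, 50, 1, 50, 0.05).
#' @return Tibble of segments: `sample_id`, `chrom`, `start`, `end`
#'   (1-based positions of the first/last SNP), `n_snps`, `length_bp`.
#' @export
roh_scan <- function(calls, density_kb_per_snp = 50, gap_kb = 100,
                     min_kb = 500, min_snp = 50, window_het = 1,
                     window_snp = 50, window_threshold = 0.05) {
  if (anyNA(calls$gt)) {
    abort("`calls` contains missing genotypes; ROH input must be complete")
  }
  sample_id <- attr(calls, "sample_id") %||% NA_character_

  purrr::map_dfr(split(calls, calls$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    n <- nrow(d)
    if (n == 0) return(tibble())
    het <- as.integer(d$gt == 1L)

    n_win <- n - window_snp + 1L
    if (n_win < 1L) return(tibble())
    het_in_win <- as.integer(stats::filter(het, rep(1, window_snp),
                                           sides = 1))[window_snp:n]
    flagged <- het_in_win <= window_het

    # windows containing SNP j: starts max(1, j - window_snp + 1) .. min(j, n_win)
    cum_flag <- c(0L, cumsum(as.integer(flagged)))
    lo <- pmax(1L, seq_len(n) - window_snp + 1L)
    hi <- pmin(seq_len(n), n_win)
    n_windows <- hi - lo + 1L
    n_flagged <- cum_flag[hi + 1L] - cum_flag[lo]
    prop <- ifelse(n_windows > 0, n_flagged / n_windows, 0)
    eligible <- n_windows > 0 & prop > window_threshold

    # candidate runs of eligible SNPs, split at large gaps
    if (!any(eligible)) return(tibble())
    gap_split <- c(FALSE, diff(d$pos) > gap_kb * 1000)
    run_id <- cumsum(!eligible | gap_split)
    runs <- tibble(idx = seq_len(n), run = run_id, elig = eligible) |>
      filter(.data$elig) |>
      group_by(.data$run) |>
      summarise(first = min(.data$idx), last = max(.data$idx),
                .groups = "drop")
    if (nrow(runs) == 0) return(tibble())

    seg <- tibble(
      sample_id = sample_id,
      chrom = d$chrom[1],
      start = d$pos[runs$first],
      end = d$pos[runs$last],
      n_snps = runs$last - runs$first + 1L
    ) |>
      mutate(length_bp = .data$end - .data$start + 1L) |>
      filter(
        .data$n_snps >= min_snp,
        .data$length_bp >= min_kb * 1000,
        .data$length_bp / .data$n_snps <= density_kb_per_snp * 1000
      )
    seg
  })
}

#' Summarise ROH totals per sample
#'
#' Totals of run length above and below a split (default 2 Mb; a segment at
#' exactly the split counts in the upper class), plus optional finer length
#' bins.
#'
#' @param segments tibble from [roh_scan()] (may pool samples).
#' @param split_bp length split in bp (default 2 Mb).
#' @param bins optional extra bin edges in bp for a finer breakdown.
#' @return Per-sample tibble: `sample_id`, `n_segments`, `total_bp`,
#'   `total_ge_split`, `total_lt_split`, and one `bin_*` column per extra
#'   bin.
#' @export
roh_summary <- function(segments, split_bp = 2e6, bins = NULL) {
  if (nrow(segments) == 0) {
    return(tibble(sample_id = character(), n_segments = integer(),
                  total_bp = numeric(), total_ge_split = numeric(),
                  total_lt_split = numeric()))
  }
  out <- segments |>
    group_by(.data$sample_id) |>
    summarise(
      n_segments = n(),
      total_bp = sum(.data$length_bp),
      total_ge_split = sum(.data$length_bp[.data$length_bp >= split_bp]),
      total_lt_split = sum(.data$length_bp[.data$length_bp < split_bp]),
      .groups = "drop"
    )
  if (!is.null(bins)) {
    edges <- c(bins, Inf)
    binned <- segments |>
      mutate(bin = cut(.data$length_bp, breaks = edges, right = FALSE,
                       dig.lab = 10)) |>
      group_by(.data$sample_id, .data$bin) |>
      summarise(bp = sum(.data$length_bp), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "bin", values_from = "bp",
                         values_fill = 0, names_prefix = "bin_")
    out <- out |> left_join(binned, by = "sample_id")
  }
  out
}
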