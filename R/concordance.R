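#' Build a MAF-stratified genotype confusion table
#'
#' Cross-tabulates truth genotype class (hom-ref / het / hom-alt) against
#' called class (plus missing) at every site where the truth is non-missing.
#' Counts are stratified by minor-allele-frequency bin (panel frequencies),
#' by a MAF threshold stratum, an overall stratum, and by site class
#' (all sites vs transversions only).
#'
#' @param truth,called call-set tibbles sharing the panel site index.
#' @param panel the `haplotype_panel` supplying allele frequencies.
#' @param maf_bins bin edges for MAF stratification; the default eight bins
#'   lie between the edges 0.005, 0.01, 0.025, 0.05, 0.10, 0.20, 0.30, 0.40,
#'   0.50.
#' @param maf_threshold threshold for the extra `maf_ge_threshold` stratum
#'   (default 0.025).
#' @return A `concordance_table` tibble: `site_class`, `maf_stratum`,
#'   `truth_class`, `call_class`, `n`.
#' @export
concordance_table <- function(truth, called, panel,
                              maf_bins = c(0.005, 0.01, 0.025, 0.05, 0.10,
                                           0.20, 0.30, 0.40, 0.50),
                              maf_threshold = 0.025) {
  if (!identical(truth$site_index, called$site_index)) {
    abort("`truth` and `called` must share the same site index")
  }
  maf <- pmin(panel$sites$alt_freq, 1 - panel$sites$alt_freq)[truth$site_index]
  tv <- !is_transition_pair(truth$ref, truth$alt)

  df <- tibble(
    maf = maf, tv = tv,
    truth_class = gt_class(truth$gt),
    call_class = gt_class(called$gt)
  ) |>
    filter(.data$truth_class != "missing")

  bin_labels <- paste0("[", utils::head(maf_bins, -1), ",",
                       utils::tail(maf_bins, -1), ")")
  df$maf_bin <- as.character(cut(df$maf, breaks = maf_bins,
                                 labels = bin_labels,
                                 right = FALSE, include.lowest = TRUE))

  tally <- function(d, stratum, site_class) {
    d |>
      count(.data$truth_class, .data$call_class, name = "n") |>
      mutate(maf_stratum = stratum, site_class = site_class)
  }
  strata_for <- function(d, site_class) {
    bind_rows(
      d |> filter(!is.na(.data$maf_bin)) |>
        group_by(.data$maf_bin) |>
        dplyr::group_modify(~ count(.x, .data$truth_class, .data$call_class,
                                    name = "n")) |>
        ungroup() |>
        rename(maf_stratum = "maf_bin") |>
        mutate(site_class = site_class),
      tally(d |> filter(.data$maf >= maf_threshold),
            "maf_ge_threshold", site_class),
      tally(d, "overall", site_class)
    )
  }
  out <- bind_rows(
    strata_for(df, "all"),
    strata_for(df |> filter(.data$tv), "transversion")
  ) |>
    select("site_class", "maf_stratum", "truth_class", "call_class", "n")

  attr(out, "maf_threshold") <- maf_threshold
  class(out) <- c("concordance_table", class(out))
  out
}

#' Construct a concordance table from explicit counts
#'
#' Convenience constructor for hand-specified confusion counts (single
#' stratum), used for checking the metric formulas.
#'
#' @param counts tibble with `truth_class`, `call_class`, `n`.
#' @return A `concordance_table` with `site_class = "all"`,
#'   `maf_stratum = "overall"`.
#' @export
concordance_counts <- function(counts) {
  out <- counts |>
    mutate(site_class = "all", maf_stratum = "overall") |>
    select("site_class", "maf_stratum", "truth_class", "call_class", "n")
  class(out) <- c("concordance_table", class(out))
  out
}

variant_classes <- function(class) {
  switch(class,
    het = "het",
    hom_alt = "hom_alt",
    alt_combined = c("het", "hom_alt"),
    all = c("hom_ref", "het", "hom_alt"),
    abort(sprintf("unknown genotype class '%s'", class))
  )
}

metric_by_stratum <- function(tab, f) {
  tab |>
    group_by(.data$site_class, .data$maf_stratum) |>
    dplyr::group_modify(~ f(.x)) |>
    ungroup()
}

#' Genotype concordance (accuracy)
#'
#' `TP / (TP + FN)` per genotype class: TP are calls matching the truth in
#' the class, FN are truth genotypes of the class called differently but
#' non-missing. Missing calls are excluded (they are recovery's concern).
#' Returns NaN with `empty = TRUE` where the class has no evaluable calls.
#'
#' @param tab a `concordance_table`.
#' @param classes genotype classes: any of `"het"`, `"hom_alt"`,
#'   `"alt_combined"`, `"all"`.
#' @return Tibble: `site_class`, `maf_stratum`, `class`, `tp`, `fn`,
#'   `accuracy`, `empty`.
#' @export
gt_accuracy <- function(tab, classes = c("het", "hom_alt", "alt_combined")) {
  metric_by_stratum(tab, function(d) {
    purrr::map_dfr(classes, function(cl) {
      in_cl <- d |> filter(.data$truth_class %in% variant_classes(cl))
      tp <- sum(in_cl$n[in_cl$call_class == in_cl$truth_class])
      fn <- sum(in_cl$n[in_cl$call_class != in_cl$truth_class &
                          in_cl$call_class != "missing"])
      tibble(class = cl, tp = tp, fn = fn,
             accuracy = if (tp + fn > 0) tp / (tp + fn) else NaN,
             empty = tp + fn == 0)
    })
  })
}

#' Genotype recovery
#'
#' Canonical form `(TP + FN) / TotalHQ` — the fraction of high-quality truth
#' genotypes that survive imputation and filtering — and the variant form
#' `TP / TotalHQ` (correctly imputed over truth total), both per class.
#' `TotalHQ` is the number of non-missing truth genotypes of the class.
#'
#' @inheritParams gt_accuracy
#' @return Tibble with `total_hq`, `recovery` (canonical),
#'   `recovery_correct` (variant), `empty`.
#' @export
gt_recovery <- function(tab, classes = c("all", "het", "hom_alt",
                                         "alt_combined")) {
  metric_by_stratum(tab, function(d) {
    purrr::map_dfr(classes, function(cl) {
      in_cl <- d |> filter(.data$truth_class %in% variant_classes(cl))
      total_hq <- sum(in_cl$n)
      tp <- sum(in_cl$n[in_cl$call_class == in_cl$truth_class])
      fn <- sum(in_cl$n[in_cl$call_class != in_cl$truth_class &
                          in_cl$call_class != "missing"])
      tibble(class = cl, total_hq = total_hq,
             recovery = if (total_hq > 0) (tp + fn) / total_hq else NaN,
             recovery_correct = if (total_hq > 0) tp / total_hq else NaN,
             empty = total_hq == 0)
    })
  })
}

#' Genotype error rate
#'
#' Incorrect non-missing calls divided by total non-missing calls, per truth
#' genotype class (reported separately for het and hom-alt by default).
#'
#' @inheritParams gt_accuracy
#' @return Tibble with `n_wrong`, `n_called`, `error_rate`, `empty`.
#' @export
gt_error_rate <- function(tab, classes = c("het", "hom_alt")) {
  metric_by_stratum(tab, function(d) {
    purrr::map_dfr(classes, function(cl) {
      in_cl <- d |> filter(.data$truth_class %in% variant_classes(cl),
                           .data$call_class != "missing")
      n_called <- sum(in_cl$n)
      n_wrong <- sum(in_cl$n[in_cl$call_class != in_cl$truth_class])
      tibble(class = cl, n_wrong = n_wrong, n_called = n_called,
             error_rate = if (n_called > 0) n_wrong / n_called else NaN,
             empty = n_called == 0)
    })
  })
}

#' Non-reference discordance
#'
#' `discordant / (discordant + concordant het + concordant hom-alt)` over all
#' non-missing calls: concordant hom-ref genotypes are excluded from both
#' numerator and denominator, weighting errors at variant genotypes.
#'
#' @param tab a `concordance_table`.
#' @return Tibble: `site_class`, `maf_stratum`, `nrd`, `empty`.
#' @export
gt_nrd <- function(tab) {
  metric_by_stratum(tab, function(d) {
    called <- d |> filter(.data$call_class != "missing")
    disc <- sum(called$n[called$call_class != called$truth_class])
    conc_var <- sum(called$n[called$call_class == called$truth_class &
                               called$truth_class %in% c("het", "hom_alt")])
    denom <- disc + conc_var
    tibble(nrd = if (denom > 0) disc / denom else NaN, empty = denom == 0)
  })
}

#' Metrics across a GP/INFO threshold sweep
#'
#' Evaluates accuracy, recovery (both variants), error rate, and NRD for each
#' filtered call set in a [filter_sweep()] grid, producing one tidy row per
#' (threshold pair, site class, MAF stratum, genotype class).
#'
#' @param truth truth call-set tibble.
#' @param sweep tibble from [filter_sweep()] (columns `min_gp`, `min_info`,
#'   list-column `calls`).
#' @param panel the `haplotype_panel`.
#' @param sample_id,coverage optional labels carried into the report.
#' @param ... passed to [concordance_table()].
#' @return A `sweep_report` tibble.
#' @export
sweep_report <- function(truth, sweep, panel, sample_id = NA_character_,
                         coverage = NA_real_, ...) {
  out <- purrr::pmap_dfr(
    list(sweep$min_gp, sweep$min_info, sweep$calls),
    function(g, i, calls) {
      tab <- concordance_table(truth, calls, panel, ...)
      keys <- c("site_class", "maf_stratum", "class")
      acc <- gt_accuracy(tab) |> select(-"empty")
      rec <- gt_recovery(tab, classes = c("het", "hom_alt", "alt_combined")) |>
        select(-"empty")
      err <- gt_error_rate(tab, classes = c("het", "hom_alt", "alt_combined")) |>
        select(-"empty")
      nrd <- gt_nrd(tab) |> select(-"empty")
      acc |>
        left_join(rec, by = keys) |>
        left_join(err, by = keys) |>
        left_join(nrd, by = c("site_class", "maf_stratum")) |>
        mutate(min_gp = g, min_info = i)
    }
  ) |>
    mutate(sample_id = sample_id, coverage = coverage) |>
    select("sample_id", "coverage", "min_gp", "min_info", dplyr::everything())
  class(out) <- c("sweep_report", class(out))
  out
}

#' @method tidy concordance_table
#' @export
tidy.concordance_table <- function(x, ...) {
  bind_rows(
    gt_accuracy(x) |> mutate(metric = "accuracy", value = .data$accuracy) |>
      select("site_class", "maf_stratum", "class", "metric", "value"),
    gt_recovery(x) |> mutate(metric = "recovery", value = .data$recovery) |>
      select("site_class", "maf_stratum", "class", "metric", "value"),
    gt_error_rate(x) |>
      mutate(metric = "error_rate", value = .data$error_rate) |>
      select("site_class", "maf_stratum", "class", "metric", "value"),
    gt_nrd(x) |> mutate(metric = "nrd", class = "all", value = .data$nrd) |>
      select("site_class", "maf_stratum", "class", "metric", "value")
  )
}

#' @method glance concordance_table
#' @export
glance.concordance_table <- function(x, ...) {
  ov <- x |> filter(.data$site_class == "transversion",
                    .data$maf_stratum == "maf_ge_threshold")
  acc <- gt_accuracy(ov, classes = "alt_combined")
  rec <- gt_recovery(ov, classes = "all")
  nrd <- gt_nrd(ov)
  tibble(
    accuracy_alt = acc$accuracy[1],
    recovery = rec$recovery[1],
    recovery_correct = rec$recovery_correct[1],
    nrd = nrd$nrd[1],
    n_truth = sum(ov$n)
  )
}
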