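# confusion tables and the accuracy / recovery / error / NRD metrics

toy_counts <- function(...) concordance_counts(tibble::tribble(...))

test_that("identity call sets give a diagonal table with perfect metrics", {
  p <- tiny_panel(seed = 1)
  t1 <- sim_individual(p, "in_panel", seed = 2)
  tc <- truth_calls(t1, p)
  tab <- concordance_table(tc, tc, p)
  ov <- tab[tab$site_class == "all" & tab$maf_stratum == "overall", ]
  expect_true(all(ov$truth_class == ov$call_class))
  acc <- gt_accuracy(tab)
  expect_true(all(acc$accuracy[!acc$empty] == 1))
  expect_true(all(gt_nrd(tab)$nrd[!gt_nrd(tab)$empty] == 0))
  rec <- gt_recovery(tab)
  expect_true(all(rec$recovery[!rec$empty] == 1))
})

test_that("a hand-built ten-site toy matches hand enumeration", {
  p <- tiny_panel(n_sites = 10, len = 5e3, seed = 4)
  p$sites$ref <- rep("A", 10); p$sites$alt <- rep("C", 10)  # all transversions
  t1 <- sim_individual(p, "in_panel", seed = 5)
  tc <- truth_calls(t1, p)
  tc$gt <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 0L, 1L)
  called <- tc
  called$gt <- c(0L, 0L, 0L, 1L, 0L, 1L, 2L, 2L, 0L, NA)  # one flip, one miss
  called$gt[3] <- 2L                                       # second flip
  tab <- concordance_table(tc, called, p)
  ov <- tab[tab$site_class == "all" & tab$maf_stratum == "overall", ]
  cell <- function(t, c) {
    x <- ov$n[ov$truth_class == t & ov$call_class == c]
    if (length(x) == 0) 0L else x
  }
  expect_equal(cell("hom_ref", "hom_ref"), 3L)
  expect_equal(cell("hom_ref", "hom_alt"), 1L)
  expect_equal(cell("het", "hom_ref"), 1L)
  expect_equal(cell("het", "het"), 2L)
  expect_equal(cell("het", "missing"), 1L)
  expect_equal(cell("hom_alt", "hom_alt"), 2L)
  expect_equal(sum(ov$n), 10L)  # all truth genotypes accounted for

  acc <- gt_accuracy(tab, classes = "het")
  a <- acc[acc$site_class == "all" & acc$maf_stratum == "overall", ]
  expect_equal(a$accuracy, 2 / 3)  # TP=2, FN=1 (missing excluded)
})

test_that("the default stratification has eight MAF bins plus threshold and overall", {
  p <- tiny_panel(n_sites = 2000, len = 1e6, seed = 6)
  # spread panel frequencies so every MAF bin is populated
  p$sites$alt_freq <- seq(0.006, 0.499, length.out = 2000)
  t1 <- sim_individual(p, "in_panel", seed = 7)
  tc <- truth_calls(t1, p)
  tab <- concordance_table(tc, tc, p)
  strata <- unique(tab$maf_stratum)
  expect_equal(sum(grepl("^\\[", strata)), 8L)
  expect_true(all(c("maf_ge_threshold", "overall") %in% strata))
  expect_setequal(unique(tab$site_class), c("all", "transversion"))
  expect_error(concordance_table(tc[-1, ], tc, p), "site index")
})

test_that("accuracy follows TP/(TP+FN) with NaN flagging for empty classes", {
  tab <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "het", "het", 99L,
    "het", "hom_ref", 1L
  )
  a <- gt_accuracy(tab, classes = c("het", "hom_alt"))
  expect_equal(a$accuracy[a$class == "het"], 0.99)
  expect_true(is.nan(a$accuracy[a$class == "hom_alt"]))
  expect_true(a$empty[a$class == "hom_alt"])
})

test_that("both recovery variants follow their formulas", {
  tab <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "het", "het", 58L,
    "het", "missing", 42L
  )
  r <- gt_recovery(tab, classes = "het")
  expect_equal(r$recovery, 0.58)
  expect_equal(r$recovery_correct, 0.58)

  tab2 <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "het", "het", 58L,
    "het", "hom_alt", 2L,
    "het", "missing", 40L
  )
  r2 <- gt_recovery(tab2, classes = "het")
  expect_equal(r2$recovery, 0.60)
  expect_equal(r2$recovery_correct, 0.58)
})

test_that("error rate counts wrong non-missing calls over called genotypes", {
  tab <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "het", "het", 98L,
    "het", "hom_alt", 2L,
    "het", "missing", 10L
  )
  e <- gt_error_rate(tab, classes = "het")
  expect_equal(e$error_rate, 0.02)

  all_wrong <- toy_counts(~truth_class, ~call_class, ~n,
                          "hom_alt", "het", 7L)
  expect_equal(gt_error_rate(all_wrong, classes = "hom_alt")$error_rate, 1)
  empty <- toy_counts(~truth_class, ~call_class, ~n, "het", "missing", 5L)
  expect_true(is.nan(gt_error_rate(empty, classes = "het")$error_rate))
})

test_that("NRD excludes concordant hom-ref and matches hand enumeration", {
  tab <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "hom_ref", "hom_ref", 90L,
    "het", "het", 5L,
    "hom_alt", "hom_alt", 3L,
    "hom_ref", "het", 2L
  )
  expect_equal(gt_nrd(tab)$nrd, 0.2)  # 2 / (2 + 5 + 3)

  no_disc <- toy_counts(~truth_class, ~call_class, ~n,
                        "hom_ref", "hom_ref", 50L, "het", "het", 5L)
  expect_equal(gt_nrd(no_disc)$nrd, 0)

  only_ref <- toy_counts(~truth_class, ~call_class, ~n,
                         "hom_ref", "hom_ref", 50L, "het", "hom_ref", 1L)
  expect_equal(gt_nrd(only_ref)$nrd, 1)

  # NRD equals error rate when no concordant hom-ref exists
  tab2 <- toy_counts(
    ~truth_class, ~call_class, ~n,
    "het", "het", 8L,
    "het", "hom_alt", 2L
  )
  expect_equal(gt_nrd(tab2)$nrd,
               gt_error_rate(tab2, classes = "het")$error_rate)
})

test_that("metrics are invariant to site order", {
  p <- tiny_panel(seed = 8)
  t1 <- sim_individual(p, "in_panel", seed = 9)
  tc <- truth_calls(t1, p)
  called <- tc
  set.seed(1)
  flip <- sample(nrow(called), 30)
  called$gt[flip] <- (called$gt[flip] + 1L) %% 3L
  tab1 <- concordance_table(tc, called, p)
  perm <- sample(nrow(tc))
  tab2 <- concordance_table(tc[perm, ], called[perm, ], p)
  expect_equal(dplyr::arrange(tibble::as_tibble(tab1), dplyr::across(dplyr::everything())),
               dplyr::arrange(tibble::as_tibble(tab2), dplyr::across(dplyr::everything())))
})

test_that("sweep reports are tidy, complete and monotone in the thresholds", {
  p <- tiny_panel(n_sites = 300, seed = 10)
  t1 <- sim_individual(p, "in_panel", seed = 11)
  st <- sim_reads(t1, p, mean_coverage = 1, seed = 12)
  imp <- impute_sample(pileup_to_likelihoods(st, p), p)
  tc <- truth_calls(t1, p)

  sw <- filter_sweep(imp, gp_grid = c(0.8, 0.99), info_grid = c(0.8, 0.99))
  rep <- sweep_report(tc, sw, p, sample_id = "t1", coverage = 1)
  expect_equal(length(unique(paste(rep$min_gp, rep$min_info))), 4L)

  ov <- rep[rep$site_class == "all" & rep$maf_stratum == "overall" &
              rep$class == "alt_combined", ]
  loose <- ov$recovery[ov$min_gp == 0.8 & ov$min_info == 0.8]
  strict <- ov$recovery[ov$min_gp == 0.99 & ov$min_info == 0.99]
  expect_gte(loose, strict)

  # a single-cell grid reproduces the direct metric calls
  sw1 <- filter_sweep(imp, gp_grid = 0.9, info_grid = 0.9)
  rep1 <- sweep_report(tc, sw1, p)
  tab <- concordance_table(tc, filter_imputed(imp, 0.9, 0.9), p)
  direct <- gt_accuracy(tab)
  joined <- dplyr::inner_join(
    rep1, direct,
    by = c("site_class", "maf_stratum", "class"), suffix = c("", ".d")
  )
  expect_equal(joined$accuracy, joined$accuracy.d)
})

test_that("class totals decompose into TP, wrong calls and missing", {
  p <- tiny_panel(seed = 13)
  t1 <- sim_individual(p, "in_panel", seed = 14)
  tc <- truth_calls(t1, p)
  called <- tc
  set.seed(2)
  called$gt[sample(nrow(called), 40)] <- NA
  called$gt[sample(nrow(called), 25)] <- 2L
  tab <- concordance_table(tc, called, p)
  ov <- tab[tab$site_class == "all" & tab$maf_stratum == "overall", ]
  for (cl in c("hom_ref", "het", "hom_alt")) {
    total <- sum(ov$n[ov$truth_class == cl])
    tp <- sum(ov$n[ov$truth_class == cl & ov$call_class == cl])
    fn <- sum(ov$n[ov$truth_class == cl & ov$call_class != cl &
                     ov$call_class != "missing"])
    miss <- sum(ov$n[ov$truth_class == cl & ov$call_class == "missing"])
    expect_equal(tp + fn + miss, total)
    expect_equal(total, sum(tc$gt == match(cl, c("hom_ref", "het", "hom_alt")) - 1L))
  }
})
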