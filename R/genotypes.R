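#' Genotype likelihoods from a read stack
#'
#' Standard pileup likelihood at biallelic sites: reads failing base- or
#' mapping-quality thresholds are dropped; for alternate-allele dose
#' `k` in 0/1/2, each read contributes
#' `P(base | allele fraction k/2)`, where a read drawn from the reference
#' allele shows the reference base with probability `1 - e` and each other
#' base with probability `e/3` (`e` from the read's Phred base quality).
#' Bases matching neither allele contribute the error term. Sites with no
#' surviving reads get the uniform triple (1/3, 1/3, 1/3) and depth 0 — they
#' are unobserved, not errors.
#'
#' @param stack read-stack tibble from [sim_reads()].
#' @param panel the matching `haplotype_panel` (site ref/alt).
#' @param min_baseq,min_mapq quality thresholds (defaults 30, 25).
#' @return Tibble with one row per panel site: `chrom`, `pos`, `ref`, `alt`,
#'   `site_index`, normalised likelihoods `l0`, `l1`, `l2`, depth `dp`,
#'   allelic depths `ad_ref`, `ad_alt`.
#' @export
pileup_to_likelihoods <- function(stack, panel, min_baseq = 30,
                                  min_mapq = 25) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_sites <- nrow(panel$sites)
  keep <- stack$base_qual >= min_baseq & stack$map_qual >= min_mapq
  st <- stack[keep, , drop = FALSE]

  ref <- panel$sites$ref[st$site_index]
  alt <- panel$sites$alt[st$site_index]
  e <- 10^(-st$base_qual / 10)

  p_ref_allele <- ifelse(st$base == ref, 1 - e, e / 3)  # read from ref allele
  p_alt_allele <- ifelse(st$base == alt, 1 - e, e / 3)  # read from alt allele

  ll0 <- log(p_ref_allele)
  ll2 <- log(p_alt_allele)
  ll1 <- log(0.5 * p_ref_allele + 0.5 * p_alt_allele)

  sum_by_site <- function(x) {
    out <- numeric(n_sites)
    s <- rowsum(x, st$site_index)
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }
  L0 <- sum_by_site(ll0); L1 <- sum_by_site(ll1); L2 <- sum_by_site(ll2)
  m <- pmax(L0, L1, L2)
  l0 <- exp(L0 - m); l1 <- exp(L1 - m); l2 <- exp(L2 - m)
  z <- l0 + l1 + l2

  dp <- tabulate(st$site_index, nbins = n_sites)
  ad_ref <- tabulate(st$site_index[st$base == ref], nbins = n_sites)
  ad_alt <- tabulate(st$site_index[st$base == alt], nbins = n_sites)

  out <- tibble(
    chrom = panel$sites$chrom, pos = panel$sites$pos,
    ref = panel$sites$ref, alt = panel$sites$alt,
    site_index = seq_len(n_sites),
    l0 = l0 / z, l1 = l1 / z, l2 = l2 / z,
    dp = dp, ad_ref = ad_ref, ad_alt = ad_alt
  )
  attr(out, "sample_id") <- attr(stack, "sample_id")
  out
}

#' Call high-quality validation genotypes from likelihoods
#'
#' Hard-calls the likelihood argmax, then sets genotypes missing unless they
#' pass the gold-standard filters: genotype quality at least `min_gq`, depth
#' within `[min_depth, max_depth_mult * mean_cov]`, and — for heterozygous
#' calls — a minor-read fraction of at least `min_allele_balance`.
#'
#' @param gl tibble from [pileup_to_likelihoods()].
#' @param mean_cov the sample's mean genomic coverage.
#' @param min_gq,min_depth,max_depth_mult,min_allele_balance filter
#'   parameters (defaults 25, 8, 3, 0.40).
#' @return A call-set tibble (`gt` NA where filtered) with `gq` and depth
#'   columns; provenance `"validation"`.
#' @export
call_validation_genotypes <- function(gl, mean_cov, min_gq = 25,
                                      min_depth = 8, max_depth_mult = 3,
                                      min_allele_balance = 0.40) {
  lmat <- cbind(gl$l0, gl$l1, gl$l2)
  gt <- max.col(lmat, ties.method = "first") - 1L
  maxp <- lmat[cbind(seq_len(nrow(lmat)), gt + 1L)]
  gq <- pmin(99, -10 * log10(pmax(1 - maxp, 1e-10)))

  ab <- pmin(gl$ad_ref, gl$ad_alt) / pmax(gl$ad_ref + gl$ad_alt, 1L)
  pass <- gq >= min_gq &
    gl$dp >= min_depth & gl$dp <= max_depth_mult * mean_cov &
    (gt != 1L | ab >= min_allele_balance)
  gt[!pass] <- NA_integer_

  out <- tibble(
    chrom = gl$chrom, pos = gl$pos, ref = gl$ref, alt = gl$alt,
    site_index = gl$site_index, gt = gt, gq = gq, dp = gl$dp,
    ad_ref = gl$ad_ref, ad_alt = gl$ad_alt
  )
  attr(out, "provenance") <- "validation"
  attr(out, "sample_id") <- attr(gl, "sample_id")
  out
}

#' Mask genotypes compatible with residual deamination
#'
#' Removes calls that C→T (or G→A) deamination could have inflated.
#' `paper_literal` masks heterozygote and homozygote-reference genotypes at
#' sites with ref T / alt C or ref A / alt G. `both_orientations`
#' (the default) additionally masks heterozygote and homozygote-alternate
#' genotypes at sites with ref C / alt T or ref G / alt A, completing the
#' symmetric rule so every damage-inflatable call at a transition site is
#' removed. Transversion sites are never touched.
#'
#' On a call set the affected genotypes are set missing; on a likelihood
#' table the triple at affected sites is set uninformative (uniform), so site
#' coordinates stay aligned for imputation.
#'
#' @param x a call-set tibble (with `gt`) or a likelihood tibble (with
#'   `l0`/`l1`/`l2`).
#' @param mode `"both_orientations"` (default) or `"paper_literal"`.
#' @return Masked copy of `x`; attribute `mask_counts` holds per-rule counts.
#' @export
damage_mask <- function(x, mode = c("both_orientations", "paper_literal")) {
  mode <- match.arg(mode)
  rule1 <- (x$ref == "T" & x$alt == "C") | (x$ref == "A" & x$alt == "G")
  rule2 <- (x$ref == "C" & x$alt == "T") | (x$ref == "G" & x$alt == "A")
  counts <- c(ref_damaged = 0L, alt_damaged = 0L)

  if ("gt" %in% names(x)) {
    m1 <- rule1 & !is.na(x$gt) & x$gt %in% c(0L, 1L)
    counts["ref_damaged"] <- sum(m1)
    x$gt[m1] <- NA_integer_
    if (mode == "both_orientations") {
      m2 <- rule2 & !is.na(x$gt) & x$gt %in% c(1L, 2L)
      counts["alt_damaged"] <- sum(m2)
      x$gt[m2] <- NA_integer_
    }
  } else if (all(c("l0", "l1", "l2") %in% names(x))) {
    m1 <- rule1
    counts["ref_damaged"] <- sum(m1)
    m <- m1
    if (mode == "both_orientations") {
      counts["alt_damaged"] <- sum(rule2)
      m <- m | rule2
    }
    x$l0[m] <- 1 / 3; x$l1[m] <- 1 / 3; x$l2[m] <- 1 / 3
  } else {
    abort("`x` must be a call set (gt) or a likelihood table (l0/l1/l2)")
  }
  attr(x, "mask_counts") <- counts
  x
}

#' Pseudohaploid calling by random read sampling
#'
#' The standard very-low-coverage ancient-DNA representation: after dropping
#' reads within `trim_bp` of a read end or failing quality thresholds, one
#' surviving read is sampled uniformly per site and its base is recorded as a
#' haploid call coded homozygous (0 or 2). Sites are set missing when
#' uncovered; a site is dropped (missing, counted) when the sampled base
#' matches neither panel allele (the panel-consistency check) or — with
#' `transversions_only` — when the site is a transition.
#'
#' @param stack read-stack tibble.
#' @param panel the matching `haplotype_panel`.
#' @param min_baseq,min_mapq,trim_bp,transversions_only parameters
#'   (defaults 30, 25, 5, TRUE).
#' @param seed optional integer seed.
#' @return A call-set tibble with provenance `"pseudohaploid"`; attribute
#'   `drop_counts` reports inconsistent and transition drops.
#' @export
pseudohaploid_call <- function(stack, panel, min_baseq = 30, min_mapq = 25,
                               trim_bp = 5, transversions_only = TRUE,
                               seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_sites <- nrow(panel$sites)
  keep <- stack$base_qual >= min_baseq & stack$map_qual >= min_mapq &
    stack$dist_end >= trim_bp
  st <- stack[keep, , drop = FALSE]

  with_opt_seed(seed, {
    # sample one read per covered site, uniformly
    ord <- sample.int(nrow(st))
    st <- st[ord, , drop = FALSE]
    pick <- st[!duplicated(st$site_index), , drop = FALSE]

    gt <- rep(NA_integer_, n_sites)
    base <- rep(NA_character_, n_sites)
    base[pick$site_index] <- pick$base

    ref <- panel$sites$ref; alt <- panel$sites$alt
    is_ts <- is_transition_pair(ref, alt)
    covered <- !is.na(base)
    consistent <- covered & (base == ref | base == alt)
    n_inconsistent <- sum(covered & !consistent)

    use <- consistent
    n_transition <- 0L
    if (transversions_only) {
      n_transition <- sum(use & is_ts)
      use <- use & !is_ts
    }
    gt[use] <- ifelse(base[use] == alt[use], 2L, 0L)

    out <- tibble(
      chrom = panel$sites$chrom, pos = panel$sites$pos,
      ref = ref, alt = alt, site_index = seq_len(n_sites), gt = gt
    )
    attr(out, "provenance") <- "pseudohaploid"
    attr(out, "sample_id") <- attr(stack, "sample_id")
    attr(out, "drop_counts") <- c(inconsistent = n_inconsistent,
                                  transition = n_transition)
    out
  })
}
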