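#' Simulate a phased multi-ancestry reference panel
#'
#' Builds a phased, biallelic haplotype panel with the structure the imputation
#' study assumes: a pool of founder haplotypes whose alternate-allele
#' frequencies are drawn from a U-shaped spectrum, ancestry groups that copy
#' from partially disjoint founder subsets, and panel haplotypes that are
#' recombinant Markov mosaics of their group's founders. Sites carry a CpG flag
#' used by the deamination model.
#'
#' The default ancestry composition is a 1/10-scale version of a mixed
#' taurine/indicine panel (8 European taurine, 3 Asian taurine, 2 African
#' taurine, 1 African hybrid, 1 southwest-Asian hybrid, 2 northeast-Asian
#' hybrid, 2 indicine; 19 individuals, 38 haplotypes).
#'
#' @param n_sites total number of biallelic SNP sites across all chromosomes.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_founders number of founder haplotypes (>= 2).
#' @param ancestry_sizes named integer vector: individuals per ancestry group.
#' @param switch_rate founder-mosaic switch rate per bp (> 0).
#' @param cpg_fraction probability a site is flagged as CpG.
#' @param freq_shape two shape parameters of the Beta spectrum from which
#'   per-site founder alternate-allele frequencies are drawn.
#' @param founder_overlap fraction of the founder pool available to each
#'   ancestry group; groups take sliding, overlapping windows of founders.
#' @param seed optional integer seed; identical seeds reproduce the panel
#'   bit-for-bit.
#'
#' @return A `haplotype_panel`: list with `sites` (tibble: chrom, pos, ref,
#'   alt, cpg, alt_freq), `haplotypes` (0/1 integer matrix, 2 rows per
#'   individual), `individuals` (tibble: id, ancestry), `chrom_lengths`,
#'   `founders`, `founder_sets`, and `site_freq` (the founder spectrum draws).
#' @export
#' @examples
#' p <- sim_panel(n_sites = 200, chrom_lengths = c(chr1 = 1e6), seed = 1)
#' p$sites
sim_panel <- function(n_sites = 5000,
                      chrom_lengths = c(chr1 = 2.5e6),
                      n_founders = 20,
                      ancestry_sizes = c(
                        european_taurus = 8, asian_taurus = 3,
                        african_taurus = 2, african_hybrid = 1,
                        swasian_hybrid = 1, neasian_hybrid = 2,
                        indicus = 2
                      ),
                      switch_rate = 1e-6,
                      cpg_fraction = 0.1,
                      freq_shape = c(0.5, 0.5),
                      founder_overlap = 0.6,
                      seed = NULL) {
  assert_scalar_number(n_sites, "n_sites", min = 1)
  assert_scalar_number(n_founders, "n_founders", min = 2)
  assert_scalar_number(switch_rate, "switch_rate", min = 0, strict_min = TRUE)
  assert_scalar_number(cpg_fraction, "cpg_fraction", min = 0, max = 1)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    abort("`chrom_lengths` must be a named vector of positive lengths")
  }
  if (is.null(names(ancestry_sizes)) || any(ancestry_sizes < 1)) {
    abort("`ancestry_sizes` must be a named vector of positive group sizes")
  }

  with_opt_seed(seed, {
    sites <- draw_sites(n_sites, chrom_lengths, cpg_fraction)

    site_freq <- rbeta(n_sites, freq_shape[1], freq_shape[2])
    site_freq <- pmin(pmax(site_freq, 1e-6), 1 - 1e-6)

    founders <- matrix(
      rbinom(n_founders * n_sites, 1L, rep(site_freq, each = n_founders)),
      nrow = n_founders, ncol = n_sites
    )

    founder_sets <- assign_founder_sets(names(ancestry_sizes), n_founders,
                                        founder_overlap)

    individuals <- tibble(
      id = unlist(purrr::imap(as.list(ancestry_sizes), function(k, nm) {
        paste0(nm, "_", seq_len(k))
      }), use.names = FALSE),
      ancestry = rep(names(ancestry_sizes), times = ancestry_sizes)
    )

    n_hap <- 2L * nrow(individuals)
    haplotypes <- matrix(0L, nrow = n_hap, ncol = n_sites)
    hap_row <- 0L
    for (i in seq_len(nrow(individuals))) {
      pool <- founder_sets[[individuals$ancestry[i]]]
      for (h in 1:2) {
        hap_row <- hap_row + 1L
        path <- founder_mosaic_path(pool, sites$chrom, sites$pos, switch_rate)
        haplotypes[hap_row, ] <- founders[cbind(path, seq_len(n_sites))]
      }
    }
    rownames(haplotypes) <- paste0(rep(individuals$id, each = 2), "_h",
                                   rep(1:2, nrow(individuals)))

    sites$alt_freq <- colMeans(haplotypes)

    structure(
      list(
        sites = sites, haplotypes = haplotypes, individuals = individuals,
        chrom_lengths = chrom_lengths, founders = founders,
        founder_sets = founder_sets, site_freq = site_freq,
        switch_rate = switch_rate
      ),
      class = "haplotype_panel"
    )
  })
}

# strictly increasing positions per chromosome, allocated by length
draw_sites <- function(n_sites, chrom_lengths, cpg_fraction) {
  alloc <- round(n_sites * chrom_lengths / sum(chrom_lengths))
  alloc[length(alloc)] <- n_sites - sum(alloc[-length(alloc)])
  if (any(alloc < 1)) abort("every chromosome must receive at least one site")
  bases <- c("A", "C", "G", "T")
  per_chrom <- purrr::imap(as.list(alloc), function(k, chrom) {
    len <- chrom_lengths[[chrom]]
    if (k > len) abort("more sites requested than positions available")
    pos <- sort(sample.int(len, k))
    tibble(chrom = chrom, pos = pos)
  })
  sites <- bind_rows(per_chrom)
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt <- purrr::map_chr(sites$ref, function(r) sample(setdiff(bases, r), 1))
  sites$cpg <- runif(nrow(sites)) < cpg_fraction
  sites
}

# overlapping founder windows: consecutive ancestries share part of the pool
assign_founder_sets <- function(groups, n_founders, overlap_frac) {
  size <- max(1L, ceiling(n_founders * overlap_frac))
  n_groups <- length(groups)
  starts <- if (n_groups == 1L) 0L else {
    round((seq_len(n_groups) - 1) * (n_founders - size) / (n_groups - 1))
  }
  sets <- purrr::map(starts, function(s) seq.int(s + 1L, s + size))
  setNames(sets, groups)
}

# Markov founder path along sites; switches reset at chromosome boundaries
founder_mosaic_path <- function(pool, chrom, pos, switch_rate) {
  n <- length(pos)
  d <- c(Inf, diff(pos))
  d[c(TRUE, chrom[-1] != chrom[-n])] <- Inf  # new chromosome: fresh draw
  p_switch <- 1 - exp(-switch_rate * d)
  switch <- runif(n) < p_switch
  switch[1] <- TRUE
  seg <- cumsum(switch)
  draws <- pool[sample.int(length(pool), max(seg), replace = TRUE)]
  draws[seg]
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d haplotypes (%d individuals, %d ancestries), %d sites on %d chromosome(s)\n",
    nrow(x$haplotypes), nrow(x$individuals),
    length(unique(x$individuals$ancestry)), nrow(x$sites),
    length(x$chrom_lengths)
  ))
  invisible(x)
}

#' Simulate a diploid test genome from a panel's founder pool
#'
#' Draws the two haplotypes of a truth genome as founder mosaics. An
#' `in_panel` genome copies from the founder pool of one panel ancestry group,
#' so imputation against the panel should perform well. A `diverged` genome
#' copies from a pool extended with private founders the panel never saw, with
#' an elevated switch rate, emulating a test individual (e.g. an aurochs)
#' diverged from all panel ancestries.
#'
#' @param panel a `haplotype_panel` from [sim_panel()].
#' @param scenario `"in_panel"` or `"diverged"`.
#' @param ancestry ancestry group supplying the founder pool; defaults to the
#'   first group.
#' @param divergence_switch_multiplier factor on the panel switch rate for the
#'   diverged scenario.
#' @param private_founder_count number of private founders (diverged only).
#' @param id sample identifier.
#' @param seed optional integer seed.
#'
#' @return A `truth_genome`: list with `id`, `scenario`, `ancestry`,
#'   `gt` (0/1/2 per panel site), and the generating haplotypes `hap1`/`hap2`.
#' @export
sim_individual <- function(panel, scenario = c("in_panel", "diverged"),
                           ancestry = NULL,
                           divergence_switch_multiplier = 3,
                           private_founder_count = 4,
                           id = "test1", seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  scenario <- match.arg(scenario)
  ancestry <- ancestry %||% names(panel$founder_sets)[1]
  if (!ancestry %in% names(panel$founder_sets)) {
    abort(sprintf("unknown ancestry group '%s'", ancestry))
  }

  with_opt_seed(seed, {
    n_sites <- nrow(panel$sites)
    founders <- panel$founders
    pool <- panel$founder_sets[[ancestry]]
    rate <- panel$switch_rate

    if (scenario == "diverged") {
      if (private_founder_count > 0) {
        private <- matrix(
          rbinom(private_founder_count * n_sites, 1L,
                 rep(panel$site_freq, each = private_founder_count)),
          nrow = private_founder_count, ncol = n_sites
        )
        founders <- rbind(founders, private)
        pool <- c(pool, nrow(panel$founders) + seq_len(private_founder_count))
      }
      rate <- rate * divergence_switch_multiplier
    }

    hap <- replicate(2, {
      path <- founder_mosaic_path(pool, panel$sites$chrom, panel$sites$pos, rate)
      founders[cbind(path, seq_len(n_sites))]
    })

    structure(
      list(id = id, scenario = scenario, ancestry = ancestry,
           hap1 = hap[, 1], hap2 = hap[, 2],
           gt = as.integer(hap[, 1] + hap[, 2])),
      class = "truth_genome"
    )
  })
}

#' @export
print.truth_genome <- function(x, ...) {
  cat(sprintf("<truth_genome> %s (%s), %d sites, het fraction %.3f\n",
              x$id, x$scenario, length(x$gt), mean(x$gt == 1L)))
  invisible(x)
}

#' Plant a long homozygous tract in a truth genome
#'
#' Copies the first haplotype over the second within an interval so the genome
#' is exactly homozygous there, emulating a long run of homozygosity from
#' recent inbreeding (e.g. a multi-megabase ROH detectable by a windowed scan).
#'
#' @param truth a `truth_genome`.
#' @param panel the panel the genome was simulated from.
#' @param chrom chromosome of the tract.
#' @param start,end tract bounds in bp (1-based, inclusive of sites at both).
#' @return The modified `truth_genome`.
#' @export
plant_roh <- function(truth, panel, chrom, start, end) {
  stopifnot(inherits(truth, "truth_genome"), inherits(panel, "haplotype_panel"))
  if (end <= start) abort("`end` must exceed `start`")
  idx <- which(panel$sites$chrom == chrom &
                 panel$sites$pos >= start & panel$sites$pos <= end)
  truth$hap2[idx] <- truth$hap1[idx]
  truth$gt <- as.integer(truth$hap1 + truth$hap2)
  truth
}

#' Extract truth genotypes as a call set
#'
#' @param truth a `truth_genome`.
#' @param panel the matching `haplotype_panel`.
#' @return A call-set tibble (chrom, pos, ref, alt, site_index, gt) with
#'   provenance `"truth"`.
#' @export
truth_calls <- function(truth, panel) {
  out <- tibble(
    chrom = panel$sites$chrom, pos = panel$sites$pos,
    ref = panel$sites$ref, alt = panel$sites$alt,
    site_index = seq_len(nrow(panel$sites)),
    gt = truth$gt
  )
  attr(out, "provenance") <- "truth"
  attr(out, "sample_id") <- truth$id
  out
}
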