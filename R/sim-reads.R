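#' Post-mortem deamination model for simulated ancient reads
#'
#' Residual cytosine deamination after UDG treatment: C→T (and, on the other
#' strand, G→A) substitutions whose rate decays exponentially with distance
#' from the nearest read end, plus a position-independent floor. With
#' `udg_treated = TRUE` damage is restricted to CpG-flagged sites, where
#' methylation protects deaminated cytosines from the UDG enzyme.
#'
#' The rate at distance `d` bp from a read end is
#' `floor + (delta_max - floor) * exp(-lambda * d)`.
#'
#' @param delta_max deamination probability at the read terminus.
#' @param lambda exponential decay per bp from the read end.
#' @param floor position-independent residual rate.
#' @param udg_treated restrict damage to CpG-flagged sites?
#' @param read_length read length in bp (default 100, single-end).
#' @param base_error sequencing miscall probability per base.
#' @return A `damage_model` list.
#' @export
#' @examples
#' damage_model()                       # plausible residual post-UDG damage
#' damage_model(delta_max = 0, floor = 0, base_error = 0)  # noise-free reads
damage_model <- function(delta_max = 0.2, lambda = 0.1, floor = 0.01,
                         udg_treated = TRUE, read_length = 100,
                         base_error = 0.001) {
  for (nm in c("delta_max", "lambda", "floor", "base_error")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  assert_scalar_number(delta_max, "delta_max", max = 1)
  assert_scalar_number(floor, "floor", max = 1)
  assert_scalar_number(base_error, "base_error", max = 1)
  assert_scalar_number(read_length, "read_length", min = 1)
  if (floor > delta_max) abort("`floor` must not exceed `delta_max`")
  structure(list(delta_max = delta_max, lambda = lambda, floor = floor,
                 udg_treated = udg_treated, read_length = read_length,
                 base_error = base_error),
            class = "damage_model")
}

#' Deamination rate at a given distance from the read end
#' @param model a [damage_model()].
#' @param d distance from the nearest read end in bp (vectorised).
#' @return Substitution probability in \[0, 1\].
#' @export
damage_rate <- function(model, d) {
  model$floor + (model$delta_max - model$floor) * exp(-model$lambda * d)
}

#' Simulate ancient sequencing reads over panel sites
#'
#' Per-site read counts are Poisson with mean `mean_coverage`. Each read copies
#' the allele of one of the truth genome's haplotypes, suffers a sequencing
#' miscall with probability `base_error` (uniform over the other three bases),
#' and is then deaminated — C→T or G→A, each with probability `damage_rate()`
#' at the read's distance from its nearest end — at CpG-flagged sites when the
#' model is UDG-treated, at all sites otherwise. Base quality reflects the
#' sequencing error rate; mapping quality is a constant 37 (alignment is not
#' modelled).
#'
#' @param truth a `truth_genome` from [sim_individual()].
#' @param panel the matching `haplotype_panel`.
#' @param mean_coverage mean read depth per site (> 0).
#' @param damage a [damage_model()].
#' @param seed optional integer seed.
#' @return A read-stack tibble: `site_index`, `chrom`, `pos`, `base`,
#'   `base_qual`, `map_qual`, `dist_end`, `hap`.
#' @export
sim_reads <- function(truth, panel, mean_coverage, damage = damage_model(),
                      seed = NULL) {
  stopifnot(inherits(truth, "truth_genome"), inherits(panel, "haplotype_panel"),
            inherits(damage, "damage_model"))
  assert_scalar_number(mean_coverage, "mean_coverage", min = 0,
                       strict_min = TRUE)

  with_opt_seed(seed, {
    n_sites <- nrow(panel$sites)
    n_reads_site <- rpois(n_sites, mean_coverage)
    total <- sum(n_reads_site)
    site_index <- rep.int(seq_len(n_sites), n_reads_site)

    hap <- sample(1:2, total, replace = TRUE)
    allele <- ifelse(hap == 1L, truth$hap1[site_index], truth$hap2[site_index])
    base <- ifelse(allele == 1L, panel$sites$alt[site_index],
                   panel$sites$ref[site_index])

    # position of the site within the read, uniform; fold to nearest end
    pos_in_read <- sample.int(damage$read_length, total, replace = TRUE) - 1L
    dist_end <- pmin(pos_in_read, damage$read_length - 1L - pos_in_read)

    # sequencing error: uniform over the three other bases
    bases <- c("A", "C", "G", "T")
    err <- runif(total) < damage$base_error
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      cur <- match(base[err], bases)
      base[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }

    # deamination on the read's current base
    eligible <- if (damage$udg_treated) panel$sites$cpg[site_index] else TRUE
    rate <- damage_rate(damage, dist_end)
    deam <- eligible & (runif(total) < rate)
    base[deam & base == "C"] <- "T"
    base[deam & base == "G"] <- "A"

    qual <- if (damage$base_error > 0) {
      as.integer(round(-10 * log10(damage$base_error)))
    } else 60L

    out <- tibble(
      site_index = site_index,
      chrom = panel$sites$chrom[site_index],
      pos = panel$sites$pos[site_index],
      base = base,
      base_qual = qual,
      map_qual = 37L,
      dist_end = dist_end,
      hap = hap
    )
    attr(out, "n_sites") <- n_sites
    attr(out, "sample_id") <- truth$id
    out
  })
}

#' Downsample a read stack to a target coverage, per chromosome
#'
#' Reads are retained independently with probability
#' `target_coverage / chromosome mean coverage`, computed per chromosome
#' (thinning is chromosomal, not genome-wide, so chromosomes at different
#' depths all land on the target).
#'
#' @param stack a read-stack tibble from [sim_reads()].
#' @param panel the matching `haplotype_panel` (supplies per-chromosome site
#'   counts).
#' @param target_coverage desired mean depth; must not exceed any
#'   chromosome's current mean coverage.
#' @param chrom_mean_coverages optional named vector of current per-chromosome
#'   mean coverages; computed from the stack when omitted.
#' @param seed optional integer seed.
#' @return The thinned read-stack tibble.
#' @export
downsample_reads <- function(stack, panel, target_coverage,
                             chrom_mean_coverages = NULL, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  assert_scalar_number(target_coverage, "target_coverage", min = 0,
                       strict_min = TRUE)

  sites_per_chrom <- table(panel$sites$chrom)
  if (is.null(chrom_mean_coverages)) {
    reads_per_chrom <- table(factor(stack$chrom, levels = names(sites_per_chrom)))
    chrom_mean_coverages <- as.numeric(reads_per_chrom) /
      as.numeric(sites_per_chrom)
    names(chrom_mean_coverages) <- names(sites_per_chrom)
  }
  if (any(target_coverage > chrom_mean_coverages + 1e-12)) {
    abort("`target_coverage` exceeds the mean coverage of at least one chromosome")
  }

  with_opt_seed(seed, {
    keep_prob <- pmin(1, target_coverage / chrom_mean_coverages[stack$chrom])
    keep <- runif(nrow(stack)) < keep_prob
    out <- stack[keep, , drop = FALSE]
    attr(out, "n_sites") <- attr(stack, "n_sites")
    attr(out, "sample_id") <- attr(stack, "sample_id")
    out
  })
}
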