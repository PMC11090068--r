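#' Plan imputation chunks
#'
#' Tiles each chromosome into consecutive cores of `chunk_bp` (last core
#' truncated) and extends each core by `buffer_bp` on both sides, clipped at
#' the chromosome ends. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param chunk_bp core size (default 2 Mb).
#' @param buffer_bp buffer size (default 200 kb); must be smaller than
#'   `chunk_bp`.
#' @return Tibble: `chrom`, `core_start`, `core_end`, `buf_start`, `buf_end`.
#' @export
#' @examples
#' plan_chunks(c(chr1 = 5e6))
plan_chunks <- function(chrom_lengths, chunk_bp = 2e6, buffer_bp = 2e5) {
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  if (buffer_bp >= chunk_bp) abort("`buffer_bp` must be smaller than `chunk_bp`")
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chrom) {
    starts <- seq(0, len - 1, by = chunk_bp)
    tibble(
      chrom = chrom,
      core_start = starts,
      core_end = pmin(starts + chunk_bp, len),
      buf_start = pmax(starts - buffer_bp, 0),
      buf_end = pmin(starts + chunk_bp + buffer_bp, len)
    )
  })
}

#' Diploid haplotype-copying forward-backward
#'
#' Low-level interface to the Li-Stephens copying model: the hidden state is
#' an (ordered) pair of reference haplotypes; per interval each haplotype
#' keeps its template with probability `exp(-rho * d / K)` and otherwise
#' switches to a uniformly drawn template; emissions perturb the copied
#' alleles with miscopy probability `eps` and weight genotype likelihoods.
#' Posterior genotype probabilities come from a scaled forward-backward pass.
#'
#' @param gl numeric matrix (sites x 3) of genotype likelihoods (rows need
#'   not be normalised).
#' @param haps integer matrix (K haplotypes x sites) of panel alleles 0/1.
#' @param pos site positions in bp (strictly increasing).
#' @param rho population-scaled recombination rate per bp
#'   (default `4 * 20000 * 1e-8`).
#' @param eps miscopy probability (default 1e-4).
#' @return List: `gp` (sites x 3 posterior matrix), `loglik`, `scale`.
#' @export
ls_forward_backward <- function(gl, haps, pos, rho = 4 * 20000 * 1e-8,
                                eps = 1e-4) {
  K <- nrow(haps)
  if (K < 2) abort("reference panel must contain at least 2 haplotypes")
  if (any(diff(pos) <= 0)) abort("`pos` must be strictly increasing")
  no_switch <- c(1, exp(-rho * diff(pos) / K))
  .ls_diploid_fb(gl, haps, no_switch, eps)
}

#' Impute one chunk against the panel
#'
#' Runs the copying model over the panel sites falling in
#' `[start, end)` (0-based half-open) of one chromosome.
#'
#' @param gl likelihood tibble from [pileup_to_likelihoods()] (uniform triples
#'   at unobserved sites).
#' @param panel a `haplotype_panel`.
#' @param chrom,start,end chunk bounds.
#' @inheritParams ls_forward_backward
#' @return Tibble (`site_index`, `gp0`, `gp1`, `gp2`) with attribute
#'   `loglik`.
#' @export
impute_chunk <- function(gl, panel, chrom, start, end,
                         rho = 4 * 20000 * 1e-8, eps = 1e-4) {
  idx <- which(panel$sites$chrom == chrom &
                 panel$sites$pos > start & panel$sites$pos <= end)
  if (length(idx) == 0) {
    return(structure(tibble(site_index = integer(), gp0 = numeric(),
                            gp1 = numeric(), gp2 = numeric()), loglik = 0))
  }
  glm <- as.matrix(gl[match(idx, gl$site_index), c("l0", "l1", "l2")])
  res <- ls_forward_backward(glm, panel$haplotypes[, idx, drop = FALSE],
                             panel$sites$pos[idx], rho = rho, eps = eps)
  structure(
    tibble(site_index = idx, gp0 = res$gp[, 1], gp1 = res$gp[, 2],
           gp2 = res$gp[, 3]),
    loglik = res$loglik
  )
}

#' Ligate imputed chunks
#'
#' Each site's posterior is taken from the chunk whose core contains it;
#' buffer-only copies are discarded. Disagreements between a kept core copy
#' and any buffer copy (posterior difference above `tol`) are counted.
#'
#' @param chunks list of per-chunk tibbles from [impute_chunk()], in the
#'   order of `plan`'s rows.
#' @param plan chunk plan from [plan_chunks()].
#' @param panel a `haplotype_panel`.
#' @param tol posterior difference counted as a buffer/core disagreement.
#' @return Tibble (`site_index`, `gp0`, `gp1`, `gp2`); attributes `loglik`
#'   (summed) and `n_buffer_disagreements`.
#' @export
ligate <- function(chunks, plan, panel, tol = 0.01) {
  stopifnot(length(chunks) == nrow(plan))
  n_sites <- nrow(panel$sites)
  gp <- matrix(NA_real_, n_sites, 3)
  from_core <- rep(FALSE, n_sites)
  disagreements <- 0L
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    if (nrow(ch) == 0) next
    pos <- panel$sites$pos[ch$site_index]
    in_core <- panel$sites$chrom[ch$site_index] == plan$chrom[i] &
      pos > plan$core_start[i] & pos <= plan$core_end[i]
    vals <- as.matrix(ch[, c("gp0", "gp1", "gp2")])
    seen <- !is.na(gp[ch$site_index, 1])
    diff_big <- seen & rowSums(abs(vals - gp[ch$site_index, ])) > tol
    disagreements <- disagreements + sum(diff_big, na.rm = TRUE)
    take <- in_core & !from_core[ch$site_index]
    gp[ch$site_index[take], ] <- vals[take, , drop = FALSE]
    from_core[ch$site_index[take]] <- TRUE
    # keep buffer copies only where no core copy exists yet
    buf_take <- !in_core & is.na(gp[ch$site_index, 1])
    gp[ch$site_index[buf_take], ] <- vals[buf_take, , drop = FALSE]
  }
  if (anyNA(gp[, 1])) abort("some panel sites are covered by no chunk core")
  if (any(!from_core)) abort("some panel sites are covered by no chunk core")
  structure(
    tibble(site_index = seq_len(n_sites), gp0 = gp[, 1], gp1 = gp[, 2],
           gp2 = gp[, 3]),
    loglik = sum(purrr::map_dbl(chunks, ~ attr(.x, "loglik") %||% 0)),
    n_buffer_disagreements = disagreements
  )
}

#' IMPUTE-style INFO score
#'
#' `1 - mean(posterior dosage variance) / (2 p (1 - p))` with `p` the panel
#' alternate-allele frequency; defined as 1 where `p` is 0 or 1, clipped to
#' \[0, 1\]. Certain posteriors give 1; a posterior equal to the
#' Hardy-Weinberg prior gives 0.
#'
#' @param gp matrix (samples x 3) or vector of length 3 of genotype
#'   posteriors for one site.
#' @param p panel alternate-allele frequency.
#' @return INFO score in \[0, 1\].
#' @export
info_score <- function(gp, p) {
  if (is.null(dim(gp))) gp <- matrix(gp, nrow = 1)
  if (p <= 0 || p >= 1) return(1)
  ds <- gp[, 2] + 2 * gp[, 3]
  v <- gp[, 2] + 4 * gp[, 3] - ds^2
  min(max(1 - mean(v) / (2 * p * (1 - p)), 0), 1)
}

#' Impute a sample from genotype likelihoods
#'
#' Chunked diploid haplotype-copying imputation: plans 2 Mb cores with 200 kb
#' buffers, imputes each chunk with [impute_chunk()], ligates, and annotates
#' hard calls (posterior argmax), dosage, genotype quality, and per-site INFO.
#'
#' @inheritParams impute_chunk
#' @param chunk_bp,buffer_bp chunking parameters (defaults 2 Mb / 200 kb).
#' @return A call-set tibble with `gt`, `gp0`-`gp2`, `ds`, `gq`, `info`;
#'   provenance `"imputed"`; attributes `loglik`, `n_buffer_disagreements`.
#' @export
impute_sample <- function(gl, panel, chunk_bp = 2e6, buffer_bp = 2e5,
                          rho = 4 * 20000 * 1e-8, eps = 1e-4) {
  plan <- plan_chunks(panel$chrom_lengths, chunk_bp, buffer_bp)
  chunks <- purrr::map(seq_len(nrow(plan)), function(i) {
    impute_chunk(gl, panel, plan$chrom[i], plan$buf_start[i], plan$buf_end[i],
                 rho = rho, eps = eps)
  })
  lig <- ligate(chunks, plan, panel)
  gp <- as.matrix(lig[, c("gp0", "gp1", "gp2")])
  gt <- max.col(gp, ties.method = "first") - 1L
  maxp <- gp[cbind(seq_len(nrow(gp)), gt + 1L)]
  p <- panel$sites$alt_freq
  # vectorised single-sample info_score()
  ds <- gp[, 2] + 2 * gp[, 3]
  v <- gp[, 2] + 4 * gp[, 3] - ds^2
  info <- ifelse(p <= 0 | p >= 1, 1,
                 pmin(pmax(1 - v / (2 * p * (1 - p)), 0), 1))

  out <- tibble(
    chrom = panel$sites$chrom, pos = panel$sites$pos,
    ref = panel$sites$ref, alt = panel$sites$alt,
    site_index = lig$site_index,
    gt = gt, gp0 = lig$gp0, gp1 = lig$gp1, gp2 = lig$gp2,
    ds = lig$gp1 + 2 * lig$gp2,
    gq = pmin(99, -10 * log10(pmax(1 - maxp, 1e-10))),
    info = info
  )
  attr(out, "provenance") <- "imputed"
  attr(out, "sample_id") <- attr(gl, "sample_id")
  attr(out, "loglik") <- attr(lig, "loglik")
  attr(out, "n_buffer_disagreements") <- attr(lig, "n_buffer_disagreements")
  out
}

#' Filter imputed genotypes on GP and INFO
#'
#' Sets genotypes missing unless the maximum genotype posterior reaches
#' `min_gp` and the site INFO score reaches `min_info`.
#'
#' @param calls imputed call-set tibble from [impute_sample()].
#' @param min_gp,min_info thresholds in \[0, 1\] (defaults 0.99, 0.99).
#' @return The filtered call-set tibble.
#' @export
filter_imputed <- function(calls, min_gp = 0.99, min_info = 0.99) {
  assert_scalar_number(min_gp, "min_gp", min = 0, max = 1)
  assert_scalar_number(min_info, "min_info", min = 0, max = 1)
  maxp <- pmax(calls$gp0, calls$gp1, calls$gp2)
  fail <- maxp < min_gp | calls$info < min_info
  calls$gt[fail] <- NA_integer_
  calls
}

#' Sweep the GP/INFO filtering grid
#'
#' Applies [filter_imputed()] over the full grid of threshold combinations
#' (default the study grid 0.8, 0.85, 0.9, 0.95, 0.99 for both parameters).
#'
#' @param calls imputed call-set tibble.
#' @param gp_grid,info_grid threshold grids.
#' @return Tibble with columns `min_gp`, `min_info`, and a list-column
#'   `calls` of filtered call sets (25 rows with the defaults).
#' @export
filter_sweep <- function(calls, gp_grid = c(0.8, 0.85, 0.9, 0.95, 0.99),
                         info_grid = gp_grid) {
  grid <- tidyr::expand_grid(min_gp = gp_grid, min_info = info_grid)
  grid$calls <- purrr::map2(grid$min_gp, grid$min_info,
                            ~ filter_imputed(calls, .x, .y))
  grid
}
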