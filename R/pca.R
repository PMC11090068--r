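#' Fit a PCA on the reference panel
#'
#' Principal components of the panel's diploid genotypes at a chosen site
#' subset (typically MAF-filtered, transversion-only, LD-pruned). Columns are
#' centered at twice the allele frequency and scaled by `sqrt(p * (1 - p))`;
#' the leading eigenvectors come from the panel only, so test samples can be
#' projected without influencing the axes. Eigenvectors are oriented so the
#' largest-magnitude loading on each axis is positive, making the output
#' deterministic.
#'
#' @param panel a `haplotype_panel`.
#' @param sites optional integer index of panel sites to use (default: all
#'   polymorphic sites).
#' @param n_pcs number of components to keep (default 10).
#' @return A `panel_pca`: list with `site_index`, `center`, `scale`,
#'   `loadings` (sites x PCs), `coords` (panel coordinates tibble),
#'   `sdev` (per-PC standard deviation of panel coordinates), `eigenvalues`.
#' @export
panel_pca <- function(panel, sites = NULL, n_pcs = 10) {
  stopifnot(inherits(panel, "haplotype_panel"))
  geno <- panel_genotypes(panel)
  sites <- sites %||% seq_len(ncol(geno))
  G <- geno[, sites, drop = FALSE]
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  sites <- sites[poly]
  p <- p[poly]
  n_pcs <- min(n_pcs, nrow(G) - 1L, ncol(G))

  center <- 2 * p
  scl <- sqrt(p * (1 - p))
  X <- sweep(sweep(G, 2, center), 2, scl, "/")

  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  V <- sv$v
  # deterministic sign: largest-|loading| positive per axis
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  coords <- X %*% V
  colnames(coords) <- paste0("PC", seq_len(n_pcs))

  structure(
    list(
      site_index = sites,
      sites = panel$sites[sites, c("chrom", "pos", "ref", "alt")],
      center = center, scale = scl, loadings = V,
      coords = tibble(id = panel$individuals$id,
                      ancestry = panel$individuals$ancestry) |>
        dplyr::bind_cols(as_tibble(coords)),
      sdev = unname(apply(coords, 2, stats::sd)),
      eigenvalues = (sv$d[seq_len(n_pcs)]^2) / (nrow(G) - 1)
    ),
    class = "panel_pca"
  )
}

# individuals x sites diploid genotypes from the phased haplotypes
panel_genotypes <- function(panel) {
  h <- panel$haplotypes
  g <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  rownames(g) <- panel$individuals$id
  g
}

#' Project samples onto panel principal components
#'
#' Least-squares projection in the smartpca `lsqproject` style: a sample's
#' coordinates solve the normal equations restricted to its non-missing
#' sites, so missingness does not shrink the projection toward the origin.
#'
#' @param model a `panel_pca`.
#' @param calls a call-set tibble (or list of them) on the panel site index.
#' @return Tibble: `sample_id`, `n_sites_used`, `PC1`..`PCk`.
#' @export
pca_project <- function(model, calls) {
  stopifnot(inherits(model, "panel_pca"))
  if (is.data.frame(calls)) calls <- list(calls)
  purrr::map_dfr(calls, function(cs) {
    gt <- cs$gt[match(model$site_index, cs$site_index)]
    obs <- !is.na(gt)
    if (sum(obs) < 10) {
      abort("sample has fewer than 10 non-missing sites on the PCA site set")
    }
    x <- (gt[obs] - model$center[obs]) / model$scale[obs]
    V <- model$loadings[obs, , drop = FALSE]
    beta <- solve(crossprod(V), crossprod(V, x))
    out <- tibble(sample_id = attr(cs, "sample_id") %||% NA_character_,
                  n_sites_used = sum(obs))
    coord <- as.numeric(beta)
    names(coord) <- paste0("PC", seq_along(coord))
    dplyr::bind_cols(out, as_tibble(as.list(coord)))
  })
}

#' Per-PC displacement between two projections
#'
#' Compares the projected coordinates of the same samples computed from two
#' call sets (typically high-quality vs imputed genotypes):
#' `|coord_hq - coord_other| / sd(panel coordinates on that PC)`.
#'
#' @param proj_hq,proj_other projection tibbles from [pca_project()] on the
#'   same `panel_pca` model, with matching samples in matching order.
#' @param model the shared `panel_pca`.
#' @param n_pcs number of components to report (default 10).
#' @return Tibble: `sample_id`, `pc`, `displacement`.
#' @export
pc_displacement <- function(proj_hq, proj_other, model, n_pcs = 10) {
  stopifnot(inherits(model, "panel_pca"))
  pcs <- paste0("PC", seq_len(min(n_pcs, length(model$sdev))))
  if (!all(pcs %in% names(proj_hq)) || !all(pcs %in% names(proj_other))) {
    abort("projections carry fewer components than requested")
  }
  if (nrow(proj_hq) != nrow(proj_other)) {
    abort("projections must contain the same samples")
  }
  purrr::map_dfr(seq_along(pcs), function(k) {
    tibble(
      sample_id = proj_hq$sample_id,
      pc = pcs[k],
      displacement = abs(proj_hq[[pcs[k]]] - proj_other[[pcs[k]]]) /
        model$sdev[k]
    )
  }) |>
    arrange(.data$sample_id)
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("<panel_pca> %d individuals, %d sites, %d components\n",
              nrow(x$coords), length(x$site_index), ncol(x$loadings)))
  invisible(x)
}

#' @method tidy panel_pca
#' @export
tidy.panel_pca <- function(x, ...) {
  x$coords |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "pc",
                        values_to = "coord")
}

#' @method glance panel_pca
#' @export
glance.panel_pca <- function(x, ...) {
  tibble(
    n_individuals = nrow(x$coords),
    n_sites = length(x$site_index),
    n_pcs = ncol(x$loadings),
    var_explained_pc1 = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}
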