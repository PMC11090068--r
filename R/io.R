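#' Write a haplotype panel as a phased VCF
#'
#' Biallelic SNPs with phased `GT` (`|` separator), `INFO/AF` carrying the
#' panel alternate-allele frequency and `INFO/CPG` flagging CpG sites;
#' `##contig` header lines carry chromosome lengths so the panel can be
#' reconstructed.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  n_ind <- nrow(panel$individuals)
  h <- panel$haplotypes
  gt <- matrix(paste0(h[seq(1, 2 * n_ind, 2), ], "|", h[seq(2, 2 * n_ind, 2), ]),
               nrow = n_ind)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=paleoimpute",
    sprintf("##contig=<ID=%s,length=%d>", names(panel$chrom_lengths),
            as.integer(panel$chrom_lengths)),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Panel ALT allele frequency\">",
    "##INFO=<ID=CPG,Number=0,Type=Flag,Description=\"Site is in CpG context\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals$id), collapse = "\t")
  )
  info <- sprintf("AF=%.6g%s", panel$sites$alt_freq,
                  ifelse(panel$sites$cpg, ";CPG", ""))
  body <- paste(panel$sites$chrom, panel$sites$pos, ".", panel$sites$ref,
                panel$sites$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a phased panel VCF written by [write_panel_vcf()]
#'
#' @param path path to the VCF.
#' @param individuals optional tibble (`id`, `ancestry`) restoring ancestry
#'   labels; defaults to a single `unknown` group.
#' @return A `haplotype_panel` (without founder bookkeeping).
#' @export
read_panel_vcf <- function(path, individuals = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  ids <- colnames(gt)

  contig <- grep("^##contig", v@meta, value = TRUE)
  chrom <- sub('.*ID=([^,>]+).*', "\\1", contig)
  len <- as.numeric(sub(".*length=([0-9]+).*", "\\1", contig))
  chrom_lengths <- setNames(len, chrom)

  hap1 <- apply(gt, 2, function(x) as.integer(substr(x, 1, 1)))
  hap2 <- apply(gt, 2, function(x) as.integer(substr(x, 3, 3)))
  n_sites <- nrow(gt)
  haplotypes <- matrix(0L, nrow = 2 * length(ids), ncol = n_sites)
  haplotypes[seq(1, 2 * length(ids), 2), ] <- t(hap1)
  haplotypes[seq(2, 2 * length(ids), 2), ] <- t(hap2)
  rownames(haplotypes) <- paste0(rep(ids, each = 2), "_h", rep(1:2, length(ids)))

  sites <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    cpg = grepl("(^|;)CPG(;|$)", fix$INFO),
    alt_freq = colMeans(haplotypes)
  )
  individuals <- individuals %||% tibble(id = ids, ancestry = "unknown")

  structure(
    list(sites = sites, haplotypes = haplotypes, individuals = individuals,
         chrom_lengths = chrom_lengths, founders = NULL, founder_sets = NULL,
         site_freq = NULL, switch_rate = NA_real_),
    class = "haplotype_panel"
  )
}

#' Write a call set as a single-sample VCF
#'
#' Emits whichever of `GT`, `GP`, `DS`, `DP`, `GQ` the call set carries, plus
#' `INFO_SCORE` in INFO when present. Genotypes are unphased (`/`).
#'
#' @param calls a call-set tibble.
#' @param path output path (plain-text `.vcf`).
#' @param sample_id column header for the sample (defaults to the call set's
#'   `sample_id` attribute).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_id = NULL) {
  sample_id <- sample_id %||% attr(calls, "sample_id") %||% "sample"
  gt_str <- dplyr::case_when(
    is.na(calls$gt) ~ "./.",
    calls$gt == 0L ~ "0/0",
    calls$gt == 1L ~ "0/1",
    TRUE ~ "1/1"
  )
  fmt_fields <- "GT"
  sample_col <- gt_str
  if (all(c("gp0", "gp1", "gp2") %in% names(calls))) {
    fmt_fields <- c(fmt_fields, "GP", "DS")
    gp <- sprintf("%.4f,%.4f,%.4f", calls$gp0, calls$gp1, calls$gp2)
    ds <- sprintf("%.4f", calls$gp1 + 2 * calls$gp2)
    sample_col <- paste(sample_col, gp, ds, sep = ":")
  }
  if ("dp" %in% names(calls)) {
    fmt_fields <- c(fmt_fields, "DP")
    sample_col <- paste(sample_col, calls$dp, sep = ":")
  }
  if ("gq" %in% names(calls)) {
    fmt_fields <- c(fmt_fields, "GQ")
    sample_col <- paste(sample_col, round(calls$gq), sep = ":")
  }
  info <- if ("info" %in% names(calls)) {
    sprintf("INFO_SCORE=%.6f", calls$info)
  } else "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=paleoimpute",
    sprintf("##paleoimpute_provenance=%s", attr(calls, "provenance") %||% "unknown"),
    "##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                "PASS", info, paste(fmt_fields, collapse = ":"),
                sample_col, sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample call VCF written by [write_calls_vcf()]
#'
#' @param path path to the VCF.
#' @return A call-set tibble (`gt` NA where `./.`; `gp0..2`, `ds`, `dp`,
#'   `gq`, `info` when present).
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_str <- as.character(vcfR::extract.gt(v)[, 1])
  gt <- dplyr::case_when(
    is.na(gt_str) | gt_str %in% c("./.", ".") ~ NA_integer_,
    gt_str %in% c("0/0", "0|0") ~ 0L,
    gt_str %in% c("0/1", "1/0", "0|1", "1|0") ~ 1L,
    TRUE ~ 2L
  )
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    site_index = seq_along(gt_str), gt = gt
  )
  fmt <- strsplit(v@gt[1, 1], ":")[[1]]
  if ("GP" %in% fmt) {
    gp <- vcfR::extract.gt(v, element = "GP")[, 1]
    gpm <- do.call(rbind, lapply(strsplit(unname(gp), ","), as.numeric))
    out$gp0 <- gpm[, 1]; out$gp1 <- gpm[, 2]; out$gp2 <- gpm[, 3]
    out$ds <- out$gp1 + 2 * out$gp2
  }
  if ("DP" %in% fmt) {
    out$dp <- as.integer(vcfR::extract.gt(v, element = "DP")[, 1])
  }
  if ("GQ" %in% fmt) {
    out$gq <- as.numeric(vcfR::extract.gt(v, element = "GQ")[, 1])
  }
  info_str <- fix$INFO
  if (any(grepl("INFO_SCORE=", info_str))) {
    out$info <- as.numeric(sub(".*INFO_SCORE=([0-9.eE+-]+).*", "\\1", info_str))
  }
  prov <- grep("^##paleoimpute_provenance=", v@meta, value = TRUE)
  if (length(prov)) {
    attr(out, "provenance") <- sub("^##paleoimpute_provenance=", "", prov[1])
  }
  attr(out, "sample_id") <- colnames(v@gt)[2]
  out
}

#' Write regions as BED
#' @param regions tibble (`chrom`, `start`, `end`, extra stat columns kept).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  readr::write_tsv(regions, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of regions (0-based half-open)
#' @param path input path.
#' @param extra_names names for columns beyond chrom/start/end.
#' @return Region tibble.
#' @export
read_regions_bed <- function(path, extra_names = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names) && ncol(df) >= 3 + length(extra_names)) {
    names(df)[seq_along(extra_names) + 3] <- extra_names
  }
  df
}

#' Write a read stack as a pileup-style TSV
#' @param stack read-stack tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(stack, path) {
  readr::write_tsv(
    stack[, c("chrom", "pos", "base", "base_qual", "map_qual", "dist_end")],
    path
  )
  invisible(path)
}
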