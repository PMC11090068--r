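# internal helpers shared across modules

# run `expr` under `seed` when given, without disturbing the caller's RNG
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, expr)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s", name, format(min)))
  }
  if (x > max) abort(sprintf("`%s` must be <= %s", name, format(max)))
  invisible(x)
}

is_transition_pair <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

# genotype class labels used throughout the evaluation modules
gt_class <- function(gt) {
  out <- rep(NA_character_, length(gt))
  out[!is.na(gt) & gt == 0L] <- "hom_ref"
  out[!is.na(gt) & gt == 1L] <- "het"
  out[!is.na(gt) & gt == 2L] <- "hom_alt"
  out[is.na(gt)] <- "missing"
  out
}

# tibble(chrom, start, end) [0-based half-open] -> GRanges (1-based closed)
regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

gr_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# point ranges for 1-based site positions
sites_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}
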