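# genotype likelihoods, validation calls, damage masking, pseudohaploid calls

# helper: minimal panel with chosen ref/alt and a constructed read stack
manual_panel <- function(ref, alt, pos = seq_along(ref) * 100L) {
  n <- length(ref)
  p <- tiny_panel(n_sites = n, len = max(pos) + 100, seed = 1)
  p$sites$ref <- ref
  p$sites$alt <- alt
  p$sites$pos <- pos
  p
}

manual_stack <- function(panel, site_index, base, base_qual = 30L,
                         map_qual = 37L, dist_end = 20L) {
  out <- tibble::tibble(
    site_index = site_index,
    chrom = panel$sites$chrom[site_index],
    pos = panel$sites$pos[site_index],
    base = base,
    base_qual = base_qual, map_qual = map_qual,
    dist_end = dist_end, hap = 1L
  )
  attr(out, "n_sites") <- nrow(panel$sites)
  out
}

test_that("pileup likelihoods match the closed-form binomial model", {
  p <- manual_panel(ref = c("A", "A", "A"), alt = c("C", "C", "C"))
  st <- manual_stack(p, site_index = c(rep(1L, 4), rep(3L, 10)),
                     base = c(rep("A", 4), rep("A", 5), rep("C", 5)),
                     base_qual = c(rep(30L, 4), rep(40L, 10)))
  gl <- pileup_to_likelihoods(st, p)

  # 4 ref reads at Q30: L0/L2 = ((1-e)/(e/3))^4
  e <- 1e-3
  expect_equal(gl$l0[1] / gl$l2[1], ((1 - e) / (e / 3))^4, tolerance = 1e-9)
  expect_equal(which.max(gl[1, c("l0", "l1", "l2")]), c(l0 = 1L))
  # unobserved site: uniform triple, depth 0
  expect_equal(unlist(gl[2, c("l0", "l1", "l2")]),
               c(l0 = 1, l1 = 1, l2 = 1) / 3)
  expect_equal(gl$dp[2], 0L)
  # balanced 5+5 at Q40: het argmax
  expect_equal(which.max(gl[3, c("l0", "l1", "l2")]), c(l1 = 2L))
  # normalisation invariant
  expect_true(all(abs(gl$l0 + gl$l1 + gl$l2 - 1) < 1e-9))
  expect_equal(gl$dp, c(4L, 0L, 10L))
  expect_equal(gl$ad_ref, c(4L, 0L, 5L))
  expect_equal(gl$ad_alt, c(0L, 0L, 5L))
})

test_that("low-quality reads are excluded from likelihoods", {
  p <- manual_panel(ref = "A", alt = "C")
  st <- manual_stack(p, rep(1L, 3), base = c("A", "A", "C"),
                     base_qual = c(35L, 20L, 35L), map_qual = c(37L, 37L, 10L))
  gl <- pileup_to_likelihoods(st, p)
  expect_equal(gl$dp, 1L)  # only the first read passes both thresholds
})

test_that("validation calling applies GQ, depth and allele-balance rules", {
  p <- manual_panel(ref = rep("A", 4), alt = rep("C", 4))
  st <- manual_stack(
    p,
    site_index = c(rep(1L, 10), rep(2L, 7), rep(3L, 20), rep(4L, 12)),
    base = c(rep("A", 9), "C",                 # site 1: het balance 0.10
             rep("A", 7),                      # site 2: depth 7 < 8
             rep("A", 20),                     # site 3: hom-ref, depth 20
             rep(c("A", "C"), 6)),             # site 4: clean het
    base_qual = 40L
  )
  calls <- call_validation_genotypes(pileup_to_likelihoods(st, p),
                                     mean_cov = 18)
  expect_true(is.na(calls$gt[1]))   # balance 1/10 < 0.40
  expect_true(is.na(calls$gt[2]))   # depth below 8
  expect_equal(calls$gt[3], 0L)     # depth 20 <= 3 * 18
  expect_equal(calls$gt[4], 1L)
  expect_equal(attr(calls, "provenance"), "validation")
})

test_that("validation calls equal truth in the high-coverage noise-free limit", {
  p <- tiny_panel(seed = 61)
  t1 <- sim_individual(p, "in_panel", seed = 62)
  clean <- damage_model(delta_max = 0, floor = 0, base_error = 1e-6)
  st <- sim_reads(t1, p, mean_coverage = 30, damage = clean, seed = 63)
  calls <- call_validation_genotypes(pileup_to_likelihoods(st, p),
                                     mean_cov = 30)
  ok <- !is.na(calls$gt)
  expect_gt(mean(ok), 0.9)
  expect_identical(calls$gt[ok], t1$gt[ok])
})

test_that("damage mask hits exactly the damage-inflatable genotype/site pairs", {
  p <- manual_panel(ref = c("T", "C", "A", "G", "A"),
                    alt = c("C", "T", "G", "A", "C"))
  calls <- truth_calls(sim_individual(p, "in_panel", seed = 2), p)
  calls$gt <- c(1L, 1L, 0L, 2L, 1L)

  lit <- damage_mask(calls, mode = "paper_literal")
  expect_true(is.na(lit$gt[1]))     # T/C het
  expect_equal(lit$gt[2], 1L)       # C/T het survives the literal rule
  expect_true(is.na(lit$gt[3]))     # A/G hom-ref
  expect_equal(lit$gt[4], 2L)       # G/A hom-alt not in literal rule
  expect_equal(lit$gt[5], 1L)       # transversion never masked

  both <- damage_mask(calls, mode = "both_orientations")
  expect_true(is.na(both$gt[1]))
  expect_true(is.na(both$gt[2]))    # C/T het masked in the symmetric mode
  expect_true(is.na(both$gt[4]))    # G/A hom-alt masked
  expect_equal(both$gt[5], 1L)
  expect_equal(unname(attr(both, "mask_counts")), c(2L, 2L))

  expect_error(damage_mask(calls, mode = "sideways"))
})

test_that("damage mask on likelihoods uniformises transition-site triples", {
  p <- manual_panel(ref = c("T", "C", "A"), alt = c("C", "T", "C"))
  st <- manual_stack(p, c(1L, 2L, 3L), base = c("T", "C", "A"),
                     base_qual = 40L)
  gl <- pileup_to_likelihoods(st, p)
  m <- damage_mask(gl, mode = "both_orientations")
  expect_equal(unlist(m[1, c("l0", "l1", "l2")]), rep(1 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(unlist(m[2, c("l0", "l1", "l2")]), rep(1 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(m$l0[3], gl$l0[3])  # transversion untouched
  lit <- damage_mask(gl, mode = "paper_literal")
  expect_equal(lit$l0[2], gl$l0[2])  # C/T site untouched by the literal rule
})

test_that("pseudohaploid calls are reproducible, panel-consistent and transversion-only", {
  p <- manual_panel(ref = c("A", "A", "C", "A"),
                    alt = c("C", "C", "T", "G"))
  st <- manual_stack(
    p,
    site_index = c(1L, 1L, 2L, 3L, 4L),
    base = c("A", "C", "G", "C", "A"),   # site 2: G matches neither allele
    dist_end = c(20L, 20L, 20L, 20L, 20L)
  )
  c1 <- pseudohaploid_call(st, p, seed = 5)
  expect_identical(c1, pseudohaploid_call(st, p, seed = 5))
  expect_true(c1$gt[1] %in% c(0L, 2L))
  expect_true(is.na(c1$gt[2]))   # inconsistent with panel alleles
  expect_true(is.na(c1$gt[3]))   # C/T transition excluded
  expect_true(is.na(c1$gt[4]))   # A/G transition excluded
  counts <- attr(c1, "drop_counts")
  expect_equal(unname(counts["inconsistent"]), 1L)
  expect_equal(unname(counts["transition"]), 2L)

  # end-trimming: reads within 5 bp of an end never contribute
  st2 <- manual_stack(p, 1L, base = "C", dist_end = 3L)
  c2 <- pseudohaploid_call(st2, p, seed = 1)
  expect_true(is.na(c2$gt[1]))
})

test_that("pseudohaploid allele frequencies converge to the population frequency", {
  p <- sim_panel(n_sites = 800, chrom_lengths = c(chr1 = 4e5), seed = 71)
  clean <- damage_model(delta_max = 0, floor = 0, base_error = 0)
  alt_count <- integer(nrow(p$sites)); n_called <- integer(nrow(p$sites))
  for (s in 1:30) {
    t1 <- sim_individual(p, "in_panel", seed = 700 + s)
    st <- sim_reads(t1, p, mean_coverage = 1, damage = clean, seed = 800 + s)
    ph <- pseudohaploid_call(st, p, transversions_only = FALSE, seed = 900 + s)
    ok <- !is.na(ph$gt)
    alt_count[ok] <- alt_count[ok] + as.integer(ph$gt[ok] == 2L)
    n_called[ok] <- n_called[ok] + 1L
  }
  # pooled over sites: empirical alt fraction ~ mean panel-pool frequency
  use <- n_called > 0
  emp <- sum(alt_count[use]) / sum(n_called[use])
  # expected frequency averaged over the sampled ancestry's founder pool
  pool <- p$founder_sets[[sim_individual(p, "in_panel", seed = 701)$ancestry]]
  exp_freq <- mean(colMeans(p$founders[pool, , drop = FALSE]))
  se <- sqrt(exp_freq * (1 - exp_freq) / sum(n_called[use]))
  expect_lt(abs(emp - exp_freq), 4 * se + 0.02)
})
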