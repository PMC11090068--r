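# chunk planning, the copying-model forward-backward, ligation, INFO, filters

test_that("chunk plans tile chromosomes with clipped buffers", {
  plan <- plan_chunks(c(chr1 = 5e6))
  expect_equal(plan$core_start, c(0, 2e6, 4e6))
  expect_equal(plan$core_end, c(2e6, 4e6, 5e6))
  expect_equal(plan$buf_start, c(0, 1.8e6, 3.8e6))
  expect_equal(plan$buf_end, c(2.2e6, 4.2e6, 5e6))

  p1 <- plan_chunks(c(chr1 = 1e6))
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$core_start, p1$core_end, p1$buf_start, p1$buf_end),
               c(0, 1e6, 0, 1e6))

  p10 <- plan_chunks(c(chr1 = 1e7))
  expect_equal(nrow(p10), 5L)
  expect_equal(sum(p10$core_end - p10$core_start), 1e7)  # cores tile exactly

  expect_error(plan_chunks(c(chr1 = 1e6), chunk_bp = 1e5, buffer_bp = 1e5),
               "buffer")
  expect_error(plan_chunks(c(chr1 = -5)), "positive")
})

test_that("forward-backward matches the dense-chain oracle (K=6, S=8)", {
  for (seed in 1:4) {
    inst <- random_hmm_instance(K = 6, S = 8, seed = seed)
    got <- ls_forward_backward(inst$gl, inst$haps, inst$pos, eps = 1e-3)
    want <- ls_fb_oracle_dense(inst$gl, inst$haps, inst$pos,
                               rho = 4 * 20000 * 1e-8, eps = 1e-3)
    expect_lt(max(abs(got$gp - want)), 1e-8)
    expect_true(all(abs(rowSums(got$gp) - 1) < 1e-6))
  }
})

test_that("forward-backward matches exhaustive path enumeration (K=3, S=4)", {
  inst <- random_hmm_instance(K = 3, S = 4, seed = 99)
  got <- ls_forward_backward(inst$gl, inst$haps, inst$pos, eps = 1e-2)
  want <- ls_fb_oracle_enum(inst$gl, inst$haps, inst$pos,
                            rho = 4 * 20000 * 1e-8, eps = 1e-2)
  expect_lt(max(abs(got$gp - want)), 1e-8)
})

test_that("a degenerate identical panel pins the posterior to its genotype", {
  S <- 6
  hap <- matrix(rep(c(0L, 1L, 1L, 0L, 1L, 0L), each = 4), nrow = 4)
  gl <- matrix(1 / 3, S, 3)
  res <- ls_forward_backward(gl, hap, pos = (1:S) * 1000, eps = 0)
  want_g <- 2L * hap[1, ]  # both copied haplotypes identical
  expect_equal(res$gp[cbind(1:S, want_g + 1L)], rep(1, S))
  expect_error(ls_forward_backward(gl, hap[1, , drop = FALSE], (1:S) * 1000),
               "2 haplotypes")
})

test_that("ligation keeps core copies and is the identity for one chunk", {
  p <- tiny_panel(n_sites = 300, len = 3e6, seed = 81)
  t1 <- sim_individual(p, "in_panel", seed = 82)
  st <- sim_reads(t1, p, mean_coverage = 1, seed = 83)
  gl <- pileup_to_likelihoods(st, p)

  whole <- impute_chunk(gl, p, "chr1", 0, 3e6)
  plan1 <- tibble::tibble(chrom = "chr1", core_start = 0, core_end = 3e6,
                          buf_start = 0, buf_end = 3e6)
  lig1 <- ligate(list(whole), plan1, p)
  expect_equal(as.matrix(lig1[, c("gp0", "gp1", "gp2")]),
               as.matrix(whole[, c("gp0", "gp1", "gp2")]))

  # two buffered chunks: a site in chunk 2's core takes chunk 2's value
  plan2 <- plan_chunks(c(chr1 = 3e6), chunk_bp = 2e6, buffer_bp = 2e5)
  chunks <- lapply(seq_len(nrow(plan2)), function(i) {
    impute_chunk(gl, p, "chr1", plan2$buf_start[i], plan2$buf_end[i])
  })
  lig2 <- ligate(chunks, plan2, p)
  in_core2 <- p$sites$pos > 2e6
  idx2 <- match(which(in_core2), chunks[[2]]$site_index)
  expect_equal(lig2$gp1[in_core2], chunks[[2]]$gp1[idx2])
  expect_true(is.numeric(attr(lig2, "n_buffer_disagreements")))
})

test_that("INFO score spans the certainty range with closed-form cases", {
  expect_equal(info_score(c(0, 1, 0), p = 0.3), 1)            # certain
  hw <- c(0.25, 0.5, 0.25)                                    # HW prior, p=0.5
  expect_equal(info_score(hw, p = 0.5), 0)
  two <- rbind(c(0, 1, 0), c(0.5, 0, 0.5))                    # vars 0 and 1
  expect_equal(info_score(rbind(c(0, 1, 0), c(0.25, 0.5, 0.25)), p = 0.5),
               1 - 0.25 / 0.5)
  expect_equal(info_score(c(1, 0, 0), p = 0), 1)              # monomorphic
})

test_that("GP/INFO filtering is monotone and the sweep covers the grid", {
  p <- tiny_panel(n_sites = 200, seed = 84)
  t1 <- sim_individual(p, "in_panel", seed = 85)
  st <- sim_reads(t1, p, mean_coverage = 0.5, seed = 86)
  imp <- impute_sample(pileup_to_likelihoods(st, p), p)

  expect_identical(filter_imputed(imp, 0, 0)$gt, imp$gt)
  n_called <- function(x) sum(!is.na(x$gt))
  grid <- c(0, 0.5, 0.8, 0.9, 0.95, 0.99, 1)
  by_gp <- sapply(grid, function(g) n_called(filter_imputed(imp, g, 0)))
  by_info <- sapply(grid, function(g) n_called(filter_imputed(imp, 0, g)))
  expect_true(all(diff(by_gp) <= 0))
  expect_true(all(diff(by_info) <= 0))

  one <- filter_imputed(imp, 0.99, 0.99)
  expect_true(all(is.na(one$gt[pmax(imp$gp0, imp$gp1, imp$gp2) < 0.99])))
  expect_error(filter_imputed(imp, 1.5, 0), "min_gp")

  sw <- filter_sweep(imp)
  expect_equal(nrow(sw), 25L)
  expect_equal(nrow(dplyr::distinct(sw[, c("min_gp", "min_info")])), 25L)
})

test_that("whole-chromosome and chunked imputation agree at core interiors", {
  p <- sim_panel(n_sites = 4000, chrom_lengths = c(chr1 = 1e7), seed = 87)
  t1 <- sim_individual(p, "in_panel", seed = 88)
  st <- sim_reads(t1, p, mean_coverage = 4, seed = 89)
  gl <- pileup_to_likelihoods(st, p)
  whole <- impute_sample(gl, p, chunk_bp = 1e7, buffer_bp = 2e5)
  edges <- seq(0, 1e7, by = 2e6)
  dist_edge <- sapply(p$sites$pos, function(x) min(abs(x - edges)))
  interior <- dist_edge > 1e5
  expect_gt(sum(interior), 1000)

  # default 200 kb buffers: chain memory past a buffer is exp(-rho*buf/K)
  # ~1.5%, so a handful of ambiguous sites can deviate by a few 1e-3;
  # bound the bulk at 1e-3 and the worst case at 1e-2
  chunked <- impute_sample(gl, p, chunk_bp = 2e6, buffer_bp = 2e5)
  d <- abs(as.matrix(whole[interior, c("gp0", "gp1", "gp2")]) -
             as.matrix(chunked[interior, c("gp0", "gp1", "gp2")]))
  expect_lt(quantile(d, 0.999), 1e-3)
  expect_lt(max(d), 1e-2)

  # doubling the buffer takes the worst case below 1e-3 outright
  chunked4 <- impute_sample(gl, p, chunk_bp = 2e6, buffer_bp = 4e5)
  d4 <- abs(as.matrix(whole[interior, c("gp0", "gp1", "gp2")]) -
              as.matrix(chunked4[interior, c("gp0", "gp1", "gp2")]))
  expect_lt(max(d4), 1e-3)
})

test_that("posteriors are calibrated when the genome copies panel haplotypes", {
  # a test genome whose haplotypes are literal panel members is the copying
  # model's ideal case: confident calls at uncovered sites must be correct
  p <- sim_panel(seed = 101)
  t1 <- structure(list(
    id = "copy", scenario = "in_panel", ancestry = "x",
    hap1 = p$haplotypes[5, ], hap2 = p$haplotypes[20, ],
    gt = as.integer(p$haplotypes[5, ] + p$haplotypes[20, ])
  ), class = "truth_genome")
  clean <- damage_model(delta_max = 0, floor = 0, base_error = 0)
  st <- sim_reads(t1, p, mean_coverage = 0.5, damage = clean, seed = 301)
  gl <- pileup_to_likelihoods(st, p)
  imp <- impute_sample(gl, p)
  maxp <- pmax(imp$gp0, imp$gp1, imp$gp2)
  sel <- maxp >= 0.99 & gl$dp == 0
  expect_gt(sum(sel), 1000)
  expect_equal(mean(imp$gt[sel] == t1$gt[sel]), 1)
})

test_that("imputed call sets carry coherent GP, dosage and GQ fields", {
  p <- tiny_panel(n_sites = 150, seed = 90)
  t1 <- sim_individual(p, "in_panel", seed = 91)
  st <- sim_reads(t1, p, mean_coverage = 2, seed = 92)
  imp <- impute_sample(pileup_to_likelihoods(st, p), p)
  expect_true(all(abs(imp$gp0 + imp$gp1 + imp$gp2 - 1) < 1e-6))
  expect_equal(imp$ds, imp$gp1 + 2 * imp$gp2, tolerance = 1e-9)
  expect_true(all(imp$info >= 0 & imp$info <= 1))
  expect_equal(attr(imp, "provenance"), "imputed")
})
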