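# Independent oracles used across the suite.  These deliberately share no
# code with the package's C++ forward-backward or its sweep implementations.

# small default panel for fast tests
tiny_panel <- function(n_sites = 400, len = 2e5, seed = 1, ...) {
  sim_panel(n_sites = n_sites, chrom_lengths = c(chr1 = len), seed = seed, ...)
}

# ---- Li-Stephens diploid oracles -------------------------------------------

# emission table over the K^2 ordered-pair states for one site
oracle_emission <- function(gl_row, alleles, eps) {
  K <- length(alleles)
  p <- ifelse(alleles == 1L, 1 - eps, eps)
  E <- matrix(0, K, K)
  W <- array(0, c(K, K, 3))
  for (j in 1:K) {
    for (k in 1:K) {
      w <- c(gl_row[1] * (1 - p[j]) * (1 - p[k]),
             gl_row[2] * (p[j] * (1 - p[k]) + (1 - p[j]) * p[k]),
             gl_row[3] * p[j] * p[k])
      E[j, k] <- sum(w)
      W[j, k, ] <- w
    }
  }
  list(E = E, W = W)
}

# dense-chain oracle: explicit K^2 x K^2 transition matrices, long-double
# vector algebra, no factorisation trick
ls_fb_oracle_dense <- function(gl, haps, pos, rho, eps) {
  K <- nrow(haps); S <- nrow(gl); KK <- K * K
  q <- c(1, exp(-rho * diff(pos) / K))
  gp <- matrix(0, S, 3)

  emis <- lapply(seq_len(S), function(t) oracle_emission(gl[t, ], haps[, t], eps))
  trans <- lapply(seq_len(S), function(t) {
    T1 <- q[t] * diag(K) + (1 - q[t]) / K
    kronecker(T1, T1)
  })

  # forward (unscaled in log-safe way: renormalise and track log)
  alpha <- vector("list", S)
  a <- rep(1 / KK, KK) * as.vector(emis[[1]]$E)
  alpha[[1]] <- a / sum(a)
  for (t in 2:S) {
    a <- as.vector(t(trans[[t]]) %*% alpha[[t - 1]]) * as.vector(emis[[t]]$E)
    alpha[[t]] <- a / sum(a)
  }
  beta <- rep(1, KK)
  for (t in S:1) {
    post <- alpha[[t]] * beta
    post <- post / sum(post)
    w <- emis[[t]]$W
    e <- as.vector(emis[[t]]$E)
    for (g in 1:3) {
      wg <- as.vector(w[, , g])
      gp[t, g] <- sum(ifelse(e > 0, post * wg / e, 0))
    }
    gp[t, ] <- gp[t, ] / sum(gp[t, ])
    if (t > 1) {
      b <- trans[[t]] %*% (as.vector(emis[[t]]$E) * beta)
      beta <- as.vector(b) / sum(b)
    }
  }
  gp
}

# exhaustive path-enumeration oracle; feasible only for tiny K and S
ls_fb_oracle_enum <- function(gl, haps, pos, rho, eps) {
  K <- nrow(haps); S <- nrow(gl); KK <- K * K
  q <- c(1, exp(-rho * diff(pos) / K))
  emis <- lapply(seq_len(S), function(t) oracle_emission(gl[t, ], haps[, t], eps))
  trans1 <- lapply(seq_len(S), function(t) q[t] * diag(K) + (1 - q[t]) / K)

  paths <- as.matrix(expand.grid(rep(list(seq_len(KK)), S)))
  jk <- cbind((paths - 1) %% K + 1, (paths - 1) %/% K + 1)  # j then k per site
  prob <- rep(1 / KK, nrow(paths))
  for (t in seq_len(S)) {
    j <- jk[, t]; k <- jk[, S + t]
    if (t > 1) {
      jp <- jk[, t - 1]; kp <- jk[, S + t - 1]
      prob <- prob * trans1[[t]][cbind(jp, j)] * trans1[[t]][cbind(kp, k)]
    }
    prob <- prob * emis[[t]]$E[cbind(j, k)]
  }
  gp <- matrix(0, S, 3)
  for (t in seq_len(S)) {
    j <- jk[, t]; k <- jk[, S + t]
    e <- emis[[t]]$E[cbind(j, k)]
    for (g in 1:3) {
      w <- emis[[t]]$W[cbind(j, k, g)]
      gp[t, g] <- sum(ifelse(e > 0, prob * w / e, 0))
    }
    gp[t, ] <- gp[t, ] / sum(gp[t, ])
  }
  gp
}

random_hmm_instance <- function(K, S, seed) {
  withr::with_seed(seed, {
    list(
      gl = {
        m <- matrix(stats::runif(S * 3), S, 3)
        m / rowSums(m)
      },
      haps = matrix(stats::rbinom(K * S, 1, 0.5), K, S),
      pos = sort(sample.int(S * 2000, S))
    )
  })
}

# ---- interval / window oracles ---------------------------------------------

# brute-force per-window recount, one window at a time
window_recount_oracle <- function(truth, called, panel, windows) {
  sapply(seq_len(nrow(windows)), function(i) {
    idx <- which(panel$sites$chrom == windows$chrom[i] &
                   panel$sites$pos - 1 >= windows$start[i] &
                   panel$sites$pos - 1 < windows$end[i])
    tg <- truth$gt[idx]; cg <- called$gt[idx]
    both <- !is.na(tg) & !is.na(cg)
    c(acc = if (sum(both) > 0) sum(tg[both] == cg[both]) / sum(both) else NaN,
      rec = if (length(idx) > 0) sum(both) / length(idx) else NaN)
  })
}

# hamming distance between two haplotype rows
hamming <- function(a, b) sum(a != b)
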