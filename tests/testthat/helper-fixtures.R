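# Shared fixtures and independent oracles, all built in code.

# Gaussian two-class expression with optional planted mean shifts, returned
# as a standardized selector input. Groups sized like the discovery
# contrast (PDND 37 vs PD-MCI 23) unless overridden.
make_planted_input <- function(seed, n1 = 37, n2 = 23, p = 500,
                               n_signal = 0, effect = 1.0) {
  set.seed(seed)
  y <- rep(c(0L, 1L), c(n1, n2))
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  if (n_signal > 0) {
    X[y == 1, seq_len(n_signal)] <- X[y == 1, seq_len(n_signal)] + effect
  }
  colnames(X) <- sprintf("f%03d", seq_len(p))
  standardize(t(X), y)
}

planted_ids <- function(n_signal) sprintf("f%03d", seq_len(n_signal))

# Orthonormal design (X'X = I exactly) for the soft-thresholding closed form.
make_orthonormal_input <- function(seed, n = 24, p = 6) {
  set.seed(seed)
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, Yc = rnorm(n))
}

# Brute-force L1 minimum over a lattice subject to the score-band
# constraint (independent of the LP solver).
lattice_l1_min <- function(X, yc, delta, lim = 2, h = 0.002) {
  b <- drop(crossprod(X, yc))
  M <- crossprod(X)
  g <- seq(-lim, lim, by = h)
  grid <- as.matrix(expand.grid(g, g))
  sc <- abs(sweep(grid %*% M, 2, b))
  feas <- rowSums(sc <= delta + 1e-9) == ncol(X)
  min(rowSums(abs(grid))[feas])
}

# Exact vertex-enumeration oracle for p <= 3: the L1 minimum over the
# polyhedron |b - M beta|_inf <= delta lies at an intersection of p active
# hyperplanes drawn from the 2p band faces and the p coordinate planes.
vertex_l1_min <- function(X, yc, delta) {
  b <- drop(crossprod(X, yc))
  M <- crossprod(X)
  p <- ncol(X)
  planes <- rbind(M, diag(p))                  # rows: band faces, coord planes
  rhs_opts <- lapply(seq_len(nrow(planes)), function(i) {
    if (i <= p) c(b[i] - delta, b[i] + delta) else 0
  })
  best <- Inf
  combos <- utils::combn(nrow(planes), p, simplify = FALSE)
  for (rows in combos) {
    A <- planes[rows, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    rhs_grid <- expand.grid(rhs_opts[rows])
    for (r in seq_len(nrow(rhs_grid))) {
      beta <- solve(A, as.numeric(rhs_grid[r, ]))
      if (max(abs(b - drop(M %*% beta))) <= delta + 1e-8) {
        best <- min(best, sum(abs(beta)))
      }
    }
  }
  best
}

# Hand evaluation of the weighted trimmed mean of M-values (the published
# TMM formula), written independently of edgeR's implementation.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  cpm_q75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(cpm_q75 - mean(cpm_q75)))
  one_factor <- function(obs, refc, nO, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    one_factor(counts[, j], counts[, ref], lib[j], lib[ref])
  }, 1)
  f / exp(mean(log(f)))
}

# Exhaustive pair-counting AUC (ties one half), independent of the rank
# formula used by the implementation.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Small validation design for fast tests.
small_validation <- function(seed = 1, n = 12) {
  validation_design(n_per_group = n, seed = seed)
}
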