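#' Solve the Dantzig selector linear program
#'
#' Computes the L1-minimizing coefficient vector subject to an infinity-norm
#' bound on the correlation of the residual with every feature:
#' \deqn{\min \|\beta\|_1 \quad \mathrm{s.t.} \quad
#'   \|X^\top(y_c - X\beta)\|_\infty \le \delta}
#' where `X` is the standardized expression matrix (samples x features) and
#' `y_c` the centered 0/1 response. The program is solved as a linear program
#' in the split variables \eqn{(\beta, u)} with \eqn{-u \le \beta \le u},
#' using a Mehrotra-style primal-dual interior-point method. The normal
#' equations exploit the rank-\eqn{n} structure of \eqn{X^\top X} (Woodbury
#' identity) so that supersaturated instances (features >> samples) solve in
#' \eqn{O(n^2 p)} per iteration rather than \eqn{O(p^3)}.
#'
#' At \eqn{\delta \ge \max_j |X_j^\top y_c|} the zero vector is feasible and
#' attains the minimal objective 0, so exact zeros are returned without
#' invoking the solver.
#'
#' @param input a `selector_input` from [standardize()], or a list with
#'   elements `X` (n x p matrix) and `Yc` (length-n centered response).
#' @param delta non-negative constraint level.
#' @param tol relative convergence tolerance of the interior-point solver.
#' @param max_iter iteration cap.
#' @return numeric vector of length p (named by feature) with attributes
#'   `iterations` and `converged`.
#' @export
dantzig_solve <- function(input, delta, tol = 1e-9, max_iter = 100L) {
  X <- input$X
  yc <- input$Yc
  stopifnot(is.matrix(X), length(yc) == nrow(X))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single non-negative number")
  b <- drop(crossprod(X, yc))
  p <- ncol(X)
  beta <- if (delta >= max(abs(b))) {
    structure(numeric(p), iterations = 0L, converged = TRUE)
  } else {
    out <- dantzig_ipm(X, b, delta, tol = tol, max_iter = max_iter)
    polish_feasibility(X, yc, b, delta, out)
  }
  names(beta) <- colnames(X)
  beta
}

# Guarantee the score constraint holds: if the solver's iterate overshoots
# the band by a small margin, move minimally along the segment toward the
# minimum-norm least-squares solution (whose score residual is exactly 0);
# each score component is linear in the step, so the smallest sufficient
# step has a closed form. The L1 objective increase is O(violation).
polish_feasibility <- function(X, yc, b, delta, beta) {
  at <- attributes(beta)
  score <- b - drop(crossprod(X, X %*% beta))
  viol <- max(abs(score)) - delta
  if (viol <= 0) return(beta)
  bls <- drop(crossprod(X, solve(tcrossprod(X) +
                                   diag(1e-10, nrow(X)), yc)))
  score_ls <- b - drop(crossprod(X, X %*% bls))   # ~0 by construction
  # need |score + t (score_ls - score)| <= delta for all components
  tmin <- 0
  d <- score_ls - score
  hit <- abs(score) > delta
  tmin <- max(0, (abs(score[hit]) - delta) / pmax(abs(d[hit]), 1e-300))
  tmin <- min(1, max(tmin) * (1 + 1e-9))
  beta <- (1 - tmin) * beta + tmin * bls
  attributes(beta) <- at
  beta
}

# Interior-point core. Constraint rows, with M = X'X and slack s >= 0:
#   [ M  0] (beta,u) <= delta + b
#   [-M  0]          <= delta - b
#   [ I -I]          <= 0
#   [-I -I]          <= 0
# Objective c = (0, 1). All products with M are matrix-free through X.
dantzig_ipm <- function(X, b, delta, tol = 1e-9, max_iter = 100L) {
  n <- nrow(X); p <- ncol(X)
  small <- p <= n || p <= 60L          # dense p x p path cheaper than Woodbury
  M <- if (small) crossprod(X) else NULL

  mv <- function(v) {                  # M %*% v
    if (small) drop(M %*% v) else drop(crossprod(X, X %*% v))
  }

  h <- c(delta + b, delta - b, numeric(p), numeric(p))
  i1 <- seq_len(p); i2 <- p + i1; i3 <- 2L * p + i1; i4 <- 3L * p + i1

  Gx <- function(beta, u) {
    mb <- mv(beta)
    c(mb, -mb, beta - u, -beta - u)
  }
  Gtz <- function(z) {
    zb <- mv(z[i1] - z[i2]) + (z[i3] - z[i4])
    zu <- -(z[i3] + z[i4])
    list(beta = zb, u = zu)
  }

  beta <- numeric(p); u <- rep(1, p)
  s <- pmax(h - Gx(beta, u), 1)
  z <- rep(1, 4L * p)
  m <- 4L * p
  norm_h <- max(1, max(abs(h)))

  accept <- 1e-5                       # fallback tolerance on early numeric stop
  best <- list(beta = beta, gap = Inf)

  for (iter in seq_len(max_iter)) {
    r_prim <- Gx(beta, u) + s - h
    gz <- Gtz(z)
    r_dual_b <- gz$beta
    r_dual_u <- gz$u + 1
    mu <- sum(s * z) / m
    gap <- max(max(abs(r_prim)) / norm_h,
               max(abs(r_dual_b), abs(r_dual_u)) / max(1, max(abs(b))),
               mu / max(1, delta))
    if (gap < best$gap) best <- list(beta = beta, gap = gap)

    if (gap < tol) {
      return(structure(beta, iterations = iter, converged = TRUE))
    }
    # late-stage divergence (ill-conditioned Newton systems past the optimum):
    # the best iterate is already essentially converged, return it
    if (gap > 100 * best$gap && best$gap < accept) break

    # clamp barrier ratios: keeps the Schur complement representable when
    # complementarity pairs become extreme near the optimum
    d <- pmin(pmax(z / s, 1e-12), 1e12)
    d1 <- d[i1]; d2 <- d[i2]; d3 <- d[i3]; d4 <- d[i4]
    E <- d1 + d2
    d34 <- d3 + d4
    Fdiag <- 4 * d3 * d4 / d34

    # Factorization for the beta Schur complement S = M E M + diag(F)
    if (small) {
      S <- M %*% (E * M)
      diag(S) <- diag(S) + Fdiag
      ch <- tryCatch(chol(S), error = function(e) {
        diag(S) <- diag(S) + 1e-12 * max(diag(S))
        chol(S)
      })
      solveS <- function(v) backsolve(ch, forwardsolve(t(ch), v))
    } else {
      # S = diag(F) + X'KX with K = X E X' PSD; factor K = (W/X)'(W/X) so the
      # Woodbury capacitance I + W F^{-1} W' stays symmetric positive definite.
      XE <- X * rep(E, each = n)           # X diag(E), n x p
      K <- tcrossprod(XE, X)               # X E X', n x n
      eK <- eigen(K, symmetric = TRUE)
      ev <- pmax(eK$values, 0)
      W <- (sqrt(ev) * t(eK$vectors)) %*% X      # n x p, W'W = X'KX
      WF <- W * rep(1 / Fdiag, each = n)
      A <- diag(n) + tcrossprod(WF, W)
      chA <- tryCatch(chol(A), error = function(e) {
        chol(A + diag(1e-10 * max(diag(A)), n))
      })
      solveS <- function(v) {
        w <- v / Fdiag
        y <- backsolve(chA, forwardsolve(t(chA), drop(W %*% w)))
        w - drop(crossprod(W, y)) / Fdiag
      }
    }

    newton <- function(comp) {
      # comp is the target of Z ds + S dz = -comp
      rz_adj <- r_prim - comp / z
      t_d <- d * rz_adj
      g <- Gtz(t_d)
      rhs_b <- -(r_dual_b + g$beta)
      rhs_u <- -(r_dual_u + g$u)
      v <- rhs_b - (d4 - d3) / d34 * rhs_u
      dbeta <- solveS(v)
      du <- (rhs_u - (d4 - d3) * dbeta) / d34
      dx_g <- Gx(dbeta, du)
      dz <- d * dx_g + t_d
      ds <- -(comp + s * dz) / z
      list(dbeta = dbeta, du = du, ds = ds, dz = dz)
    }

    step_len <- function(v, dv) {
      neg <- which(dv < 0)
      if (!length(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
    }

    ok <- TRUE
    res <- tryCatch({
      aff <- newton(s * z)
      if (!all(is.finite(aff$ds)) || !all(is.finite(aff$dz))) stop("nonfinite")
      ap <- step_len(s, aff$ds); ad <- step_len(z, aff$dz)
      mu_aff <- sum((s + ap * aff$ds) * (z + ad * aff$dz)) / m
      sigma <- min(1, (mu_aff / mu)^3)
      cr <- newton(s * z + aff$ds * aff$dz - sigma * mu)
      if (!all(is.finite(cr$ds)) || !all(is.finite(cr$dz))) stop("nonfinite")
      cr
    }, error = function(e) NULL)
    if (is.null(res)) { ok <- FALSE } else {
      ap <- 0.995 * step_len(s, res$ds)
      ad <- 0.995 * step_len(z, res$dz)
      beta <- beta + ap * res$dbeta
      u <- u + ap * res$du
      s <- s + ap * res$ds
      z <- z + ad * res$dz
      if (!all(is.finite(s)) || !all(is.finite(z)) || !all(is.finite(beta)))
        ok <- FALSE
    }
    if (!ok) break                     # numeric breakdown: fall back below
  }
  if (best$gap < accept) {
    return(structure(best$beta, iterations = iter, converged = TRUE))
  }
  warning("interior-point solver did not reach tolerance at delta = ", delta,
          " (residual ", signif(best$gap, 3), ")")
  structure(best$beta, iterations = iter, converged = FALSE)
}
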