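## Brute-force oracle for the r-concave tail maximization on small grids.
## Independent method: penalized multistart optimization over probability
## vectors on contiguous supports, p = softmax(z).  r-concavity (convexity
## of p^r on the effective support) and the mean constraint enter as
## penalties; only final iterates that satisfy the constraints are kept.
## Convexity is checked locally scaled (scale-invariant), the effective
## support (p above 1e-10 of the max) must be contiguous.

.oracle_feasible <- function(p, supp, mu, r, tol = 1e-7) {
  if (sum(supp * p) > mu + tol) return(FALSE)
  pos <- which(p >= 1e-10 * max(p))
  if (any(diff(pos) != 1L)) return(FALSE)        # support not contiguous
  if (length(pos) > 2) {
    x <- p[pos]^r
    d2 <- x[-(1:2)] - 2 * x[-c(1, length(x))] + x[1:(length(x) - 2)]
    scale <- x[-(1:2)] + x[-c(1, length(x))] + x[1:(length(x) - 2)]
    if (any(d2 / scale < -tol)) return(FALSE)
  }
  TRUE
}

oracle_d <- function(theta, tau, N, r, n_shapes = 2000, n_polish = 4,
                     seed = 42) {
  set.seed(seed)
  if (tau <= 0) return(1)
  t <- as.integer(ceiling(tau * N - 1e-9))
  if (t > N) return(0)
  mu <- theta * N
  if (mu >= t) return(1)
  best <- 0
  for (l in 0:min(t - 1, floor(mu + 1e-9))) for (m in t:N) {
    L <- m - l + 1
    supp <- l:m
    tail_ix <- supp >= t
    make_pen <- function(W) function(z) {
      p <- exp(z - max(z)); p <- pmax(p / sum(p), 1e-300)
      pen <- max(0, sum(supp * p) - mu)^2
      if (L > 2) {
        x <- p^r
        d2 <- x[-(1:2)] - 2 * x[-c(1, L)] + x[1:(L - 2)]
        scale <- x[-(1:2)] + x[-c(1, L)] + x[1:(L - 2)]
        pen <- pen + sum(pmax(0, -d2 / scale)^2)
      }
      -sum(p[tail_ix]) + W * pen
    }
    ## stage 1: dense sweep over random convex shapes
    ## x = a + b i + sum c_k (i - k)_+, p = x^(1/r)
    i <- 0:(L - 1)
    cand <- matrix(NA_real_, 0, L)
    tails <- numeric(0)
    for (sh in seq_len(n_shapes)) {
      x <- exp(stats::runif(1, -1, 1)) +
        stats::runif(1, -3, 3) * stats::rexp(1, 2) * i
      if (L > 2 && stats::runif(1) < 0.7)
        for (k in sample(1:(L - 2), sample(L - 2, 1)))
          x <- x + stats::rexp(1, rate = 2) * pmax(i - k, 0)
      if (any(x <= 0)) x <- x - min(x) + stats::rexp(1, 10) + 1e-4
      p <- x^(1 / r); p <- p / sum(p)
      if (sum(supp * p) > mu) next
      tl <- sum(p[tail_ix])
      if (tl > best) best <- tl
      cand <- rbind(cand, log(p)); tails <- c(tails, tl)
    }
    ## stage 2: polish the best sweep points with an escalating penalty
    if (nrow(cand)) {
      for (ix in utils::head(order(tails, decreasing = TRUE), n_polish)) {
        o <- stats::optim(cand[ix, ], make_pen(1e4), method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-12))
        o <- stats::optim(o$par, make_pen(1e8), method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-14))
        p <- exp(o$par - max(o$par)); p <- p / sum(p)
        if (.oracle_feasible(p, supp, mu, r))
          best <- max(best, sum(p[tail_ix]))
      }
    }
  }
  best
}
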