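## Per-family error rate (PFER) calculus for stability selection:
## worst-case bound, unimodal and r-concave complementary-pairs bounds,
## and solving for whichever of (q, pi_thr, PFER) is missing.

#' Assumptions available for the PFER bound
#'
#' @return Character vector of the three supported assumption labels, in
#'   increasing order of strength: `"none"` (worst case), `"unimodal"`,
#'   `"r_concave"`.
#' @export
bound_assumptions <- function() c("none", "unimodal", "r_concave")

.check_bound_args <- function(q, p, pi_thr, B) {
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q))
    stop("'q' must be a single positive integer", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop("'p' must be a single positive integer", call. = FALSE)
  if (q > p)
    stop("'q' must not exceed the number of base-learners 'p'", call. = FALSE)
  if (!is.numeric(pi_thr) || length(pi_thr) != 1L || pi_thr <= 0.5 || pi_thr > 1)
    stop("'pi_thr' must lie in (0.5, 1]: got ", format(pi_thr), call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop("'B' must be a positive integer", call. = FALSE)
  invisible(TRUE)
}

## Worst-case bound q^2 / ((2 tau - 1) p); valid for any selection procedure
## on |n/2| subsamples.
.pfer_none <- function(q, p, tau) q^2 / ((2 * tau - 1) * p)

## Unimodal complementary-pairs constant C(tau, B).  Piecewise in tau with a
## break at 3/4; requires 2 tau - 1 > 1/(2B) in the lower branch.  Below the
## assumption-specific validity limit we fall back to the worst-case bound
## (conservative).
.unimodal_constant <- function(tau, B) {
  if (tau <= 3 / 4) {
    denom <- 2 * tau - 1 - 1 / (2 * B)
    if (denom <= 0) return(NA_real_)
    1 / (2 * denom)
  } else {
    4 * (1 - tau + 1 / (2 * B)) / (1 + 1 / B)
  }
}

.pfer_unimodal <- function(q, p, tau, B) {
  theta <- q / p
  ## validity limit: the unimodal bound is derived for thresholds a little
  ## above 1/2 + theta^2; below it, keep the worst-case bound
  tmin <- 1 / 2 + min(theta^2, 1 / (2 * B) + 3 / 4 * theta^2)
  cc <- .unimodal_constant(tau, B)
  ub <- if (is.na(cc) || tau < tmin) Inf else cc * q^2 / p
  min(ub, .pfer_none(q, p, tau))
}

.pfer_rconcave <- function(q, p, tau, B) {
  theta <- q / p
  d1 <- d_value(theta^2, 2 * tau - 1, B, r = -1 / 2)
  d2 <- d_value(theta, tau, 2 * B, r = -1 / 4)
  ## r-concavity (r = -1/2) implies unimodality, so the unimodal bound
  ## remains valid and the minimum of all three bounds can be taken
  min(min(d1, d2) * p, .pfer_unimodal(q, p, tau, B))
}

#' Upper bound on the per-family error rate of stability selection
#'
#' Computes an upper bound for the expected number of falsely selected
#' noise variables \eqn{E(V)} when each of the subsample fits selects `q`
#' base-learners out of `p` and the stable set is cut at threshold
#' `pi_thr`.
#'
#' Three bounds are available, in increasing order of strength of the
#' assumptions on the (simultaneous) selection probabilities:
#' \describe{
#'   \item{`"none"`}{the worst-case bound
#'     \eqn{q^2 / ((2\pi_{thr} - 1) p)}, valid without assumptions;}
#'   \item{`"unimodal"`}{assumes a unimodal distribution of the
#'     simultaneous selection proportions under complementary pairs
#'     subsampling;}
#'   \item{`"r_concave"`}{additionally assumes r-concavity (r = -1/2 for
#'     the simultaneous selection proportions on the grid of `B`
#'     complementary pairs, r = -1/4 for the selection proportions on the
#'     `2B` grid); the bound is the minimum of the two corresponding
#'     tail-probability maximizations, see [d_value()], times `p`.}
#' }
#' Below the assumption-specific validity limits the next weaker bound is
#' used, so the reported value is always a valid (conservative) bound and
#' the three variants are monotone: r-concave <= unimodal <= worst case.
#'
#' @param q number of distinct base-learners selected per subsample fit.
#' @param p total number of base-learners.
#' @param pi_thr selection-frequency threshold, in (0.5, 1].
#' @param B number of complementary pairs (2B subsample fits); ignored by
#'   the worst-case bound.
#' @param assumption one of `"none"`, `"unimodal"`, `"r_concave"`.
#' @return A single number: the PFER upper bound.
#' @seealso [solve_cutoff()], [solve_q()], [d_value()]
#' @examples
#' pfer_bound(q = 10, p = 57, pi_thr = 1, assumption = "none")
#' pfer_bound(q = 10, p = 57, pi_thr = 0.87, B = 50, assumption = "unimodal")
#' @export
pfer_bound <- function(q, p, pi_thr, B = 50,
                       assumption = c("none", "unimodal", "r_concave")) {
  assumption <- match.arg(assumption)
  .check_bound_args(q, p, pi_thr, B)
  switch(assumption,
         none      = .pfer_none(q, p, pi_thr),
         unimodal  = .pfer_unimodal(q, p, pi_thr, B),
         r_concave = .pfer_rconcave(q, p, pi_thr, B))
}

## ---------------------------------------------------------------------------
## r-concave tail probability maximization
##
## d_value(theta, tau, gridB, r) = max P(X >= tau) over random variables X
## supported on {0, 1/gridB, ..., 1} whose probability sequence p_k is
## r-concave (p_k^r convex on a contiguous support, r < 0) subject to
## E[X] <= theta.
##
## Extremal structure: on the support the convex sequence x_k = p_k^r can be
## taken affine, x_k = c (a + b k), giving p_k proportional to (a + k)^(-s)
## with s = -1/r for decreasing sequences (b > 0), the mirrored form for
## increasing sequences (b < 0), possibly with a depressed end point
## (equivalently a mixture of the affine-x law with a point mass adjacent
## to the support, subject to the convexity constraint that the end mass
## not exceed the affine extrapolation).  We maximize the tail over these
## families with the mean constraint active; a brute-force oracle over
## small supports backs this construction in the unit tests.  Increasing
## shapes can only compete when the tail point is below twice the mean
## budget, so that (more expensive) branch is gated on tau <= 2 theta.
## ---------------------------------------------------------------------------

## mean (in index units, support 0..m) of q_j propto (a + j)^(-s)
.rc_weights <- function(a, m, s) (a + 0:m)^(-s)

.rc_mean <- function(a, m, s) {
  w <- .rc_weights(a, m, s)
  sum((0:m) * w) / sum(w)
}

## solve .rc_mean(a) = target for a (monotone increasing in a); NA if the
## target is outside (0, m/2)
.rc_solve_a <- function(target, m, s, lo = 1e-9, hi = 1e9) {
  if (target <= .rc_mean(lo, m, s) || target >= .rc_mean(hi, m, s))
    return(NA_real_)
  exp(stats::uniroot(function(la) .rc_mean(exp(la), m, s) - target,
                     lower = log(lo), upper = log(hi), tol = 1e-12)$root)
}

.rc_tail <- function(a, m, s, t) {
  w <- .rc_weights(a, m, s)
  if (t > m) return(0)
  sum(w[(t + 1):(m + 1)]) / sum(w)
}

#' Maximal tail probability of an r-concave distribution
#'
#' Returns \eqn{\max P(X \ge \tau)} over random variables supported on
#' the grid \eqn{\{0, 1/B, \ldots, 1\}} (with `gridB` = B) whose
#' probability sequence is r-concave (\eqn{p_k^r} convex on a contiguous
#' support, `r` < 0) and whose mean is at most `theta`.  This is the
#' quantity entering the r-concave PFER bound, where it is evaluated once
#' for the simultaneous selection proportions (mean \eqn{(q/p)^2}, tail
#' point \eqn{2\pi_{thr} - 1}, grid B, r = -1/2) and once for the plain
#' selection proportions (mean \eqn{q/p}, tail point \eqn{\pi_{thr}},
#' grid 2B, r = -1/4).
#'
#' @param theta upper bound on the mean, in (0, 1).
#' @param tau tail point, in \[0, 1\]; `tau = 0` trivially gives 1.
#' @param gridB support grid resolution (number of subintervals of
#'   \[0, 1\]).
#' @param r concavity order, must be negative.
#' @return The maximal tail probability, a number in \[0, 1\], never
#'   exceeding the Markov bound `theta / tau`.
#' @examples
#' d_value(0.2, 0.8, gridB = 50, r = -1/2)
#' @export
d_value <- function(theta, tau, gridB, r = -1 / 2) {
  if (!is.numeric(r) || length(r) != 1L || r >= 0)
    stop("'r' must be negative", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("'theta' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("'tau' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(gridB) || length(gridB) != 1L || gridB < 1)
    stop("'gridB' must be a positive integer", call. = FALSE)
  N <- as.integer(round(gridB))
  if (tau == 0) return(1)
  s <- -1 / r
  t <- as.integer(ceiling(tau * N - 1e-9))   # smallest index with k/N >= tau
  if (t > N) return(0)
  mu <- theta * N
  if (mu >= t) return(1)                     # point mass at t is feasible
  best <- 0

  ## -- decreasing affine-x families on {0..m} (mean constraint active) ----
  for (m in t:N) {
    if (mu < m / 2) {
      a <- .rc_solve_a(mu, m, s)
      if (!is.na(a)) best <- max(best, .rc_tail(a, m, s, t))
    } else {
      ## mean constraint inactive for the flat limit: uniform on {0..m}
      best <- max(best, (m - t + 1) / (m + 1))
    }
  }

  ## -- right mixtures: decreasing base on {0..k} plus point mass at k+1 ---
  ## mean constraint active; convexity requires the end mass not to exceed
  ## the affine extrapolation of the base
  for (k in max(t - 1L, 0L):(N - 1L)) {
    objective <- function(la) {
      a <- exp(la)
      mq <- .rc_mean(a, k, s)
      w <- (mu - mq) / (k + 1 - mq)
      if (w < 0 || w > 1) return(-1)
      wt <- .rc_weights(a, k, s)
      if (w > (1 - w) * (a + k + 1)^(-s) / sum(wt) + 1e-12) return(-1)
      w + (1 - w) * (if (k >= t) sum(wt[(t + 1):(k + 1)]) / sum(wt) else 0)
    }
    a_ub <- if (.rc_mean(1e9, k, s) <= mu) 1e9 else .rc_solve_a(mu, k, s)
    if (is.na(a_ub)) a_ub <- 1e9
    opt <- stats::optimize(objective, lower = log(1e-9), upper = log(a_ub),
                           maximum = TRUE, tol = 1e-8)
    best <- max(best, opt$objective, objective(log(a_ub)))
  }

  ## -- increasing shapes: only competitive when the tail point is within
  ##    reach of the mean budget --------------------------------------------
  if (t <= 2 * mu + 1) {
    ## pure increasing affine-x on {l..m}: p_j = w_{m-j} with w decreasing
    for (l in 0:(t - 1L)) {
      for (m in t:N) {
        L <- m - l                           # support size minus one
        target <- m - mu                     # required mean of mirrored w
        if (target <= 0 || target >= L / 2) next
        a <- .rc_solve_a(target, L, s)
        if (!is.na(a)) best <- max(best, 1 - .rc_tail(a, L, s, m - t + 1L))
      }
    }
    ## left mixtures: increasing base on {l..m} plus point mass at l-1
    for (l in 1:t) {
      for (m in t:N) {
        L <- m - l
        if (L < 1) next
        objective <- function(la) {
          a <- exp(la)
          mb <- m - .rc_mean(a, L, s)        # mean of the increasing base
          w <- (mb - mu) / (mb - (l - 1))    # point-mass weight at l-1
          if (w < 0 || w > 1) return(-1)
          wt <- .rc_weights(a, L, s)
          ## convexity at the bottom point (mirror of the right mixture)
          if (w > (1 - w) * (a + L + 1)^(-s) / sum(wt) + 1e-12) return(-1)
          tail_base <- sum(wt[seq_len(m - t + 1L)]) / sum(wt)
          (1 - w) * tail_base + (if (l - 1 >= t) w else 0)
        }
        opt <- stats::optimize(objective, lower = log(1e-9), upper = log(1e9),
                               maximum = TRUE, tol = 1e-8)
        best <- max(best, opt$objective)
      }
    }
  }

  min(max(best, 0), 1)
}

## ---------------------------------------------------------------------------
## parameter solving
## ---------------------------------------------------------------------------

#' Solve for the selection threshold given an error bound
#'
#' Returns the smallest threshold \eqn{\pi_{thr}} on the empirical
#' frequency grid (multiples of 1/(2B)) in (0.5, 1] whose PFER bound does
#' not exceed `PFER_max`.  If even \eqn{\pi_{thr} = 1} violates the bound,
#' the threshold is capped at 1 and flagged as not attainable; the
#' realized bound at the cap is still reported (with a warning).
#'
#' @inheritParams pfer_bound
#' @param PFER_max requested upper bound for the per-family error rate
#'   (may exceed 1: it is an expected count, not a probability).
#' @return A list with elements `pi_thr`, `bound` (the realized PFER bound
#'   at the returned threshold), and `attainable` (logical).
#' @examples
#' solve_cutoff(q = 10, p = 57, PFER_max = 1, B = 50, assumption = "unimodal")
#' @export
solve_cutoff <- function(q, p, PFER_max, B = 50,
                         assumption = c("none", "unimodal", "r_concave")) {
  assumption <- match.arg(assumption)
  if (!is.numeric(PFER_max) || length(PFER_max) != 1L || PFER_max <= 0)
    stop("'PFER_max' must be a single positive number", call. = FALSE)
  .check_bound_args(q, p, 1, B)
  grid <- seq_len(2 * B)[seq_len(2 * B) > B] / (2 * B)   # (0.5, 1] on k/(2B)
  for (tau in grid) {
    b <- pfer_bound(q, p, tau, B, assumption)
    if (b <= PFER_max)
      return(list(pi_thr = tau, bound = b, attainable = TRUE))
  }
  b1 <- pfer_bound(q, p, 1, B, assumption)
  warning(sprintf(
    "PFER_max = %g not attainable for q = %d, p = %d (%s): smallest bound %.4g at pi_thr = 1",
    PFER_max, as.integer(q), as.integer(p), assumption, b1), call. = FALSE)
  list(pi_thr = 1, bound = b1, attainable = FALSE)
}

#' Solve for the per-fit selection count given an error bound
#'
#' Returns the largest integer `q` in \[1, p\] whose PFER bound at the
#' given threshold does not exceed `PFER_max`.
#'
#' @inheritParams pfer_bound
#' @inheritParams solve_cutoff
#' @return A single integer.
#' @examples
#' solve_q(pi_thr = 0.9, p = 100, PFER_max = 1, assumption = "none")
#' @export
solve_q <- function(pi_thr, p, PFER_max, B = 50,
                    assumption = c("none", "unimodal", "r_concave")) {
  assumption <- match.arg(assumption)
  if (!is.numeric(PFER_max) || length(PFER_max) != 1L || PFER_max <= 0)
    stop("'PFER_max' must be a single positive number", call. = FALSE)
  .check_bound_args(1, p, pi_thr, B)
  ok <- 0L
  for (q in seq_len(p)) {         # bound is increasing in q: scan upwards
    if (pfer_bound(q, p, pi_thr, B, assumption) <= PFER_max) ok <- q
    else break
  }
  if (ok == 0L)
    stop(sprintf(
      "no feasible q: even q = 1 gives PFER bound %.4g > PFER_max = %g",
      pfer_bound(1, p, pi_thr, B, assumption), PFER_max), call. = FALSE)
  ok
}

#' Per-comparison error rate equivalent of a PFER bound
#'
#' Divides the per-family error rate by the number of candidate
#' base-learners, yielding the comparable unadjusted significance level
#' (e.g. PFER = 1 with p = 57 corresponds to alpha = 1/57 = 0.0175).
#'
#' @param PFER_max per-family error bound.
#' @param p number of candidate base-learners.
#' @return `PFER_max / p`.
#' @export
pcer_equivalent <- function(PFER_max, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop("'p' must be a positive integer", call. = FALSE)
  PFER_max / p
}

#' Resolve the missing member of the (q, pi_thr, PFER) triple
#'
#' Exactly two of `q`, `pi_thr` and `PFER_max` must be supplied; the third
#' is computed from the selected error bound with equality assumed.  When
#' all the subsample fits select `q` base-learners, re-thresholding a
#' finished run only needs this function (no re-subsampling).
#'
#' @inheritParams pfer_bound
#' @param q,pi_thr,PFER_max supply exactly two; the missing one is solved
#'   for (`q` via [solve_q()], `pi_thr` via [solve_cutoff()], `PFER_max`
#'   via [pfer_bound()]).
#' @return A list with `q`, `pi_thr`, `PFER_max` (the requested bound, or
#'   the realized one when it was solved for), `bound` (realized bound at
#'   the resolved parameters), `attainable`, `B` and `assumption`.
#' @examples
#' stabsel_parameters(q = 10, PFER_max = 1, p = 57, B = 50,
#'                    assumption = "unimodal")
#' @export
stabsel_parameters <- function(q = NULL, pi_thr = NULL, PFER_max = NULL,
                               p, B = 50,
                               assumption = c("none", "unimodal", "r_concave")) {
  assumption <- match.arg(assumption)
  given <- c(q = !is.null(q), pi_thr = !is.null(pi_thr),
             PFER = !is.null(PFER_max))
  if (sum(given) != 2L)
    stop("supply exactly two of 'q', 'pi_thr', 'PFER_max'", call. = FALSE)
  attainable <- TRUE
  if (is.null(pi_thr)) {
    sol <- solve_cutoff(q, p, PFER_max, B, assumption)
    pi_thr <- sol$pi_thr
    bound <- sol$bound
    attainable <- sol$attainable
  } else if (is.null(q)) {
    q <- solve_q(pi_thr, p, PFER_max, B, assumption)
    bound <- pfer_bound(q, p, pi_thr, B, assumption)
  } else {
    bound <- pfer_bound(q, p, pi_thr, B, assumption)
    PFER_max <- bound
  }
  list(q = as.integer(q), pi_thr = pi_thr, PFER_max = PFER_max,
       bound = bound, attainable = attainable, B = as.integer(B),
       assumption = assumption, p = as.integer(p))
}
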