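## Data generators and experiment harness for the two simulation
## scenarios: a linear logistic model with Gaussian (optionally Toeplitz
## correlated) predictors, and a Gaussian additive model with uniform
## predictors and eight reference effect shapes, noise calibrated to a
## target explained variation R^2.

#' Define a simulation scenario
#'
#' @param family `"logistic_linear"` or `"gaussian_additive"`.
#' @param n number of observations.
#' @param p number of covariates.
#' @param p_infl number of influential (signal) covariates.
#' @param correlation `"independent"`, or `"toeplitz"` for covariance /
#'   correlation `rho^|k-l|` between covariates k and l.
#' @param rho Toeplitz decay parameter.
#' @param r_squared target explained variation (Gaussian additive only).
#' @param signal_placement `"contiguous"` puts the signals in the first
#'   `p_infl` columns (under Toeplitz they are then mutually correlated);
#'   `"spread"` spaces them equally across the columns.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(family = c("logistic_linear", "gaussian_additive"),
                         n = 100, p = 100, p_infl = 3,
                         correlation = c("independent", "toeplitz"),
                         rho = 0.9, r_squared = 0.33,
                         signal_placement = c("contiguous", "spread"),
                         seed = 1) {
  family <- match.arg(family)
  correlation <- match.arg(correlation)
  signal_placement <- match.arg(signal_placement)
  stopifnot(n >= 4, p >= 1, p_infl >= 0, p_infl <= p,
            rho > -1, rho < 1, r_squared > 0, r_squared < 1)
  structure(list(family = family, n = as.integer(n), p = as.integer(p),
                 p_infl = as.integer(p_infl), correlation = correlation,
                 rho = rho, r_squared = r_squared,
                 signal_placement = signal_placement,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

.signal_columns <- function(scn) {
  if (scn$p_infl == 0) return(integer(0))
  if (scn$signal_placement == "contiguous") seq_len(scn$p_infl)
  else unique(round(seq(1, scn$p, length.out = scn$p_infl)))
}

## upper Cholesky factor of the Toeplitz correlation matrix rho^|k-l|
.toeplitz_chol <- function(p, rho) {
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  tryCatch(chol(S), error = function(e)
    stop("Toeplitz correlation matrix is not positive definite",
         call. = FALSE))
}

#' Generate data from the linear logistic scenario
#'
#' Covariate rows are i.i.d. multivariate normal with identity or
#' Toeplitz covariance; signal coefficients are drawn uniformly from
#' \{-1, +1\} and the response is Bernoulli with success probability
#' `plogis(X beta)`.
#'
#' @param scenario a [sim_scenario()] with family `"logistic_linear"`.
#' @return List with `X` (matrix with columns `x1..xp`), `y` (0/1
#'   vector), and `truth` (list: `signal` column indices, `beta`, `noise`
#'   indices).
#' @export
gen_logistic_linear <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"),
            scenario$family == "logistic_linear")
  scn <- scenario
  .with_seed(scn$seed, {
    Z <- matrix(stats::rnorm(scn$n * scn$p), scn$n, scn$p)
    X <- if (scn$correlation == "toeplitz")
      Z %*% .toeplitz_chol(scn$p, scn$rho) else Z
    colnames(X) <- paste0("x", seq_len(scn$p))
    sig <- .signal_columns(scn)
    beta <- numeric(scn$p)
    beta[sig] <- sample(c(-1, 1), length(sig), replace = TRUE)
    eta <- drop(X %*% beta)
    y <- stats::rbinom(scn$n, 1, stats::plogis(eta))
    list(X = X, y = y,
         truth = list(signal = sig, beta = beta,
                      noise = setdiff(seq_len(scn$p), sig)))
  })
}

## centering constant of f4 under U(-2, 2), frozen from
## integrate(function(x) x * tanh(2 * x), -2, 2) / 4 (tested against the
## quadrature in the suite)
.f4_center <- 0.948784478253585

#' Reference effect functions
#'
#' Eight analytic effect shapes used for the influential covariates of
#' the Gaussian additive scenario, all centered to mean zero under
#' U(-2, 2): oscillating `f1(x) = sin(3x)`, quadratic `f2(x) = x^2 -
#' 4/3`, smooth `f3(x) = x^3/3 - x` and `f4(x) = x tanh(2x) - c`, cosine
#' `f5(x) = cos(pi x / 2)`, piecewise linear `f6(x) = |x| - 1`, and
#' linear `f7(x) = x/2`, `f8(x) = -x/2`.  The shapes are stand-ins
#' matching the usual taxonomy (oscillating, quadratic, smooth, cosine,
#' piecewise linear, linear); with two influential covariates f1-f2 are
#' used, with three f1-f3, with eight all of them.
#'
#' @param id integer in 1..8.
#' @param x numeric vector, nominally in \[-2, 2\].
#' @return `f_id(x)`, vectorized.
#' @export
effect_function <- function(id, x) {
  if (!is.numeric(id) || length(id) != 1 || !(id %in% 1:8))
    stop("'id' must be an integer in 1..8", call. = FALSE)
  switch(id,
         sin(3 * x),
         x^2 - 4 / 3,
         x^3 / 3 - x,
         x * tanh(2 * x) - .f4_center,
         cos(pi * x / 2),
         abs(x) - 1,
         x / 2,
         -x / 2)
}

#' Generate data from the Gaussian additive scenario
#'
#' Covariates are U(-2, 2), independent or coupled through a Gaussian
#' copula with Toeplitz correlation.  The additive predictor sums the
#' reference [effect_function()]s over the signal columns (f1..f2 for two
#' signals, f1..f3 for three, f1..f8 for eight, recycled beyond eight)
#' and the noise variance is calibrated to the realized predictor
#' variance so that the explained variation is approximately `r_squared`:
#' `sigma^2 = var(eta) (1 - R^2) / R^2`.
#'
#' @param scenario a [sim_scenario()] with family `"gaussian_additive"`.
#' @return List with `X`, `y`, and `truth` (list: `signal`, `effect_ids`,
#'   `sigma2`, `noise`).
#' @export
gen_gaussian_additive <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"),
            scenario$family == "gaussian_additive")
  scn <- scenario
  .with_seed(scn$seed, {
    if (scn$correlation == "toeplitz") {
      ## Gaussian copula: Toeplitz normals (unit variances by construction)
      ## mapped through the normal CDF onto (-2, 2)
      Z <- matrix(stats::rnorm(scn$n * scn$p), scn$n, scn$p) %*%
        .toeplitz_chol(scn$p, scn$rho)
      X <- 4 * stats::pnorm(Z) - 2
    } else {
      X <- matrix(stats::runif(scn$n * scn$p, -2, 2), scn$n, scn$p)
    }
    colnames(X) <- paste0("x", seq_len(scn$p))
    sig <- .signal_columns(scn)
    eff <- if (length(sig)) ((seq_along(sig) - 1L) %% 8L) + 1L else integer(0)
    eta <- rep(0, scn$n)
    for (k in seq_along(sig))
      eta <- eta + effect_function(eff[k], X[, sig[k]])
    v <- stats::var(eta)
    sigma2 <- if (v > 0) v * (1 - scn$r_squared) / scn$r_squared else 1
    y <- eta + stats::rnorm(scn$n, sd = sqrt(sigma2))
    list(X = X, y = y,
         truth = list(signal = sig, effect_ids = eff, sigma2 = sigma2,
                      noise = setdiff(seq_len(scn$p), sig)))
  })
}

#' Generate data for a scenario
#'
#' Dispatches to [gen_logistic_linear()] or [gen_gaussian_additive()].
#'
#' @param scenario a [sim_scenario()].
#' @return See the family-specific generators.
#' @export
gen_scenario <- function(scenario) {
  switch(scenario$family,
         logistic_linear = gen_logistic_linear(scenario),
         gaussian_additive = gen_gaussian_additive(scenario))
}

#' True positive rate and false positive count of a selection
#'
#' @param stable_set selected covariate indices (or learner names of the
#'   form `x<j>`; names are matched by their digits).
#' @param truth the `truth` component of a generated scenario.
#' @return List with `tpr` = |selected and signal| / |signal| and `fp` =
#'   |selected and noise|.  Requesting the TPR with an empty signal set is
#'   an error.
#' @export
evaluate_selection <- function(stable_set, truth) {
  sel <- if (is.character(stable_set))
    as.integer(sub("\\D*(\\d+)\\)?$", "\\1", stable_set))
  else as.integer(stable_set)
  if (length(truth$signal) == 0)
    stop("TPR undefined: the scenario has no signal variables",
         call. = FALSE)
  list(tpr = length(intersect(sel, truth$signal)) / length(truth$signal),
       fp = length(intersect(sel, truth$noise)))
}

.scenario_learners <- function(scn, X) {
  cols <- colnames(X)
  if (scn$family == "logistic_linear")
    lapply(cols, function(cn) bl_linear(cn, id = cn))
  else
    lapply(cols, function(cn) bl_pspline(cn, id = cn))
}

#' Run a stability-selection simulation experiment
#'
#' For every combination of scenario and (q, PFER_max, assumption) cell,
#' generates `reps` replicate data sets, runs [stabsel()] and records the
#' true positive rate and false positive count.  Because the subsample
#' fits depend only on `q`, all cells sharing a `q` reuse the same fits
#' and only the threshold is re-derived (the "re-threshold" property of
#' stability selection).
#'
#' @param scenarios list of [sim_scenario()] objects (seeds are
#'   overwritten per replicate from `master_seed`).
#' @param cells data.frame with columns `q`, `PFER_max`, `assumption`.
#' @param reps replicates per scenario.
#' @param B number of complementary pairs.
#' @param nu boosting step length.
#' @param master_seed seed from which all replicate and subsampling seeds
#'   are derived.
#' @param max_iter per-fit iteration cap.
#' @return data.frame with one row per scenario x cell x replicate:
#'   scenario descriptors, cell parameters, resolved `pi_thr`, realized
#'   `bound`, `tpr`, `fp`, and the replicate `seed` (NA rows with an
#'   `error` message if a replicate failed).
#' @export
run_experiment <- function(scenarios, cells, reps = 10, B = 50, nu = 0.1,
                           master_seed = 1, max_iter = 2500) {
  stopifnot(reps >= 1, is.data.frame(cells),
            all(c("q", "PFER_max", "assumption") %in% names(cells)))
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  seeds <- .with_seed(master_seed,
                      matrix(sample.int(2^30, length(scenarios) * reps),
                             length(scenarios), reps))
  out <- list()
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    for (rep in seq_len(reps)) {
      scn$seed <- seeds[si, rep]
      dat <- gen_scenario(scn)
      learners <- .scenario_learners(scn, dat$X)
      family <- if (scn$family == "logistic_linear") "binomial"
                else "gaussian"
      for (qv in unique(cells$q)) {
        res <- tryCatch(
          stabsel(dat$X, dat$y, learners, q = qv, PFER_max = Inf,
                  family = family, assumption = "none", B = B, nu = nu,
                  max_iter = max_iter, seed = scn$seed + 1L),
          error = function(e) e)
        sub <- cells[cells$q == qv, , drop = FALSE]
        for (ci in seq_len(nrow(sub))) {
          row <- data.frame(scenario = si, family = scn$family, n = scn$n,
                            p = scn$p, p_infl = scn$p_infl,
                            correlation = scn$correlation, rep = rep,
                            seed = scn$seed, q = qv,
                            PFER_max = sub$PFER_max[ci],
                            assumption = sub$assumption[ci],
                            pi_thr = NA_real_, bound = NA_real_,
                            tpr = NA_real_, fp = NA_integer_,
                            error = NA_character_,
                            stringsAsFactors = FALSE)
          if (inherits(res, "error")) {
            row$error <- conditionMessage(res)
          } else {
            rt <- tryCatch(
              rethreshold(res, PFER_max = sub$PFER_max[ci],
                          assumption = sub$assumption[ci]),
              error = function(e) e)
            if (inherits(rt, "error")) {
              row$error <- conditionMessage(rt)
            } else {
              ev <- evaluate_selection(rt$stable_set, dat$truth)
              row$pi_thr <- rt$parameters$pi_thr
              row$bound <- rt$parameters$bound
              row$tpr <- ev$tpr
              row$fp <- ev$fp
            }
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Cell means of an experiment table
#'
#' @param results output of [run_experiment()].
#' @return data.frame of mean TPR and FP (plus replicate counts) per
#'   scenario x cell.
#' @export
experiment_summary <- function(results) {
  ok <- results[is.na(results$error), , drop = FALSE]
  agg <- stats::aggregate(cbind(tpr, fp) ~ scenario + family + n + p +
                            p_infl + correlation + q + PFER_max + assumption,
                          data = ok, FUN = mean)
  cnt <- stats::aggregate(cbind(reps = rep) ~ scenario + q + PFER_max +
                            assumption, data = ok, FUN = length)
  merge(agg, cnt)
}
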