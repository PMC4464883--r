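## Component-wise functional gradient descent boosting.  Each iteration
## computes the negative-gradient residuals u, fits every base-learner to
## u by (penalized) least squares, updates only the best-fitting learner
## by a shrunken step nu, and records the empirical risk.
##
## The engine works on a "boost_prep" workspace: the stacked design F and
## block-diagonal solve operators are precomputed once per (data subset),
## so one iteration costs two matrix-vector products plus per-block sums.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## core loop; stop_q = NULL runs exactly m_stop iterations, otherwise runs
## until stop_q distinct learners were selected (or max_iter)
.boost_core <- function(prep, y, loss, nu, m_stop, offset_eta,
                        stop_q = NULL, record_increments = FALSE) {
  n <- prep$n
  p <- prep$p
  eta <- offset_eta
  coefs <- numeric(sum(prep$d))
  sel <- integer(0)
  risk <- numeric(0)
  ndist <- integer(0)
  incs <- if (record_increments) vector("list", m_stop) else NULL
  seen <- logical(p)
  n_seen <- 0L
  m <- 0L
  lin <- prep$lin
  npen <- length(prep$pen)
  pen_j <- vapply(prep$pen, `[[`, 0L, "j")
  expl <- numeric(p)
  while (m < m_stop) {
    u <- loss$ngradient(y, eta)
    ## linear learners: closed-form explained sum of squares
    slope <- NULL
    if (!is.null(lin)) {
      Su <- sum(u)
      Sxu <- drop(crossprod(lin$X, u))
      slope <- (Sxu - lin$Sx * Su / n) / lin$denom
      expl[lin$which] <- Su^2 / n + slope^2 * lin$denom
    }
    ## penalized learners: c = (C + lambda P)^-1 B'u, explained
    ## 2 c'B'u - c'C c = c'B'u + lambda c'P c
    pen_cf <- NULL
    pen_cm <- NULL
    if (npen) {
      bu <- drop(crossprod(prep$Fpen, u))
      bt <- prep$pen_batch
      if (!is.null(bt)) {
        U <- matrix(bu, bt$d, bt$np)
        cflat <- rowSums(bt$W * t(U)[bt$rep_ix, , drop = FALSE])
        pen_cm <- matrix(cflat, bt$d, bt$np)
        cBu <- colSums(pen_cm * U)
        penq <- if (bt$kind == "pspline")
          colSums(diff(pen_cm, differences = bt$diff_order)^2)
        else colSums(pen_cm^2)
        expl[pen_j] <- cBu + bt$lambda * penq
      } else {
        pen_cf <- vector("list", npen)
        for (k in seq_len(npen)) {
          po <- prep$pen[[k]]
          bk <- bu[prep$pen_idx[[k]]]
          cf <- drop(po$Ainv %*% bk)
          pen_cf[[k]] <- cf
          expl[po$j] <- sum(cf * bk) + po$lambda * po$pen_quad(cf)
        }
      }
    }
    j <- which.max(expl)                          # ties: lowest index
    if (!is.null(lin) && j %in% lin$which) {
      k <- match(j, lin$which)
      b1 <- slope[k]
      b0 <- (Su - b1 * lin$Sx[k]) / n
      cj <- c(b0, b1)
      eta <- eta + nu * (b0 + b1 * lin$X[, k])
    } else {
      k <- match(j, pen_j)
      cj <- if (!is.null(pen_cm)) pen_cm[, k] else pen_cf[[k]]
      eta <- eta + nu * drop(prep$pen[[k]]$B %*% cj)
    }
    idx <- prep$idx[[j]]
    coefs[idx] <- coefs[idx] + nu * cj
    m <- m + 1L
    sel[m] <- j
    risk[m] <- mean(loss$rho(y, eta))
    if (!seen[j]) { seen[j] <- TRUE; n_seen <- n_seen + 1L }
    ndist[m] <- n_seen
    if (record_increments) incs[[m]] <- cj
    if (!is.null(stop_q) && n_seen >= stop_q) break
  }
  list(coefs = coefs, eta = eta, selection_path = sel, risk_path = risk,
       n_distinct_path = ndist, m = m, increments = incs)
}

.resolve_offset <- function(loss, y, offset, offset_mode, n) {
  base <- if (is.null(offset)) rep(0, n) else {
    stopifnot(length(offset) == n)
    as.numeric(offset)
  }
  off_scalar <- if (offset_mode == "zero") 0 else loss$offset_fun(y, base)
  list(base = base, scalar = off_scalar, eta0 = base + off_scalar)
}

.split_coefs <- function(coefs, prep) {
  out <- lapply(prep$idx, function(ix) coefs[ix])
  names(out) <- prep$ids
  out
}

.new_boost_fit <- function(core, prep, compiled, loss, nu, off) {
  structure(list(
    coefficients = .split_coefs(core$coefs, prep),
    offset = off$scalar,
    offset_base = if (all(off$base == 0)) NULL else off$base,
    nu = nu,
    m_stop = core$m,
    selection_path = core$selection_path,
    selected_ids = prep$ids[core$selection_path],
    risk_path = core$risk_path,
    n_distinct_path = core$n_distinct_path,
    fitted_eta = core$eta,
    family = loss$name,
    compiled = compiled),
    class = "boost_fit")
}

#' Component-wise gradient boosting
#'
#' Fits a model by component-wise functional gradient descent: starting
#' from a constant offset, each iteration fits every base-learner to the
#' negative-gradient residuals by (penalized) least squares, selects the
#' learner with the smallest residual sum of squares (ties broken towards
#' the lowest learner index) and adds `nu` times its fit to the additive
#' predictor.
#'
#' @param X data.frame or matrix of covariates.
#' @param y response vector.
#' @param learners list of [bl_linear()], [bl_pspline()], [bl_ridge()]
#'   objects, or an already compiled set from [compile_learners()].
#' @param family `"gaussian"`, `"binomial"`, or a `"boost_loss"` object.
#' @param nu step length in (0, 1].
#' @param m_stop number of boosting iterations (>= 0).
#' @param offset_mode `"loss_minimizer"` initializes the predictor at the
#'   scalar minimizing the empirical risk (mean of `y` for Gaussian,
#'   logit of the mean for binomial); `"zero"` starts at 0.
#' @param offset optional fixed per-observation offset vector added to the
#'   predictor (e.g. the fit of a previous model stage).
#' @return An object of class `"boost_fit"` with the per-learner
#'   coefficient vectors, selection path, and risk path.
#' @examples
#' d <- data.frame(x = rnorm(50))
#' y <- 2 * d$x + rnorm(50, sd = 0.1)
#' f <- boost(d, y, list(bl_linear("x")), m_stop = 200)
#' coef(f)
#' @export
boost <- function(X, y, learners, family = "gaussian", nu = 0.1,
                  m_stop = 100, offset_mode = c("loss_minimizer", "zero"),
                  offset = NULL) {
  offset_mode <- match.arg(offset_mode)
  loss <- get_loss(family)
  stopifnot(nu > 0, nu <= 1, m_stop >= 0)
  if (anyNA(y) || any(!is.finite(y)))
    stop("non-finite values in 'y'", call. = FALSE)
  y <- loss$check_y(y)
  compiled <- if (inherits(learners, "compiled_learners")) learners
              else compile_learners(learners, X)
  if (compiled$n != length(y))
    stop("nrow(X) and length(y) differ", call. = FALSE)
  prep <- .prepare_fit(compiled)
  off <- .resolve_offset(loss, y, offset, offset_mode, length(y))
  core <- .boost_core(prep, y, loss, nu, m_stop, off$eta0)
  .new_boost_fit(core, prep, compiled, loss, nu, off)
}

#' Boost until q distinct base-learners are selected
#'
#' Runs boosting iterations until the set of distinct selected
#' base-learners reaches size `q` (the iteration that first selects the
#' q-th distinct learner is included), as required by each subsample fit
#' of stability selection.
#'
#' @inheritParams boost
#' @param q target number of distinct selected base-learners, between 1
#'   and the number of learners.
#' @param max_iter iteration cap; if `q` distinct learners are not
#'   reached, an error of class `"boostsel_q_not_reached"` is thrown that
#'   carries the partial fit (`condition$fit`) and the count reached
#'   (`condition$reached`).
#' @return An object of class `"boost_fit"`.
#' @export
boost_until_q <- function(X, y, learners, q, family = "gaussian", nu = 0.1,
                          max_iter = 2500,
                          offset_mode = c("loss_minimizer", "zero"),
                          offset = NULL) {
  offset_mode <- match.arg(offset_mode)
  loss <- get_loss(family)
  compiled <- if (inherits(learners, "compiled_learners")) learners
              else compile_learners(learners, X)
  p <- length(compiled$learners)
  if (q < 1 || q > p)
    stop("'q' must lie between 1 and the number of base-learners (", p, ")",
         call. = FALSE)
  if (max_iter < q) stop("'max_iter' must be at least q", call. = FALSE)
  y <- loss$check_y(y)
  prep <- .prepare_fit(compiled)
  off <- .resolve_offset(loss, y, offset, offset_mode, length(y))
  core <- .boost_core(prep, y, loss, nu, max_iter, off$eta0, stop_q = q)
  fit <- .new_boost_fit(core, prep, compiled, loss, nu, off)
  if (core$n_distinct_path[core$m] < q)
    stop(errorCondition(
      sprintf("only %d of q = %d distinct base-learners selected within %d iterations",
              core$n_distinct_path[core$m], q, max_iter),
      class = c("boostsel_q_not_reached", "error"),
      fit = fit, reached = core$n_distinct_path[core$m]))
  fit
}

#' @export
print.boost_fit <- function(x, ...) {
  cat(sprintf("<boost_fit> family = %s, m_stop = %d, nu = %g\n",
              x$family, x$m_stop, x$nu))
  sel <- unique(x$selected_ids)
  cat(sprintf("  %d distinct base-learners selected", length(sel)))
  if (length(sel)) cat(":", paste(utils::head(sel, 8), collapse = ", "),
                       if (length(sel) > 8) "..." else "")
  cat("\n")
  invisible(x)
}

#' @export
coef.boost_fit <- function(object, ...) object$coefficients

#' Predict from a boosting fit
#'
#' @param object a `"boost_fit"`.
#' @param newdata covariates; omit to use the training data.
#' @param type `"link"` returns the additive predictor eta, `"response"`
#'   applies the response function (identity for Gaussian, logistic for
#'   binomial).
#' @param offset optional per-observation offset for `newdata` (required
#'   if the fit was built on one and `newdata` is given).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.boost_fit <- function(object, newdata = NULL,
                              type = c("link", "response"), offset = NULL,
                              ...) {
  type <- match.arg(type)
  loss <- get_loss(object$family)
  if (is.null(newdata)) {
    eta <- object$fitted_eta
  } else {
    n <- nrow(newdata)
    base <- if (!is.null(offset)) as.numeric(offset)
            else if (!is.null(object$offset_base))
              stop("fit uses a per-observation offset; supply 'offset' for newdata",
                   call. = FALSE)
            else rep(0, n)
    eta <- base + object$offset
    for (lc in object$compiled$learners) {
      cf <- object$coefficients[[lc$id]]
      if (all(cf == 0)) next
      B <- tryCatch(.bl_design(lc$spec, newdata, lc$meta), error = function(e)
        stop("cannot build design for learner '", lc$id, "' on newdata: ",
             conditionMessage(e), call. = FALSE))
      eta <- eta + drop(B %*% cf)
    }
  }
  if (type == "response") loss$response(eta) else eta
}

#' Choose the stopping iteration by cross-validation
#'
#' K-fold cross-validation of the empirical risk over a grid of stopping
#' iterations: each fold is fitted once up to `max(m_grid)` iterations and
#' the out-of-fold risk is evaluated along the path.
#'
#' @inheritParams boost
#' @param m_grid candidate stopping iterations (positive integers).
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return The element of `m_grid` minimizing the mean out-of-fold risk
#'   (ties towards the smallest), with the risk curve attached as
#'   attribute `"cv_risk"`.
#' @export
cv_mstop <- function(X, y, learners, family = "gaussian", nu = 0.1,
                     m_grid = c(10, 25, 50, 100, 250, 500), folds = 5,
                     seed = 1, offset = NULL) {
  loss <- get_loss(family)
  if (length(m_grid) == 0) stop("'m_grid' is empty", call. = FALSE)
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid < 1)) stop("'m_grid' must be positive", call. = FALSE)
  if (folds < 2) stop("'folds' must be >= 2", call. = FALSE)
  y <- loss$check_y(y)
  n <- length(y)
  compiled <- if (inherits(learners, "compiled_learners")) learners
              else compile_learners(learners, X)
  fold_id <- .with_seed(seed, sample(rep_len(seq_len(folds), n)))
  m_max <- max(m_grid)
  base <- if (is.null(offset)) rep(0, n) else as.numeric(offset)
  cv_risk <- matrix(NA_real_, folds, length(m_grid))
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k)
    te <- which(fold_id == k)
    prep <- .prepare_fit(compiled, tr)
    off <- .resolve_offset(loss, y[tr], base[tr], "loss_minimizer",
                           length(tr))
    core <- .boost_core(prep, y[tr], loss, nu, m_max, off$eta0,
                        record_increments = TRUE)
    ## replay the update path on the held-out rows
    eta_te <- base[te] + off$scalar
    Fte <- lapply(compiled$learners, function(lc) lc$B[te, , drop = FALSE])
    risk_te <- numeric(core$m)
    for (m in seq_len(core$m)) {
      j <- core$selection_path[m]
      eta_te <- eta_te + nu * drop(Fte[[j]] %*% core$increments[[m]])
      risk_te[m] <- mean(loss$rho(y[te], eta_te))
    }
    cv_risk[k, ] <- risk_te[pmin(m_grid, core$m)]
  }
  mean_risk <- colMeans(cv_risk)
  best <- m_grid[which.min(mean_risk)]
  structure(best, cv_risk = stats::setNames(mean_risk, m_grid))
}
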