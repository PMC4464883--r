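## Base-learners for component-wise boosting: linear effects (with an
## absorbed per-learner intercept), penalized B-spline smooths (P-splines),
## and ridge-penalized categorical blocks used as random-effect surrogates.
## Penalized learners fix their ridge multiplier once, before boosting, so
## that the trace of the smoother matrix equals the requested degrees of
## freedom.

#' Linear base-learner
#'
#' A straight-line fit in one covariate with its own intercept (absorbed
#' by including a constant column), estimated by ordinary least squares.
#'
#' @param col column name or index of the covariate.
#' @param id identifier; defaults to the column.
#' @return An object of class `"base_learner"`.
#' @export
bl_linear <- function(col, id = NULL) {
  structure(list(id = if (is.null(id)) paste0("lin(", col, ")") else id,
                 kind = "linear", col = col, df = NA_real_),
            class = "base_learner")
}

#' P-spline base-learner
#'
#' A penalized smooth in one covariate: cubic B-splines on equally spaced
#' interior knots over the observed range with a difference penalty on
#' adjacent spline coefficients, fitted by penalized least squares.  The
#' ridge multiplier is resolved (once, by root finding on the smoother
#' trace) so that the effective degrees of freedom equal `df`.
#'
#' @inheritParams bl_linear
#' @param df target effective degrees of freedom (> order of the
#'   difference penalty, which spans polynomials the penalty leaves free).
#' @param knots number of interior knots.
#' @param degree B-spline degree.
#' @param diff_order order of the difference penalty.
#' @return An object of class `"base_learner"`.
#' @export
bl_pspline <- function(col, id = NULL, df = 4, knots = 20, degree = 3,
                       diff_order = 2) {
  stopifnot(df > diff_order, knots >= 1, degree >= 1, diff_order >= 1)
  structure(list(id = if (is.null(id)) paste0("bbs(", col, ")") else id,
                 kind = "pspline", col = col, df = df, knots = knots,
                 degree = degree, diff_order = diff_order),
            class = "base_learner")
}

#' Ridge-penalized categorical base-learner
#'
#' One indicator column per level of a categorical covariate with a ridge
#' penalty on the level effects, resolved to `df` effective degrees of
#' freedom.  This is the usual boosting surrogate for a random effect
#' (e.g. a subject identifier); an optional numeric `by` column multiplies
#' the indicators, giving group-specific (interaction) random effects.
#'
#' @inheritParams bl_pspline
#' @param by optional column name/index of a numeric multiplier.
#' @return An object of class `"base_learner"`.
#' @export
bl_ridge <- function(col, id = NULL, df = 4, by = NULL) {
  stopifnot(df > 0)
  structure(list(id = if (is.null(id))
                   paste0("brandom(", col,
                          if (!is.null(by)) paste0(", by = ", by) else "", ")")
                 else id,
                 kind = "ridge_categorical", col = col, df = df, by = by),
            class = "base_learner")
}

#' @export
print.base_learner <- function(x, ...) {
  cat(sprintf("<base_learner> %s [%s]%s\n", x$id, x$kind,
              if (!is.na(x$df)) sprintf(" df = %g", x$df) else ""))
  invisible(x)
}

.get_col <- function(X, col) {
  if (is.character(col) && is.null(colnames(X)))
    stop("X has no column names but learner refers to column '", col, "'",
         call. = FALSE)
  X[, col]
}

## build the design matrix of a learner on (new) data, using the basis
## metadata frozen at compile time when available
.bl_design <- function(bl, X, meta = NULL) {
  switch(bl$kind,
    linear = {
      x <- as.numeric(.get_col(X, bl$col))
      cbind(1, x)
    },
    pspline = {
      x <- as.numeric(.get_col(X, bl$col))
      kn <- if (!is.null(meta)) meta$knot_seq else {
        rng <- range(x)
        if (diff(rng) <= 0)
          stop("constant covariate in P-spline learner '", bl$id, "'",
               call. = FALSE)
        h <- diff(rng) / (bl$knots + 1)
        seq(rng[1] - bl$degree * h, rng[2] + bl$degree * h, by = h)
      }
      splines::splineDesign(kn, x, ord = bl$degree + 1, outer.ok = TRUE)
    },
    ridge_categorical = {
      f <- .get_col(X, bl$col)
      lev <- if (!is.null(meta)) meta$levels else sort(unique(as.character(f)))
      f <- factor(as.character(f), levels = lev)
      if (anyNA(f))
        stop("unknown level in categorical learner '", bl$id, "'",
             call. = FALSE)
      B <- stats::model.matrix(~ 0 + f)
      if (!is.null(bl$by)) B <- B * as.numeric(.get_col(X, bl$by))
      B
    })
}

.bl_meta <- function(bl, X) {
  switch(bl$kind,
    linear = list(),
    pspline = {
      x <- as.numeric(.get_col(X, bl$col))
      rng <- range(x)
      if (diff(rng) <= 0)
        stop("constant covariate in P-spline learner '", bl$id, "'",
             call. = FALSE)
      h <- diff(rng) / (bl$knots + 1)
      list(knot_seq = seq(rng[1] - bl$degree * h, rng[2] + bl$degree * h,
                          by = h))
    },
    ridge_categorical = list(levels = sort(unique(as.character(.get_col(X, bl$col))))))
}

.bl_penalty <- function(bl, d) {
  switch(bl$kind,
    linear = NULL,
    pspline = {
      D <- diff(diag(d), differences = bl$diff_order)
      crossprod(D)
    },
    ridge_categorical = diag(d))
}

## trace of the smoother B (C + lambda P)^-1 B' = trace((C + lambda P)^-1 C)
.smoother_trace <- function(C, P, lambda) {
  sum(diag(solve(C + lambda * P, C)))
}

## resolve the ridge multiplier so that the smoother trace equals df
.df_to_lambda <- function(C, P, df, id) {
  f <- function(ll) .smoother_trace(C, P, exp(ll)) - df
  lo <- log(1e-10); hi <- log(1e12)
  flo <- tryCatch(f(lo), error = function(e) NA)
  fhi <- f(hi)
  if (is.na(flo) || flo < 0)
    stop("cannot reach df = ", df, " for learner '", id,
         "' (design too small?)", call. = FALSE)
  if (fhi > 0)
    stop("df = ", df, " below the penalty null-space dimension for learner '",
         id, "'", call. = FALSE)
  ## tol on log-lambda; the trace changes by O(df) per unit of log-lambda,
  ## so 1e-11 here comfortably meets the 1e-6 trace contract
  exp(stats::uniroot(f, lower = lo, upper = hi, tol = 1e-11)$root)
}

#' Compile base-learners against a data set
#'
#' Builds each learner's design matrix and penalty on the given data,
#' freezes basis metadata (spline knots, factor levels) and resolves the
#' ridge multipliers of penalized learners so that the trace of the
#' smoother matrix equals the learner's target degrees of freedom (within
#' 1e-6).  The compiled object can be restricted to row subsets cheaply,
#' which is what the stability-selection subsampling uses: bases and
#' penalties are shared across subsamples.
#'
#' @param learners list of `"base_learner"` objects; ids must be unique.
#' @param X data.frame or matrix of covariates.
#' @param lambdas optional named numeric vector of pre-resolved ridge
#'   multipliers (skips the degrees-of-freedom calibration).
#' @return An object of class `"compiled_learners"`.
#' @export
compile_learners <- function(learners, X, lambdas = NULL) {
  if (length(learners) == 0) stop("no base-learners given", call. = FALSE)
  if (inherits(learners, "base_learner")) learners <- list(learners)
  ids <- vapply(learners, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate base-learner ids", call. = FALSE)
  n <- nrow(X)
  comp <- vector("list", length(learners))
  for (j in seq_along(learners)) {
    bl <- learners[[j]]
    meta <- .bl_meta(bl, X)
    B <- .bl_design(bl, X, meta)
    if (anyNA(B) || any(!is.finite(B)))
      stop("non-finite values in design of learner '", bl$id, "'",
           call. = FALSE)
    d <- ncol(B)
    P <- .bl_penalty(bl, d)
    lambda <- 0
    if (!is.null(P)) {
      lambda <- if (!is.null(lambdas) && bl$id %in% names(lambdas))
        lambdas[[bl$id]]
      else .df_to_lambda(crossprod(B), P, bl$df, bl$id)
    }
    comp[[j]] <- list(spec = bl, id = bl$id, B = B, P = P, lambda = lambda,
                      d = d, meta = meta)
  }
  structure(list(learners = comp, ids = ids, n = n),
            class = "compiled_learners")
}

#' @export
print.compiled_learners <- function(x, ...) {
  cat(sprintf("<compiled_learners> %d learners on n = %d\n",
              length(x$learners), x$n))
  invisible(x)
}

## Assemble the fitting workspace for a row subset.  Linear learners
## (intercept + slope) are scored in closed form from one matrix-vector
## product per iteration; penalized learners get precomputed small
## (C + lambda P)^-1 blocks.  This keeps the boosting hot loop at two
## dense GEMVs plus O(sum d_j) scalar work.
.prepare_fit <- function(compiled, rows = NULL) {
  ls <- compiled$learners
  if (is.null(rows)) rows <- seq_len(compiled$n)
  n <- length(rows)
  kinds <- vapply(ls, function(lc) lc$spec$kind, "")
  d <- vapply(ls, `[[`, 0L, "d")
  idx <- split(seq_len(sum(d)), rep(seq_along(ls), d))
  lin <- which(kinds == "linear")
  pen <- which(kinds != "linear")
  lin_ops <- NULL
  if (length(lin)) {
    Xlin <- vapply(ls[lin], function(lc) lc$B[rows, 2], numeric(n))
    if (n == 1) Xlin <- matrix(Xlin, 1)
    Sx <- colSums(Xlin)
    Sxx <- colSums(Xlin^2)
    denom <- Sxx - Sx^2 / n
    bad <- which(denom <= 1e-12 * pmax(Sxx, 1))
    if (length(bad))
      stop("singular design for base-learner '",
           ls[[lin[bad[1]]]]$id, "' (constant column)", call. = FALSE)
    lin_ops <- list(which = lin, X = Xlin, Sx = Sx, denom = denom)
  }
  pen_ops <- lapply(pen, function(j) {
    lc <- ls[[j]]
    B <- lc$B[rows, , drop = FALSE]
    A <- crossprod(B) + lc$lambda * lc$P
    Ainv <- tryCatch(solve(A), error = function(e)
      stop("singular design for base-learner '", lc$id, "'", call. = FALSE))
    pq <- if (lc$spec$kind == "pspline")
      function(cf) sum(diff(cf, differences = lc$spec$diff_order)^2)
    else function(cf) sum(cf^2)
    list(j = j, B = B, Ainv = Ainv, lambda = lc$lambda, pen_quad = pq)
  })
  Fpen <- if (length(pen)) do.call(cbind, lapply(pen_ops, `[[`, "B"))
          else NULL
  pen_idx <- if (length(pen)) split(seq_len(sum(d[pen])), rep(seq_along(pen),
                                                              d[pen]))
             else list()
  ## batched scorer when all penalized learners share kind and size
  ## (e.g. one P-spline per covariate): stack the Ainv blocks row-wise so
  ## all coefficient fits come from one elementwise product + rowSums
  pen_batch <- NULL
  if (length(pen) > 1 && length(unique(kinds[pen])) == 1 &&
      length(unique(d[pen])) == 1) {
    dp <- d[pen][1]
    np <- length(pen)
    pen_batch <- list(
      W = do.call(rbind, lapply(pen_ops, `[[`, "Ainv")),
      rep_ix = rep(seq_len(np), each = dp),
      lambda = vapply(pen_ops, `[[`, 0, "lambda"),
      kind = kinds[pen][1],
      diff_order = if (kinds[pen][1] == "pspline")
        ls[[pen[1]]]$spec$diff_order else NA_integer_,
      d = dp, np = np)
  }
  structure(list(n = n, p = length(ls), idx = idx, d = d,
                 ids = compiled$ids, lin = lin_ops,
                 pen = pen_ops, Fpen = Fpen, pen_idx = pen_idx,
                 pen_batch = pen_batch),
            class = "boost_prep")
}

#' Fit a single base-learner to residuals
#'
#' (Penalized) least-squares fit of one base-learner's basis expansion to
#' a residual vector, as performed inside every boosting iteration.
#'
#' @param learner a `"base_learner"` object, or one element of a compiled
#'   set.
#' @param X covariate data (ignored when a compiled learner is given).
#' @param u residual vector.
#' @return List with `coef` (coefficients at the minimizer of the
#'   penalized residual sum of squares) and `rss` (residual sum of
#'   squares at the minimizer, penalty excluded).
#' @examples
#' fit_component(bl_linear("x"), data.frame(x = c(1, 2, 3)), u = c(2, 4, 6))
#' @export
fit_component <- function(learner, X, u) {
  if (inherits(learner, "base_learner"))
    learner <- compile_learners(list(learner), X)$learners[[1]]
  B <- learner$B
  if (nrow(B) != length(u))
    stop("residual vector length does not match the design", call. = FALSE)
  A <- crossprod(B)
  if (!is.null(learner$P)) A <- A + learner$lambda * learner$P
  cf <- tryCatch(drop(solve(A, crossprod(B, u))), error = function(e)
    stop("singular design for base-learner '", learner$id, "'",
         call. = FALSE))
  fitted <- drop(B %*% cf)
  list(coef = cf, rss = sum((u - fitted)^2))
}
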