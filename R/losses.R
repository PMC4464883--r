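## Loss functions for component-wise gradient boosting.  A loss object
## bundles the pointwise loss rho(y, eta), its negative gradient in eta,
## the scalar offset minimizing the empirical risk, and the response
## function h mapping the linear predictor back to the response scale.

new_boost_loss <- function(name, rho, ngradient, offset_fun, response,
                           check_y = function(y) y) {
  structure(list(name = name, rho = rho, ngradient = ngradient,
                 offset_fun = offset_fun, response = response,
                 check_y = check_y),
            class = "boost_loss")
}

#' Gaussian (squared error) loss
#'
#' Loss \eqn{\rho(y, \eta) = (y - \eta)^2 / 2}, so the negative gradient
#' is the raw residual \eqn{y - \eta}.  The offset minimizing the
#' empirical risk is the mean of `y`.
#'
#' @return An object of class `"boost_loss"`.
#' @export
loss_gaussian <- function() {
  new_boost_loss(
    name = "gaussian",
    rho = function(y, eta) (y - eta)^2 / 2,
    ngradient = function(y, eta) y - eta,
    offset_fun = function(y, base = 0) mean(y - base),
    response = identity)
}

#' Binomial loss with logit link
#'
#' Negative log-likelihood \eqn{-[y \log p + (1 - y)\log(1 - p)]} with
#' \eqn{p = \mathrm{logistic}(\eta)}, evaluated in numerically stable
#' log-sum-exp form; the negative gradient is \eqn{y - p}.  The response
#' must be coded 0/1.
#'
#' @return An object of class `"boost_loss"`.
#' @export
loss_binomial <- function() {
  new_boost_loss(
    name = "binomial",
    ## log(1 + exp(eta)) - y * eta, computed without overflow
    rho = function(y, eta) pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta,
    ngradient = function(y, eta) y - stats::plogis(eta),
    offset_fun = function(y, base = 0) {
      if (all(base == 0)) {
        pr <- mean(y)
        if (pr <= 0 || pr >= 1)
          stop("binomial loss: response is all one class, offset undefined",
               call. = FALSE)
        return(stats::qlogis(pr))
      }
      ## with a fixed base offset, solve sum(y - logistic(base + c)) = 0
      stats::uniroot(function(cc) sum(y - stats::plogis(base + cc)),
                     lower = -30, upper = 30, tol = 1e-10)$root
    },
    response = stats::plogis,
    check_y = function(y) {
      if (!all(y %in% c(0, 1)))
        stop("binomial loss requires a 0/1 response", call. = FALSE)
      y
    })
}

#' Get a loss object by name
#'
#' @param family `"gaussian"` or `"binomial"`, or an existing
#'   `"boost_loss"` object (returned unchanged).
#' @return An object of class `"boost_loss"`.
#' @export
get_loss <- function(family) {
  if (inherits(family, "boost_loss")) return(family)
  switch(match.arg(family, c("gaussian", "binomial")),
         gaussian = loss_gaussian(),
         binomial = loss_binomial())
}

#' Negative gradient of a loss
#'
#' Evaluates the working residuals \eqn{u_i = -\partial\rho(y_i, \eta) /
#' \partial\eta} at \eqn{\eta = } `eta`: for the Gaussian loss the raw
#' residual \eqn{y - \eta}, for the binomial loss \eqn{y -
#' \mathrm{logistic}(\eta)}.
#'
#' @param loss a `"boost_loss"` object or family name.
#' @param y response vector (0/1 for binomial).
#' @param eta linear predictor vector, same length as `y`.
#' @return Numeric vector of residuals.
#' @examples
#' negative_gradient(loss_binomial(), y = 1, eta = 0)  # 0.5
#' @export
negative_gradient <- function(loss, y, eta) {
  loss <- get_loss(loss)
  if (length(y) != length(eta))
    stop("'y' and 'eta' must have the same length", call. = FALSE)
  y <- loss$check_y(y)
  loss$ngradient(y, eta)
}

#' Empirical risk of a fit
#'
#' Mean loss \eqn{n^{-1}\sum_i \rho(y_i, \eta_i)}.
#'
#' @inheritParams negative_gradient
#' @return A single number.
#' @export
empirical_risk <- function(loss, y, eta) {
  loss <- get_loss(loss)
  mean(loss$rho(loss$check_y(y), eta))
}

#' @export
print.boost_loss <- function(x, ...) {
  cat("<boost_loss>", x$name, "\n")
  invisible(x)
}
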