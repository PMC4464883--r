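## Losses, base-learners and the component-wise boosting engine.

test_that("negative gradients match the losses and their finite differences", {
  expect_equal(negative_gradient("gaussian", y = 1, eta = 0), 1)
  expect_equal(negative_gradient("binomial", y = 1, eta = 0), 0.5)
  ## saturation: logistic at large eta
  expect_equal(negative_gradient("binomial", y = 0, eta = 30), -1,
               tolerance = 1e-8)
  expect_error(negative_gradient("binomial", y = c(0, 2), eta = c(0, 0)),
               "0/1 response")
  expect_error(negative_gradient("gaussian", y = 1:3, eta = 1:2),
               "same length")
  ## finite differences, both losses, random points
  set.seed(42)
  eps <- 1e-5
  for (fam in c("gaussian", "binomial")) {
    loss <- get_loss(fam)
    y <- if (fam == "binomial") rbinom(40, 1, 0.5) else rnorm(40)
    eta <- rnorm(40, sd = 2)
    num <- (loss$rho(y, eta + eps) - loss$rho(y, eta - eps)) / (2 * eps)
    expect_lt(max(abs(negative_gradient(fam, y, eta) + num)), 1e-6)
  }
})

test_that("binomial loss is finite and stable at extreme predictors", {
  loss <- loss_binomial()
  expect_true(all(is.finite(loss$rho(c(0, 1), c(800, -800)))))
  expect_error(loss$offset_fun(rep(1, 5)), "all one class")
})

test_that("fit_component solves the penalized least-squares problems", {
  ## exact linear relation: slope 2, zero residual
  f <- fit_component(bl_linear("x"), data.frame(x = c(1, 2, 3)),
                     u = c(2, 4, 6))
  expect_equal(unname(f$coef[2]), 2)
  expect_equal(f$rss, 0, tolerance = 1e-12)
  ## residuals orthogonal to [1, x]: slope 0, rss = |u|^2
  f0 <- fit_component(bl_linear("x"), data.frame(x = c(1, 2, 3)),
                      u = c(1, -2, 1))
  expect_equal(unname(f0$coef), c(0, 0), tolerance = 1e-12)
  expect_equal(f0$rss, 6)
  ## singular design is reported with the learner id
  expect_error(fit_component(bl_linear("x", id = "const"),
                             data.frame(x = rep(1, 5)), u = rnorm(5)),
               "const")
  ## P-spline with lambda -> Inf collapses onto the least-squares line
  ## (the 2nd-order difference penalty leaves linear functions free)
  set.seed(3)
  X <- data.frame(x = runif(80, -2, 2))
  u <- 1 + 2 * X$x + rnorm(80, sd = 0.3)
  lc <- compile_learners(list(bl_pspline("x")), X)$learners[[1]]
  lc$lambda <- 1e10
  fs <- fit_component(lc, X, u)
  line <- fitted(lm(u ~ x, X))
  Bc <- drop(lc$B %*% fs$coef)
  expect_lt(max(abs(Bc - line)), 1e-3)
})

test_that("penalized learners resolve their ridge multiplier to the target df", {
  set.seed(4)
  X <- data.frame(x = runif(100, -2, 2),
                  g = sample(letters[1:10], 100, replace = TRUE))
  comp <- compile_learners(list(bl_pspline("x", df = 4),
                                bl_ridge("g", df = 4)), X)
  for (lc in comp$learners) {
    tr <- sum(diag(solve(crossprod(lc$B) + lc$lambda * lc$P,
                         crossprod(lc$B))))
    expect_equal(tr, 4, tolerance = 1e-6)
  }
})

test_that("boost reproduces closed-form references", {
  d <- make_linear_data(n = 50, p = 3)
  ls <- linear_learners(d$X)
  ## m_stop = 0: predictor is the offset
  f0 <- boost(d$X, d$y, ls, m_stop = 0)
  expect_true(all(unlist(f0$coefficients) == 0))
  expect_equal(predict(f0), rep(mean(d$y), 50))
  ## single learner, nu = 1, many iterations: OLS slope
  ols <- coef(lm(d$y ~ x1, d$X))
  f1 <- boost(d$X, d$y, list(bl_linear("x1")), nu = 1, m_stop = 400)
  expect_equal(unname(f1$coefficients[[1]][2]), unname(ols[2]),
               tolerance = 1e-8)
  ## one shrunken step from a zero offset
  f2 <- boost(d$X, d$y, list(bl_linear("x1")), nu = 0.1, m_stop = 1,
              offset_mode = "zero")
  expect_equal(unname(f2$coefficients[[1]][2]), 0.1 * unname(ols[2]),
               tolerance = 1e-12)
  expect_error(boost(d$X, d$y, list()), "no base-learners")
  yy <- d$y; yy[1] <- NA
  expect_error(boost(d$X, yy, ls), "non-finite")
})

test_that("L2 boosting converges to the OLS fit on a full-rank design", {
  d <- make_linear_data(n = 50, p = 5, beta = c(1.5, -2, 1, 0, 0.5))
  f <- boost(d$X, d$y, linear_learners(d$X), nu = 0.1, m_stop = 5000)
  ols_fit <- fitted(lm(d$y ~ ., d$X))
  expect_lt(max(abs(predict(f) - ols_fit)), 1e-4)
})

test_that("risk path is non-increasing across random instances", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(15:30, 1)
    p <- sample(2:4, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", 1:p)
    fam <- sample(c("gaussian", "binomial"), 1)
    nu <- if (fam == "binomial") 0.1 else sample(c(0.1, 0.5, 1), 1)
    y <- if (fam == "binomial") rbinom(n, 1, plogis(X$x1))
         else X$x1 + rnorm(n)
    if (fam == "binomial" && (mean(y) == 0 || mean(y) == 1)) next
    f <- boost(X, y, linear_learners(X), family = fam, nu = nu, m_stop = 30)
    expect_true(all(diff(f$risk_path) <= 1e-12))
  }
})

test_that("selection path is equivariant under learner permutation", {
  d <- make_linear_data(n = 60, p = 4, beta = c(1, -1, 0.5, 0), seed = 8)
  ls <- linear_learners(d$X)
  f_a <- boost(d$X, d$y, ls, m_stop = 50)
  f_b <- boost(d$X, d$y, ls[c(3, 1, 4, 2)], m_stop = 50)
  expect_identical(f_a$selected_ids, f_b$selected_ids)
})

test_that("boost_until_q stops at q distinct learners and errors beyond", {
  d <- make_linear_data(n = 80, p = 5, beta = c(1, 1, 0, 0, 0), sd = 0.1,
                        seed = 10)
  ls <- linear_learners(d$X)
  f1 <- boost_until_q(d$X, d$y, ls, q = 1)
  expect_equal(f1$m_stop, 1L)
  f2 <- boost_until_q(d$X, d$y, ls, q = 2)
  expect_setequal(unique(f2$selected_ids), c("x1", "x2"))
  expect_error(boost_until_q(d$X, d$y, ls, q = 6), "between 1 and")
  ## unreachable q carries the partial fit in the condition
  cnd <- tryCatch(boost_until_q(d$X, d$y, ls, q = 5, max_iter = 5),
                  boostsel_q_not_reached = function(e) e)
  expect_s3_class(cnd, "boostsel_q_not_reached")
  expect_s3_class(cnd$fit, "boost_fit")
  expect_lt(cnd$reached, 5)
})

test_that("predict matches the stored fit and response scale", {
  d <- make_linear_data(n = 40, p = 3, seed = 12)
  f <- boost(d$X, d$y, linear_learners(d$X), m_stop = 120)
  ## recomputing the empirical risk of the training predictions
  ## reproduces the last risk-path entry
  expect_equal(empirical_risk("gaussian", d$y, predict(f, d$X)),
               tail(f$risk_path, 1), tolerance = 1e-12)
  yb <- rbinom(40, 1, 0.5)
  fb <- boost(d$X, yb, linear_learners(d$X), family = "binomial",
              m_stop = 0, offset_mode = "zero")
  expect_equal(predict(fb, d$X, type = "response"), rep(0.5, 40))
  expect_error(predict(f, d$X[, 1:2]), "x3")
})

test_that("cv_mstop picks sensible stopping iterations", {
  d <- make_linear_data(n = 60, p = 3, beta = c(2, -2, 1), sd = 0.3,
                        seed = 14)
  ls <- linear_learners(d$X)
  expect_equal(as.integer(cv_mstop(d$X, d$y, ls, m_grid = 77)), 77L)
  expect_error(cv_mstop(d$X, d$y, ls, m_grid = integer(0)), "empty")
  ## strong signal: long stopping wins
  expect_equal(as.integer(cv_mstop(d$X, d$y, ls, m_grid = c(1, 500),
                                   seed = 2)), 500L)
  ## pure noise: smallest grid entry wins in the majority of seeds
  small <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    Xn <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
    names(Xn) <- paste0("x", 1:5)
    yn <- rnorm(40)
    m <- cv_mstop(Xn, yn, linear_learners(Xn), m_grid = c(1, 50, 200),
                  folds = 3, seed = s)
    if (as.integer(m) == 1L) small <- small + 1L
  }
  expect_gt(small, 10)
})
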