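## Subsampling, selection frequencies, stable sets, stability paths and
## the stabsel() driver.

test_that("complementary pairs are disjoint halves, mb draws are halves", {
  s <- draw_subsamples(10, subsample_scheme("complementary_pairs", B = 1,
                                            seed = 3))
  expect_length(s, 2)
  expect_length(s[[1]], 5)
  expect_length(intersect(s[[1]], s[[2]]), 0)
  expect_setequal(c(s[[1]], s[[2]]), 1:10)
  ## odd n: one index unused per pair
  s11 <- draw_subsamples(11, subsample_scheme("complementary_pairs", B = 2,
                                              seed = 3))
  expect_true(all(lengths(s11) == 5))
  expect_length(intersect(s11[[1]], s11[[2]]), 0)
  ## determinism and stream independence from B
  s_a <- draw_subsamples(20, subsample_scheme("mb", B = 5, seed = 9))
  s_b <- draw_subsamples(20, subsample_scheme("mb", B = 5, seed = 9))
  expect_identical(s_a, s_b)
  expect_true(all(lengths(s_a) == 10))
  expect_error(draw_subsamples(1, subsample_scheme(B = 1)), "n >= 2")
})

test_that("selection frequencies follow the counting definition", {
  sf <- selection_frequencies(list(c("1", "2"), "1", c("1", "3"), "1"),
                              universe = c("1", "2", "3", "4"))
  expect_equal(unname(sf$freqs), c(1, 0.25, 0.25, 0))
  expect_equal(sf$n_fits, 4)
  expect_error(selection_frequencies(list("z"), universe = c("a", "b")),
               "not in universe")
  expect_error(selection_frequencies(list(), universe = "a"), "empty")
  ## frequencies live on the grid of multiples of 1/n_fits
  set.seed(11)
  ids <- letters[1:8]
  sets <- replicate(12, sample(ids, sample(1:4, 1)), simplify = FALSE)
  sf2 <- selection_frequencies(sets, ids)
  expect_true(all(abs(sf2$freqs * sf2$n_fits -
                        round(sf2$freqs * sf2$n_fits)) < 1e-12))
})

test_that("stable_set applies an inclusive threshold", {
  fr <- stats::setNames(c(1, 0.97, 0.5), c("a", "b", "c"))
  expect_setequal(stable_set(fr, 0.87), c("a", "b"))
  expect_setequal(stable_set(fr, 1), "a")
  expect_setequal(stable_set(stats::setNames(0.87, "x"), 0.87), "x")
  expect_error(stable_set(fr, 0.5), "0.5")
})

test_that("stabsel controls frequencies, stable set, and rethreshold", {
  d <- make_linear_data(n = 80, p = 6, beta = c(2, -2, rep(0, 4)),
                        sd = 0.4, seed = 21)
  ls <- linear_learners(d$X)
  res <- stabsel(d$X, d$y, ls, q = 3, PFER_max = 1, B = 25,
                 assumption = "unimodal", seed = 5)
  fr <- res$frequencies
  ## grid property and the sum bound (every fit selected exactly q)
  expect_true(all(abs(fr$freqs * fr$n_fits -
                        round(fr$freqs * fr$n_fits)) < 1e-12))
  expect_true(all(lengths(res$selected_sets) == 3))
  expect_equal(sum(fr$freqs), 3, tolerance = 1e-12)
  ## strong signals dominate
  expect_setequal(res$stable_set, c("x1", "x2"))
  ## rethreshold reuses frequencies and matches a fresh resolution
  rt <- rethreshold(res, PFER_max = 2, assumption = "none")
  expect_identical(rt$frequencies, res$frequencies)
  pars <- stabsel_parameters(q = 3, PFER_max = 2, p = 6, B = 25,
                             assumption = "none")
  expect_equal(rt$parameters$pi_thr, pars$pi_thr)
  expect_setequal(rt$stable_set, stable_set(fr, pars$pi_thr))
  expect_error(stabsel(d$X, d$y, ls, q = 3, family = "gaussian"),
               "exactly two")
})

test_that("near-duplicate signal columns attain near-equal frequencies", {
  ## exact duplicates would always lose the deterministic lowest-index
  ## tie-break, so the exchangeability check uses two noisy copies of a
  ## common latent signal: which copy wins then varies by subsample
  set.seed(22)
  n <- 100
  z <- rnorm(n)
  X <- data.frame(x1 = z + rnorm(n, sd = 0.1), x2 = z + rnorm(n, sd = 0.1),
                  x3 = rnorm(n), x4 = rnorm(n))
  y <- 2 * z + rnorm(n, sd = 0.5)
  res <- stabsel(X, y, linear_learners(X), q = 2, pi_thr = 0.9, B = 50,
                 seed = 7)
  fr <- res$frequencies$freqs
  expect_lt(abs(fr[["x1"]] - fr[["x2"]]), 0.15)
  expect_gt(fr[["x1"]] + fr[["x2"]], 1.5)
})

test_that("pure-noise data yields an empty stable set in most seeds", {
  empty <- 0L
  for (s in 1:20) {
    set.seed(3000 + s)
    X <- as.data.frame(matrix(rnorm(100 * 50), 100, 50))
    names(X) <- paste0("x", 1:50)
    y <- rnorm(100)
    res <- stabsel(X, y, linear_learners(X), q = 2, pi_thr = 0.9, B = 25,
                   seed = s)
    if (length(res$stable_set) == 0) empty <- empty + 1L
  }
  expect_gte(empty, 18L)
})

test_that("all-noise error control holds on average (stochastic)", {
  ## PFER_max = 1 with the worst-case bound; 50 replicates, small design
  counts <- integer(50)
  for (s in 1:50) {
    set.seed(4000 + s)
    X <- as.data.frame(matrix(rnorm(60 * 20), 60, 20))
    names(X) <- paste0("x", 1:20)
    y <- rnorm(60)
    res <- stabsel(X, y, linear_learners(X), q = 2, PFER_max = 1, B = 25,
                   assumption = "none", seed = s)
    counts[s] <- length(res$stable_set)
  }
  ## one-sided 95% check: mean minus 1.645 SE must not exceed the bound
  se <- sd(counts) / sqrt(length(counts))
  expect_lte(mean(counts) - 1.645 * se, 1)
})

test_that("signal frequencies dominate noise frequencies", {
  set.seed(23)
  X <- as.data.frame(matrix(rnorm(100 * 15), 100, 15))
  names(X) <- paste0("x", 1:15)
  y <- 3 * X$x1 + 3 * X$x2 - rnorm(100)
  res <- stabsel(X, y, linear_learners(X), q = 4, pi_thr = 0.9, B = 25,
                 seed = 2)
  fr <- res$frequencies$freqs
  expect_gt(mean(fr[c("x1", "x2")]), mean(fr[paste0("x", 3:15)]))
})

test_that("stability paths are monotone and end at the plain frequencies", {
  set.seed(24)
  X <- as.data.frame(matrix(rnorm(100 * 10), 100, 10))
  names(X) <- paste0("x", 1:10)
  y <- 3 * X$x1 + rnorm(100)
  paths <- stability_paths(X, y, linear_learners(X), max_m = 40, B = 10,
                           seed = 5)
  expect_equal(dim(paths), c(10, 40))
  expect_true(all(apply(paths, 1, function(r) all(diff(r) >= 0))))
  ## the signal learner saturates and plateaus
  expect_equal(paths["x1", 40], 1)
  expect_equal(paths["x1", 20], 1)
  ## last column reproduces the fixed-m selection frequencies computed
  ## independently from the same subsample fits
  comp <- compile_learners(linear_learners(X), X)
  loss <- get_loss("gaussian")
  subs <- draw_subsamples(100, subsample_scheme("complementary_pairs",
                                                B = 10, seed = 5))
  sets <- lapply(subs, function(rows) {
    prep <- boostsel:::.prepare_fit(comp, rows)
    off <- boostsel:::.resolve_offset(loss, y[rows], NULL,
                                      "loss_minimizer", length(rows))
    core <- boostsel:::.boost_core(prep, y[rows], loss, 0.1, 40, off$eta0)
    unique(comp$ids[core$selection_path])
  })
  fr <- selection_frequencies(sets, comp$ids)
  expect_equal(paths[, 40], fr$freqs)
})

test_that("subsample fit failures propagate with the subsample index", {
  set.seed(26)
  X <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
  names(X) <- paste0("x", 1:6)
  y <- rnorm(40)
  ## max_iter = q leaves no room for repeated selections, so reaching q
  ## distinct learners fails on the first subsample
  cnd <- tryCatch(
    stabsel(X, y, linear_learners(X), q = 6, pi_thr = 0.9, B = 5,
            max_iter = 6, seed = 1),
    boostsel_q_not_reached = function(e) e)
  expect_s3_class(cnd, "boostsel_q_not_reached")
  expect_match(conditionMessage(cnd), "subsample fit 1")
  expect_lt(cnd$reached, 6)
})

test_that("cluster-level subsampling moves whole clusters", {
  set.seed(25)
  n <- 60
  cl <- rep(sprintf("s%02d", 1:12), each = 5)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- X$x1 + rnorm(n, sd = 0.3)
  res <- stabsel(X, y, linear_learners(X), q = 1, pi_thr = 0.9, B = 10,
                 seed = 3, cluster = cl)
  expect_s3_class(res, "stabsel_result")
  expect_equal(res$frequencies$freqs[["x1"]], 1)
})
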