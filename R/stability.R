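## Stability selection: subsampling schemes (Meinshausen-Buhlmann halves
## and Shah-Samworth complementary pairs), relative selection frequencies,
## stable-set extraction, stability paths, and the stabsel() driver that
## ties them to boosting and to the PFER bound calculus.

#' Subsampling scheme
#'
#' @param kind `"complementary_pairs"` (Shah-Samworth: B random splits
#'   into two disjoint halves, both used, 2B fits) or `"mb"`
#'   (Meinshausen-Buhlmann: B independent half-size subsamples).
#' @param B number of pairs (complementary pairs) or subsamples (mb).
#' @param seed master seed; each subsample draw uses its own stream
#'   derived by counter, so runs are reproducible and parallelizable.
#' @return An object of class `"subsample_scheme"`.
#' @export
subsample_scheme <- function(kind = c("complementary_pairs", "mb"), B = 50,
                             seed = 1) {
  kind <- match.arg(kind)
  stopifnot(B >= 1, is.numeric(seed), length(seed) == 1)
  structure(list(kind = kind, B = as.integer(B), seed = as.integer(seed)),
            class = "subsample_scheme")
}

#' Draw half-size subsamples
#'
#' All subsamples have size `floor(n / 2)`.  Under complementary pairs
#' each of the `B` random permutations yields two disjoint halves (for odd
#' `n` one index per pair is left out, re-randomized each pair); the
#' returned list has 2B elements with pairs adjacent.  Under `"mb"`, `B`
#' subsamples are drawn independently without replacement.
#'
#' @param n number of observations (>= 2).
#' @param scheme a [subsample_scheme()].
#' @return List of integer index vectors, each of length `floor(n / 2)`,
#'   with attribute `"n_fits"`.
#' @export
draw_subsamples <- function(n, scheme) {
  stopifnot(inherits(scheme, "subsample_scheme"))
  if (n < 2) stop("need n >= 2 observations to subsample", call. = FALSE)
  half <- floor(n / 2)
  out <- vector("list", if (scheme$kind == "mb") scheme$B else 2L * scheme$B)
  for (b in seq_len(scheme$B)) {
    .with_seed(scheme$seed + b, {
      if (scheme$kind == "mb") {
        out[[b]] <- sort(sample.int(n, half))
      } else {
        perm <- sample.int(n)
        out[[2L * b - 1L]] <- sort(perm[seq_len(half)])
        out[[2L * b]] <- sort(perm[half + seq_len(half)])
      }
    })
  }
  structure(out, n_fits = length(out))
}

#' Relative selection frequencies
#'
#' For each base-learner id in `universe`, the fraction of subsample fits
#' whose selected set contains it (zero for never-selected ids).
#' Frequencies lie on the grid of multiples of 1 / (number of fits).
#'
#' @param selected_sets non-empty list of character vectors (the distinct
#'   base-learner ids selected in each subsample fit).
#' @param universe character vector of all base-learner ids; every
#'   selected id must occur in it.
#' @return An object of class `"selection_frequencies"`: list with
#'   `freqs` (named numeric, in `universe` order) and `n_fits`.
#' @export
selection_frequencies <- function(selected_sets, universe) {
  if (length(selected_sets) == 0)
    stop("'selected_sets' is empty", call. = FALSE)
  universe <- as.character(universe)
  all_sel <- unlist(lapply(selected_sets, unique), use.names = FALSE)
  unknown <- setdiff(all_sel, universe)
  if (length(unknown))
    stop("selected ids not in universe: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(all_sel, levels = universe))
  structure(list(freqs = stats::setNames(as.numeric(counts) /
                                           length(selected_sets), universe),
                 n_fits = length(selected_sets)),
            class = "selection_frequencies")
}

#' @export
print.selection_frequencies <- function(x, ...) {
  cat(sprintf("<selection_frequencies> %d ids over %d fits\n",
              length(x$freqs), x$n_fits))
  print(utils::head(sort(x$freqs, decreasing = TRUE), 10))
  invisible(x)
}

#' Extract the stable set
#'
#' All ids whose relative selection frequency is at least `pi_thr`
#' (inclusive comparison).
#'
#' @param freqs a `"selection_frequencies"` object or a named numeric
#'   vector of frequencies.
#' @param pi_thr threshold in (0.5, 1].
#' @return Character vector of stable ids.
#' @export
stable_set <- function(freqs, pi_thr) {
  if (inherits(freqs, "selection_frequencies")) freqs <- freqs$freqs
  if (!is.numeric(pi_thr) || pi_thr <= 0.5 || pi_thr > 1)
    stop("'pi_thr' must lie in (0.5, 1]", call. = FALSE)
  names(freqs)[freqs >= pi_thr - 1e-9]
}

## run one boosting fit per subsample and return the distinct selected ids
.stabsel_fits <- function(X, y, compiled, loss, q, nu, max_iter, subsamples,
                          offset, cluster = NULL) {
  lapply(seq_along(subsamples), function(b) {
    rows <- if (is.null(cluster)) subsamples[[b]]
            else which(cluster %in% subsamples[[b]])
    prep <- .prepare_fit(compiled, rows)
    off <- .resolve_offset(loss, y[rows],
                           if (is.null(offset)) NULL else offset[rows],
                           "loss_minimizer", length(rows))
    core <- tryCatch(
      .boost_core(prep, y[rows], loss, nu, max_iter, off$eta0, stop_q = q),
      error = function(e)
        stop("subsample fit ", b, " failed: ", conditionMessage(e),
             call. = FALSE))
    if (core$n_distinct_path[core$m] < q)
      stop(errorCondition(
        sprintf("subsample fit %d: only %d of q = %d distinct base-learners selected within %d iterations",
                b, core$n_distinct_path[core$m], q, max_iter),
        class = c("boostsel_q_not_reached", "error"),
        subsample = b, reached = core$n_distinct_path[core$m]))
    unique(compiled$ids[core$selection_path])
  })
}

#' Stability selection with boosting
#'
#' Runs [boost_until_q()] on every half-size subsample, aggregates the
#' relative selection frequencies over all fits (2B for complementary
#' pairs, B for mb), resolves the missing member of the (q, pi_thr,
#' PFER_max) triple via the chosen error bound, and returns the stable
#' set together with the realized bound.
#'
#' @inheritParams boost
#' @param q number of distinct base-learners each subsample fit selects.
#' @param pi_thr,PFER_max supply exactly one of the two (with `q`); the
#'   other is resolved by [stabsel_parameters()].
#' @param assumption error-bound variant, see [pfer_bound()].
#' @param sampling subsampling scheme kind, see [subsample_scheme()].
#' @param B number of complementary pairs (default 50, i.e. 100 fits) or
#'   mb subsamples (use 100 to mirror the original proposal).
#' @param seed master seed for the subsample draws.
#' @param max_iter per-fit iteration cap for [boost_until_q()].
#' @param cluster optional grouping vector of length `nrow(X)`: when
#'   given, subsampling is done at the cluster level (all rows of a
#'   cluster enter or leave together), e.g. biological replicates with
#'   repeated measurements.
#' @param stratify optional factor: subsample draws are made within each
#'   stratum (e.g. to keep a binary outcome balanced).  Not combinable
#'   with `cluster`.
#' @param offset optional per-observation fixed offset (e.g. a first-stage
#'   model), passed to every subsample fit.
#' @return An object of class `"stabsel_result"`: list with
#'   `frequencies`, `stable_set`, `selected_sets`, and the resolved
#'   `parameters` (q, pi_thr, PFER_max, realized bound, B, assumption,
#'   sampling, seed).
#' @seealso [rethreshold()] to change pi_thr / PFER_max / assumption
#'   without re-running the subsampling, [stability_paths()].
#' @export
stabsel <- function(X, y, learners, q = NULL, pi_thr = NULL, PFER_max = NULL,
                    family = "gaussian",
                    assumption = c("unimodal", "r_concave", "none"),
                    sampling = c("complementary_pairs", "mb"), B = 50,
                    nu = 0.1, max_iter = 2500, seed = 1, cluster = NULL,
                    stratify = NULL, offset = NULL) {
  assumption <- match.arg(assumption)
  sampling <- match.arg(sampling)
  loss <- get_loss(family)
  y <- loss$check_y(y)
  compiled <- if (inherits(learners, "compiled_learners")) learners
              else compile_learners(learners, X)
  p <- length(compiled$learners)
  pars <- stabsel_parameters(q = q, pi_thr = pi_thr, PFER_max = PFER_max,
                             p = p, B = B, assumption = assumption)
  scheme <- subsample_scheme(sampling, B = B, seed = seed)
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == length(y))
    if (!is.null(stratify))
      stop("'cluster' and 'stratify' cannot be combined", call. = FALSE)
    units <- unique(cluster)
    subsamples <- lapply(draw_subsamples(length(units), scheme),
                         function(ix) units[ix])
  } else if (!is.null(stratify)) {
    stopifnot(length(stratify) == length(y))
    strata <- split(seq_along(y), stratify)
    per <- lapply(seq_along(strata), function(h) {
      ix <- strata[[h]]
      sch <- subsample_scheme(sampling, B = B, seed = seed + 7919L * h)
      lapply(draw_subsamples(length(ix), sch), function(s) ix[s])
    })
    n_fits <- length(per[[1]])
    subsamples <- lapply(seq_len(n_fits), function(b)
      sort(unlist(lapply(per, `[[`, b), use.names = FALSE)))
  } else {
    subsamples <- draw_subsamples(length(y), scheme)
  }
  sets <- .stabsel_fits(X, y, compiled, loss, pars$q, nu, max_iter,
                        subsamples, offset, cluster = cluster)
  freqs <- selection_frequencies(sets, compiled$ids)
  structure(list(frequencies = freqs,
                 stable_set = stable_set(freqs, pars$pi_thr),
                 selected_sets = sets,
                 parameters = c(pars, list(sampling = sampling, seed = seed,
                                           nu = nu, family = loss$name))),
            class = "stabsel_result")
}

#' @export
print.stabsel_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<stabsel_result> q = %d, pi_thr = %.2f, PFER bound = %.4g (%s), B = %d (%s)\n",
              p$q, p$pi_thr, p$bound, p$assumption, p$B, p$sampling))
  if (!p$attainable)
    cat("  note: requested PFER_max not attainable, threshold capped at 1\n")
  cat("stable set:",
      if (length(x$stable_set)) paste(x$stable_set, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

#' Re-threshold a finished stability selection
#'
#' For fixed `q` the subsample fits do not depend on the threshold or the
#' error bound, so changing `pi_thr`, `PFER_max` or the assumption only
#' requires re-cutting the stored frequencies - no re-subsampling.
#'
#' @param result a `"stabsel_result"`.
#' @param pi_thr,PFER_max supply exactly one.
#' @param assumption error-bound variant; defaults to the original one.
#' @return A new `"stabsel_result"` sharing the frequencies.
#' @export
rethreshold <- function(result, pi_thr = NULL, PFER_max = NULL,
                        assumption = NULL) {
  stopifnot(inherits(result, "stabsel_result"))
  old <- result$parameters
  if (is.null(assumption)) assumption <- old$assumption
  pars <- stabsel_parameters(q = old$q, pi_thr = pi_thr,
                             PFER_max = PFER_max, p = old$p, B = old$B,
                             assumption = assumption)
  result$stable_set <- stable_set(result$frequencies, pars$pi_thr)
  result$parameters <- c(pars, old[setdiff(names(old), names(pars))])
  result
}

#' Stability paths
#'
#' Relative selection frequency of each base-learner as a function of the
#' number of boosting iterations: entry (j, m) is the fraction of
#' subsample fits in which learner j was selected at least once within
#' the first m iterations.  Rows are non-decreasing in m; the last column
#' reproduces the plain selection frequencies of a fixed-m run.
#'
#' @inheritParams stabsel
#' @param max_m number of boosting iterations to track (>= 1).
#' @return Numeric matrix (learners x max_m) with the learner ids as row
#'   names, class `"stability_paths"`.
#' @export
stability_paths <- function(X, y, learners, family = "gaussian", nu = 0.1,
                            max_m = 100,
                            sampling = c("complementary_pairs", "mb"),
                            B = 50, seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(max_m >= 1)
  loss <- get_loss(family)
  y <- loss$check_y(y)
  compiled <- if (inherits(learners, "compiled_learners")) learners
              else compile_learners(learners, X)
  subsamples <- draw_subsamples(length(y), subsample_scheme(sampling, B, seed))
  p <- length(compiled$learners)
  counts <- matrix(0, p, max_m)
  for (b in seq_along(subsamples)) {
    rows <- subsamples[[b]]
    prep <- .prepare_fit(compiled, rows)
    off <- .resolve_offset(loss, y[rows], NULL, "loss_minimizer", length(rows))
    core <- .boost_core(prep, y[rows], loss, nu, max_m, off$eta0)
    first <- rep(NA_integer_, p)
    sel <- core$selection_path
    for (m in seq_along(sel))
      if (is.na(first[sel[m]])) first[sel[m]] <- m
    for (j in which(!is.na(first)))
      counts[j, first[j]:max_m] <- counts[j, first[j]:max_m] + 1
  }
  paths <- counts / length(subsamples)
  rownames(paths) <- compiled$ids
  colnames(paths) <- seq_len(max_m)
  structure(paths, class = c("stability_paths", "matrix"))
}
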