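## JSON / TSV result serialization.  All outputs carry a provenance block
## (package version, seed, resolved parameters) and are deterministic:
## no timestamps, so re-running with identical inputs reproduces files
## byte for byte.

.provenance <- function(extra = list()) {
  c(list(package = "boostsel",
         version = as.character(utils::packageVersion("boostsel"))),
    extra)
}

#' Serialize a boosting fit to JSON
#'
#' Writes offset, step length, per-learner coefficient arrays, the
#' selection path and the risk path.
#'
#' @param fit a `"boost_fit"`.
#' @param path output file; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "boost_fit"))
  obj <- list(provenance = .provenance(),
              family = fit$family,
              offset = fit$offset,
              nu = fit$nu,
              m_stop = fit$m_stop,
              coefficients = fit$coefficients,
              selection_path = fit$selected_ids,
              risk_path = fit$risk_path)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Serialize a stability-selection result to JSON
#'
#' Writes the selection frequencies (sorted decreasing), the stable set,
#' the resolved parameter triple with the realized error bound, and the
#' seeds.
#'
#' @param result a `"stabsel_result"`.
#' @param path output file; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
stabsel_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "stabsel_result"))
  p <- result$parameters
  obj <- list(provenance = .provenance(list(seed = p$seed)),
              parameters = list(q = p$q, pi_thr = p$pi_thr,
                                PFER_max = p$PFER_max, bound = p$bound,
                                attainable = p$attainable, B = p$B,
                                p = p$p, assumption = p$assumption,
                                sampling = p$sampling, nu = p$nu,
                                family = p$family),
              n_fits = result$frequencies$n_fits,
              frequencies = as.list(sort(result$frequencies$freqs,
                                         decreasing = TRUE)),
              stable_set = as.list(result$stable_set))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Read a serialized stability-selection result
#'
#' @param path JSON file written by [stabsel_to_json()].
#' @return List with `parameters`, `frequencies` (named numeric),
#'   `stable_set`, `n_fits`.
#' @export
stabsel_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$frequencies <- unlist(obj$frequencies)
  obj$stable_set <- as.character(unlist(obj$stable_set))
  obj
}

#' Write stability paths as TSV
#'
#' Rows are base-learners, columns boosting-iteration checkpoints.
#'
#' @param paths a `"stability_paths"` matrix.
#' @param path output file.
#' @return The path, invisibly.
#' @export
paths_to_tsv <- function(paths, path) {
  df <- data.frame(learner = rownames(paths), unclass(paths),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
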