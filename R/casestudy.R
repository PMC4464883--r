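## Log-linear amino-acid interaction pipeline for phenotype-microarray
## (PM) data: long-format records (one well measurement per biological
## replicate), a design of 1 + 2 * (#amino acids) + 2 base-learners
## (global group effect, per-amino-acid main effects, sum-to-zero coded
## group-specific amino-acid interactions, and an overall plus a
## group-specific random effect), and a two-stage procedure - fit an
## offset model on the main effects, then run stability selection over
## the full learner list starting from the offset predictions.
## A synthetic fixture generator emulates the data shape (35 replicates
## x 384 wells, 27 amino-acid incidence annotations) so the pipeline is
## testable without the original data.

#' Default amino-acid annotation names
#'
#' The 20 proteinogenic amino acids plus 7 non-proteinogenic ones
#' (ornithine, citrulline, hydroxyproline, 2-aminobutyrate, norvaline,
#' norleucine, sarcosine), 27 in total, matching the number of incidence
#' annotations of the phenotype-microarray case study.
#'
#' @return Character vector of length 27.
#' @export
pm_amino_acids <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
    "Orn", "Cit", "Hyp", "Aba", "Nva", "Nle", "Sar")
}

#' Generate a synthetic phenotype-microarray fixture
#'
#' Emulates the shape of the case-study data: `n_cases + n_controls`
#' biological replicates, each measured on the same plate layout of
#' `wells` wells, every well annotated with 1-4 amino acids (the layout
#' is drawn once per fixture and shared by all replicates).  On the log
#' scale each measurement is
#' \deqn{\log y = \beta_0 + \sum_j \beta_{2,j} I_{Pj} + b_{id}
#'   + X(g) \sum_j (s_j / 2) I_{Pj} + X(g) \tilde b_{id} + \epsilon,}
#' with group code \eqn{X(g)} equal to +1 for cases and -1 for controls,
#' so a differential shift `s_j` is the full case-minus-control
#' difference for amino acid j.
#'
#' @param n_cases,n_controls numbers of case / control replicates
#'   (default 17 + 18 = 35).
#' @param wells wells per plate set (default 384).
#' @param amino_names annotation names (default [pm_amino_acids()]).
#' @param differential named numeric vector of log-scale case-minus-
#'   control shifts, names in `amino_names`; default none.
#' @param main_sd standard deviation of the amino-acid main effects
#'   `beta_2` (log scale).
#' @param re_sd standard deviation of the overall and the group-specific
#'   replicate random effects.
#' @param noise_sd residual standard deviation (log scale).
#' @param intercept overall intercept `beta_0` (log scale).
#' @param seed integer seed; the fixture is byte-reproducible from it.
#' @return data.frame with columns `id`, `group` (case/control), `well`,
#'   `value` (positive relative absorbance) and one 0/1 incidence column
#'   per amino acid; `n_replicates * wells` rows.
#' @export
gen_pm_fixture <- function(n_cases = 17, n_controls = 18, wells = 384,
                           amino_names = pm_amino_acids(),
                           differential = numeric(0), main_sd = 0.15,
                           re_sd = 0.1, noise_sd = 0.2, intercept = 0,
                           seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, wells >= 1,
            re_sd >= 0, noise_sd >= 0, main_sd >= 0)
  if (length(differential)) {
    if (is.null(names(differential)) ||
        !all(names(differential) %in% amino_names))
      stop("'differential' must be named with amino acids from 'amino_names'",
           call. = FALSE)
    if (any(!is.finite(differential)))
      stop("'differential' shifts must be finite", call. = FALSE)
  }
  A <- length(amino_names)
  ids <- c(sprintf("case%02d", seq_len(n_cases)),
           sprintf("ctrl%02d", seq_len(n_controls)))
  if (anyDuplicated(ids)) stop("duplicate replicate ids", call. = FALSE)
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  .with_seed(seed, {
    ## plate layout: incidence matrix wells x amino acids, 1-4 annotations
    ## per well, identical for every replicate
    inc <- matrix(0L, wells, A, dimnames = list(NULL, amino_names))
    n_ann <- sample(seq_len(min(4, A)), wells, replace = TRUE)
    for (w in seq_len(wells)) inc[w, sample.int(A, n_ann[w])] <- 1L
    beta2 <- stats::rnorm(A, sd = main_sd)
    shift <- stats::setNames(numeric(A), amino_names)
    shift[names(differential)] <- differential
    b_id <- stats::rnorm(length(ids), sd = re_sd)
    b_grp <- stats::rnorm(length(ids), sd = re_sd)
    gcode <- ifelse(group == "case", 1, -1)
    well_main <- drop(inc %*% beta2)
    well_diff <- drop(inc %*% (shift / 2))
    n_rep <- length(ids)
    logy <- rep(intercept + well_main, n_rep) +
      rep(b_id, each = wells) +
      rep(gcode, each = wells) * (rep(well_diff, n_rep) +
                                    rep(b_grp, each = wells)) +
      stats::rnorm(n_rep * wells, sd = noise_sd)
    out <- data.frame(id = rep(ids, each = wells),
                      group = rep(group, each = wells),
                      well = rep(sprintf("W%03d", seq_len(wells)), n_rep),
                      value = exp(logy),
                      stringsAsFactors = FALSE)
    cbind(out, inc[rep(seq_len(wells), n_rep), , drop = FALSE],
          row.names = NULL)
  })
}

#' Write a phenotype-microarray table
#'
#' @param records data.frame as returned by [gen_pm_fixture()].
#' @param path output path; `.tsv`/`.txt` writes tab-separated, anything
#'   else comma-separated.
#' @return `path`, invisibly.
#' @export
write_pm_long <- function(records, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and validate a long-format phenotype-microarray table
#'
#' Expects columns `id`, `group`, `well`, `value` and one 0/1 incidence
#' column per amino-acid annotation.  Validates that every value is
#' present and positive (the model is fitted on `log(value)`), that
#' group labels match `case_label` / `control_label`, and that incidence
#' entries are 0 or 1; offending rows are named in the error.
#'
#' @param path CSV (or TSV, by extension) file with a header row.
#' @param case_label,control_label accepted group labels.
#' @return data.frame with `group` normalized to `"case"` / `"control"`
#'   and attribute `"amino_names"`.
#' @export
read_pm_long <- function(path, case_label = "case",
                         control_label = "control") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "group", "well", "value")
  if (!all(need %in% names(dat)))
    stop("missing required columns: ",
         paste(setdiff(need, names(dat)), collapse = ", "), call. = FALSE)
  amino <- setdiff(names(dat), need)
  if (length(amino) == 0)
    stop("no amino-acid incidence columns found", call. = FALSE)
  bad <- which(!is.finite(dat$value) | dat$value <= 0)
  if (length(bad))
    stop("non-positive or missing 'value' (log is taken) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(dat$group), c(case_label, control_label))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (a in amino) {
    if (!all(dat[[a]] %in% c(0, 1)))
      stop("incidence column '", a, "' has entries other than 0/1",
           call. = FALSE)
  }
  dat$group <- ifelse(dat$group == case_label, "case", "control")
  message(sprintf("read %d records: %d replicates x %d wells, %d annotations",
                  nrow(dat), length(unique(dat$id)),
                  length(unique(dat$well)), length(amino)))
  structure(dat, amino_names = amino)
}

#' Build the log-linear interaction design
#'
#' Constructs the model frame and base-learner list of the case-study
#' model on `log(value)`: a global group effect (sum-to-zero coded,
#' control = -1 / case = +1), one main-effect learner per amino acid,
#' one group-specific interaction learner per amino acid (group code
#' times incidence), and an overall plus a group-specific ridge random
#' effect over replicate ids - `1 + 2 A + 2` learners for `A` amino
#' acids (57 for the case-study's 27).
#'
#' @param records validated records ([read_pm_long()] or
#'   [gen_pm_fixture()] output).
#' @param amino_names annotation columns to use; defaults to the
#'   `"amino_names"` attribute or every column after the four required
#'   ones.
#' @param ranef_df degrees of freedom of the two random-effect learners.
#' @return List with `data` (model frame: `y = log(value)`, `group_code`,
#'   incidence and interaction columns, `id`), `learners` (length
#'   `1 + 2A + 2`), `amino_names`, and learner-id helpers
#'   `main_ids` / `interaction_ids`.
#' @export
build_pm_design <- function(records, amino_names = NULL, ranef_df = 4) {
  if (is.null(amino_names))
    amino_names <- attr(records, "amino_names") %||%
      setdiff(names(records), c("id", "group", "well", "value"))
  miss <- setdiff(amino_names, names(records))
  if (length(miss))
    stop("amino-acid columns missing from records: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(unlist(records[amino_names]) %in% c(0, 1)))
    stop("incidence entries must be 0/1", call. = FALSE)
  if (length(unique(records$id[records$group == "case"])) < 2 ||
      length(unique(records$id[records$group == "control"])) < 2)
    stop("need at least 2 replicates per group", call. = FALSE)
  gcode <- ifelse(records$group == "case", 1, -1)
  dat <- data.frame(y = log(records$value), group_code = gcode,
                    id = as.character(records$id),
                    stringsAsFactors = FALSE)
  for (a in amino_names) {
    dat[[paste0("I_", a)]] <- as.numeric(records[[a]])
    dat[[paste0("GI_", a)]] <- gcode * as.numeric(records[[a]])
  }
  learners <- c(
    list(bl_linear("group_code", id = "group")),
    lapply(amino_names, function(a)
      bl_linear(paste0("I_", a), id = paste0("main(", a, ")"))),
    lapply(amino_names, function(a)
      bl_linear(paste0("GI_", a), id = paste0("int(", a, ")"))),
    list(bl_ridge("id", id = "ranef(id)", df = ranef_df),
         bl_ridge("id", by = "group_code", id = "ranef(id:group)",
                  df = ranef_df)))
  list(data = dat, learners = learners, amino_names = amino_names,
       main_ids = c("group", paste0("main(", amino_names, ")"), "ranef(id)"),
       interaction_ids = paste0("int(", amino_names, ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Offset model followed by stability selection with interactions
#'
#' Stage 1 boosts the main-effect learners only (group, amino-acid main
#' effects, overall random effect) on `log(value)`, with the stopping
#' iteration chosen by cross-validation; its predictions become a fixed
#' per-observation offset.  Stage 2 runs [stabsel()] over the full
#' learner list (main effects stay available) starting from that offset.
#' Subsampling is done at the replicate level: all wells of a subject
#' enter or leave a subsample together (use `cluster = FALSE` for plain
#' row-level subsampling).
#'
#' @param records validated PM records.
#' @param q,PFER_max,assumption,B,nu,max_iter,seed passed to [stabsel()].
#' @param m_grid candidate stopping iterations for the stage-1
#'   cross-validation.
#' @param cv_folds folds of the stage-1 cross-validation.
#' @param cluster subsample replicates (`TRUE`, default) or rows.
#' @param amino_names,ranef_df passed to [build_pm_design()].
#' @param final_mstop iterations of the full-data reporting fit; long
#'   enough that the effect estimates are essentially unshrunken (as
#'   `m` grows, component-wise boosting approaches the penalized
#'   least-squares fit on all learners).
#' @return List with `design`, `offset_mstop`, `offset_fit` (stage-1
#'   `"boost_fit"`), `result` (`"stabsel_result"`), and `final_fit` (a
#'   full-data stage-2 boosting fit used for effect-size reporting).
#' @export
fit_offset_then_stabsel <- function(records, q = 10, PFER_max = 1,
                                    assumption = c("unimodal", "r_concave",
                                                   "none"),
                                    B = 50, nu = 0.1, max_iter = 2500,
                                    seed = 1,
                                    m_grid = c(100, 250, 500, 1000, 2500),
                                    cv_folds = 5, cluster = TRUE,
                                    amino_names = NULL, ranef_df = 4,
                                    final_mstop = 1500) {
  assumption <- match.arg(assumption)
  design <- build_pm_design(records, amino_names, ranef_df)
  dat <- design$data
  stage1 <- design$learners[vapply(design$learners, `[[`, "", "id") %in%
                              design$main_ids]
  comp1 <- compile_learners(stage1, dat)
  m_opt <- cv_mstop(dat, dat$y, comp1, family = "gaussian", nu = nu,
                    m_grid = m_grid, folds = cv_folds, seed = seed)
  offset_fit <- boost(dat, dat$y, comp1, family = "gaussian", nu = nu,
                      m_stop = as.integer(m_opt))
  eta1 <- predict(offset_fit)
  comp_full <- compile_learners(design$learners, dat)
  result <- stabsel(dat, dat$y, comp_full, q = q, PFER_max = PFER_max,
                    family = "gaussian", assumption = assumption, B = B,
                    nu = nu, max_iter = max_iter, seed = seed,
                    cluster = if (isTRUE(cluster)) dat$id else NULL,
                    offset = eta1)
  final_fit <- boost(dat, dat$y, comp_full, family = "gaussian", nu = nu,
                     m_stop = final_mstop, offset = eta1)
  list(design = design, offset_mstop = as.integer(m_opt),
       offset_fit = offset_fit, result = result, final_fit = final_fit)
}

#' Per-amino-acid group differences from a fitted model
#'
#' Under the sum-to-zero group coding (+1 case, -1 control) the
#' case-minus-control difference for amino acid j is twice its
#' group-specific interaction coefficient; this extracts the interaction
#' slopes from a boosting fit over the case-study design and reports
#' `2 * beta_3j` on the log scale.
#'
#' @param fit a `"boost_fit"` over the [build_pm_design()] learners (for
#'   a pipeline result, its `final_fit`).
#' @param design the matching design list.
#' @return data.frame with `amino`, `beta3` (interaction slope) and
#'   `difference` (= 2 * beta3, case minus control, log scale), sorted by
#'   absolute difference.
#' @export
effect_size_report <- function(fit, design) {
  if (!inherits(fit, "boost_fit")) stop("'fit' must be a boost_fit",
                                        call. = FALSE)
  b3 <- vapply(design$interaction_ids, function(id) {
    cf <- fit$coefficients[[id]]
    if (is.null(cf)) 0 else cf[2]
  }, 0)
  out <- data.frame(amino = design$amino_names, beta3 = unname(b3),
                    difference = unname(2 * b3), stringsAsFactors = FALSE)
  out[order(-abs(out$difference)), ]
}
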