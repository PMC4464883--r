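## Small data builders shared across test files.

## linear-model toy data with known coefficients
make_linear_data <- function(n = 50, p = 3, beta = NULL, sd = 0.5,
                             seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- c(1.5, -2, rep(0, p - 2))
  y <- as.matrix(X) %*% beta + rnorm(n, sd = sd)
  list(X = X, y = drop(y), beta = beta)
}

linear_learners <- function(X) {
  lapply(names(X), function(cn) bl_linear(cn, id = cn))
}

## a tiny phenotype-microarray fixture (for fast unit tests; the
## full-shape fixture is exercised in the acceptance suite)
small_pm_fixture <- function(seed = 1, wells = 40, n_cases = 4,
                             n_controls = 4, amino = pm_amino_acids()[1:6],
                             differential = numeric(0)) {
  gen_pm_fixture(n_cases = n_cases, n_controls = n_controls, wells = wells,
                 amino_names = amino, differential = differential,
                 seed = seed)
}
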