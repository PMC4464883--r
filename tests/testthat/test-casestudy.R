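## Phenotype-microarray fixture generator, IO validation, design
## construction and effect reporting.  The full-scale pipeline-recovery
## runs live in the acceptance suite.

test_that("fixture has the stated shape and is reproducible", {
  fx <- gen_pm_fixture(seed = 3)
  expect_equal(nrow(fx), 35 * 384)
  expect_equal(length(unique(fx$id)), 35)
  expect_equal(sum(table(unique(fx[c("id", "group")])$group)), 35)
  expect_true(all(fx$value > 0))
  inc <- as.matrix(fx[pm_amino_acids()])
  expect_true(all(inc %in% c(0, 1)))
  expect_true(all(rowSums(inc) >= 1 & rowSums(inc) <= 4))
  ## plate layout identical across replicates
  w1 <- fx[fx$id == fx$id[1], pm_amino_acids()]
  w2 <- fx[fx$id == fx$id[nrow(fx)], pm_amino_acids()]
  expect_equal(unname(as.matrix(w1)), unname(as.matrix(w2)))
  ## byte-identical file for a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pm_long(gen_pm_fixture(seed = 7, wells = 24, n_cases = 3,
                               n_controls = 3), f1)
  write_pm_long(gen_pm_fixture(seed = 7, wells = 24, n_cases = 3,
                               n_controls = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_pm_fixture(differential = c(1)), "named")
  expect_error(gen_pm_fixture(differential = c(Zzz = 1)), "amino_names")
})

test_that("zero shifts and sds give values constant per composition class", {
  fx <- gen_pm_fixture(n_cases = 3, n_controls = 3, wells = 30,
                       amino_names = pm_amino_acids()[1:5],
                       re_sd = 0, noise_sd = 0, seed = 5)
  key <- apply(fx[pm_amino_acids()[1:5]], 1, paste, collapse = "")
  spread <- tapply(fx$value, key, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("read_pm_long validates records and rejects bad rows", {
  fx <- small_pm_fixture(seed = 9)
  path <- tempfile(fileext = ".csv")
  write_pm_long(fx, path)
  rd <- suppressMessages(read_pm_long(path))
  expect_equal(nrow(rd), nrow(fx))
  expect_equal(attr(rd, "amino_names"), pm_amino_acids()[1:6])
  ## non-positive value is rejected with its row index
  bad <- fx; bad$value[17] <- 0
  write_pm_long(bad, path)
  expect_error(suppressMessages(read_pm_long(path)), "17")
  ## missing value
  bad$value[17] <- NA
  write_pm_long(bad, path)
  expect_error(suppressMessages(read_pm_long(path)), "17")
  ## unknown group label
  bad <- fx; bad$group[1] <- "patient"
  write_pm_long(bad, path)
  expect_error(suppressMessages(read_pm_long(path)), "patient")
  ## incidence entry outside 0/1
  bad <- fx; bad$Ala[3] <- 2
  write_pm_long(bad, path)
  expect_error(suppressMessages(read_pm_long(path)), "Ala")
})

test_that("design has 1 + 2A + 2 learners with sum-to-zero coding", {
  fx <- gen_pm_fixture(n_cases = 3, n_controls = 3, wells = 30, seed = 11)
  des <- build_pm_design(fx)
  expect_length(des$learners, 57)          # 27 amino acids
  fx1 <- small_pm_fixture(amino = pm_amino_acids()[1], wells = 12, seed = 2)
  expect_length(build_pm_design(fx1)$learners, 5)   # 1 + 2 + 2
  ## interaction column: control-group record with incidence 1 codes -1
  d <- des$data
  ctrl1 <- which(d$group_code == -1 & d$I_Ala == 1)
  expect_true(all(d$GI_Ala[ctrl1] == -1))
  case1 <- which(d$group_code == 1 & d$I_Ala == 1)
  expect_true(all(d$GI_Ala[case1] == 1))
  expect_error(build_pm_design(fx, amino_names = c("Ala", "Qqq")), "Qqq")
})

test_that("effect sizes recover planted shifts and flip with the labels", {
  fx <- gen_pm_fixture(n_cases = 6, n_controls = 6, wells = 96,
                       amino_names = pm_amino_acids()[1:8],
                       differential = c(Ala = 0.3, Gly = -0.25),
                       re_sd = 0.05, noise_sd = 0.1, seed = 13)
  des <- build_pm_design(fx)
  comp <- compile_learners(des$learners, des$data)
  fit <- boost(des$data, des$data$y, comp, m_stop = 800)
  eff <- effect_size_report(fit, des)
  expect_equal(eff$difference[eff$amino == "Ala"], 0.3, tolerance = 0.08)
  expect_equal(eff$difference[eff$amino == "Gly"], -0.25, tolerance = 0.08)
  ## zero coefficient reports zero difference
  f0 <- boost(des$data, des$data$y, comp, m_stop = 0)
  expect_true(all(effect_size_report(f0, des)$difference == 0))
  ## relabeling the groups negates every reported difference
  fx_flip <- fx
  fx_flip$group <- ifelse(fx$group == "case", "control", "case")
  des_f <- build_pm_design(fx_flip)
  fit_f <- boost(des_f$data, des_f$data$y,
                 compile_learners(des_f$learners, des_f$data), m_stop = 800)
  eff_f <- effect_size_report(fit_f, des_f)
  m <- match(eff$amino, eff_f$amino)
  expect_equal(eff_f$difference[m], -eff$difference, tolerance = 1e-8)
})

test_that("the two-stage pipeline runs on a small fixture", {
  fx <- gen_pm_fixture(n_cases = 5, n_controls = 5, wells = 60,
                       amino_names = pm_amino_acids()[1:8],
                       differential = c(Cys = 0.5), re_sd = 0.05,
                       noise_sd = 0.1, seed = 17)
  pip <- fit_offset_then_stabsel(fx, q = 3, PFER_max = 1,
                                 assumption = "unimodal", B = 10,
                                 seed = 3, m_grid = c(25, 50),
                                 cv_folds = 3, final_mstop = 300)
  expect_s3_class(pip$result, "stabsel_result")
  expect_length(pip$design$learners, 1 + 16 + 2)
  fr <- pip$result$frequencies$freqs
  ## the planted interaction dominates all other interactions
  ints <- fr[pip$design$interaction_ids]
  expect_equal(names(which.max(ints)), "int(Cys)")
})
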