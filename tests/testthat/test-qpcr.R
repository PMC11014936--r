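make_ct <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- c("ct_table", class(out))
  out
}

test_that("ddCt arithmetic matches hand calculation", {
  # sample dCt 5, calibrator dCt 7 -> ddCt -2 -> fold 4
  ct <- make_ct(tibble::tribble(
    ~condition, ~gene,    ~replicate, ~ct,
    "cal",      "GAPDH",  1L,         20,
    "cal",      "ACTA2",  1L,         27,
    "trt",      "GAPDH",  1L,         20,
    "trt",      "ACTA2",  1L,         25
  ))
  rel <- delta_delta_ct(ct, calibrator = "cal")
  expect_equal(rel$fold_change[rel$condition == "trt"], 4)
  expect_equal(rel$fold_change[rel$condition == "cal"], 1)
})

test_that("the calibrator reads exactly 1 even under replicate noise", {
  for (s in 1:10) {
    ct <- generate_ct_table(
      c("DMSO", "a", "b"), c("GAPDH", "ACTA2", "TCF21"),
      tibble::tibble(condition = "a", gene = "ACTA2", log2fc = -1.3),
      ct_noise_sd = 0.5, seed = s
    )
    rel <- delta_delta_ct(ct, calibrator = "DMSO")
    expect_equal(rel$fold_change[rel$condition == "DMSO"], c(1, 1))
  }
})

test_that("programmed fold changes round-trip through the pipeline", {
  eff <- tibble::tribble(
    ~condition, ~gene,    ~log2fc,
    "drug",     "ACTA2",  -2,
    "drug",     "TCF21",  1.5
  )
  ct <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2", "TCF21"),
                          eff, ct_noise_sd = 0, seed = 3)
  rel <- delta_delta_ct(ct, calibrator = "DMSO")
  expect_equal(rel$fold_change[rel$condition == "drug" & rel$gene == "ACTA2"], 0.25)
  expect_equal(rel$fold_change[rel$condition == "drug" & rel$gene == "TCF21"], 2^1.5)

  # zero programme -> all folds 1
  ct0 <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"),
                           ct_noise_sd = 0, seed = 4)
  rel0 <- delta_delta_ct(ct0, calibrator = "DMSO")
  expect_true(all(rel0$fold_change == 1))

  # unbiased at bench-level noise
  ct_n <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"),
                            tibble::tibble(condition = "drug", gene = "ACTA2",
                                           log2fc = -2),
                            ct_noise_sd = 0.2, n_replicates = 100, seed = 5)
  rel_n <- delta_delta_ct(ct_n, calibrator = "DMSO")
  est <- log2(rel_n$fold_change[rel_n$condition == "drug"])
  expect_lt(abs(est - (-2)), 0.05)
})

test_that("ddCt is invariant to per-replicate plate shifts and handles gaps", {
  ct <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"),
                          tibble::tibble(condition = "drug", gene = "ACTA2",
                                         log2fc = -1),
                          ct_noise_sd = 0.3, seed = 6)
  shifted <- ct
  # add a constant to every Ct of each (condition, replicate) "plate run"
  shifted$ct <- shifted$ct + 3 * as.numeric(interaction(shifted$condition,
                                                        shifted$replicate))
  a <- delta_delta_ct(ct, calibrator = "DMSO")
  b <- delta_delta_ct(shifted, calibrator = "DMSO")
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)

  # missing reference replicate: dropped with a warning
  gap <- ct[!(ct$gene == "GAPDH" & ct$condition == "drug" & ct$replicate == 1), ]
  expect_warning(rel <- delta_delta_ct(gap, calibrator = "DMSO"), "dropped")
  expect_equal(rel$n_replicates[rel$condition == "drug"], 2)

  expect_error(delta_delta_ct(ct, calibrator = "nope"), "calibrator")
  expect_error(delta_delta_ct(ct, reference = "ACTB", calibrator = "DMSO"),
               "reference")
})

test_that("ANOVA versus control matches brute-force F on random panels", {
  d <- data.frame(cond = rep(c("DMSO", "drug"), each = 3), y = 1:6)
  res <- anova_vs_control(d, "y", "cond", control = "DMSO")
  expect_equal(res$f_statistic, 13.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)

  same <- data.frame(cond = rep(c("DMSO", "x"), each = 3), y = rep(1:3, 2))
  r0 <- anova_vs_control(same, "y", "cond", control = "DMSO")
  expect_equal(r0$f_statistic, 0)
  expect_equal(r0$p_value, 1)

  flat <- data.frame(cond = rep(c("DMSO", "x"), each = 3), y = rep(2, 6))
  expect_error(anova_vs_control(flat, "y", "cond", control = "DMSO"),
               "variance")

  withr::with_seed(9, {
    for (i in 1:30) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      d <- data.frame(
        cond = c(rep("DMSO", n1), rep("t", n2)),
        y = c(rnorm(n1), rnorm(n2, 0.5))
      )
      got <- anova_vs_control(d, "y", "cond", control = "DMSO")$f_statistic
      expect_equal(got, brute_anova_f(d$y, d$cond), tolerance = 1e-10)
    }
  })
})

test_that("the deactivation classifier applies the panel rules", {
  panel <- function(acta2, col1a1, tcf21, lrat, lhx2, dose = 2000) {
    tibble::tibble(
      compound_id = "X", dose_nM = dose,
      gene = c("ACTA2", "COL1A1", "TCF21", "LRAT", "LHX2"),
      fold_change = c(acta2, col1a1, tcf21, lrat, lhx2)
    )
  }
  expect_equal(classify_deactivation(panel(0.4, 0.3, 3, 2, 1.5))$classification,
               "deactivating")
  expect_equal(classify_deactivation(panel(1, 1, 1, 1, 1))$classification,
               "inactive")
  expect_equal(classify_deactivation(panel(0.5, 0.6, 0.9, 0.8, 0.7))$classification,
               "partial")
  expect_error(classify_deactivation(panel(1, 1, 1, 1, 1)[-1, ]), "ACTA2")

  # monotone: lowering ACTA2 never demotes
  ranks <- c(inactive = 1, partial = 2, deactivating = 3)
  base <- classify_deactivation(panel(0.9, 0.8, 2, 2, 0.5))$classification
  lower <- classify_deactivation(panel(0.1, 0.8, 2, 2, 0.5))$classification
  expect_gte(ranks[lower], ranks[base])

  # compound-level call uses the top dose
  two_dose <- dplyr::bind_rows(panel(0.4, 0.3, 3, 2, 1.5, dose = 2000),
                               panel(1.2, 1.1, 0.9, 0.8, 0.7, dose = 125))
  expect_equal(classify_deactivation(two_dose)$classification, "deactivating")
  expect_equal(classify_deactivation(two_dose)$top_dose_nM, 2000)
})

test_that("the heatmap table is complete, DMSO-anchored and round-trips", {
  expr <- tidyr::expand_grid(
    compound_id = c("DMSO", "A"), dose_nM = c(125, 500, 2000),
    gene = c("ACTA2", "COL1A1", "TCF21", "LRAT", "LHX2")
  )
  expr$fold_change <- ifelse(expr$compound_id == "DMSO", 1, 0.5)
  wide <- expression_heatmap_table(expr)
  expect_equal(nrow(wide), 2)
  expect_equal(ncol(wide), 16)       # compound_id + 5 genes x 3 doses
  dmso <- unlist(wide[wide$compound_id == "DMSO", -1])
  expect_true(all(dmso == 1))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(wide))
})
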