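test_that("plate layout generation respects counts, capacity and seeding", {
  layout <- generate_plate_layout(360, n_neg = 16, n_pos = 8, seed = 1)
  expect_equal(nrow(layout), 384)
  expect_equal(sum(layout$kind == "negative_control"), 16)
  expect_equal(sum(layout$kind == "positive_control"), 8)
  expect_equal(sum(layout$kind == "compound"), 360)
  expect_false(any(duplicated(layout$well)))
  expect_true(all(layout$well %in% well_addresses()))
  # controls carry no compound id; compound wells carry a dose
  expect_true(all(is.na(layout$compound_id[layout$kind != "compound"])))
  expect_true(all(!is.na(layout$dose_nM[layout$kind == "compound"])))

  expect_error(generate_plate_layout(400, 16, 8, seed = 1), "capacity")
  expect_error(generate_plate_layout(10, n_neg = 1, n_pos = 8, seed = 1),
               "at least 2")

  expect_identical(
    generate_plate_layout(100, 16, 8, seed = 42),
    generate_plate_layout(100, 16, 8, seed = 42)
  )
  expect_false(identical(
    generate_plate_layout(100, 16, 8, seed = 1)$well[1:50],
    generate_plate_layout(100, 16, 8, seed = 2)$well[1:50]
  ))
})

test_that("rendered phenotypes separate: activated wells outscore deactivated ones", {
  score_of <- function(d, seed) {
    img <- render_well_image(small_sim_params(deactivation_level = d, seed = seed))
    measure_well(img, segment_actin_area(img))$actin_score
  }
  act <- vapply(1:20, function(s) score_of(0, s), numeric(1))
  dea <- vapply(1:20, function(s) score_of(1, s + 1000), numeric(1))
  expect_gt(mean(act), mean(dea))
})

test_that("expected Actin score decreases monotonically with deactivation level", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(levels, function(d) {
    mean(vapply(1:50, function(s) {
      img <- render_well_image(
        small_sim_params(deactivation_level = d, seed = 7000 + 50 * d * 100 + s)
      )
      measure_well(img, segment_actin_area(img))$actin_score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("degenerate renders behave: no cells, no fibers, bad geometry", {
  empty <- render_well_image(small_sim_params(cells_per_well = 0, seed = 1))
  m <- segment_actin_area(empty)
  expect_lt(sum(m) / length(m), 0.01)

  # fibers are the only score driver: without them the two phenotypes tie
  no_fib <- function(d, seed) {
    img <- render_well_image(small_sim_params(
      deactivation_level = d, fiber_intensity = 0, seed = seed
    ))
    measure_well(img, segment_actin_area(img))$actin_score
  }
  s0 <- vapply(1:15, function(s) no_fib(0, s), numeric(1))
  s1 <- vapply(1:15, function(s) no_fib(1, s + 500), numeric(1))
  expect_lt(abs(mean(s0) - mean(s1)) / mean(s0), 0.15)

  expect_error(sim_params(cell_radius_px = 50, image_size = 96), "geometry")
  expect_error(sim_params(deactivation_level = 1.2), "deactivation_level")
  expect_error(sim_params(image_size = 32), "64")
})

test_that("rendering is a pure function of parameters and seed", {
  p <- small_sim_params(deactivation_level = 0.3, seed = 11)
  expect_identical(render_well_image(p)$pixels, render_well_image(p)$pixels)
})

test_that("screen generation books ground truth deterministically", {
  scr <- generate_screen(1000, hit_fraction = 0.02, seed = 3)
  expect_equal(sum(scr$ground_truth$is_true_hit), 20)
  expect_equal(nrow(scr$ground_truth), 1000)
  expect_false(any(duplicated(scr$ground_truth$compound_id)))
  expect_true(all(scr$ground_truth$max_effect[!scr$ground_truth$is_true_hit] == 0))
  # every compound appears once per tier
  per_tier <- dplyr::count(
    dplyr::filter(scr$scores, kind == "compound"), tier
  )
  expect_equal(per_tier$n, c(1000, 1000))

  none <- generate_screen(200, hit_fraction = 0, seed = 1)
  expect_equal(sum(none$ground_truth$is_true_hit), 0)

  a <- generate_screen(300, 0.05, seed = 9)
  b <- generate_screen(300, 0.05, seed = 9)
  expect_identical(a$scores, b$scores)
})

test_that("Ct table generator implements the doubling model with a silent reference", {
  eff <- tibble::tibble(condition = "drug", gene = "ACTA2", log2fc = -2)
  ct <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"), eff,
                          ct_noise_sd = 0, n_replicates = 3, seed = 1)
  expect_equal(nrow(ct), 2 * 2 * 3)
  # -2 doublings raises Ct by 2 cycles relative to the baseline state
  base <- unique(ct$ct[ct$condition == "DMSO" & ct$gene == "ACTA2"])
  drug <- unique(ct$ct[ct$condition == "drug" & ct$gene == "ACTA2"])
  expect_equal(drug - base, 2)
  # reference gene identical across conditions at zero noise
  expect_equal(length(unique(ct$ct[ct$gene == "GAPDH"])), 1)

  expect_error(
    generate_ct_table("a", c("GAPDH", "X"),
                      tibble::tibble(condition = "a", gene = "NOPE", log2fc = 1)),
    "unknown gene"
  )
  expect_error(
    generate_ct_table("a", c("GAPDH", "X"),
                      tibble::tibble(condition = "a", gene = "GAPDH", log2fc = 1)),
    "reference gene"
  )
  expect_error(generate_ct_table("a", "ACTA2"), "reference")
})

test_that("expression generator reproduces the programmed group structure", {
  es <- generate_expression_matrix(seed = 1)
  expect_equal(dim(es$counts), c(509, 12))
  expect_identical(es$counts, generate_expression_matrix(seed = 1)$counts)

  # programmed mean profiles: deactivated cells resemble quiescent, not
  # activated, cells (computed from the stated program before noise)
  m <- es$mean_log2
  r_q <- brute_pearson(m[, "daHSC_d10"], m[, "qHSC_d0"])
  r_a <- brute_pearson(m[, "daHSC_d10"], m[, "aHSC_d7"])
  expect_gt(r_q, r_a)

  # NGFR is not restored on deactivation
  prog <- default_marker_program()
  ngfr <- prog[prog$gene == "NGFR", ]
  expect_lt(ngfr$daHSC_d10, ngfr$qHSC_d0 - 2)

  # zero dispersion gives deterministic rounded means
  es0 <- generate_expression_matrix(dispersion = 0, seed = 2)
  mu <- 2^es0$mean_log2[, es0$sample_groups]
  expect_equal(unname(es0$counts), unname(round(mu)))

  expect_error(generate_expression_matrix(group_design = c(s1 = "qHSC_d0")),
               "named|at least 2")
  bad <- setNames(rep(c("qHSC_d0", "aHSC_d7", "aHSC_d10", "weird"), each = 2),
                  paste0("s", 1:8))
  expect_error(generate_expression_matrix(group_design = bad), "unknown group")
})
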