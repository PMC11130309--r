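test_that("generation is bit-identical under a fixed seed and config", {
  cfg <- tiny_config(cells = 120, seed = 42)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(as.matrix(e1$counts), as.matrix(e2$counts))
  expect_identical(e1$cell_meta, e2$cell_meta)
})

test_that("doublet planting follows the configured rate and conserves counts", {
  e0 <- generate_experiment(tiny_config(cells = 150, seed = 3,
                                        doublet_rate = 0))
  expect_false(any(e0$cell_meta$is_doublet))

  e1 <- generate_experiment(tiny_config(cells = 200, seed = 3,
                                        doublet_rate = 0.1))
  expect_equal(sum(e1$cell_meta$is_doublet), 4 * round(0.1 * 200))
  expect_equal(nrow(e1$counts), 4 * 200)

  # doublet construction is the sum of the two parents' gene vectors
  m <- matrix(rpois(50, 5), 10, 5)
  d <- make_doublets(m, c(1, 3), c(2, 4))
  expect_identical(d[1, ], m[1, ] + m[2, ])
  expect_identical(d[2, ], m[3, ] + m[4, ])
})

test_that("per-sample type counts follow the configured multinomial", {
  cfg <- simulation_config(seed = 5, doublet_rate = 0)
  ex <- generate_experiment(cfg)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.10)
  counts <- tapply(ex$cell_meta$celltype == "TAM_C3", ex$cell_meta$sample, sum)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("marginal gene means match the configured mean model", {
  cfg <- simulation_config(
    n_samples_per_arm = c(sensitive_vehicle = 1),
    cells_per_sample = 1000,
    cell_type_fractions = c(malignant = 1),
    marker_table = default_marker_table()["malignant"],
    planted_programs = list(), doublet_rate = 0, seed = 9)
  ex <- generate_experiment(cfg)
  w <- ex$gene_meta$base_weight
  names(w) <- ex$gene_meta$symbol
  mk <- default_marker_table()$malignant
  w[names(mk)] <- w[names(mk)] * mk
  expected <- cfg$library_size_mean * w / sum(w)
  obs <- Matrix::colMeans(ex$counts)
  se <- apply(as.matrix(ex$counts), 2, sd) / sqrt(nrow(ex$counts))
  zdev <- abs(obs - expected) / pmax(se, 1e-9)
  expect_gt(mean(zdev < 3), 0.98)
  expect_true(all(zdev < 6))
})

test_that("configuration errors are caught", {
  expect_error(simulation_config(cells_per_sample = 10), "cells_per_sample")
  expect_error(simulation_config(
    cell_type_fractions = c(malignant = 0.9, TAM_C3 = 0.2),
    marker_table = default_marker_table()[c("malignant", "TAM_C3")],
    planted_programs = list()), "sum to 1")
  expect_error(simulation_config(
    marker_table = c(default_marker_table(), list(ghost = c(Xyz = 2)))),
    "unknown cell type")
  bad <- planted_program("Rps19", "C5ar1", "malignant", "not_a_type",
                         strength_by_arm = c(sensitive_vehicle = 1,
                                             sensitive_treated = 1,
                                             resistant_vehicle = 1,
                                             resistant_treated = 1))
  expect_error(simulation_config(planted_programs = list(bad)),
               "sender/receiver")
  expect_error(planted_program("A", "A", "x", "y", c(arm = 1)), "differ")
})

test_that("hashtag generation marks the true sample and refuses shared tags", {
  ex <- generate_experiment(tiny_config(cells = 80, seed = 2,
                                        doublet_rate = 0))
  # noiseless limit: zero background, argmax tag identifies the sample
  ht0 <- generate_hashtags(ex, signal_to_noise = 10, background_mean = 0,
                           seed = 1)
  top <- colnames(ht0)[max.col(ht0)]
  tag_of <- attr(ht0, "tag_of_sample")
  expect_identical(top, paste0("tag", tag_of[ex$cell_meta$sample]))

  expect_error(generate_hashtags(ex, n_tags = 2), "n_tags")
  expect_error(generate_hashtags(
    ex, tag_of_sample = c(sensitive_vehicle_1 = 1, sensitive_treated_1 = 1,
                          resistant_vehicle_1 = 2, resistant_treated_1 = 3)),
    "share")
})

test_that("cohort generator respects its contracts", {
  co <- generate_cohort(40, seed = 11)
  expect_true(all(co$time_days > 0))
  expect_true(all(co$event %in% c(0, 1)))
  expect_true(all(co$c5ar1_hi >= 0 & co$cd86_hi >= 0 & co$other >= 0))
  expect_identical(co, generate_cohort(40, seed = 11))
  expect_error(generate_cohort(5), "n_patients")
  expect_error(generate_cohort(20, baseline_hazard = 0), "baseline_hazard")
})

test_that("a strong ratio-hazard coefficient shortens high-quartile survival", {
  worse <- 0
  for (s in 1:25) {
    co <- generate_cohort(60, beta = 1.2, censor_rate = 0, seed = 200 + s)
    grp <- stratify_quartile(co$ratio)
    med <- tapply(co$time_days, grp, median)
    worse <- worse + (med[["high"]] < med[["rest"]])
  }
  expect_gte(worse, 24)
})

test_that("experiment and cohort writers produce readable text files", {
  ex <- generate_experiment(tiny_config(cells = 60, seed = 4,
                                        doublet_rate = 0))
  d <- withr::local_tempdir()
  write_experiment(ex, d)
  m <- Matrix::readMM(file.path(d, "counts.mtx"))
  expect_equal(dim(m), dim(ex$counts))
  cells <- read.delim(file.path(d, "cells.tsv"))
  expect_equal(nrow(cells), nrow(ex$cell_meta))

  co <- generate_cohort(12, seed = 1)
  f <- file.path(d, "cohort.csv")
  write_cohort(co, f)
  expect_equal(nrow(read.csv(f)), 12)
})
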