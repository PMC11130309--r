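test_that("cells are filtered on detected genes and mito content", {
  m <- qc_toy_matrix()
  expect_identical(filter_cells(m, qc_thresholds()),
                   c(TRUE, FALSE, FALSE, FALSE))
})

test_that("boundary cells are kept (strict-inequality exclusions)", {
  genes <- c(sprintf("g%04d", 1:1600), sprintf("mt-%03d", 1:400))
  boundary <- numeric(2000)
  boundary[seq_len(800)] <- 1      # 1000 genes detected in total,
  boundary[1600 + seq_len(200)] <- 1  # exactly 20% of UMIs mitochondrial
  m999 <- numeric(2000)
  m999[seq_len(999)] <- 1          # 999 genes, no mito
  m <- rbind(boundary, m999)
  colnames(m) <- genes
  expect_identical(unname(filter_cells(m, qc_thresholds())), c(TRUE, FALSE))
})

test_that("filtering is idempotent and warns without mito genes", {
  m <- matrix(rpois(200 * 1200, 2), 200, 1200,
              dimnames = list(NULL, sprintf("g%04d", 1:1200)))
  expect_warning(keep <- filter_cells(m, qc_thresholds(min_genes_detected = 100)),
                 "mito")
  m2 <- m[keep, , drop = FALSE]
  expect_warning(keep2 <- filter_cells(m2, qc_thresholds(min_genes_detected = 100)),
                 "mito")
  expect_true(all(keep2))
  expect_error(filter_cells(m[0, , drop = FALSE]), "empty")
})

test_that("normalization identities hold", {
  m <- matrix(0, 3, 4, dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  m[1, 2] <- 10
  m[2, ] <- c(1, 2, 3, 4)
  m[3, ] <- 2 * m[2, ]
  nm <- normalize_log(m, target_sum = 1e4)
  # single nonzero gene takes the whole library
  expect_equal(nm$values[1, 2], log1p(1e4))
  # pre-log row sums equal the target
  expect_equal(unname(rowSums(expm1(as.matrix(nm$values)))),
               rep(1e4, 3), tolerance = 1e-9)
  # depth scaling cancels
  expect_equal(unname(nm$values[2, ]), unname(nm$values[3, ]))

  m0 <- rbind(m, c0 = 0)
  expect_error(normalize_log(m0), "c0")
})

test_that("HVG selection is exact, deterministic and excludes constants", {
  set.seed(1)
  m <- matrix(rpois(300 * 50, 5), 300, 50,
              dimnames = list(NULL, sprintf("g%02d", 1:50)))
  m[, 50] <- 0   # never-detected gene stays constant after normalization
  nm <- normalize_log(m)
  mask_all <- select_hvg(nm, n_top = 50)
  expect_equal(sum(mask_all), 49)
  expect_false(mask_all["g50"])
  mask10 <- select_hvg(nm, n_top = 10)
  expect_equal(sum(mask10), 10)
  expect_identical(mask10, select_hvg(nm, n_top = 10))
  expect_error(select_hvg(nm, n_top = 0), "positive")
  expect_error(select_hvg(nm, n_top = 51), "exceeds")
})

test_that("planted marker genes are highly variable in synthetic data", {
  ex <- generate_experiment(tiny_config(cells = 250, seed = 6,
                                        doublet_rate = 0))
  nm <- normalize_log(ex$counts)
  mask <- select_hvg(nm, n_top = 80)
  markers <- c("Epcam", "Mrc1", "Pf4", "Cd3e", "Dcn")
  expect_true(all(mask[markers]))
})

test_that("doublet flagging respects the percentile cut and depth invariance", {
  set.seed(2)
  m <- matrix(rpois(150 * 300, 3), 150, 300,
              dimnames = list(NULL, sprintf("g%04d", 1:300)))
  none <- flag_doublets(m, qc_thresholds(doublet_score_percentile = 100),
                        seed = 1)
  expect_false(any(none$flag))
  # library-size normalization: doubling every cell's counts changes nothing
  s1 <- flag_doublets(m, seed = 7)
  s2 <- flag_doublets(2 * m, seed = 7)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
  expect_error(flag_doublets(m[1:50, ]), "100 cells")
})

test_that("planted doublets are recovered at a matched score cut", {
  hits <- fps <- 0
  for (s in 1:3) {
    ex <- generate_experiment(tiny_config(cells = 400, seed = 20 + s,
                                          doublet_rate = 0.10))
    fd <- flag_doublets(ex$counts,
                        qc_thresholds(doublet_score_percentile = 90),
                        seed = s)
    truth <- ex$cell_meta$is_doublet
    hits <- hits + sum(fd$flag & truth) / sum(truth)
    fps <- fps + sum(fd$flag & !truth) / sum(!truth)
  }
  expect_gte(hits / 3, 0.60)
  expect_lte(fps / 3, 0.10)
})

test_that("hashtag demultiplexing recovers samples and obeys the rules", {
  ex <- generate_experiment(tiny_config(cells = 200, seed = 8,
                                        doublet_rate = 0))
  tag_of <- NULL
  # clean signal: all cells assigned to their true sample
  ht <- generate_hashtags(ex, signal_to_noise = 50, background_mean = 2,
                          seed = 1)
  asg <- demux_hashtags(ht, seed = 1)
  truth <- paste0("tag", attr(ht, "tag_of_sample")[ex$cell_meta$sample])
  expect_true(mean(asg == truth, na.rm = TRUE) > 0.99)

  # realistic signal-to-noise of 10: at least 95% of cells correct
  ht10 <- generate_hashtags(ex, signal_to_noise = 10, background_mean = 20,
                            seed = 2)
  asg10 <- demux_hashtags(ht10, seed = 1)
  truth10 <- paste0("tag", attr(ht10, "tag_of_sample")[ex$cell_meta$sample])
  expect_gte(mean(asg10 == truth10, na.rm = TRUE) *
               mean(!is.na(asg10)), 0.95)

  # a community split 50/50 between two dominant tags stays unassigned
  asg_amb <- tamscreen:::tags_for_communities(
    dominant = rep(c(1L, 2L), 50), membership = rep(1L, 100),
    tag_names = c("tag1", "tag2"))
  expect_true(all(is.na(asg_amb)))

  amb <- matrix(rpois(200, 10), 100, 2,
                dimnames = list(NULL, c("tag1", "tag2")))
  expect_error(demux_hashtags(amb[, 1, drop = FALSE]), "two tags")
})
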