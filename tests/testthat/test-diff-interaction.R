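sig_table <- function(units, sig) {
  data.frame(pair_id = units$pair_id, sender = units$sender,
             receiver = units$receiver, strength = 1, p = 0.01,
             significant = sig, stringsAsFactors = FALSE)
}

one_unit <- data.frame(pair_id = "L_R", sender = "malignant",
                       receiver = "TAM_C3", stringsAsFactors = FALSE)

test_that("presence-mode pairwise calls follow the significance rule", {
  ta <- sig_table(one_unit, TRUE)
  tb <- sig_table(one_unit, FALSE)
  expect_identical(pairwise_delta(ta, tb)$call, "up")
  expect_identical(pairwise_delta(tb, ta)$call, "down")
  expect_identical(pairwise_delta(ta, ta)$call, "unchanged")
  expect_identical(pairwise_delta(tb, tb)$call, "unchanged")
})

test_that("strength-mode calls use the fold threshold", {
  mk <- function(s) {
    t <- sig_table(one_unit, TRUE)
    t$strength <- s
    t
  }
  expect_identical(pairwise_delta(mk(5), mk(2), mode = "strength",
                                  tau = 2)$call, "up")
  expect_identical(pairwise_delta(mk(2), mk(5), mode = "strength",
                                  tau = 2)$call, "down")
  expect_identical(pairwise_delta(mk(3), mk(2), mode = "strength",
                                  tau = 2)$call, "unchanged")
})

test_that("the maximal replicate design gives N = a x b", {
  ta <- lapply(1:2, function(i) sig_table(one_unit, TRUE))
  tb <- lapply(1:4, function(i) sig_table(one_unit, FALSE))
  res <- interaction_count(ta, tb)
  expect_equal(res$n_up, 8L)
  expect_equal(res$n_dn, 0L)
  expect_equal(res$N, 8L)
  expect_error(interaction_count(list(), tb), "at least one")
})

test_that("interaction counting matches brute-force enumeration exactly", {
  set.seed(11)
  for (rep in 1:30) {
    a <- sample(1:4, 1)
    b <- sample(1:4, 1)
    k <- sample(1:20, 1)
    units <- random_units(k)
    ta <- lapply(seq_len(a), function(i) random_sig_table(units))
    tb <- lapply(seq_len(b), function(i) random_sig_table(units))
    res <- interaction_count(ta, tb)
    oracle <- oracle_interaction_count(ta, tb)
    m <- match(res$unit, oracle$unit)
    expect_identical(res$N, oracle$N[m])
    expect_identical(res$n_up, oracle$n_up[m])
    # antisymmetry and bound
    swapped <- interaction_count(tb, ta)
    expect_identical(swapped$N[match(res$unit, swapped$unit)], -res$N)
    expect_true(all(abs(res$N) <= a * b))
    expect_true(all(res$n_up + res$n_dn <= a * b))
  }
})

test_that("receptor aggregation is linear over ligands", {
  units <- data.frame(pair_id = c("Rps19_C5ar1", "Hc_C5ar1"),
                      sender = "malignant", receiver = "TAM_C3",
                      stringsAsFactors = FALSE)
  # over a = b = 2 pairs: ligand 1 ends at N = 4, ligand 2 at N = -2
  mk <- function(sig1, sig2) sig_table(units, c(sig1, sig2))
  ta <- list(mk(TRUE, FALSE), mk(TRUE, FALSE))
  tb <- list(mk(FALSE, TRUE), mk(FALSE, FALSE))
  res <- interaction_count(ta, tb)
  expect_setequal(res$N, c(4L, -2L))
  agg <- aggregate_by_receptor(res, default_lr_db())
  expect_equal(nrow(agg), 1)
  expect_equal(agg$N, sum(res$N))
  expect_equal(agg$n_up, sum(res$n_up))

  # single-ligand receptors pass through unchanged
  single <- res[res$pair_id == "Rps19_C5ar1", ]
  class(single) <- class(res)
  agg1 <- aggregate_by_receptor(single, default_lr_db())
  expect_equal(agg1$N, single$N)

  bad <- res
  bad$pair_id <- c("Nope_X", "Hc_C5ar1")
  expect_error(aggregate_by_receptor(bad, default_lr_db()), "absent")
})

test_that("aggregation equals independent group-summing on random tables", {
  set.seed(21)
  units <- data.frame(
    pair_id = c("L1_R1", "L2_R1", "L3_R2"),
    sender = "malignant", receiver = "TAM_C3", stringsAsFactors = FALSE)
  db <- lr_database(data.frame(ligand = c("L1", "L2", "L3"),
                               receptor = c("R1", "R1", "R2")))
  ta <- lapply(1:3, function(i) random_sig_table(units))
  tb <- lapply(1:2, function(i) random_sig_table(units))
  res <- interaction_count(ta, tb)
  agg <- aggregate_by_receptor(res, db)
  manual <- tapply(res$N, db$receptor[match(res$pair_id, db$pair_id)], sum)
  expect_equal(stats::setNames(agg$N, agg$pair_id),
               stats::setNames(as.integer(manual), names(manual)))
})

test_that("the discordance screen thresholds, ranks and errors correctly", {
  mk_count <- function(units, N) {
    out <- data.frame(unit = paste(units$pair_id, units$sender,
                                   units$receiver, sep = "|"),
                      pair_id = units$pair_id, sender = units$sender,
                      receiver = units$receiver,
                      n_up = pmax(N, 0L), n_dn = pmax(-N, 0L), N = N,
                      stringsAsFactors = FALSE)
    class(out) <- c("interaction_count", "data.frame")
    out
  }
  units <- data.frame(pair_id = c("A_X", "B_Y", "C_Z"), sender = "m",
                      receiver = "t", stringsAsFactors = FALSE)
  sen <- mk_count(units, c(-8L, -2L, 0L))
  res <- mk_count(units, c(8L, 2L, 5L))
  s1 <- screen_discordant(sen, res, min_magnitude = 1)
  expect_identical(s1$pair_id, c("A_X", "B_Y"))   # ranked by delta
  s0 <- screen_discordant(sen, res, min_magnitude = 0)
  expect_true(all(s1$unit %in% s0$unit))          # threshold monotonicity
  s4 <- screen_discordant(sen, res, min_magnitude = 4)
  expect_identical(s4$pair_id, "A_X")

  other <- mk_count(data.frame(pair_id = "D_W", sender = "m", receiver = "t",
                               stringsAsFactors = FALSE), 1L)
  expect_error(screen_discordant(sen, other), "disjoint")
})
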