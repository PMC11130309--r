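# Independent oracle implementations used to cross-check the package.
# These deliberately use explicit enumeration / hand-rolled arithmetic and
# share no code with the implementation paths they verify.

# trimmed mean by explicit element removal
oracle_trimmed_mean <- function(x, trim = 0.1) {
  n <- length(x)
  k <- as.integer(ceiling(trim * n - 1e-9))
  if (2 * k >= n) return(sum(x) / n)
  xs <- x[order(x)]
  kept <- xs[seq.int(k + 1L, n - k)]
  sum(kept) / length(kept)
}

# brute-force replicate-pairwise counting: loops over every ordered
# (A sample, B sample) pair and every unit, presence mode
oracle_interaction_count <- function(tablesA, tablesB) {
  key <- function(t) paste(t$pair_id, t$sender, t$receiver, sep = "|")
  units <- sort(unique(unlist(c(lapply(tablesA, key), lapply(tablesB, key)))))
  res <- data.frame(unit = units, n_up = 0L, n_dn = 0L)
  for (u in seq_along(units)) {
    for (ta in tablesA) for (tb in tablesB) {
      sa <- ta$significant[match(units[u], key(ta))]
      sb <- tb$significant[match(units[u], key(tb))]
      sa <- isTRUE(sa)
      sb <- isTRUE(sb)
      if (sa && !sb) res$n_up[u] <- res$n_up[u] + 1L
      if (!sa && sb) res$n_dn[u] <- res$n_dn[u] + 1L
    }
  }
  res$N <- res$n_up - res$n_dn
  res
}

# explicit rank-table signature score: positions assigned by sorting, tie
# groups averaged by hand, cap applied afterwards
oracle_ucell <- function(v, set_idx, r_max) {
  ord <- order(v, decreasing = TRUE)
  pos <- integer(length(v))
  pos[ord] <- seq_along(v)
  rk <- numeric(length(v))
  for (val in unique(v)) {
    ties <- which(v == val)
    rk[ties] <- mean(pos[ties])
  }
  rk <- pmin(rk, r_max)
  n <- length(set_idx)
  u <- sum(rk[set_idx]) - n * (n + 1) / 2
  max(0, 1 - u / (n * r_max))
}

# spreadsheet-style two-group log-rank: walk the distinct event times,
# accumulate observed minus expected and the hypergeometric variance
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  o_minus_e^2 / v
}

# all-pairs concordance AUC, ties counted one half
oracle_auc <- function(score, positive) {
  sp <- score[positive]
  sn <- score[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# random interaction tables over k units for the counting tests
random_sig_table <- function(units, p_sig = 0.4) {
  data.frame(pair_id = units$pair_id, sender = units$sender,
             receiver = units$receiver,
             strength = stats::runif(nrow(units), 0, 5),
             p = stats::runif(nrow(units)),
             significant = stats::runif(nrow(units)) < p_sig,
             stringsAsFactors = FALSE)
}

random_units <- function(k) {
  data.frame(pair_id = paste0("L", seq_len(k), "_R", seq_len(k)),
             sender = sample(c("malignant", "TAM"), k, replace = TRUE),
             receiver = sample(c("TAM_C3", "TAM_C1"), k, replace = TRUE),
             stringsAsFactors = FALSE)
}

# a small, fast synthetic experiment used by several module tests
tiny_config <- function(cells = 300, seed = 1, ...) {
  simulation_config(
    n_samples_per_arm = c(sensitive_vehicle = 1, sensitive_treated = 1,
                          resistant_vehicle = 1, resistant_treated = 1),
    cells_per_sample = cells, seed = seed, ...)
}

# build a cell with a requested number of detected genes and mito fraction
qc_toy_matrix <- function() {
  genes <- c(sprintf("g%04d", 1:1600), sprintf("mt-%03d", 1:400))
  cell <- function(n_genes, mito_frac) {
    n_mito <- round(n_genes * mito_frac)
    v <- numeric(2000)
    v[seq_len(n_genes - n_mito)] <- 1
    if (n_mito > 0) v[1600 + seq_len(n_mito)] <- 1
    v
  }
  m <- rbind(cell(1500, 0.05), cell(800, 0.05),
             cell(1500, 0.25), cell(800, 0.25))
  colnames(m) <- genes
  m
}

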