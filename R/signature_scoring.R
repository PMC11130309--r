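#' Rank-based signature score per cell
#'
#' For each cell, all genes are ranked by expression in descending order
#' (ties get mid-ranks), ranks are capped at `r_max` after tie resolution,
#' and the score is the normalized Mann-Whitney statistic of the signature
#' genes' ranks:
#' `U = sum(R_i) - n (n + 1) / 2`, `score = max(0, 1 - U / (n * r_max))`.
#' A cell whose signature genes occupy the top `n` ranks scores 1; genes at
#' or beyond the rank cap floor the score at `(n + 1) / (2 * r_max)`. Being
#' rank-based, the score is invariant under any strictly monotone transform
#' of a cell's expression vector.
#'
#' @param values cell-by-gene expression matrix (any monotone scale).
#' @param gene_set non-empty character vector, a subset of the genes.
#' @param r_max rank cap.
#' @return numeric vector of per-cell scores in `[0, 1]`.
#' @export
ucell_score <- function(values, gene_set, r_max = 1500) {
  if (length(gene_set) == 0) stop("empty gene set")
  missing <- setdiff(gene_set, colnames(values))
  if (length(missing))
    stop("gene set not in gene universe: ", paste(missing, collapse = ", "))
  n <- length(gene_set)
  x <- as.matrix(values)
  set_idx <- match(gene_set, colnames(x))
  apply(x, 1L, function(v) {
    r <- rank(-v, ties.method = "average")
    r <- pmin(r, r_max)
    u <- sum(r[set_idx]) - n * (n + 1) / 2
    max(0, 1 - u / (n * r_max))
  })
}

#' Top differentially expressed genes per cluster
#'
#' Wilcoxon rank-sum of each cluster against the rest, per gene, on
#' normalized data; genes are ranked by the signed z statistic (high-in-
#' cluster first), ties broken by symbol.
#'
#' @param values cell-by-gene normalized expression.
#' @param clusters per-cell cluster labels.
#' @param n_top genes per cluster.
#' @return named list mapping cluster to its top gene symbols.
#' @export
top_degs <- function(values, clusters, n_top = 3) {
  x <- as.matrix(values)
  cl <- factor(clusters)
  genes <- colnames(x) %||% sprintf("g%05d", seq_len(ncol(x)))
  n <- nrow(x)
  ranks <- apply(x, 2L, rank, ties.method = "average")
  out <- list()
  for (l in levels(cl)) {
    in_cl <- cl == l
    n1 <- sum(in_cl)
    n2 <- n - n1
    r1 <- colSums(ranks[in_cl, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (n + 1) / 12)
    z <- (u - mu) / pmax(sigma, .Machine$double.eps)
    ord <- order(-z, genes)
    out[[l]] <- genes[ord[seq_len(min(n_top, length(genes)))]]
  }
  out
}

#' Cross-subcluster Z of signature scores within samples
#'
#' Subcluster mean scores are standardized (mean 0, sd 1) across the
#' subclusters of each sample. Samples with a single subcluster yield `NA`
#' and are flagged.
#'
#' @param scores per-cell signature scores.
#' @param subclusters,samples per-cell labels.
#' @return data.frame with `sample`, `subcluster`, `mean_score`, `z`,
#'   `degenerate`.
#' @export
score_rank_z <- function(scores, subclusters, samples) {
  df <- data.frame(score = scores, sub = as.character(subclusters),
                   sample = as.character(samples), stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(df$sample)) {
    d <- df[df$sample == s, ]
    m <- tapply(d$score, d$sub, mean)
    if (length(m) < 2) {
      warning("sample ", s, " has a single subcluster; Z undefined")
      z <- rep(NA_real_, length(m))
      degenerate <- TRUE
    } else {
      z <- as.numeric(scale(as.numeric(m)))
      degenerate <- FALSE
    }
    out[[s]] <- data.frame(sample = s, subcluster = names(m),
                           mean_score = as.numeric(m), z = z,
                           degenerate = degenerate,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binned-control pathway score per cell
#'
#' The per-cell mean expression of the gene set minus the mean of a control
#' set: for each signature gene, `n_ctrl` control genes are sampled from the
#' same mean-expression bin (signature genes excluded from the pool), so the
#' null expectation of the score is 0. If the universe is too small for
#' `n_bins` informative bins the bin count is reduced with a warning.
#'
#' @param values cell-by-gene normalized expression.
#' @param gene_set non-empty character vector of signature genes.
#' @param n_bins mean-expression bins.
#' @param n_ctrl control genes sampled per signature gene.
#' @param seed integer seed (control sampling).
#' @return numeric vector of per-cell scores.
#' @export
pathway_score <- function(values, gene_set, n_bins = 25, n_ctrl = 50,
                          seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  genes <- colnames(values)
  missing <- setdiff(gene_set, genes)
  if (length(missing))
    stop("gene set not in gene universe: ", paste(missing, collapse = ", "))
  m <- col_means(values)
  pool <- setdiff(genes, gene_set)
  if (length(pool) < 2 * length(gene_set))
    stop("control pool too small for this gene set")
  eff_bins <- min(n_bins, max(1L, floor(length(genes) / 10)))
  if (eff_bins < n_bins)
    warning("reduced bins from ", n_bins, " to ", eff_bins,
            " (small gene universe)")
  r <- rank(m, ties.method = "first")
  bin <- ceiling(r / (length(genes) / eff_bins))
  names(bin) <- genes
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      cand <- pool[bin[pool] == bin[g]]
      if (length(cand) == 0) cand <- pool
      sample(cand, min(n_ctrl, length(cand)))
    })))
  })
  set_mean <- if (length(gene_set) == 1) as.numeric(values[, gene_set]) else
    as.numeric(row_sums(values[, gene_set, drop = FALSE])) / length(gene_set)
  ctrl_mean <- as.numeric(row_sums(values[, ctrl, drop = FALSE])) / length(ctrl)
  set_mean - ctrl_mean
}

#' Pseudobulk profiles over a cell subset
#'
#' Per-sample mean expression of selected genes (or per-cell scores) over a
#' stated cell subset, e.g. all macrophages.
#'
#' @param values cell-by-gene normalized expression, or a named list of
#'   per-cell score vectors.
#' @param samples per-cell sample ids.
#' @param subset logical per-cell mask defining the cell subset (default:
#'   all cells).
#' @param genes genes (columns) to average; default all.
#' @return samples-by-variables matrix, subset definition recorded in
#'   `attr(, "subset_n")`.
#' @export
pseudobulk_profile <- function(values, samples, subset = NULL, genes = NULL) {
  if (is.list(values) && !is.data.frame(values))
    values <- do.call(cbind, values)
  subset <- subset %||% rep(TRUE, nrow(values))
  v <- values[subset, genes %||% colnames(values), drop = FALSE]
  s <- factor(samples[subset])
  out <- t(vapply(levels(s), function(l)
    col_means(v[s == l, , drop = FALSE]), numeric(ncol(v))))
  colnames(out) <- colnames(v)
  attr(out, "subset_n") <- sum(subset)
  out
}

#' Pairwise Pearson correlation across pseudobulk profiles
#'
#' Pearson r for every variable pair with a two-sided p-value from
#' `t = r*sqrt(n - 2)/sqrt(1 - r^2)`. A pair is significant when the
#' correlation exceeds `r_threshold` (its absolute value, with
#' `signed = FALSE`) and
#' `p < alpha`; both inequalities are strict. Zero-variance variables yield
#' `NA` and are flagged.
#'
#' @param profiles samples-by-variables matrix (>= 4 samples).
#' @param r_threshold,alpha significance thresholds.
#' @param signed if `TRUE` only positive correlations can be significant.
#' @return list with matrices `r`, `p`, `significant`, and
#'   `zero_variance` (logical per variable).
#' @export
pseudobulk_correlation <- function(profiles, r_threshold = 0.3, alpha = 0.05,
                                   signed = TRUE) {
  n <- nrow(profiles)
  if (n < 4) stop("at least 4 samples are required")
  v <- apply(profiles, 2, stats::var)
  zero_var <- v == 0
  r <- suppressWarnings(stats::cor(profiles))
  r[zero_var, ] <- NA
  r[, zero_var] <- NA
  diag(r) <- ifelse(zero_var, NA, 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sig <- if (signed) r > r_threshold & p < alpha else
    abs(r) > r_threshold & p < alpha
  sig[is.na(sig)] <- FALSE
  diag(sig) <- !zero_var   # self-correlation: trivially significant
  list(r = r, p = p, significant = sig, zero_variance = zero_var)
}
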