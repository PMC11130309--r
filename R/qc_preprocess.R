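#' Cell-level QC thresholds
#'
#' Default filters: cells with fewer than 1000 detected
#' genes or more than 20% mitochondrial UMIs are excluded; doublet flagging
#' uses a 6% expected rate and a 95th-percentile score cut. `min_umi` is an
#' optional extra total-count filter (off by default; the detected-genes rule
#' is the primary filter).
#'
#' @param min_genes_detected minimum detected genes per kept cell.
#' @param max_mito_fraction maximum mitochondrial UMI fraction (strict
#'   "more than" exclusion), in (0, 1).
#' @param mito_gene_prefix prefix identifying mitochondrial genes.
#' @param expected_doublet_rate expected doublet fraction, in [0, 0.5).
#' @param doublet_score_percentile percentile of doublet scores above which a
#'   cell is flagged.
#' @param min_umi optional minimum total UMI per cell (`NULL` disables).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes_detected = 1000,
                          max_mito_fraction = 0.20,
                          mito_gene_prefix = "mt-",
                          expected_doublet_rate = 0.06,
                          doublet_score_percentile = 95,
                          min_umi = NULL) {
  if (max_mito_fraction <= 0 || max_mito_fraction >= 1)
    stop("max_mito_fraction must be in (0, 1)")
  if (expected_doublet_rate < 0 || expected_doublet_rate >= 0.5)
    stop("expected_doublet_rate must be in [0, 0.5)")
  if (doublet_score_percentile < 0 || doublet_score_percentile > 100)
    stop("doublet_score_percentile must be in [0, 100]")
  structure(list(min_genes_detected = min_genes_detected,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix,
                 expected_doublet_rate = expected_doublet_rate,
                 doublet_score_percentile = doublet_score_percentile,
                 min_umi = min_umi), class = "qc_thresholds")
}

#' Filter cells on detected genes and mitochondrial content
#'
#' A cell is kept iff it has at least `min_genes_detected` detected genes and
#' a mitochondrial UMI fraction of at most `max_mito_fraction` (boundary
#' cells are kept: exclusion is strictly "fewer than" / "more than").
#'
#' @param counts cell-by-gene nonnegative count matrix (dense or sparse),
#'   with gene symbols as column names.
#' @param thresholds a [qc_thresholds()].
#' @return logical kept-cell mask of length `nrow(counts)`.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  genes_detected <- row_sums(counts > 0)
  total <- row_sums(counts)
  mito <- startsWith(colnames(counts) %||% character(),
                     thresholds$mito_gene_prefix)
  if (!any(mito)) {
    warning("no mitochondrial genes matched prefix '",
            thresholds$mito_gene_prefix, "'; mito filter passes all cells")
    mito_frac <- rep(0, nrow(counts))
  } else {
    mito_frac <- row_sums(counts[, mito, drop = FALSE]) / pmax(total, 1)
  }
  keep <- genes_detected >= thresholds$min_genes_detected &
    mito_frac <= thresholds$max_mito_fraction
  if (!is.null(thresholds$min_umi)) keep <- keep & total >= thresholds$min_umi
  unname(keep)
}

#' Score and flag likely doublets
#'
#' A simplified simulated-doublet nearest-neighbor score: a pool of
#' artificial doublets (sums of random cell pairs) is embedded together with
#' the observed cells in a PCA of log-normalized highly variable genes. For
#' each cell, `f` is the fraction of artificial doublets among its k nearest
#' neighbors in the combined embedding; the likelihood-ratio-normalized
#' fraction `q = (f / rho) / (f / rho + (1 - f) / (1 - rho))` (rho the pool
#' share of the embedding) is converted to a posterior score using
#' `expected_doublet_rate` as the prior. Cells scoring above the
#' `doublet_score_percentile` of all scores are flagged. Scores are computed
#' on library-size-normalized data, so they are invariant to per-cell depth
#' scaling.
#'
#' @param counts cell-by-gene count matrix (>= 100 cells).
#' @param thresholds a [qc_thresholds()].
#' @param seed integer seed (doublet pool).
#' @param n_hvg,n_pcs embedding sizes.
#' @param k neighbors; default `sqrt(n)` clamped to `[10, 100]`.
#' @param sim_pool_ratio artificial-doublet pool size as a fraction of the
#'   number of cells.
#' @return data.frame with per-cell `score` and logical `flag`.
#' @export
flag_doublets <- function(counts, thresholds = qc_thresholds(), seed = 1L,
                          n_hvg = 200, n_pcs = 20, k = NULL,
                          sim_pool_ratio = 0.5) {
  n <- nrow(counts)
  if (n < 100) stop("at least 100 cells are required to simulate doublets")
  k <- k %||% max(10L, min(100L, as.integer(round(sqrt(n)))))
  with_seed(seed, {
    n_sim <- as.integer(round(sim_pool_ratio * n))
    p1 <- sample.int(n, n_sim, replace = TRUE)
    p2 <- sample.int(n, n_sim, replace = TRUE)
    sim <- counts[p1, , drop = FALSE] + counts[p2, , drop = FALSE]

    norm_all <- normalize_log(rbind2_any(counts, sim))
    hvg <- select_hvg(norm_all, n_top = min(n_hvg, ncol(counts)))
    x <- as.matrix(norm_all$values[, hvg, drop = FALSE])
    xc <- scale(x, center = TRUE, scale = FALSE)
    pcs <- min(n_pcs, ncol(xc) - 1L)
    pr <- stats::prcomp(xc[seq_len(n), , drop = FALSE], rank. = pcs,
                        center = FALSE)
    comb <- rbind(pr$x, xc[n + seq_len(n_sim), , drop = FALSE] %*% pr$rotation)

    f <- knn_label_fraction_cpp(
      comb[seq_len(n), , drop = FALSE], comb,
      labels = c(rep(0L, n), rep(1L, n_sim)), k = k,
      self_index = seq_len(n) - 1L)
    rho <- n_sim / (n_sim + n - 1)
    q <- (f / rho) / (f / rho + (1 - f) / (1 - rho))
    e <- thresholds$expected_doublet_rate
    score <- if (e > 0) q * e / (q * e + (1 - q) * (1 - e)) else q
    cut <- stats::quantile(score, thresholds$doublet_score_percentile / 100,
                           type = 7, names = FALSE)
    data.frame(score = score, flag = score > cut)
  })
}

# rbind that tolerates a mix of base and Matrix matrices
rbind2_any <- function(a, b) {
  if (inherits(a, "Matrix") || inherits(b, "Matrix"))
    rbind(Matrix::Matrix(a, sparse = TRUE), Matrix::Matrix(b, sparse = TRUE))
  else rbind(a, b)
}

#' Demultiplex cells from hashtag-oligo counts
#'
#' Cells are clustered on log-normalized tag counts with Louvain community
#' detection on a shared k-nearest-neighbor graph at the given resolution.
#' A community is assigned to tag `t` iff `t` is the dominant (argmax) tag
#' for at least `dominance_fraction` of its cells; communities without such
#' an exclusively dominant tag are left unassigned.
#'
#' @param hashtags cell-by-tag nonnegative count matrix (>= 2 tags).
#' @param resolution Louvain resolution.
#' @param dominance_fraction exclusivity threshold for assigning a community.
#' @param k neighbors for the kNN graph.
#' @param seed integer seed (community detection).
#' @return character vector of tag names per cell (`NA` = unassigned).
#' @export
demux_hashtags <- function(hashtags, resolution = 1.2,
                           dominance_fraction = 0.9, k = 15, seed = 1L) {
  if (ncol(hashtags) < 2) stop("at least two tags are required")
  n <- nrow(hashtags)
  tot <- pmax(row_sums(hashtags), 1)
  x <- log1p(as.matrix(hashtags) / tot * 100)
  k <- min(k, n - 1L)
  # block-wise kNN on the (low-dimensional) tag space
  t2 <- rowSums(x^2)
  nbr <- matrix(0L, n, k)
  block <- 1000L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(x[idx, , drop = FALSE]^2), t2, "+") -
      2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nbr[idx, ] <- t(apply(d2, 1L, function(v) order(v)[seq_len(k)]))
  }
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution)$membership)
  dominant <- max.col(x, ties.method = "first")
  dominant[row_sums(hashtags) == 0] <- NA
  tags_for_communities(dominant, comm, colnames(hashtags),
                       dominance_fraction)
}

# assign each community to its exclusively dominant tag, or NA; a community
# split between tags (e.g. 50/50) stays unassigned
tags_for_communities <- function(dominant, membership, tag_names,
                                 dominance_fraction = 0.9) {
  out <- rep(NA_character_, length(dominant))
  for (cl in unique(membership)) {
    cells <- which(membership == cl)
    tab <- table(factor(dominant[cells], levels = seq_along(tag_names)))
    top <- which.max(tab)
    if (tab[top] / length(cells) >= dominance_fraction)
      out[cells] <- tag_names[top]
  }
  out
}

#' Size-normalize and log-transform counts
#'
#' Scales each cell's counts to `target_sum` and applies `log1p`.
#'
#' @param counts cell-by-gene count matrix; no all-zero cells allowed.
#' @param target_sum per-cell total after scaling.
#' @return an object of class `normalized_matrix`: list with `values`
#'   (same shape as `counts`), `target_sum` and an initially `NULL`
#'   `hvg_mask`.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  if (target_sum <= 0) stop("target_sum must be positive")
  tot <- row_sums(counts)
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    ids <- rownames(counts)[bad] %||% as.character(bad)
    stop("all-zero cell(s): ", paste(utils::head(ids, 5), collapse = ", "))
  }
  values <- if (inherits(counts, "Matrix")) {
    log1p(Matrix::Diagonal(x = target_sum / tot) %*% counts)
  } else {
    log1p(counts / tot * target_sum)
  }
  rownames(values) <- rownames(counts)
  colnames(values) <- colnames(counts)
  structure(list(values = values, target_sum = target_sum, hvg_mask = NULL),
            class = "normalized_matrix")
}

#' Select highly variable genes
#'
#' Genes are ranked by a binned dispersion statistic: the variance/mean
#' dispersion of the log-normalized values is z-scored within bins of
#' similar mean expression, and the top `n_top` genes are selected. Constant
#' genes are never selected; ties are broken by gene symbol so the selection
#' is deterministic.
#'
#' @param normalized a [normalize_log()] result (or a plain matrix of
#'   normalized values).
#' @param n_top number of genes to select (`0 < n_top <=` number of genes).
#' @param n_bins mean-expression bins for dispersion normalization.
#' @return named logical mask over genes with exactly
#'   `min(n_top, #non-constant genes)` `TRUE` entries.
#' @export
select_hvg <- function(normalized, n_top = 4000, n_bins = 20) {
  values <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  if (n_top <= 0) stop("n_top must be positive")
  if (n_top > ncol(values)) stop("n_top exceeds the number of genes")
  m <- col_means(values)
  v <- col_vars(values)
  genes <- colnames(values) %||% sprintf("g%05d", seq_along(m))
  eligible <- v > 0 & m > 0
  disp <- rep(NA_real_, length(m))
  disp[eligible] <- v[eligible] / m[eligible]
  z <- rep(-Inf, length(m))
  if (any(eligible)) {
    r <- rank(m[eligible], ties.method = "first")
    bins <- ceiling(r / (sum(eligible) / min(n_bins, sum(eligible))))
    ze <- disp[eligible]
    for (b in unique(bins)) {
      in_b <- bins == b
      mu <- mean(ze[in_b])
      sdv <- stats::sd(ze[in_b])
      ze[in_b] <- if (is.na(sdv) || sdv == 0) 0 else (ze[in_b] - mu) / sdv
    }
    z[eligible] <- ze
  }
  ord <- order(-z, genes)
  n_sel <- min(n_top, sum(eligible))
  mask <- stats::setNames(rep(FALSE, length(m)), genes)
  if (n_sel > 0) mask[ord[seq_len(n_sel)]] <- TRUE
  mask
}
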