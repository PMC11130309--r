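#' Build a ligand-receptor pair database
#'
#' @param pairs data.frame with `ligand` and `receptor` columns; duplicate
#'   (ligand, receptor) rows are not allowed, but many ligands may share one
#'   receptor.
#' @return data.frame of class `lr_database` with an added `pair_id`.
#' @export
lr_database <- function(pairs) {
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stop("pairs must have 'ligand' and 'receptor' columns")
  if (nrow(pairs) == 0) stop("empty ligand-receptor database")
  key <- paste(pairs$ligand, pairs$receptor)
  if (anyDuplicated(key)) stop("duplicate (ligand, receptor) rows")
  pairs$pair_id <- paste(pairs$ligand, pairs$receptor, sep = "_")
  class(pairs) <- c("lr_database", "data.frame")
  pairs
}

#' Bundled mouse ligand-receptor pair set
#'
#' A small curated mouse subset covering the tumor-macrophage axes relevant
#' here (Rps19/Hc-C5ar1, Csf1-Csf1r, Cx3cl1-Cx3cr1, Ccl7-Ccr2, Lgals9-Ptprc
#' and several T/NK co-stimulation pairs). Shipped as a two-column TSV under
#' `extdata`.
#'
#' @return an `lr_database`.
#' @export
default_lr_db <- function() {
  path <- system.file("extdata", "lr_pairs_mouse.tsv", package = "tamscreen",
                      mustWork = TRUE)
  lr_database(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Genes expressed by more than a given fraction of cells
#'
#' @param x cell-by-gene matrix for the cells of one type.
#' @param min_fraction strict detection-fraction threshold (a gene detected
#'   in exactly this fraction of cells is excluded).
#' @param min_cells minimum number of cells required; with fewer the type is
#'   skipped (`NULL` returned) with a warning.
#' @return character vector of gene symbols, or `NULL` when skipped.
#' @export
expressed_genes <- function(x, min_fraction = 0.10, min_cells = 10) {
  if (nrow(x) < min_cells) {
    warning("type skipped: ", nrow(x), " cells < min_cells = ", min_cells)
    return(NULL)
  }
  frac <- col_means(x > 0)
  colnames(x)[frac > min_fraction]
}

#' Ligand-receptor interaction strength
#'
#' The product of the trimmed mean ligand expression in sender cells and the
#' trimmed mean receptor expression in receiver cells, where the trimmed
#' mean averages the central `1 - 2 * trim` fraction of cells ranked by that
#' gene's expression. If either gene fails the expression gate
#' ([expressed_genes()]) in its compartment, the strength is 0.
#'
#' @param ligand,receptor gene symbols.
#' @param sender,receiver cell-by-gene normalized expression matrices.
#' @param trim per-tail trim fraction.
#' @param min_fraction,min_cells expression gate parameters.
#' @return a single nonnegative number.
#' @export
interaction_strength <- function(ligand, receptor, sender, receiver,
                                 trim = 0.10, min_fraction = 0.10,
                                 min_cells = 10) {
  eg_s <- expressed_genes(sender, min_fraction, min_cells)
  eg_r <- expressed_genes(receiver, min_fraction, min_cells)
  if (is.null(eg_s) || is.null(eg_r)) return(0)
  if (!(ligand %in% eg_s) || !(receptor %in% eg_r)) return(0)
  trimmed_mean(as.numeric(sender[, ligand]), trim) *
    trimmed_mean(as.numeric(receiver[, receptor]), trim)
}

#' Permutation test for one ligand-receptor strength
#'
#' Sender/receiver labels are shuffled over the union of the two
#' compartments; the p-value is the pseudo-count estimator
#' `(1 + #\{permuted strength >= observed\}) / (1 + n_perm)`. An observed
#' strength of 0 returns p = 1 without permuting.
#'
#' @param ligand_values,receptor_values expression of the two genes over the
#'   union of sender and receiver cells (same cell order).
#' @param sender_mask logical; `TRUE` marks sender cells.
#' @param n_perm number of permutations (>= 100).
#' @param trim per-tail trim fraction.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `n_perm`.
#' @export
lr_permutation_test <- function(ligand_values, receptor_values, sender_mask,
                                n_perm = 1000, trim = 0.10, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- length(sender_mask)
  stopifnot(length(ligand_values) == n, length(receptor_values) == n)
  n_s <- sum(sender_mask)
  if (n_s == 0 || n_s == n) stop("both compartments must be non-empty")
  ord <- c(which(sender_mask), which(!sender_mask))
  observed <- trimmed_mean(ligand_values[sender_mask], trim) *
    trimmed_mean(receptor_values[!sender_mask], trim)
  if (observed == 0)
    return(list(p = 1, observed = 0, n_perm = n_perm))
  x <- cbind(ligand_values[ord], receptor_values[ord])
  p <- with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) sample.int(n) - 1L,
                   integer(n))
    pm <- perm_trimmed_means_cpp(x, perm, n_s, trim)
    strength_perm <- pm$sender[1, ] * pm$receiver[2, ]
    (1 + sum(strength_perm >= observed)) / (1 + n_perm)
  })
  list(p = p, observed = observed, n_perm = n_perm)
}

#' Call ligand-receptor interactions for one sample
#'
#' For every database pair and every ordered (sender type, receiver type)
#' combination with both genes passing the expression gate, computes the
#' trimmed-mean interaction strength and a permutation p-value (labels
#' shuffled jointly over the union of the two compartments, one shared set
#' of permutations per compartment pair). Types with fewer than `min_cells`
#' cells are skipped with a warning.
#'
#' @param normalized a [normalize_log()] result or a cell-by-gene matrix of
#'   normalized values.
#' @param cell_types character vector of per-cell type labels (`NA` ignored).
#' @param lr_db an [lr_database()].
#' @param senders,receivers type labels to test (defaults: all labels).
#' @param alpha significance level.
#' @param n_perm permutations per compartment pair (>= 100).
#' @param trim per-tail trim fraction.
#' @param min_fraction,min_cells expression gate parameters.
#' @param seed integer seed.
#' @return data.frame of class `interaction_table`: `pair_id`, `ligand`,
#'   `receptor`, `sender`, `receiver`, `strength`, `p`, `significant`.
#' @export
call_interactions <- function(normalized, cell_types, lr_db = default_lr_db(),
                              senders = NULL, receivers = NULL,
                              alpha = 0.05, n_perm = 1000, trim = 0.10,
                              min_fraction = 0.10, min_cells = 10,
                              seed = 1L) {
  if (!inherits(lr_db, "lr_database")) lr_db <- lr_database(lr_db)
  values <- if (inherits(normalized, "normalized_matrix"))
    normalized$values else normalized
  stopifnot(nrow(values) == length(cell_types))
  if (n_perm < 100) stop("n_perm must be >= 100")

  tab <- table(cell_types[!is.na(cell_types)])
  present <- names(tab)[tab >= min_cells]
  skipped <- setdiff(names(tab), present)
  if (length(skipped))
    warning("types skipped (fewer than ", min_cells, " cells): ",
            paste(skipped, collapse = ", "))
  senders <- intersect(senders %||% present, present)
  receivers <- intersect(receivers %||% present, present)

  expr_sets <- lapply(stats::setNames(union(senders, receivers),
                                      union(senders, receivers)),
                      function(t) {
    idx <- which(cell_types == t)
    suppressWarnings(expressed_genes(values[idx, , drop = FALSE],
                                     min_fraction, min_cells))
  })

  rows <- list()
  with_seed(seed, {
    for (s in senders) for (r in receivers) {
      if (s == r) next
      pass <- lr_db$ligand %in% expr_sets[[s]] &
        lr_db$receptor %in% expr_sets[[r]]
      if (!any(pass)) next
      db <- lr_db[pass, , drop = FALSE]
      idx_s <- which(cell_types == s)
      idx_r <- which(cell_types == r)
      idx <- c(idx_s, idx_r)
      genes <- unique(c(db$ligand, db$receptor))
      x <- as.matrix(values[idx, genes, drop = FALSE])
      n_s <- length(idx_s)
      tm_s <- apply(x[seq_len(n_s), , drop = FALSE], 2, trimmed_mean, trim)
      tm_r <- apply(x[-seq_len(n_s), , drop = FALSE], 2, trimmed_mean, trim)
      strength <- tm_s[db$ligand] * tm_r[db$receptor]
      p <- rep(1, nrow(db))
      live <- strength > 0
      if (any(live)) {
        perm <- vapply(seq_len(n_perm),
                       function(b) sample.int(length(idx)) - 1L,
                       integer(length(idx)))
        pm <- perm_trimmed_means_cpp(x, perm, n_s, trim)
        rownames(pm$sender) <- rownames(pm$receiver) <- genes
        sp <- pm$sender[db$ligand[live], , drop = FALSE] *
          pm$receiver[db$receptor[live], , drop = FALSE]
        p[live] <- (1 + rowSums(sp >= strength[live])) / (1 + n_perm)
      }
      rows[[paste(s, r)]] <- data.frame(
        pair_id = db$pair_id, ligand = db$ligand, receptor = db$receptor,
        sender = s, receiver = r,
        strength = unname(strength), p = p,
        significant = p <= alpha & strength > 0,
        stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), ligand = character(),
               receptor = character(), sender = character(),
               receiver = character(), strength = numeric(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  class(out) <- c("interaction_table", "data.frame")
  out
}
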