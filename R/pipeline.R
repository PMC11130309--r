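#' Annotate an experiment with marker rules
#'
#' Runs the cluster-level rule cascade: lineage rules over all clusters,
#' myeloid subtype rules over the monocyte/macrophage clusters, and the
#' C5ar1 hi/lo split within TAM_C3 cells. Expression clustering itself is an
#' input: `clusters` can be any partition of the cells (for synthetic
#' experiments the generator's anonymized partition is the natural choice,
#' so the result measures the rules rather than a clustering algorithm).
#' Malignant clusters are identified from `malignant_mask` (the stand-in for
#' CNV-based calling) by majority vote.
#'
#' @param counts cell-by-gene counts (for the detection-based C5ar1 split).
#' @param values cell-by-gene normalized expression.
#' @param clusters per-cell cluster ids.
#' @param malignant_mask logical per-cell malignant indicator.
#' @param samples per-cell sample ids.
#' @param rules,subtype_rules rule sets, see [lineage_rules()] and
#'   [myeloid_rules()].
#' @return data.frame of class `annotation_result`: per-cell `cluster`,
#'   `lineage`, `subtype`, `label` (subtype where available, else lineage)
#'   and `c5ar1_class` (`hi`/`lo` for TAM_C3 cells, `n/a` otherwise).
#' @export
annotate_cells <- function(counts, values, clusters, malignant_mask,
                           samples, rules = lineage_rules(),
                           subtype_rules = myeloid_rules()) {
  cl <- as.character(clusters)
  prof <- cluster_profiles(values, cl)
  lineage_by_cl <- assign_lineage(prof, rules)
  mal_frac <- tapply(malignant_mask, cl, mean)
  mal_cl <- names(mal_frac)[mal_frac > 0.5]
  lineage_by_cl[mal_cl] <- "malignant"
  my_cl <- names(lineage_by_cl)[lineage_by_cl == "monocyte/macrophage"]
  subtype_by_cl <- stats::setNames(rep(NA_character_, nrow(prof)),
                                   rownames(prof))
  if (length(my_cl) > 0)
    subtype_by_cl[my_cl] <- subtype_myeloid(
      prof[my_cl, , drop = FALSE], subtype_rules)
  lineage <- unname(lineage_by_cl[cl])
  subtype <- unname(subtype_by_cl[cl])
  label <- ifelse(is.na(subtype), lineage, subtype)
  c5 <- rep("n/a", length(cl))
  is_c3 <- !is.na(subtype) & subtype == "TAM_C3"
  if (any(is_c3) && "C5ar1" %in% colnames(counts))
    c5[is_c3] <- split_c5ar1(counts[is_c3, , drop = FALSE])
  out <- data.frame(cluster = cl, sample = samples, lineage = lineage,
                    subtype = subtype, label = label, c5ar1_class = c5,
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(values)
  class(out) <- c("annotation_result", "data.frame")
  out
}

#' End-to-end discordant-interaction screen on a synthetic experiment
#'
#' Runs the full chain on a [generate_experiment()] result: cell filtering,
#' doublet flagging, normalization and HVG selection, marker-rule
#' annotation, per-sample permutation interaction calling between malignant
#' senders and myeloid receivers, replicate-pairwise interaction counting
#' for the treated-vs-vehicle contrast within each model, and the
#' discordance screen (up in the resistant contrast, down in the sensitive
#' contrast).
#'
#' @param experiment a `synthetic_experiment`.
#' @param lr_db ligand-receptor database.
#' @param qc [qc_thresholds()]; the default is scaled to the synthetic gene
#'   universe (~240 genes), not the full-transcriptome defaults.
#' @param senders,receivers annotated type labels to test.
#' @param n_perm,alpha,trim interaction-caller parameters.
#' @param min_magnitude screen threshold on |N| per contrast.
#' @param n_top_hvg HVG count recorded on the normalized matrix.
#' @param remove_doublets drop flagged cells before analysis.
#' @param contrasts named list of `c(treated_arm, vehicle_arm)` pairs for the
#'   `sensitive` and `resistant` contrasts.
#' @param seed integer seed driving QC and the permutation caller.
#' @return list with `annotation`, `tables` (per-sample interaction tables),
#'   `count_sensitive`, `count_resistant`, `screen`, `kept` (QC mask) and
#'   `hvg`.
#' @export
run_screen_pipeline <- function(
    experiment,
    lr_db = default_lr_db(),
    qc = qc_thresholds(min_genes_detected = 100),
    senders = "malignant",
    receivers = c("TAM_C0", "TAM_C1", "TAM_C3", "TAM_C4",
                  "Mono_C2", "Mono_C5"),
    n_perm = 1000, alpha = 0.05, trim = 0.10, min_magnitude = 1,
    n_top_hvg = 150, remove_doublets = TRUE,
    contrasts = list(sensitive = c("sensitive_treated", "sensitive_vehicle"),
                     resistant = c("resistant_treated", "resistant_vehicle")),
    seed = 1L) {
  counts <- experiment$counts
  meta <- experiment$cell_meta

  kept <- filter_cells(counts, qc)
  if (remove_doublets) {
    db_flags <- flag_doublets(counts[kept, , drop = FALSE], qc, seed = seed)
    kept[kept] <- !db_flags$flag
  }
  counts <- counts[kept, , drop = FALSE]
  meta <- meta[kept, , drop = FALSE]

  norm <- normalize_log(counts)
  norm$hvg_mask <- select_hvg(norm, n_top = min(n_top_hvg, ncol(counts)))

  clusters <- paste0("cl", as.integer(factor(meta$celltype)))
  annotation <- annotate_cells(counts, norm$values, clusters,
                               malignant_mask = meta$celltype == "malignant",
                               samples = meta$sample)

  samples <- unique(meta$sample)
  tables <- list()
  for (i in seq_along(samples)) {
    idx <- meta$sample == samples[i]
    tables[[samples[i]]] <- call_interactions(
      norm$values[idx, , drop = FALSE], annotation$label[idx], lr_db,
      senders = senders, receivers = receivers,
      alpha = alpha, n_perm = n_perm, trim = trim,
      seed = seed + i)
  }

  arm_of <- stats::setNames(meta$arm[match(samples, meta$sample)], samples)
  count_for <- function(contrast) {
    a_ids <- samples[arm_of == contrast[1]]
    b_ids <- samples[arm_of == contrast[2]]
    interaction_count(tables[a_ids], tables[b_ids],
                      comparison_design(a_ids, b_ids, mode = "presence"))
  }
  count_sensitive <- count_for(contrasts$sensitive)
  count_resistant <- count_for(contrasts$resistant)
  screen <- screen_discordant(count_sensitive, count_resistant,
                              min_magnitude = min_magnitude)
  list(annotation = annotation, tables = tables,
       count_sensitive = count_sensitive,
       count_resistant = count_resistant,
       screen = screen, kept = kept, hvg = norm$hvg_mask)
}
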