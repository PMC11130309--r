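#' Build a marker rule
#'
#' A rule matches a cluster when every `high` marker is expressed, at least
#' one `any` marker (if given) is expressed, and no `low` marker is
#' expressed.
#'
#' @param label label assigned on match.
#' @param high markers that must all be expressed.
#' @param any markers of which at least one must be expressed.
#' @param low markers that must not be expressed.
#' @return an object of class `marker_rule`.
#' @export
marker_rule <- function(label, high = character(), any = character(),
                        low = character()) {
  structure(list(label = label, high = high, any = any, low = low),
            class = "marker_rule")
}

#' Default lineage rules
#'
#' The murine tumor lineage rule table, in listing order (first match wins):
#' central memory T (Ptprc/Cd3e/Cd4/Tcf7), regulatory T (.../Foxp3), naive
#' CD8 T (.../Cd8a/Ccr7), proliferative T (.../Mki67), NK (Ncr1/Nkg7),
#' B (Cd79a/Cd19), plasmacytoid DC (Clec10a/Siglech/Cd300c), fibroblast
#' (Dcn or Acta2), endothelial (Epas1), and monocyte/macrophage
#' (Itgam/Cd14/Adgre1). Malignant cells are identified separately (by CNV in
#' the original workflow; by a caller-provided mask here).
#'
#' @return list of [marker_rule()]s.
#' @export
lineage_rules <- function() {
  list(
    marker_rule("Tcm", high = c("Ptprc", "Cd3e", "Cd4", "Tcf7")),
    marker_rule("Treg", high = c("Ptprc", "Cd3e", "Cd4", "Foxp3")),
    marker_rule("CD8_Tn", high = c("Ptprc", "Cd3e", "Cd8a", "Ccr7")),
    marker_rule("Tprf", high = c("Ptprc", "Cd3e", "Mki67")),
    marker_rule("NK", high = c("Ptprc", "Ncr1", "Nkg7")),
    marker_rule("B", high = c("Cd79a", "Cd19")),
    marker_rule("pDC", high = c("Clec10a", "Siglech", "Cd300c")),
    marker_rule("fibroblast", any = c("Dcn", "Acta2")),
    marker_rule("endothelial", high = "Epas1"),
    marker_rule("monocyte/macrophage", high = c("Itgam", "Cd14", "Adgre1"))
  )
}

#' Default myeloid subtype rules
#'
#' TAM states require macrophage-level `Cd68`; monocyte states require
#' monocyte-level `Cd14`. Characteristic DEG pairs: Hexb/Gatm (TAM_C0),
#' Il1b/Rgs1 (TAM_C1), Mrc1/Pf4 (TAM_C3), Lsp1/Napsa (TAM_C4),
#' S100a6/S100a10 (Mono_C2), Cebpb/Mcl1 (Mono_C5).
#'
#' @return list of [marker_rule()]s.
#' @export
myeloid_rules <- function() {
  list(
    marker_rule("TAM_C0", high = c("Hexb", "Gatm", "Cd68")),
    marker_rule("TAM_C1", high = c("Il1b", "Rgs1", "Cd68")),
    marker_rule("TAM_C3", high = c("Mrc1", "Pf4", "Cd68")),
    marker_rule("TAM_C4", high = c("Lsp1", "Napsa", "Cd68")),
    marker_rule("Mono_C2", high = c("S100a6", "S100a10", "Cd14")),
    marker_rule("Mono_C5", high = c("Cebpb", "Mcl1", "Cd14"))
  )
}

# expression calls for a profile matrix (clusters x genes):
# zscore mode: cluster-mean z-scored across clusters > threshold;
# detected mode: profile value > 0
expressed_calls <- function(profiles, mode = c("zscore", "detected"),
                            z_threshold = 0.25) {
  mode <- match.arg(mode)
  if (mode == "detected") return(profiles > 0)
  z <- scale(profiles)
  z[is.nan(z)] <- 0   # constant gene across clusters: never "expressed"
  z > z_threshold
}

match_rules <- function(profiles, rules, mode, z_threshold) {
  if (length(rules) == 0) stop("empty rule set")
  labels <- vapply(rules, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("rule labels must be unique")
  genes <- colnames(profiles)
  used <- unique(unlist(lapply(rules, function(r) c(r$high, r$any, r$low))))
  missing <- setdiff(used, genes)
  if (length(missing))
    warning("markers absent from gene universe (treated as not expressed): ",
            paste(missing, collapse = ", "))
  expr <- expressed_calls(profiles, mode, z_threshold)
  is_expr <- function(cl, g) {
    g_in <- intersect(g, genes)
    out <- stats::setNames(rep(FALSE, length(g)), g)
    out[g_in] <- expr[cl, g_in]
    out
  }
  out <- rep("unassigned", nrow(profiles))
  names(out) <- rownames(profiles)
  for (cl in seq_len(nrow(profiles))) {
    for (r in rules) {
      hi_ok <- all(is_expr(cl, r$high))
      any_ok <- length(r$any) == 0 || any(is_expr(cl, r$any))
      lo_ok <- length(r$low) == 0 || !any(is_expr(cl, r$low))
      # a rule none of whose positive markers exist is inert
      inert <- length(intersect(c(r$high, r$any), genes)) == 0
      if (hi_ok && any_ok && lo_ok && !inert) {
        out[cl] <- r$label
        break
      }
    }
  }
  out
}

#' Assign lineage labels to clusters from marker rules
#'
#' Each cluster receives the label of the first rule (in listing order) whose
#' required markers are all expressed and whose excluded markers are not.
#' "Expressed" is decided at cluster level: the cluster's mean normalized
#' expression, z-scored across clusters, must exceed `z_threshold`
#' (`mode = "detected"` instead requires a positive profile value).
#' Unmatched clusters are labeled `"unassigned"`.
#'
#' @param cluster_profiles clusters-by-genes matrix of mean normalized
#'   expression.
#' @param rules list of [marker_rule()]s (default [lineage_rules()]).
#' @param mode,z_threshold expression-call mode, see above.
#' @return named character vector of labels, one per cluster.
#' @export
assign_lineage <- function(cluster_profiles, rules = lineage_rules(),
                           mode = c("zscore", "detected"), z_threshold = 0.25) {
  match_rules(cluster_profiles, rules, match.arg(mode), z_threshold)
}

#' Assign myeloid subtype labels to myeloid clusters
#'
#' Applies the subtype rule set to clusters previously identified as
#' monocyte/macrophage; expression calls are made relative to the myeloid
#' clusters only (z-scores across the supplied profiles).
#'
#' @param myeloid_profiles myeloid clusters-by-genes mean-expression matrix.
#' @param rules list of [marker_rule()]s (default [myeloid_rules()]).
#' @param mode,z_threshold as in [assign_lineage()].
#' @return named character vector of subtype labels.
#' @export
subtype_myeloid <- function(myeloid_profiles, rules = myeloid_rules(),
                            mode = c("zscore", "detected"),
                            z_threshold = 0.25) {
  if (nrow(myeloid_profiles) == 0) stop("myeloid cluster set is empty")
  match_rules(myeloid_profiles, rules, match.arg(mode), z_threshold)
}

#' Split cells by C5ar1 expression
#'
#' Classifies cells (typically TAM_C3 cells) as `hi` or `lo` on the
#' complement receptor C5ar1. Default threshold mode `"detected"` calls a
#' cell `hi` when its C5ar1 count is above zero; `"median"` calls `hi` at or
#' above the median value (for an odd number of distinct values exactly
#' `ceiling(n/2)` cells are `hi`).
#'
#' @param counts cell-by-gene matrix covering the cells to classify.
#' @param gene receptor gene symbol (must be present).
#' @param threshold_mode `"detected"` or `"median"`.
#' @return character vector `"hi"`/`"lo"` per cell.
#' @export
split_c5ar1 <- function(counts, gene = "C5ar1",
                        threshold_mode = c("detected", "median")) {
  threshold_mode <- match.arg(threshold_mode)
  if (!gene %in% colnames(counts))
    stop("gene '", gene, "' absent from gene universe")
  x <- as.numeric(counts[, gene])
  hi <- switch(threshold_mode,
               detected = x > 0,
               median = x >= stats::median(x))
  ifelse(hi, "hi", "lo")
}

#' Per-sample composition table with derived ratios
#'
#' Tabulates label fractions per sample (fractions over labeled cells sum to
#' 1) and computes requested label-count ratios. A zero-denominator ratio is
#' reported as `Inf` and flagged.
#'
#' @param labels character vector of per-cell labels (`NA` ignored).
#' @param samples character vector of per-cell sample ids.
#' @param ratios list of 2-element character vectors
#'   `c(numerator_label, denominator_label)`.
#' @return list with `counts` and `fractions` (sample x label data frames)
#'   and `ratios` (sample, numerator, denominator, ratio, zero_denominator).
#' @export
composition_table <- function(labels, samples, ratios = list()) {
  keep <- !is.na(labels)
  labels <- labels[keep]
  samples <- samples[keep]
  if (length(labels) == 0) stop("no labeled cells")
  tab <- table(sample = samples, label = labels)
  counts <- as.data.frame.matrix(tab)
  fractions <- counts / rowSums(counts)
  ratio_df <- NULL
  if (length(ratios)) {
    rows <- lapply(ratios, function(r) {
      num <- if (r[1] %in% colnames(counts)) counts[[r[1]]] else rep(0, nrow(counts))
      den <- if (r[2] %in% colnames(counts)) counts[[r[2]]] else rep(0, nrow(counts))
      data.frame(sample = rownames(counts), numerator = r[1],
                 denominator = r[2],
                 ratio = ifelse(den == 0, Inf, num / den),
                 zero_denominator = den == 0,
                 stringsAsFactors = FALSE)
    })
    ratio_df <- do.call(rbind, rows)
  }
  list(counts = counts, fractions = fractions, ratios = ratio_df)
}

#' Mean-expression profiles per cluster
#'
#' @param values cell-by-gene normalized expression.
#' @param clusters per-cell cluster ids.
#' @return clusters-by-genes matrix of means.
#' @export
cluster_profiles <- function(values, clusters) {
  cl <- factor(clusters)
  out <- t(vapply(levels(cl), function(l)
    col_means(values[cl == l, , drop = FALSE]),
    numeric(ncol(values))))
  colnames(out) <- colnames(values)
  out
}
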