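#' Default per-arm cell-type fractions
#'
#' Sixteen populations: malignant cells, four TAM states (`TAM_C0`, `TAM_C1`,
#' `TAM_C3`, `TAM_C4`), two monocyte states (`Mono_C2`, `Mono_C5`), lymphoid
#' populations and stroma. Fractions sum to 1 and are used for every arm
#' unless an arm-specific list is supplied. The study design the generator
#' emulates reports per-arm compositions only as bar charts, so these defaults
#' are free parameters of the simulator, not calibrated estimates.
#'
#' @return a named numeric vector of fractions summing to 1.
#' @export
default_cell_type_fractions <- function() {
  c(malignant = 0.40,
    TAM_C0 = 0.06, TAM_C1 = 0.08, TAM_C3 = 0.10, TAM_C4 = 0.04,
    Mono_C2 = 0.06, Mono_C5 = 0.04,
    Tcm = 0.03, Treg = 0.02, CD8_Tn = 0.05, Tprf = 0.02,
    NK = 0.03, B = 0.03, pDC = 0.01,
    fibroblast = 0.02, endothelial = 0.01)
}

#' Default marker multiplier table
#'
#' For each simulated cell type, a named vector of genes whose baseline mean
#' is multiplied in cells of that type. Markers follow the murine
#' tumor/immune marker conventions used for lineage calling (Ptprc = CD45,
#' Cd3e = CD3) and the characteristic DEGs of the TAM/monocyte states
#' (e.g. `Mrc1`/`Pf4` for the anti-inflammatory TAM_C3 state, `Il1b`/`Rgs1`
#' for the pro-inflammatory TAM_C1 state). TAM states carry high `Cd68` and
#' intermediate `Cd14`; monocyte states the converse.
#'
#' @return a named list mapping cell type to a named multiplier vector.
#' @export
default_marker_table <- function() {
  tam_core <- c(Ptprc = 8, Itgam = 8, Adgre1 = 8, Cd68 = 8, Cd14 = 5,
                Csf1r = 8, Cx3cr1 = 8)
  mono_core <- c(Ptprc = 8, Itgam = 8, Adgre1 = 4, Cd68 = 2, Cd14 = 8,
                 Csf1r = 8, Cx3cr1 = 8)
  list(
    malignant   = c(Epcam = 8, Krt8 = 8, Krt18 = 8, Csf1 = 8, Cx3cl1 = 8),
    TAM_C0      = c(tam_core, Hexb = 8, Gatm = 8),
    TAM_C1      = c(tam_core, Il1b = 8, Rgs1 = 8),
    TAM_C3      = c(tam_core, Mrc1 = 8, Pf4 = 8),
    TAM_C4      = c(tam_core, Lsp1 = 8, Napsa = 8),
    Mono_C2     = c(mono_core, S100a6 = 8, S100a10 = 8),
    Mono_C5     = c(mono_core, Cebpb = 8, Mcl1 = 8),
    Tcm         = c(Ptprc = 8, Cd3e = 8, Cd4 = 8, Tcf7 = 8),
    Treg        = c(Ptprc = 8, Cd3e = 8, Cd4 = 8, Foxp3 = 8),
    CD8_Tn      = c(Ptprc = 8, Cd3e = 8, Cd8a = 8, Ccr7 = 8),
    Tprf        = c(Ptprc = 8, Cd3e = 8, Mki67 = 8),
    NK          = c(Ptprc = 8, Ncr1 = 8, Nkg7 = 8),
    B           = c(Ptprc = 8, Cd79a = 8, Cd19 = 8),
    pDC         = c(Ptprc = 8, Clec10a = 8, Siglech = 8, Cd300c = 8),
    fibroblast  = c(Dcn = 8, Acta2 = 8),
    endothelial = c(Epas1 = 8)
  )
}

#' Planted ligand-receptor program
#'
#' Describes a condition-dependent communication program: in cells of the
#' `sender` type the `ligand` gene's mean is multiplied by the arm's strength;
#' in a `receiver_fraction` subset of the `receiver` type the `receptor`
#' gene's mean is multiplied by `receptor_scale` times the arm's strength.
#' The receptor baseline is kept near zero (see
#' [simulation_config()]'s `base_weight_override`), so receptor detection
#' marks the planted receptor-high receiver subset.
#'
#' @param ligand,receptor gene symbols (must differ).
#' @param sender,receiver configured cell types.
#' @param strength_by_arm named nonnegative multipliers, one per arm.
#' @param receiver_fraction fraction of receiver cells carrying the receptor
#'   program.
#' @param receptor_scale fixed multiplier applied to the receptor gene on top
#'   of the arm strength.
#' @return an object of class `planted_program`.
#' @export
planted_program <- function(ligand, receptor, sender, receiver,
                            strength_by_arm,
                            receiver_fraction = 0.5,
                            receptor_scale = 400) {
  if (identical(ligand, receptor)) stop("ligand and receptor must differ")
  if (any(strength_by_arm < 0)) stop("strengths must be nonnegative")
  if (receiver_fraction < 0 || receiver_fraction > 1)
    stop("receiver_fraction must be in [0, 1]")
  structure(list(ligand = ligand, receptor = receptor,
                 sender = sender, receiver = receiver,
                 strength_by_arm = strength_by_arm,
                 receiver_fraction = receiver_fraction,
                 receptor_scale = receptor_scale),
            class = "planted_program")
}

#' Default planted program: malignant Rps19 to TAM_C3 C5ar1
#'
#' The discordant program the screen is built to find: strong under vehicle
#' in the sensitive model (lost on treatment) and strong under treatment in
#' the resistant model (gained on treatment).
#'
#' @return a `planted_program`.
#' @export
default_planted_program <- function() {
  planted_program(
    ligand = "Rps19", receptor = "C5ar1",
    sender = "malignant", receiver = "TAM_C3",
    strength_by_arm = c(sensitive_vehicle = 6, sensitive_treated = 0.01,
                        resistant_vehicle = 0.01, resistant_treated = 6))
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic single-cell
#' generator. The default design mirrors a two-model, two-treatment study
#' with 2 vehicle and 4 treated replicates per model.
#'
#' @param n_samples_per_arm named integer vector: replicates per arm; names
#'   are arm identifiers of the form `model_treatment`.
#' @param cells_per_sample cells generated per sample (>= 50).
#' @param cell_type_fractions named fraction vector (applied to every arm) or
#'   a list mapping arm to such a vector; each must sum to 1.
#' @param marker_table see [default_marker_table()]; all multipliers > 0.
#' @param n_background_genes unstructured genes added to the universe.
#' @param base_weight_meanlog,base_weight_sdlog log-normal parameters of the
#'   per-gene baseline expression weights.
#' @param base_weight_override named vector of fixed baseline weights (used
#'   to pin ligand/receptor baselines).
#' @param nb_dispersion shared negative-binomial size parameter (> 0).
#' @param library_size_mean,library_size_sdlog log-normal library sizes
#'   (mean is the arithmetic mean of the distribution).
#' @param n_mito_genes,mito_weight mitochondrial (`mt-`) genes and their
#'   common baseline weight.
#' @param planted_programs list of [planted_program()]s.
#' @param doublet_rate fraction of output cells that are doublets, in [0, 1).
#' @param seed integer seed; the full experiment is reproducible from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples_per_arm = c(sensitive_vehicle = 2, sensitive_treated = 4,
                          resistant_vehicle = 2, resistant_treated = 4),
    cells_per_sample = 1000,
    cell_type_fractions = default_cell_type_fractions(),
    marker_table = default_marker_table(),
    n_background_genes = 200,
    base_weight_meanlog = 0,
    base_weight_sdlog = 1,
    base_weight_override = c(Rps19 = 2, C5ar1 = 0.002, Csf1 = 1, Csf1r = 1,
                             Cx3cl1 = 1, Cx3cr1 = 1),
    nb_dispersion = 2,
    library_size_mean = 3000,
    library_size_sdlog = 0.3,
    n_mito_genes = 5,
    mito_weight = 4,
    planted_programs = list(default_planted_program()),
    doublet_rate = 0.06,
    seed = 1L) {

  if (cells_per_sample < 50) stop("cells_per_sample must be >= 50")
  if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must be in [0, 1)")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (library_size_mean <= 0) stop("library_size_mean must be positive")
  arms <- names(n_samples_per_arm)
  if (is.null(arms) || any(n_samples_per_arm < 1))
    stop("n_samples_per_arm must be a named vector of positive counts")

  if (!is.list(cell_type_fractions))
    cell_type_fractions <- stats::setNames(
      rep(list(cell_type_fractions), length(arms)), arms)
  if (!setequal(names(cell_type_fractions), arms))
    stop("cell_type_fractions must cover exactly the configured arms")
  types <- names(cell_type_fractions[[1]])
  for (a in arms) {
    fr <- cell_type_fractions[[a]]
    if (!setequal(names(fr), types))
      stop("all arms must share the same cell types")
    if (abs(sum(fr) - 1) > 1e-9)
      stop("per-arm cell type fractions must sum to 1")
    if (any(fr < 0)) stop("fractions must be nonnegative")
  }
  unknown <- setdiff(names(marker_table), types)
  if (length(unknown))
    stop("unknown cell type in marker_table: ", paste(unknown, collapse = ", "))
  for (m in marker_table)
    if (any(m <= 0)) stop("marker multipliers must be > 0")
  for (pp in planted_programs) {
    if (!inherits(pp, "planted_program")) stop("planted_programs entries must be planted_program objects")
    if (!pp$sender %in% types || !pp$receiver %in% types)
      stop("planted program sender/receiver must be configured cell types")
    missing_arms <- setdiff(arms, names(pp$strength_by_arm))
    if (length(missing_arms))
      stop("planted program lacks strengths for arms: ",
           paste(missing_arms, collapse = ", "))
  }

  structure(list(
    n_samples_per_arm = n_samples_per_arm,
    cells_per_sample = as.integer(cells_per_sample),
    cell_type_fractions = cell_type_fractions,
    marker_table = marker_table,
    n_background_genes = as.integer(n_background_genes),
    base_weight_meanlog = base_weight_meanlog,
    base_weight_sdlog = base_weight_sdlog,
    base_weight_override = base_weight_override,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog,
    n_mito_genes = as.integer(n_mito_genes),
    mito_weight = mito_weight,
    planted_programs = planted_programs,
    doublet_rate = doublet_rate,
    seed = as.integer(seed)), class = "simulation_config")
}

# assemble the gene universe implied by a config
config_gene_universe <- function(config) {
  marker_genes <- unique(unlist(lapply(config$marker_table, names)))
  program_genes <- unique(unlist(lapply(config$planted_programs,
                                        function(p) c(p$ligand, p$receptor))))
  mito <- if (config$n_mito_genes > 0)
    paste0("mt-g", seq_len(config$n_mito_genes)) else character()
  bg <- if (config$n_background_genes > 0)
    sprintf("bg%04d", seq_len(config$n_background_genes)) else character()
  genes <- unique(c(marker_genes, program_genes,
                    names(config$base_weight_override), mito, bg))
  list(genes = genes, mito = mito)
}

#' Combine cells into doublets
#'
#' Returns the gene-wise sums of paired rows, the count model used when the
#' generator plants doublets. Exposed so the count-conservation property of
#' doublet construction can be exercised directly.
#'
#' @param counts cell-by-gene count matrix.
#' @param i,j equal-length index vectors of parent cells.
#' @return a `length(i)`-by-gene matrix of summed counts.
#' @export
make_doublets <- function(counts, i, j) {
  if (length(i) != length(j)) stop("parent index vectors must match in length")
  counts[i, , drop = FALSE] + counts[j, , drop = FALSE]
}

#' Generate a synthetic single-cell experiment
#'
#' Draws negative-binomial counts for every sample of the configured design.
#' A cell of type `t` in arm `a` has gene-`g` mean proportional to
#' `base_g * marker(t, g) * program(a, g)`, scaled so the expected total per
#' cell equals its log-normal library size. Cell types are assigned
#' multinomially from the arm's fractions; a `doublet_rate` fraction of the
#' output cells are sums of two independently generated parent cells.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_experiment`: list with sparse
#'   `counts` (cells x genes), `cell_meta`, `gene_meta` and the `config`
#'   (ground truth).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    uni <- config_gene_universe(config)
    genes <- uni$genes
    G <- length(genes)
    base_w <- stats::rlnorm(G, config$base_weight_meanlog,
                            config$base_weight_sdlog)
    names(base_w) <- genes
    if (length(uni$mito)) base_w[uni$mito] <- config$mito_weight
    ov <- config$base_weight_override
    ov <- ov[names(ov) %in% genes]
    base_w[names(ov)] <- ov

    arms <- names(config$n_samples_per_arm)
    types <- names(config$cell_type_fractions[[1]])
    # per-type weight matrix (types x genes)
    W <- matrix(rep(base_w, each = length(types)), nrow = length(types),
                dimnames = list(types, genes))
    for (t in names(config$marker_table)) {
      m <- config$marker_table[[t]]
      W[t, names(m)] <- W[t, names(m)] * m
    }

    n <- config$cells_per_sample
    n_doub <- as.integer(round(config$doublet_rate * n))
    counts_list <- list()
    meta_list <- list()
    for (a in arms) {
      fr <- config$cell_type_fractions[[a]][types]
      for (r in seq_len(config$n_samples_per_arm[[a]])) {
        sample_id <- paste0(a, "_", r)
        n_base <- n + n_doub
        ct <- sample(types, n_base, replace = TRUE, prob = fr)
        meanlog <- log(config$library_size_mean) -
          config$library_size_sdlog^2 / 2
        libs <- stats::rlnorm(n_base, meanlog, config$library_size_sdlog)
        w <- W[ct, , drop = FALSE]
        prog_receiver <- rep(FALSE, n_base)
        for (pp in config$planted_programs) {
          s <- pp$strength_by_arm[[a]]
          is_sender <- ct == pp$sender
          w[is_sender, pp$ligand] <- w[is_sender, pp$ligand] * s
          is_recv <- ct == pp$receiver &
            stats::runif(n_base) < pp$receiver_fraction
          w[is_recv, pp$receptor] <-
            w[is_recv, pp$receptor] * s * pp$receptor_scale
          prog_receiver <- prog_receiver | is_recv
        }
        mu <- w * (libs / rowSums(w))
        cts <- matrix(stats::rnbinom(length(mu), size = config$nb_dispersion,
                                     mu = as.vector(mu)),
                      nrow = n_base, dimnames = list(NULL, genes))
        if (n_doub > 0) {
          n_single <- n - n_doub
          p1 <- (n_single + 1L):n
          p2 <- (n + 1L):(n + n_doub)
          out <- rbind(cts[seq_len(n_single), , drop = FALSE],
                       make_doublets(cts, p1, p2))
          keep_idx <- c(seq_len(n_single), p1)
          meta <- data.frame(
            sample = sample_id, arm = a,
            celltype = ct[keep_idx],
            is_doublet = c(rep(FALSE, n_single), rep(TRUE, n_doub)),
            program_receiver = prog_receiver[keep_idx],
            stringsAsFactors = FALSE)
        } else {
          out <- cts[seq_len(n), , drop = FALSE]
          meta <- data.frame(
            sample = sample_id, arm = a, celltype = ct[seq_len(n)],
            is_doublet = FALSE,
            program_receiver = prog_receiver[seq_len(n)],
            stringsAsFactors = FALSE)
        }
        ord <- sample(nrow(out))
        counts_list[[sample_id]] <- out[ord, , drop = FALSE]
        meta_list[[sample_id]] <- meta[ord, , drop = FALSE]
      }
    }
    counts <- do.call(rbind, counts_list)
    cell_meta <- do.call(rbind, meta_list)
    cell_meta$model <- sub("_[^_]+$", "", cell_meta$arm)
    cell_meta$treatment <- sub("^.*_", "", cell_meta$arm)
    cell_meta$cell_id <- sprintf("cell%05d", seq_len(nrow(cell_meta)))
    rownames(cell_meta) <- cell_meta$cell_id
    rownames(counts) <- cell_meta$cell_id
    gene_meta <- data.frame(symbol = genes,
                            is_mito = genes %in% uni$mito,
                            base_weight = unname(base_w),
                            stringsAsFactors = FALSE)
    structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                   cell_meta = cell_meta, gene_meta = gene_meta,
                   config = config),
              class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic_experiment:", nrow(x$counts), "cells x",
      ncol(x$counts), "genes,",
      length(unique(x$cell_meta$sample)), "samples,",
      sum(x$cell_meta$is_doublet), "planted doublets\n")
  invisible(x)
}

#' Generate a hashtag-oligo count matrix for an experiment
#'
#' Each cell receives Poisson counts for every tag: `background_mean` for
#' off-target tags and `signal_to_noise * background_mean` for the tag of its
#' true sample. With `background_mean = 0` the off-target counts are exactly
#' zero and the signal mean is fixed at 100 (the noiseless limit).
#'
#' @param experiment a `synthetic_experiment`.
#' @param n_tags number of tags (>= number of samples).
#' @param signal_to_noise ratio of on-target to off-target mean counts.
#' @param background_mean off-target Poisson mean.
#' @param tag_of_sample optional named integer vector mapping sample id to a
#'   tag index; must be injective (one tag per sample).
#' @param seed integer seed.
#' @return integer matrix, cells x tags, with the true sample stored in
#'   `attr(, "true_sample")`.
#' @export
generate_hashtags <- function(experiment, n_tags = NULL, signal_to_noise = 10,
                              background_mean = 20, tag_of_sample = NULL,
                              seed = 1L) {
  samples <- unique(experiment$cell_meta$sample)
  n_tags <- n_tags %||% length(samples)
  if (n_tags < length(samples))
    stop("n_tags must be at least the number of samples")
  if (is.null(tag_of_sample))
    tag_of_sample <- stats::setNames(seq_along(samples), samples)
  if (anyDuplicated(tag_of_sample))
    stop("two samples may not share one tag id")
  if (signal_to_noise <= 0) stop("signal_to_noise must be positive")
  with_seed(seed, {
    n <- nrow(experiment$cell_meta)
    signal <- if (background_mean > 0) signal_to_noise * background_mean else 100
    lam <- matrix(background_mean, n, n_tags)
    true_tag <- tag_of_sample[experiment$cell_meta$sample]
    lam[cbind(seq_len(n), true_tag)] <- signal
    ht <- matrix(stats::rpois(length(lam), as.vector(lam)), n, n_tags,
                 dimnames = list(rownames(experiment$counts),
                                 paste0("tag", seq_len(n_tags))))
    attr(ht, "true_sample") <- experiment$cell_meta$sample
    attr(ht, "tag_of_sample") <- tag_of_sample
    ht
  })
}

#' Generate a synthetic patient cohort
#'
#' Per patient: myeloid class counts (`c5ar1_hi`, `cd86_hi`, `other`) drawn
#' from negative binomials, the pseudocounted ratio covariate, a survival
#' time from an exponential model with hazard
#' `baseline_hazard * exp(beta * z)` (z the cohort-standardized ratio),
#' independent exponential censoring, and a binary response (`NE` = no
#' T-cell expansion) from a logistic model in z.
#'
#' @param n_patients cohort size (>= 8).
#' @param baseline_hazard exponential baseline hazard per day (> 0).
#' @param beta log-hazard coefficient on the standardized ratio.
#' @param censor_rate exponential censoring hazard (0 disables censoring).
#' @param logistic_beta,logistic_intercept logistic model for `NE` response.
#' @param c5_mu,cd86_mu,other_mu negative-binomial means of the class counts.
#' @param pseudocount passed to [ratio_statistic()].
#' @param seed integer seed.
#' @return a `data.frame` of class `synthetic_cohort` with columns
#'   `patient_id`, `c5ar1_hi`, `cd86_hi`, `other`, `ratio`, `z_ratio`,
#'   `response`, `time_days`, `event`; generator parameters in
#'   `attr(, "params")`.
#' @export
generate_cohort <- function(n_patients, baseline_hazard = 0.002, beta = 0.8,
                            censor_rate = 0.0008, logistic_beta = 1.5,
                            logistic_intercept = 0,
                            c5_mu = 60, cd86_mu = 60, other_mu = 180,
                            pseudocount = 1, seed = 1L) {
  if (n_patients < 8) stop("n_patients must be >= 8")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_rate < 0) stop("censor_rate must be nonnegative")
  with_seed(seed, {
    c5 <- stats::rnbinom(n_patients, mu = c5_mu, size = 3)
    cd86 <- stats::rnbinom(n_patients, mu = cd86_mu, size = 3)
    other <- stats::rnbinom(n_patients, mu = other_mu, size = 5)
    ratio <- ratio_statistic(c5, cd86, pseudocount = pseudocount)
    z <- if (stats::sd(ratio) > 0) as.numeric(scale(ratio)) else rep(0, n_patients)
    death <- stats::rexp(n_patients, baseline_hazard * exp(beta * z))
    cens <- if (censor_rate > 0) stats::rexp(n_patients, censor_rate) else Inf
    time <- pmin(death, cens)
    event <- as.integer(death <= cens)
    p_ne <- stats::plogis(logistic_intercept + logistic_beta * z)
    response <- ifelse(stats::runif(n_patients) < p_ne, "NE", "E")
    out <- data.frame(patient_id = sprintf("pt%03d", seq_len(n_patients)),
                      c5ar1_hi = c5, cd86_hi = cd86, other = other,
                      ratio = ratio, z_ratio = z,
                      response = response,
                      time_days = time, event = event,
                      stringsAsFactors = FALSE)
    attr(out, "params") <- list(baseline_hazard = baseline_hazard,
                                beta = beta, censor_rate = censor_rate,
                                logistic_beta = logistic_beta,
                                logistic_intercept = logistic_intercept,
                                pseudocount = pseudocount, seed = seed)
    class(out) <- c("synthetic_cohort", "data.frame")
    out
  })
}

#' Write a synthetic experiment to disk
#'
#' Counts as Matrix Market (`counts.mtx`), cell and gene annotation and the
#' truth table as TSV.
#'
#' @param experiment a `synthetic_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(experiment$counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.table(experiment$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a synthetic cohort as CSV
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
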