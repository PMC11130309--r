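#' Comparison design for replicate-pairwise interaction counting
#'
#' Condition A with `a` replicate samples is compared against condition B
#' with `b` replicates, yielding `a x b` ordered comparison pairs. In
#' `"presence"` mode an interaction unit is "increased" in a pair when it is
#' called significant in the A sample but not the B sample; in `"strength"`
#' mode when its strength exceeds `tau` times the B strength among units
#' significant in either sample.
#'
#' @param a_ids,b_ids disjoint, non-empty sample id vectors.
#' @param mode `"presence"` or `"strength"`.
#' @param tau fold threshold for strength mode (> 1).
#' @return an object of class `comparison_design`.
#' @export
comparison_design <- function(a_ids, b_ids,
                              mode = c("presence", "strength"), tau = 1.5) {
  mode <- match.arg(mode)
  if (length(a_ids) < 1 || length(b_ids) < 1)
    stop("both conditions need at least one replicate")
  if (length(intersect(a_ids, b_ids)))
    stop("condition sample sets must be disjoint")
  if (mode == "strength" && tau <= 1) stop("tau must exceed 1")
  structure(list(a_ids = a_ids, b_ids = b_ids, mode = mode, tau = tau),
            class = "comparison_design")
}

unit_key <- function(tbl) paste(tbl$pair_id, tbl$sender, tbl$receiver,
                                sep = "|")

# align two interaction tables on the union of unit keys; absent units carry
# significant = FALSE and strength = 0 (not expressed in that sample)
align_units <- function(tableA, tableB) {
  ka <- unit_key(tableA)
  kb <- unit_key(tableB)
  keys <- sort(union(ka, kb))
  ia <- match(keys, ka)
  ib <- match(keys, kb)
  list(keys = keys,
       sigA = ifelse(is.na(ia), FALSE, tableA$significant[ia]),
       sigB = ifelse(is.na(ib), FALSE, tableB$significant[ib]),
       sA = ifelse(is.na(ia), 0, tableA$strength[ia]),
       sB = ifelse(is.na(ib), 0, tableB$strength[ib]))
}

#' Per-unit up/down/unchanged call for one comparison pair
#'
#' @param tableA,tableB [call_interactions()] results for one A sample and
#'   one B sample (same ligand-receptor database and typing).
#' @param mode,tau see [comparison_design()].
#' @return data.frame with `unit` (pair|sender|receiver key) and
#'   `call` in `{"up", "down", "unchanged"}` over the union of units.
#' @export
pairwise_delta <- function(tableA, tableB,
                           mode = c("presence", "strength"), tau = 1.5) {
  mode <- match.arg(mode)
  al <- align_units(tableA, tableB)
  call <- rep("unchanged", length(al$keys))
  if (mode == "presence") {
    call[al$sigA & !al$sigB] <- "up"
    call[!al$sigA & al$sigB] <- "down"
  } else {
    in_play <- al$sigA | al$sigB
    up <- in_play & al$sA >= tau * al$sB & al$sA > 0
    dn <- in_play & al$sB >= tau * al$sA & al$sB > 0
    call[up & !dn] <- "up"
    call[dn & !up] <- "down"
  }
  data.frame(unit = al$keys, call = call, stringsAsFactors = FALSE)
}

#' Replicate-pairwise interaction count estimate
#'
#' The core differential statistic: every A replicate is compared with every
#' B replicate (`a x b` ordered pairs); for each interaction unit, `n_up`
#' counts the pairs where the unit increased and `n_dn` the pairs where it
#' decreased, and `N = n_up - n_dn` (exact integer arithmetic). Units absent
#' from both samples of a pair count as unchanged.
#'
#' @param tablesA,tablesB lists of [call_interactions()] results (the A and
#'   B replicates).
#' @param design optional [comparison_design()]; defaults to presence mode
#'   over the supplied tables.
#' @return data.frame of class `interaction_count`: `unit`, `pair_id`,
#'   `sender`, `receiver`, `n_up`, `n_dn`, `N`, with `a`, `b`, `mode`
#'   attributes.
#' @export
interaction_count <- function(tablesA, tablesB, design = NULL) {
  a <- length(tablesA)
  b <- length(tablesB)
  if (a == 0 || b == 0) stop("both conditions need at least one table")
  mode <- if (is.null(design)) "presence" else design$mode
  tau <- if (is.null(design)) 1.5 else design$tau
  if (!is.null(design) &&
      (a != length(design$a_ids) || b != length(design$b_ids)))
    stop("design replicate counts do not match the supplied tables")

  keys <- sort(unique(unlist(c(lapply(tablesA, unit_key),
                               lapply(tablesB, unit_key)))))
  n_up <- n_dn <- stats::setNames(integer(length(keys)), keys)
  for (ta in tablesA) for (tb in tablesB) {
    d <- pairwise_delta(ta, tb, mode = mode, tau = tau)
    up <- d$unit[d$call == "up"]
    dn <- d$unit[d$call == "down"]
    n_up[up] <- n_up[up] + 1L
    n_dn[dn] <- n_dn[dn] + 1L
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(unit = keys,
                    pair_id = vapply(parts, `[`, "", 1),
                    sender = vapply(parts, `[`, "", 2),
                    receiver = vapply(parts, `[`, "", 3),
                    n_up = as.integer(n_up), n_dn = as.integer(n_dn),
                    N = as.integer(n_up - n_dn),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "a") <- a
  attr(out, "b") <- b
  attr(out, "mode") <- mode
  class(out) <- c("interaction_count", "data.frame")
  out
}

#' Aggregate interaction counts over the ligands of each receptor
#'
#' Where multiple ligands signal through one receptor, the receptor-level
#' count is the sum of the per-ligand counts (`n_up`, `n_dn` and `N` are all
#' summed).
#'
#' @param result an [interaction_count()] at pair granularity.
#' @param lr_db the [lr_database()] the pairs came from.
#' @return data.frame of class `interaction_count` keyed by
#'   `receptor|sender|receiver`.
#' @export
aggregate_by_receptor <- function(result, lr_db) {
  if (!inherits(lr_db, "lr_database")) lr_db <- lr_database(lr_db)
  m <- match(result$pair_id, lr_db$pair_id)
  if (anyNA(m))
    stop("receptor absent from database for pair(s): ",
         paste(utils::head(result$pair_id[is.na(m)], 5), collapse = ", "))
  receptor <- lr_db$receptor[m]
  grp <- paste(receptor, result$sender, result$receiver, sep = "|")
  agg <- function(v) as.integer(tapply(v, grp, sum))
  keys <- sort(unique(grp))
  ord <- match(keys, sort(unique(grp)))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(unit = keys,
                    pair_id = vapply(parts, `[`, "", 1),
                    sender = vapply(parts, `[`, "", 2),
                    receiver = vapply(parts, `[`, "", 3),
                    n_up = agg(result$n_up)[ord],
                    n_dn = agg(result$n_dn)[ord],
                    stringsAsFactors = FALSE)
  out$N <- out$n_up - out$n_dn
  attr(out, "a") <- attr(result, "a")
  attr(out, "b") <- attr(result, "b")
  attr(out, "mode") <- attr(result, "mode")
  attr(out, "level") <- "receptor"
  class(out) <- c("interaction_count", "data.frame")
  out
}

#' Screen for condition-discordant interaction units
#'
#' Returns the units whose interaction count is at least `+min_magnitude` in
#' the resistant contrast and at most `-min_magnitude` in the sensitive
#' contrast — i.e. interactions gained under treatment where treatment
#' fails and lost where it works. Units are ranked by
#' `N_resistant - N_sensitive` (descending), ties broken lexicographically
#' by unit key. Units absent from one result are treated as N = 0.
#'
#' @param count_sensitive,count_resistant [interaction_count()] results for
#'   the sensitive and resistant contrasts (must share at least part of
#'   their unit universe).
#' @param min_magnitude minimum |N| in each contrast (>= 0).
#' @return data.frame with `unit`, `pair_id`, `sender`, `receiver`,
#'   `N_sensitive`, `N_resistant`, `delta`.
#' @export
screen_discordant <- function(count_sensitive, count_resistant,
                              min_magnitude = 1) {
  if (!length(intersect(count_sensitive$unit, count_resistant$unit)))
    stop("disjoint unit universes")
  keys <- sort(union(count_sensitive$unit, count_resistant$unit))
  ns <- count_sensitive$N[match(keys, count_sensitive$unit)]
  nr <- count_resistant$N[match(keys, count_resistant$unit)]
  ns[is.na(ns)] <- 0L
  nr[is.na(nr)] <- 0L
  hit <- nr >= min_magnitude & ns <= -min_magnitude
  parts <- strsplit(keys[hit], "|", fixed = TRUE)
  out <- data.frame(unit = keys[hit],
                    pair_id = vapply(parts, `[`, "", 1),
                    sender = vapply(parts, `[`, "", 2),
                    receiver = vapply(parts, `[`, "", 3),
                    N_sensitive = ns[hit], N_resistant = nr[hit],
                    delta = nr[hit] - ns[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
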