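# ROC/AUC detection scoring and statistical comparison of AUC across
# regularization choices.

#' ROC curve and AUC for a source map against ground truth
#'
#' The threshold sweeps over every distinct evaluable map value (plus
#' infinite endpoints), giving the exact ROC: at threshold `a`,
#' `TP(a) = #{truth vertices with value >= a}` and
#' `FP(a) = #{evaluable non-truth vertices with value >= a}`; fractions are
#' `TP / n_truth` and `FP / (n_evaluable - n_truth)`.  Vertices in
#' `excluded` (e.g. the reference patch of a seed-based coherence map) are
#' removed from both numerators and denominators.  The AUC is the
#' trapezoidal area under `(FPF, TPF)`, which equals the normalized
#' Mann-Whitney statistic (ties counted 1/2).
#'
#' @param map a `spectral_map` or numeric vector of per-vertex values.
#' @param truth_vertices integer indices of the simulated (true) vertices.
#' @param excluded integer indices excluded from scoring; defaults to the
#'   map's own exclusion set when `map` is a `spectral_map`.
#' @return An object of class `roc_result`: `thresholds` (increasing),
#'   `tpf`, `fpf` (non-increasing in the threshold), `auc`, `n_truth`,
#'   `n_total` (evaluable vertices).
#' @export
roc_auc <- function(map, truth_vertices, excluded = NULL) {
  if (inherits(map, "spectral_map")) {
    if (is.null(excluded)) excluded <- map$excluded
    values <- map$values
  } else {
    values <- as.numeric(map)
    if (is.null(excluded)) excluded <- integer(0)
  }
  n <- length(values)
  evaluable <- setdiff(seq_len(n), excluded)
  truth <- intersect(setdiff(unique(truth_vertices), excluded), evaluable)
  if (!length(truth))
    stop("undefined ROC: no truth vertices remain after exclusion")
  vals <- values[evaluable]
  if (any(!is.finite(vals)))
    stop("map values must be finite on evaluable vertices")
  is_truth <- evaluable %in% truth
  n_t <- sum(is_truth)
  n_f <- length(evaluable) - n_t
  if (n_f == 0) stop("undefined ROC: no non-truth vertices to score")

  thr <- c(Inf, sort(unique(vals), decreasing = TRUE), -Inf)
  tp <- vapply(thr, function(a) sum(vals[is_truth] >= a), numeric(1))
  fp <- vapply(thr, function(a) sum(vals[!is_truth] >= a), numeric(1))
  tpf <- tp / n_t
  fpf <- fp / n_f
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)

  o <- rev(seq_along(thr))  # store with increasing threshold
  structure(list(thresholds = thr[o], tpf = tpf[o], fpf = fpf[o],
                 auc = auc, n_truth = n_t, n_total = length(evaluable)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d truth / %d evaluable vertices)\n",
              x$auc, x$n_truth, x$n_total))
  invisible(x)
}

#' Paired two-tailed t-test between two AUC vectors
#'
#' Classical paired t-test on per-configuration AUC differences, used to
#' compare detection performance under two regularization choices applied
#' to the same simulated configurations.
#'
#' @param auc_a,auc_b numeric vectors of equal length (>= 3), paired by
#'   configuration.
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`.
#' @export
compare_auc_paired <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b))
    stop("paired comparison requires equal-length AUC vectors")
  if (length(auc_a) < 3)
    stop("paired comparison requires at least 3 configurations")
  d <- auc_a - auc_b
  if (stats::sd(d) == 0)
    stop("degenerate test: AUC differences have zero variance")
  tt <- stats::t.test(auc_a, auc_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Mean AUC per regularization weight and the optimal weight, by group
#'
#' Averages AUC over configurations within each group (or overall for an
#' empty `group_by`), per regularization weight, and reports the weight
#' with the highest mean AUC.  Exact ties are broken toward the larger
#' weight and flagged.
#'
#' @param table study table (data.frame) with at least columns `config_id`,
#'   `reg_weight`, `analysis`, `auc`, plus any grouping factors.
#' @param analysis `"power"` or `"coherence"`.
#' @param group_by character vector of column names to group by (default
#'   none: a single overall group).
#' @return List with `mean_auc` (data.frame: group columns, `reg_weight`,
#'   `mean_auc`, `n`) and `optima` (data.frame: group columns,
#'   `optimal_weight`, `mean_auc`, `tie`, `at_grid_edge`).
#' @export
aggregate_optimal_lambda <- function(table, analysis = c("power", "coherence"),
                                     group_by = character(0)) {
  analysis <- match.arg(analysis)
  tab <- table[table$analysis == analysis, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for analysis '", analysis, "'")
  grid <- sort(unique(table$reg_weight))
  key <- if (length(group_by))
    interaction(tab[group_by], drop = TRUE) else factor(rep("all", nrow(tab)))

  # every group must cover the full weight grid
  gaps <- tapply(tab$reg_weight, key,
                 function(w) setdiff(grid, unique(w)), simplify = FALSE)
  bad <- names(gaps)[vapply(gaps, length, integer(1)) > 0]
  if (length(bad))
    stop("incomplete design: groups missing grid cells: ",
         paste(bad, collapse = ", "))

  agg <- stats::aggregate(tab$auc,
                          by = c(tab[group_by],
                                 list(reg_weight = tab$reg_weight),
                                 if (!length(group_by))
                                   list(group = key) else NULL),
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- "mean_auc"
  cnt <- stats::aggregate(tab$auc,
                          by = c(tab[group_by],
                                 list(reg_weight = tab$reg_weight),
                                 if (!length(group_by))
                                   list(group = key) else NULL),
                          FUN = length)
  agg$n <- cnt$x

  gcols <- if (length(group_by)) group_by else "group"
  gkey <- interaction(agg[gcols], drop = TRUE)
  optima <- do.call(rbind, lapply(levels(gkey), function(g) {
    sub <- agg[gkey == g, , drop = FALSE]
    sub <- sub[order(sub$reg_weight), , drop = FALSE]
    best <- max(sub$mean_auc)
    hits <- which(abs(sub$mean_auc - best) < 1e-15)
    pick <- max(hits)  # tie broken toward the larger weight
    out <- sub[pick, gcols, drop = FALSE]
    out$optimal_weight <- sub$reg_weight[pick]
    out$mean_auc <- sub$mean_auc[pick]
    out$tie <- length(hits) > 1
    out$at_grid_edge <- pick %in% c(1L, nrow(sub))
    out
  }))
  rownames(optima) <- NULL
  list(mean_auc = agg, optima = optima)
}
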