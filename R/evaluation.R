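#' Confusion-matrix metrics for a DE call against known truth
#'
#' Given the set of genes called DE, the ground-truth DE set, and the
#' universe of evaluated genes, computes the confusion counts and the
#' derived indices used to benchmark DE methods: TPR (recall), precision,
#' F1, specificity and empirical FDR. A ratio whose denominator is zero
#' (e.g. precision with an empty call set) is reported as 0 and listed in
#' the `undefined` field rather than propagating NaN.
#'
#' @param called Character vector of gene ids called DE.
#' @param truth Character vector of true DE gene ids.
#' @param universe Character vector of all evaluated gene ids.
#' @return A one-row data frame with columns tp, fp, fn, tn, tpr,
#'   precision, f1, specificity, fdr and `undefined` (comma-separated
#'   names of metrics whose denominator was zero, or "").
#' @examples
#' confusion_metrics(c("g1", "g2"), c("g1", "g3"), paste0("g", 1:10))
#' @export
confusion_metrics <- function(called, truth, universe) {
  called <- unique(as.character(called))
  truth <- unique(as.character(truth))
  universe <- unique(as.character(universe))
  if (!all(called %in% universe))
    stop("called genes outside the evaluation universe")
  if (!all(truth %in% universe))
    stop("truth genes outside the evaluation universe")
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  tn <- length(universe) - tp - fp - fn
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den > 0) return(num / den)
    undef <<- c(undef, name)
    0
  }
  tpr <- ratio(tp, tp + fn, "tpr")
  precision <- ratio(tp, tp + fp, "precision")
  fdr <- ratio(fp, tp + fp, "fdr")
  specificity <- ratio(tn, tn + fp, "specificity")
  f1 <- if (precision + tpr > 0) {
    2 * precision * tpr / (precision + tpr)
  } else {
    undef <- c(undef, "f1")
    0
  }
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             tpr = tpr, precision = precision, f1 = f1,
             specificity = specificity, fdr = fdr,
             undefined = paste(undef, collapse = ","),
             stringsAsFactors = FALSE)
}

.run_one_replicate <- function(generator, cfg, seed, alpha, df_fit) {
  if (generator == "semisim") {
    src_args <- cfg[names(cfg) %in%
                      c("n_genes", "n_cells", "sparsity_target",
                        "mean_shape", "dispersion", "libsize_scale")]
    src <- do.call(simulate_pbmc_like_source, c(src_args, list(seed = seed)))
    sim_args <- cfg[names(cfg) %in% c("fc", "k", "s1", "null_mode")]
    ds <- do.call(make_semisim,
                  c(list(counts = src, seed = seed + 1L), sim_args))
  } else {
    sim_args <- cfg[names(cfg) %in%
                      c("n_genes_nonde", "n_genes_de", "n_cells",
                        "de_factor", "de_factor_scale", "mean_shape",
                        "mean_rate", "libsize_loc", "libsize_scale", "bcv",
                        "dropout_mid", "dropout_shape")]
    ds <- do.call(simulate_splat_like, c(sim_args, list(seed = seed)))
  }
  res <- run_heart(ds$counts, ds$groups, alpha = alpha, df_fit = df_fit)
  called <- res$table$gene_id[res$table$is_de]
  cm <- confusion_metrics(called, ds$truth_de, rownames(ds$counts))
  cm$fitted_df <- res$fitted_df
  cm
}

#' Benchmark HEART over a grid of simulator configurations
#'
#' Runs seeded replicates of a generator configuration, applies HEART,
#' scores each replicate with [confusion_metrics()], and aggregates. By
#' default metrics are computed per replicate and then averaged (mean and
#' sd); `aggregate = "pooled"` instead sums the confusion counts over
#' replicates and derives the metrics once.
#'
#' @param generator `"semisim"` or `"splat"`.
#' @param grid A list of named configuration lists. Semisim configs may
#'   set n_genes, n_cells, sparsity_target (source) and fc, k, s1,
#'   null_mode (swap); splat configs take [simulate_splat_like()]
#'   arguments.
#' @param replicates Replicates per configuration.
#' @param seeds Either one base seed (replicate r uses `seeds + r - 1`) or
#'   a vector of length `replicates`.
#' @param alpha FDR level of the DE call.
#' @param df_fit Passed to [run_heart()].
#' @param aggregate `"mean_of_replicates"` (default) or `"pooled"`.
#' @return A data frame, one row per configuration, with the configuration
#'   fields and `<metric>_mean` / `<metric>_sd` columns (pooled mode:
#'   plain metric columns).
#' @export
benchmark_grid <- function(generator = c("semisim", "splat"), grid,
                           replicates = 1, seeds = 1, alpha = 0.05,
                           df_fit = "mle",
                           aggregate = c("mean_of_replicates", "pooled")) {
  generator <- match.arg(generator)
  aggregate <- match.arg(aggregate)
  stopifnot(replicates >= 1)
  if (length(seeds) == 1) seeds <- seeds + seq_len(replicates) - 1
  if (length(seeds) != replicates)
    stop("`seeds` must be a scalar or of length `replicates`")

  metric_cols <- c("tpr", "precision", "f1", "specificity", "fdr")
  rows <- lapply(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    reps <- lapply(seeds, function(s)
      .run_one_replicate(generator, cfg, as.integer(s), alpha, df_fit))
    reps <- do.call(rbind, reps)
    id <- cfg[vapply(cfg, function(v)
      is.atomic(v) && length(v) == 1, logical(1))]
    id <- as.data.frame(id, stringsAsFactors = FALSE)
    if (aggregate == "pooled") {
      pooled <- confusion_metrics_from_counts(
        sum(reps$tp), sum(reps$fp), sum(reps$fn), sum(reps$tn))
      return(cbind(id, pooled))
    }
    means <- vapply(reps[metric_cols], mean, numeric(1))
    sds <- vapply(reps[metric_cols], function(x)
      if (length(x) > 1) stats::sd(x) else NA_real_, numeric(1))
    out <- c(means, sds)
    names(out) <- c(paste0(metric_cols, "_mean"), paste0(metric_cols, "_sd"))
    cbind(id, as.data.frame(as.list(out)),
          fitted_df_mean = mean(reps$fitted_df))
  })
  do.call(rbind, rows)
}

#' Metrics from raw confusion counts
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return One-row data frame as in [confusion_metrics()].
#' @export
confusion_metrics_from_counts <- function(tp, fp, fn, tn) {
  universe <- character(0)
  mk <- function(n, pre) if (n > 0) paste0(pre, seq_len(n)) else character(0)
  called <- c(mk(tp, "tp"), mk(fp, "fp"))
  truth <- c(mk(tp, "tp"), mk(fn, "fn"))
  universe <- c(mk(tp, "tp"), mk(fp, "fp"), mk(fn, "fn"), mk(tn, "tn"))
  confusion_metrics(called, truth, universe)
}
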