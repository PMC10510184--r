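# Cross-patient statistics: an exact Wilcoxon rank-sum test by full
# permutation enumeration (normal approximation with tie correction beyond
# the enumerable range), per-metric pre/post comparisons, repaired/new
# mutated-gene partitions and their cross-patient intersections, driver-gene
# annotation, and median dichotomization.

#' Exact Wilcoxon rank-sum test
#'
#' The statistic is the rank sum `W` of `x` in the pooled sample (midranks
#' for ties). When `n + m <= exact_max_n`, the two-sided p-value is computed
#' by full enumeration: the fraction of all `choose(n+m, n)` assignments of
#' the pooled values to the first group whose rank sum is at least as far
#' from the null mean `n(n+m+1)/2` as the observed one. Larger samples use
#' the normal approximation with tie-corrected variance.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max_n Largest pooled size for exact enumeration; default 12.
#' @return One-row tibble: `statistic` (W), `p_value`, `method`
#'   (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum_exact <- function(x, y, exact_max_n = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  EW <- n * (N + 1) / 2
  if (N <= exact_max_n) {
    picks <- utils::combn(N, n)
    Wdist <- colSums(matrix(r[picks], nrow = n))
    p <- mean(abs(Wdist - EW) >= abs(W - EW) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    V <- n * m / 12 * ((N + 1) - tie_term)
    z <- if (V > 0) (W - EW) / sqrt(V) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = W, p_value = p, method = method, n_x = n, n_y = m)
}

#' Compare heterogeneity metrics between pre- and post-treatment samples
#'
#' Runs [wilcoxon_rank_sum_exact()] for each metric on the pre-treatment
#' versus post-treatment value lists across patients (unpaired rank-sum by
#' default, matching the usual reporting for this design; `paired = TRUE`
#' switches to the Wilcoxon signed-rank test on per-patient differences).
#'
#' @param profiles Heterogeneity profile tibble (one row per tumor sample,
#'   columns `patient`, `timepoint` plus the metrics).
#' @param metrics Metric columns to compare; default all six.
#' @param paired Use the signed-rank test on paired differences instead of
#'   the rank-sum test; default `FALSE`.
#' @return Tibble with one row per metric: `metric`, `statistic`, `p_value`,
#'   `method`, `median_pre`, `median_post`.
#' @export
compare_pre_post <- function(profiles,
                             metrics = c("tmb", "cna_burden", "wgii",
                                         "sdi", "ith", "math"),
                             paired = FALSE) {
  missing_m <- setdiff(metrics, names(profiles))
  if (length(missing_m) > 0) {
    abort(sprintf("profiles lack metric(s): %s", paste(missing_m, collapse = ", ")))
  }
  pre <- profiles[profiles$timepoint == "pre", , drop = FALSE]
  post <- profiles[profiles$timepoint == "post", , drop = FALSE]
  if (nrow(pre) == 0 || nrow(post) == 0) {
    abort("profiles must contain both pre and post samples")
  }
  purrr::map_dfr(metrics, function(mt) {
    xv <- pre[[mt]]; yv <- post[[mt]]
    if (any(is.na(xv)) || any(is.na(yv))) {
      abort(sprintf("metric '%s' has missing values", mt))
    }
    res <- if (paired) {
      post_m <- post[match(pre$patient, post$patient), , drop = FALSE]
      wt <- suppressWarnings(stats::wilcox.test(xv, post_m[[mt]], paired = TRUE))
      tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
             method = "signed-rank", n_x = length(xv), n_y = length(yv))
    } else {
      wilcoxon_rank_sum_exact(xv, yv)
    }
    tibble(metric = mt, statistic = res$statistic, p_value = res$p_value,
           method = res$method, median_pre = median(xv),
           median_post = median(yv))
  })
}

normalize_symbol <- function(x) toupper(trimws(x))

#' Partition mutated genes into repaired, shared and new sets
#'
#' Set algebra on the unique gene symbols mutated before and after
#' treatment: genes only mutated pre-treatment ("repaired"), genes mutated
#' at both timepoints, and genes only mutated post-treatment (new). Empty
#' symbols are dropped; symbols are matched case-insensitively after
#' trimming.
#'
#' @param pre_variants,post_variants Variant tibbles with a `gene` column
#'   (or plain character vectors of symbols).
#' @return A list of class `gene_partition`: `pre_only`, `shared`,
#'   `post_only` (sorted character vectors, pairwise disjoint).
#' @export
partition_genes <- function(pre_variants, post_variants) {
  get_genes <- function(v) {
    g <- if (is.data.frame(v)) v$gene else v
    g <- normalize_symbol(g)
    sort(unique(g[!is.na(g) & g != ""]))
  }
  pre <- get_genes(pre_variants)
  post <- get_genes(post_variants)
  structure(list(
    pre_only = setdiff(pre, post),
    shared = intersect(pre, post),
    post_only = setdiff(post, pre)
  ), class = "gene_partition")
}

#' Genes shared by a set of patients in one partition component
#'
#' Intersection over the chosen patients of the chosen component of their
#' gene partitions (the cross-patient Venn overlap).
#'
#' @param partitions Named list of [partition_genes()] results, one per
#'   patient.
#' @param patients Non-empty subset of `names(partitions)`.
#' @param which One of `"pre_only"`, `"shared"`, `"post_only"`.
#' @return Sorted character vector of shared symbols.
#' @export
shared_across_patients <- function(partitions, patients,
                                   which = c("pre_only", "shared", "post_only")) {
  which <- match.arg(which)
  if (length(patients) == 0) abort("patients subset must be non-empty")
  unknown <- setdiff(patients, names(partitions))
  if (length(unknown) > 0) {
    abort(sprintf("unknown patient id(s): %s", paste(unknown, collapse = ", ")))
  }
  sets <- lapply(partitions[patients], function(p) p[[which]])
  sort(Reduce(intersect, sets))
}

#' Annotate genes against a driver-gene list
#'
#' @param genes Character vector of gene symbols.
#' @param driver_list Path to a newline-delimited symbol file (see
#'   [read_driver_list()]) or a character vector of driver symbols.
#' @return Tibble `gene`, `is_driver`; matching is case-insensitive after
#'   trimming.
#' @export
annotate_drivers <- function(genes, driver_list) {
  looks_like_path <- length(driver_list) == 1 && is.character(driver_list) &&
    (grepl("[/\\\\]", driver_list) || file.exists(driver_list))
  drivers <- if (looks_like_path) {
    read_driver_list(driver_list)
  } else if (is.character(driver_list)) {
    unique(normalize_symbol(driver_list))
  } else {
    abort("driver_list must be a file path or a character vector")
  }
  tibble(gene = genes, is_driver = normalize_symbol(genes) %in% drivers)
}

#' Dichotomize values at their median
#'
#' Labels a value `"high"` when strictly above the median (midpoint of the
#' two central order statistics for even n), `"low"` otherwise — so the
#' median element itself falls in the low group.
#'
#' @param values Non-empty numeric vector.
#' @return Character vector of `"high"`/`"low"` labels, same length as
#'   `values`, with the median attached as attribute `"cutoff"`.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) == 0) abort("cannot dichotomize an empty vector")
  med <- median(values)
  structure(ifelse(values > med, "high", "low"), cutoff = med)
}

#' Plot pre/post heterogeneity metric comparison
#'
#' Dot plot of each metric by timepoint across patients, faceted per metric
#' with free scales — the standard paired-cohort comparison figure.
#'
#' @param profiles Heterogeneity profile tibble.
#' @param metrics Metric columns to show; default all six.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(profiles,
                               metrics = c("tmb", "cna_burden", "wgii",
                                           "sdi", "ith", "math")) {
  long <- tidyr::pivot_longer(profiles[, c("patient", "timepoint", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$timepoint <- factor(long$timepoint, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$timepoint), size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
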