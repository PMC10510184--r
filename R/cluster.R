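# Subclonal clustering of somatic variants by a Dirichlet-process binomial
# mixture over joint pre/post cellular prevalences, with purity and
# copy-number correction. This re-implements the classic total-copy-number
# binomial model: a mutation at cellular prevalence phi in a tumor of purity
# t, locus copy number C_t (normal copy number c_n) and multiplicity m is
# expected at VAF xi = t*phi*m / ((1-t)*c_n + t*C_t).

#' Expected variant allele fraction at a given cellular prevalence
#'
#' `xi = (purity * phi * multiplicity) / ((1 - purity) * normal_cn +
#' purity * tumor_cn)`. Vectorized over all arguments.
#'
#' @param phi Cellular prevalence in \[0, 1\].
#' @param purity Tumor purity in (0, 1\].
#' @param tumor_cn Total copy number at the locus in tumor cells; default 2.
#' @param multiplicity Number of mutated copies; default 1.
#' @param normal_cn Copy number in contaminating normal cells; default 2.
#' @return Expected VAF in \[0, 1\].
#' @export
expected_vaf <- function(phi, purity, tumor_cn = 2, multiplicity = 1,
                         normal_cn = 2) {
  denom <- (1 - purity) * normal_cn + purity * tumor_cn
  if (any(denom <= 0)) abort("expected_vaf: nonpositive denominator")
  purity * phi * multiplicity / denom
}

#' Sampler settings for subclonal clustering
#'
#' @param grid_size Number of equally spaced prevalence grid points per
#'   sample (the DP base measure is uniform over this grid); default 101.
#' @param iterations Total Gibbs sweeps; default 1000.
#' @param burn_in Sweeps discarded before accumulating the co-assignment
#'   matrix; default 500.
#' @param alpha DP concentration parameter; default 1.
#' @param cut_height Co-assignment distance at which the average-linkage
#'   consensus dendrogram is cut for the hard assignment; default 0.5.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(grid_size = 101, iterations = 1000, burn_in = 500,
                           alpha = 1, cut_height = 0.5) {
  stopifnot(grid_size >= 2, iterations > burn_in, burn_in >= 0, alpha > 0,
            cut_height > 0, cut_height < 1)
  structure(list(grid_size = grid_size, iterations = iterations,
                 burn_in = burn_in, alpha = alpha, cut_height = cut_height),
            class = "cluster_config")
}

#' Cluster somatic variants into subclones
#'
#' Fits a Dirichlet-process binomial mixture to the per-sample alternate
#' read counts of each mutation by Gibbs sampling. A cluster's parameter is
#' one cellular prevalence per sample on a discrete grid; mutation `i`'s
#' likelihood in a cluster is the product over samples of
#' `Binomial(alt | depth, expected_vaf(phi, purity, tumor_cn, multiplicity))`.
#' Chinese-restaurant-process sweeps reassign mutations; after burn-in the
#' posterior co-assignment matrix is accumulated, and the hard assignment is
#' obtained by average-linkage clustering of co-assignment distances cut at
#' `cut_height`. Per-cluster prevalences are posterior means over the grid
#' given the consensus membership. Identical input and seed give identical
#' output.
#'
#' A mutation observed in only a subset of samples (depth 0 elsewhere)
#' contributes no likelihood in the samples without reads; a mutation with
#' zero depth in *every* sample is an error naming the mutation.
#'
#' @param observations Long tibble with one row per mutation and sample:
#'   columns `id`, `sample`, `alt`, `depth`, and optionally `tumor_cn`
#'   (default 2) and `multiplicity` (default 1).
#' @param purity Named numeric vector of tumor purities, one per sample
#'   appearing in `observations`.
#' @param config A [cluster_config()].
#' @param seed Integer RNG seed; required.
#' @param normal_cn Copy number in normal cells; default 2.
#' @return An object of class `clone_clusters`: list with `assignments`
#'   (tibble `id`, `cluster`), `phi` (tibble `cluster`, `sample`, `phi`),
#'   `sizes` (named integer vector), `coassign` matrix and `diagnostics`
#'   (iterations, burn-in, seed, alpha, grid size, per-sweep cluster-count
#'   trace).
#' @export
cluster_mutations <- function(observations, purity, config = cluster_config(),
                              seed, normal_cn = 2) {
  if (missing(seed) || is.null(seed)) abort("cluster_mutations: seed is required")
  stopifnot(inherits(config, "cluster_config"))
  obs <- tibble::as_tibble(observations)
  need <- c("id", "sample", "alt", "depth")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols) > 0) {
    abort(sprintf("observations lack column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"tumor_cn" %in% names(obs)) obs$tumor_cn <- 2
  if (!"multiplicity" %in% names(obs)) obs$multiplicity <- 1
  obs$tumor_cn <- dplyr::coalesce(obs$tumor_cn, 2)
  obs$multiplicity <- dplyr::coalesce(obs$multiplicity, 1)
  if (any(obs$alt < 0) || any(obs$alt > obs$depth)) {
    abort("observations must satisfy 0 <= alt <= depth")
  }
  samples <- unique(obs$sample)
  if (!all(samples %in% names(purity))) {
    abort(sprintf("purity missing for sample(s): %s",
                  paste(setdiff(samples, names(purity)), collapse = ", ")))
  }
  ids <- unique(obs$id)
  n <- length(ids)
  if (n == 0) abort("no observations")
  tot_depth <- tapply(obs$depth, factor(obs$id, levels = ids), sum)
  dead <- names(tot_depth)[is.na(tot_depth) | tot_depth == 0]
  if (length(dead) > 0) {
    abort(sprintf("mutation(s) with zero depth in every sample: %s",
                  paste(dead, collapse = ", ")))
  }

  G <- config$grid_size
  S <- length(samples)
  grid <- seq(0, 1, length.out = G)
  # per-mutation log-likelihood over the prevalence grid, per sample
  loglik <- array(0, dim = c(n, G, S))
  for (s in seq_len(S)) {
    sub <- obs[obs$sample == samples[s], , drop = FALSE]
    idx <- match(sub$id, ids)
    for (k in seq_len(nrow(sub))) {
      if (sub$depth[k] == 0) next
      xi <- expected_vaf(grid, purity[[samples[s]]], sub$tumor_cn[k],
                         sub$multiplicity[k], normal_cn)
      loglik[idx[k], , s] <- dbinom(sub$alt[k], sub$depth[k], xi, log = TRUE)
    }
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  fit <- .dp_gibbs(as.numeric(loglik), n, G, S, config$alpha,
                   config$iterations, config$burn_in)
  co <- fit$coassign

  cluster_raw <- if (n == 1) 1L else {
    hc <- hclust(as.dist(1 - co), method = "average")
    cutree(hc, h = config$cut_height)
  }
  # renumber clusters by order of first appearance for determinism
  first <- match(unique(cluster_raw), cluster_raw)
  relabel <- setNames(seq_along(first), cluster_raw[first])
  cluster <- unname(relabel[as.character(cluster_raw)])

  assignments <- tibble(id = ids, cluster = as.integer(cluster))
  phi <- posterior_phi(loglik, grid, assignments$cluster, samples)
  sizes <- table(factor(assignments$cluster, levels = sort(unique(cluster))))
  structure(list(
    assignments = assignments,
    phi = phi,
    sizes = setNames(as.integer(sizes), names(sizes)),
    coassign = co,
    diagnostics = list(
      iterations = config$iterations, burn_in = config$burn_in,
      seed = seed, alpha = config$alpha, grid_size = G,
      samples = samples, k_trace = as.integer(fit$k_trace))
  ), class = "clone_clusters")
}

# posterior-mean prevalence per (cluster, sample) over the uniform grid,
# conditional on the hard assignment
posterior_phi <- function(loglik, grid, cluster, samples) {
  out <- list()
  for (cl in sort(unique(cluster))) {
    rows <- which(cluster == cl)
    for (s in seq_along(samples)) {
      ll <- colSums(loglik[rows, , s, drop = FALSE])
      w <- exp(ll - max(ll))
      out[[length(out) + 1L]] <- tibble(
        cluster = as.integer(cl), sample = samples[s],
        phi = sum(grid * w) / sum(w))
    }
  }
  dplyr::bind_rows(out)
}

#' Drop clusters with too few mutations
#'
#' Clusters with fewer than `min_mutations` members are removed: their
#' mutations become unassigned (`cluster = NA`) and their prevalence rows are
#' dropped. Surviving cluster ids are unchanged.
#'
#' @param result A `clone_clusters` object.
#' @param min_mutations Minimum cluster size to retain; default 2.
#' @return The filtered `clone_clusters` object.
#' @export
filter_clusters <- function(result, min_mutations = 2) {
  stopifnot(inherits(result, "clone_clusters"))
  keep <- names(result$sizes)[result$sizes >= min_mutations]
  keep_int <- as.integer(keep)
  result$assignments$cluster[!result$assignments$cluster %in% keep_int] <- NA_integer_
  result$phi <- result$phi[result$phi$cluster %in% keep_int, , drop = FALSE]
  result$sizes <- result$sizes[keep]
  result
}

# prevalence vector for one sample, named by cluster id
cluster_phis <- function(result, sample) {
  stopifnot(inherits(result, "clone_clusters"))
  ph <- result$phi[result$phi$sample == sample, , drop = FALSE]
  if (nrow(ph) == 0 && !sample %in% result$diagnostics$samples) {
    abort(sprintf("sample '%s' not present in cluster result", sample))
  }
  setNames(ph$phi, as.character(ph$cluster))
}

cluster_sizes <- function(result) result$sizes

#' Joint model log-likelihood at a given assignment
#'
#' Sum over clusters and samples of the log marginal binomial likelihood at
#' the posterior-mean prevalence of each cluster. Used for sanity checks
#' (a recovered assignment should beat a random one).
#'
#' @param observations,purity,normal_cn As in [cluster_mutations()].
#' @param assignment Integer vector of cluster labels, one per unique
#'   mutation id (in order of first appearance).
#' @return Log-likelihood (numeric scalar).
#' @export
assignment_loglik <- function(observations, purity, assignment, normal_cn = 2) {
  obs <- tibble::as_tibble(observations)
  if (!"tumor_cn" %in% names(obs)) obs$tumor_cn <- 2
  if (!"multiplicity" %in% names(obs)) obs$multiplicity <- 1
  ids <- unique(obs$id)
  stopifnot(length(assignment) == length(ids))
  total <- 0
  for (cl in unique(assignment)) {
    mem <- ids[assignment == cl]
    for (s in unique(obs$sample)) {
      sub <- obs[obs$sample == s & obs$id %in% mem & obs$depth > 0, ]
      if (nrow(sub) == 0) next
      # profile likelihood over phi on a fine grid
      grid <- seq(0, 1, length.out = 1001)
      ll <- vapply(grid, function(p) {
        xi <- expected_vaf(p, purity[[s]], sub$tumor_cn, sub$multiplicity,
                           normal_cn)
        sum(dbinom(sub$alt, sub$depth, xi, log = TRUE))
      }, numeric(1))
      total <- total + max(ll)
    }
  }
  total
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("<clone_clusters> %d mutations in %d cluster(s) [%s]\n",
              nrow(x$assignments), length(x$sizes),
              paste(x$diagnostics$samples, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.clone_clusters <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$phi, names_from = "sample",
                             values_from = "phi", names_prefix = "phi_")
  dplyr::left_join(x$assignments, wide, by = "cluster")
}

#' @export
glance.clone_clusters <- function(x, ...) {
  tibble(n_mutations = nrow(x$assignments),
         n_clusters = length(x$sizes),
         n_unassigned = sum(is.na(x$assignments$cluster)),
         iterations = x$diagnostics$iterations,
         burn_in = x$diagnostics$burn_in,
         seed = x$diagnostics$seed)
}

#' Plot subclonal cluster prevalences
#'
#' Scatter of per-cluster cellular prevalence in the first sample against the
#' second (point size = cluster size), the standard paired-sample subclone
#' view.
#'
#' @param object A `clone_clusters` object with two samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_clusters <- function(object, ...) {
  samples <- object$diagnostics$samples
  stopifnot(length(samples) >= 2)
  wide <- tidyr::pivot_wider(object$phi, names_from = "sample",
                             values_from = "phi")
  wide$size <- as.integer(object$sizes[as.character(wide$cluster)])
  ggplot2::ggplot(wide, ggplot2::aes(
    x = .data[[samples[1]]], y = .data[[samples[2]]],
    size = .data$size, colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("prevalence,", samples[1]),
                  y = paste("prevalence,", samples[2]),
                  colour = "cluster", size = "mutations") +
    ggplot2::theme_minimal()
}
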