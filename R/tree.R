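# Clone-tree inference by exhaustive search over labeled rooted trees,
# scored by the subclonal sum rule: in every sample, the prevalences of a
# clone's children may not exceed the parent's. At the scale of interest
# (<= 7 retained clusters) Cayley's K^(K-2) labeled trees are enumerable
# exactly, so the minimizer is deterministic and exactly testable. The
# stricter crossing rule (no child above an ancestor in any single sample)
# is deliberately not enforced; only the children-sum excess is penalized.

# decode a Pruefer sequence (values in 1..K) into an edge matrix
decode_prufer <- function(seq, K) {
  degree <- rep(1L, K)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = K - 1, ncol = 2)
  ptr <- 0L
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[k]] <- degree[seq[k]] - 1L
    ptr <- k
  }
  last <- which(degree == 1L)
  edges[K - 1, ] <- last
  edges
}

# orient an edge list away from the root; returns parent vector (0 at root)
orient_edges <- function(edges, K, root) {
  adj <- vector("list", K)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(K)
  parent[root] <- 0L
  queue <- root
  seen <- rep(FALSE, K)
  seen[root] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  parent
}

#' Enumerate every labeled rooted tree on a set of clusters
#'
#' Generates all `K^(K-2)` labeled trees on `K` nodes (Cayley's formula; one
#' tree for `K <= 2`) via Pruefer sequences, rooted at `root`, each exactly
#' once, ordered lexicographically by parent vector.
#'
#' @param cluster_ids Vector of cluster identifiers (`K = length`).
#' @param root The id to use as root; must be in `cluster_ids`.
#' @return A list of integer parent vectors (0 marks the root; entries index
#'   into `cluster_ids`), with `cluster_ids` attached as the
#'   `"cluster_ids"` attribute. `K > 7` is an error: enumerate smaller
#'   problems or merge clusters first.
#' @export
enumerate_rooted_trees <- function(cluster_ids, root) {
  K <- length(cluster_ids)
  if (K < 1) abort("need at least one cluster")
  if (K > 7) {
    abort(sprintf(
      "exhaustive enumeration is limited to 7 clusters (got %d); merge clusters first",
      K))
  }
  ri <- match(root, cluster_ids)
  if (is.na(ri)) abort("root must be one of cluster_ids")
  trees <- if (K == 1) {
    list(0L)
  } else if (K == 2) {
    p <- integer(2); p[ri] <- 0L; p[-ri] <- ri
    list(p)
  } else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), K - 2)))
    lapply(seq_len(nrow(seqs)), function(r) {
      orient_edges(decode_prufer(seqs[r, ], K), K, ri)
    })
  }
  if (length(trees) > 1) {
    ord <- do.call(order, as.data.frame(do.call(rbind, trees)))
    trees <- trees[ord]
  }
  attr(trees, "cluster_ids") <- cluster_ids
  attr(trees, "root") <- root
  trees
}

#' Sum-rule violation score of a clone tree
#'
#' `V = sum_s sum_v max(0, sum_{c in children(v)} phi[c, s] - phi[v, s])`:
#' the total excess, over all samples and internal nodes, of children's
#' prevalences over their parent's. Zero iff the sum rule holds everywhere.
#'
#' @param parent Integer parent vector as produced by
#'   [enumerate_rooted_trees()] (0 at the root).
#' @param phi Numeric matrix of prevalences, rows = clusters in parent-vector
#'   order, columns = samples.
#' @return Nonnegative violation score.
#' @export
tree_violation_score <- function(parent, phi) {
  phi <- as.matrix(phi)
  K <- length(parent)
  if (nrow(phi) != K) abort("phi must have one row per cluster")
  if (any(is.na(phi))) abort("every cluster needs a prevalence in every sample")
  v <- 0
  for (node in seq_len(K)) {
    children <- which(parent == node)
    if (length(children) == 0) next
    child_sum <- colSums(phi[children, , drop = FALSE])
    v <- v + sum(pmax(0, child_sum - phi[node, ]))
  }
  v
}

# root choice: maximal mean prevalence across samples; ties -> larger
# cluster, then lower id
choose_root <- function(phi_mat, sizes, ids) {
  means <- rowMeans(phi_mat)
  ord <- order(-means, -sizes, ids)
  ids[ord[1]]
}

# phi matrix (clusters x samples) from a clone_clusters object
phi_matrix <- function(result) {
  wide <- tidyr::pivot_wider(result$phi, names_from = "sample",
                             values_from = "phi")
  wide <- wide[order(wide$cluster), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cluster
  m
}

#' Infer the best-fitting clone tree by exhaustive search
#'
#' Roots the tree at the cluster with maximal mean prevalence across samples
#' (ties broken by larger cluster size, then lower id), enumerates every
#' labeled rooted tree, and returns the one minimizing the sum-rule
#' violation score; ties go to the lexicographically smallest parent vector.
#'
#' @param result A (retained) `clone_clusters` object, or a list with
#'   elements `phi` (matrix clusters x samples, rownames = ids) and `sizes`.
#' @return An object of class `clone_tree`: `nodes` (cluster ids), `root`,
#'   `parent` (named vector, `NA` at root), `phi` matrix and `score`.
#' @export
infer_best_tree <- function(result) {
  if (inherits(result, "clone_clusters")) {
    phi <- phi_matrix(result)
    sizes <- as.integer(result$sizes[rownames(phi)])
  } else {
    phi <- as.matrix(result$phi)
    sizes <- result$sizes
  }
  ids <- as.integer(rownames(phi))
  if (length(ids) == 0 || any(is.na(ids))) ids <- seq_len(nrow(phi))
  if (nrow(phi) == 0) abort("no retained clusters to build a tree from")
  root <- choose_root(phi, sizes, ids)
  trees <- enumerate_rooted_trees(ids, root)
  best <- NULL
  best_v <- Inf
  for (tr in trees) {
    v <- tree_violation_score(tr, phi)
    if (v < best_v - 1e-12) {
      best_v <- v
      best <- tr
    }
  }
  parent_ids <- ifelse(best == 0L, NA_integer_, ids[best])
  structure(list(nodes = ids, root = root,
                 parent = setNames(parent_ids, ids),
                 phi = phi, score = best_v),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d node(s), root %s, violation score %.4g\n",
              length(x$nodes), x$root, x$score))
  invisible(x)
}

#' @export
tidy.clone_tree <- function(x, ...) {
  ph <- as.data.frame(x$phi)
  names(ph) <- paste0("phi_", names(ph))
  tibble(cluster = x$nodes, parent = unname(x$parent[as.character(x$nodes)])) |>
    dplyr::bind_cols(tibble::as_tibble(ph))
}

#' @export
glance.clone_tree <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), root = x$root, violation_score = x$score)
}

node_depths <- function(tree) {
  depth <- setNames(rep(NA_integer_, length(tree$nodes)), tree$nodes)
  depth[as.character(tree$root)] <- 0L
  repeat {
    todo <- names(depth)[is.na(depth)]
    if (length(todo) == 0) break
    for (v in todo) {
      p <- tree$parent[[v]]
      if (!is.na(depth[as.character(p)])) {
        depth[v] <- depth[as.character(p)] + 1L
      }
    }
  }
  depth
}

#' Plot a clone tree
#'
#' Simple layered layout: depth below the root on the vertical axis, edges as
#' segments, nodes labeled by cluster id.
#'
#' @param object A `clone_tree` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clone_tree <- function(object, ...) {
  depth <- node_depths(object)
  ord <- order(depth, object$nodes)
  xs <- setNames(numeric(length(object$nodes)), object$nodes)
  for (d in sort(unique(depth))) {
    at <- names(depth)[depth == d]
    xs[at] <- seq_along(at) - (length(at) + 1) / 2
  }
  nodes <- tibble(id = names(depth), x = unname(xs), y = -unname(depth))
  edges <- nodes |>
    dplyr::mutate(parent = as.character(object$parent[.data$id])) |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::left_join(nodes, by = c(parent = "id"), suffix = c("", "_p"))
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges, ggplot2::aes(
      xend = .data$x_p, yend = .data$y_p)) +
    ggplot2::geom_point(size = 8, colour = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$id)) +
    ggplot2::theme_void()
}

#' Classify a patient's clonal evolution model
#'
#' The main clone is the retained cluster with the highest pre-treatment
#' prevalence (ties: larger cluster, then lower id). The patient is labeled
#' `"homogeneous"` when that clone is still present post-treatment
#' (prevalence at or above `presence_threshold`), `"heterogeneous"` when it
#' is not. Resistant clusters are those present above threshold in both
#' samples.
#'
#' @param result A retained `clone_clusters` object with paired samples.
#' @param presence_threshold Presence cutoff; default 0.10.
#' @param pre,post Sample names of the pre- and post-treatment samples;
#'   defaults `"pre"` and `"post"`.
#' @param patient Optional patient id carried into the result.
#' @param pfs_months Optional progression-free survival carried into the
#'   result.
#' @return One-row tibble of class `evolution_call`: `patient`, `label`,
#'   `main_clone`, `main_phi_pre`, `main_phi_post`, `resistant` (list column
#'   of cluster ids), `pfs_months`.
#' @export
classify_evolution_model <- function(result, presence_threshold = 0.10,
                                     pre = "pre", post = "post",
                                     patient = NA_character_,
                                     pfs_months = NA_real_) {
  phi_pre <- cluster_phis(result, pre)
  phi_post <- cluster_phis(result, post)
  if (length(phi_pre) == 0) abort("no retained clusters to classify")
  ids <- as.integer(names(phi_pre))
  sizes <- as.integer(result$sizes[names(phi_pre)])
  ord <- order(-phi_pre, -sizes, ids)
  main <- ids[ord[1]]
  main_key <- as.character(main)
  label <- if (phi_post[[main_key]] >= presence_threshold) "homogeneous" else "heterogeneous"
  resistant <- ids[phi_pre >= presence_threshold &
                     phi_post[names(phi_pre)] >= presence_threshold]
  out <- tibble(
    patient = patient, label = label, main_clone = main,
    main_phi_pre = unname(phi_pre[[main_key]]),
    main_phi_post = unname(phi_post[[main_key]]),
    resistant = list(resistant), pfs_months = pfs_months
  )
  class(out) <- c("evolution_call", class(out))
  out
}

#' Summarize progression-free survival by evolution model
#'
#' @param calls Tibble of evolution calls (rows from
#'   [classify_evolution_model()], bound together) with `label` and
#'   `pfs_months` present for every patient.
#' @return Tibble with one row per label: `label`, `n`, `pfs` (list column)
#'   and `median_pfs`. No hypothesis test is run (cohorts of this design are
#'   far too small).
#' @export
group_pfs_by_model <- function(calls) {
  miss <- calls$patient[is.na(calls$pfs_months)]
  if (length(miss) > 0) {
    abort(sprintf("missing PFS for patient(s): %s", paste(miss, collapse = ", ")))
  }
  calls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     pfs = list(sort(.data$pfs_months)),
                     median_pfs = median(.data$pfs_months),
                     .groups = "drop")
}
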