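test_that("rooted-tree enumeration matches Cayley's formula and brute force", {
  expect_length(enumerate_rooted_trees(1, 1), 1)
  expect_length(enumerate_rooted_trees(1:2, 1), 1)
  expect_length(enumerate_rooted_trees(1:3, 1), 3)
  expect_length(enumerate_rooted_trees(1:4, 2), 16)
  expect_length(enumerate_rooted_trees(1:5, 1), 125)
  expect_length(enumerate_rooted_trees(1:6, 3), 1296)
  # independent brute-force count over all parent vectors
  for (K in 2:4) {
    expect_equal(length(enumerate_rooted_trees(seq_len(K), 1)),
                 count_rooted_trees_bruteforce(K, 1))
  }
  expect_error(enumerate_rooted_trees(1:8, 1), "7")
})

test_that("enumerated trees are distinct, valid and lexicographically ordered", {
  trees <- enumerate_rooted_trees(1:4, 1)
  keys <- vapply(trees, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0)
  mat <- do.call(rbind, trees)
  expect_true(all(mat[, 1] == 0))                     # rooted at node 1
  expect_false(is.unsorted(keys))                     # would be 0-padded ties only
  for (tr in trees) {
    # every node reaches the root
    for (v in 2:4) {
      cur <- v; hops <- 0
      while (cur != 1 && hops < 5) { cur <- tr[cur]; hops <- hops + 1 }
      expect_equal(cur, 1)
    }
  }
})

test_that("violation score is zero for nested chains and counts child excess", {
  # chain root(0.9) -> child(0.4) -> grandchild(0.1)
  expect_equal(tree_violation_score(c(0L, 1L, 2L),
                                    matrix(c(0.9, 0.4, 0.1))), 0)
  # root(0.5) with children 0.4 and 0.3: excess 0.2
  expect_equal(tree_violation_score(c(0L, 1L, 1L),
                                    matrix(c(0.5, 0.4, 0.3))), 0.2)
  # all zero except root
  expect_equal(tree_violation_score(c(0L, 1L, 1L),
                                    matrix(c(0.7, 0, 0))), 0)
  # summed over samples
  phi2 <- cbind(c(0.5, 0.4, 0.3), c(0.5, 0.5, 0.3))
  expect_equal(tree_violation_score(c(0L, 1L, 1L), phi2), 0.2 + 0.3)
  expect_error(tree_violation_score(c(0L, 1L, 1L), matrix(c(0.5, NA, 0.1))),
               "prevalence")
})

test_that("exhaustive search recovers a sum-rule-consistent topology", {
  # phis satisfy the sum rule only for A -> B, A -> C
  phi <- rbind(A = c(0.95, 0.9), B = c(0.5, 0.1), C = c(0.3, 0.6))
  rownames(phi) <- 1:3
  tree <- infer_best_tree(list(phi = phi, sizes = c(10, 5, 5)))
  expect_equal(tree$root, 1)
  expect_equal(tree$score, 0)
  expect_equal(unname(tree$parent), c(NA, 1L, 1L))

  single <- infer_best_tree(list(phi = matrix(0.8, 1, 2,
                                              dimnames = list("1", NULL)),
                                 sizes = 5))
  expect_equal(single$score, 0)
  expect_length(single$nodes, 1)

  two <- infer_best_tree(list(
    phi = matrix(c(0.9, 0.4, 0.8, 0.3), 2, 2, dimnames = list(1:2, NULL)),
    sizes = c(6, 4)))
  expect_equal(unname(two$parent), c(NA, 1L))
})

test_that("prevalences generated under the sum rule always admit a zero-violation tree", {
  withr::local_seed(404)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    parent <- integer(K)
    for (k in seq(2, K)) parent[k] <- sample.int(k - 1, 1)
    gen_phi <- function() {
      phi <- numeric(K)
      phi[1] <- runif(1, 0.7, 1)
      for (k in 2:K) {
        sibs <- which(parent == parent[k] & seq_len(K) < k)
        avail <- phi[parent[k]] - sum(phi[sibs])
        phi[k] <- runif(1, 0, max(avail, 0))
      }
      phi
    }
    phi <- cbind(gen_phi(), gen_phi())
    rownames(phi) <- seq_len(K)
    expect_equal(tree_violation_score(parent, phi), 0)
    tree <- infer_best_tree(list(phi = phi, sizes = rep(5, K)))
    expect_equal(tree$score, 0)
  }
})

test_that("evolution-model classification follows the main-clone presence rule", {
  mk <- function(phi_pre, phi_post, sizes = NULL) {
    K <- length(phi_pre)
    if (is.null(sizes)) sizes <- rep(5L, K)
    structure(list(
      assignments = tibble::tibble(id = as.character(seq_len(sum(sizes))),
                                   cluster = rep(seq_len(K), sizes)),
      phi = dplyr::bind_rows(
        tibble::tibble(cluster = seq_len(K), sample = "pre", phi = phi_pre),
        tibble::tibble(cluster = seq_len(K), sample = "post", phi = phi_post)),
      sizes = setNames(as.integer(sizes), seq_len(K)),
      diagnostics = list(samples = c("pre", "post"))), class = "clone_clusters")
  }
  # unchanged tumor: homogeneous, every present cluster resistant
  same <- classify_evolution_model(mk(c(0.9, 0.4, 0.05), c(0.9, 0.4, 0.05)))
  expect_equal(same$label, "homogeneous")
  expect_setequal(same$resistant[[1]], c(1, 2))
  # main clone eradicated, new cluster expands: heterogeneous
  gone <- classify_evolution_model(mk(c(0.9, 0.0), c(0.0, 0.8)))
  expect_equal(gone$label, "heterogeneous")
  expect_equal(gone$main_clone, 1)
  # threshold boundary: presence at exactly 0.10 counts as present
  edge <- classify_evolution_model(mk(c(0.9, 0.3), c(0.10, 0.5)))
  expect_equal(edge$label, "homogeneous")
  # tie on phi_pre broken by larger cluster size
  tie <- classify_evolution_model(mk(c(0.8, 0.8), c(0.0, 0.8),
                                     sizes = c(3, 9)))
  expect_equal(tie$main_clone, 2)
  expect_equal(tie$label, "homogeneous")
  # adding sub-threshold clusters in both samples changes nothing
  base <- classify_evolution_model(mk(c(0.9, 0.4), c(0.0, 0.8)))
  extra <- classify_evolution_model(mk(c(0.9, 0.4, 0.05), c(0.0, 0.8, 0.03)))
  expect_equal(extra$label, base$label)
  expect_equal(extra$main_clone, base$main_clone)
  expect_setequal(extra$resistant[[1]], base$resistant[[1]])
})

test_that("PFS grouping returns per-label lists and medians", {
  calls <- tibble::tibble(
    patient = paste0("P", 1:5),
    label = c("heterogeneous", "heterogeneous", "heterogeneous",
              "homogeneous", "homogeneous"),
    pfs_months = c(23, 11.6, 7.3, 2.4, 2.9))
  g <- group_pfs_by_model(calls)
  expect_equal(g$median_pfs[g$label == "homogeneous"], 2.65)
  expect_equal(g$median_pfs[g$label == "heterogeneous"], 11.6)
  expect_equal(g$pfs[g$label == "heterogeneous"][[1]], c(7.3, 11.6, 23))
  # single label present
  g1 <- group_pfs_by_model(calls[4:5, ])
  expect_equal(nrow(g1), 1)
  # all equal PFS
  eq <- calls; eq$pfs_months <- 5
  expect_true(all(group_pfs_by_model(eq)$median_pfs == 5))
  # missing PFS errors with the patient name
  bad <- calls; bad$pfs_months[2] <- NA
  expect_error(group_pfs_by_model(bad), "P2")
})
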