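test_that("expected_vaf matches hand evaluations of the purity/CN model", {
  expect_equal(expected_vaf(1, 1, 2, 1, 2), 0.5)
  expect_equal(expected_vaf(0, 0.7, 3, 2, 2), 0)
  expect_equal(expected_vaf(0.5, 0.8, 2, 1, 2), 0.4 / 2.0)
  # vectorized and monotone in phi
  phis <- seq(0, 1, by = 0.25)
  xi <- expected_vaf(phis, 0.8)
  expect_true(all(diff(xi) > 0))
})

test_that("single-component data collapses to one cluster", {
  withr::local_seed(301)
  sim <- sim_observations(0.6, 0.6, n_per_cluster = 60, depth = 500, purity = 1)
  cl <- cluster_mutations(sim$obs, purity = c(pre = 1, post = 1), seed = 17)
  expect_equal(length(cl$sizes), 1)
  expect_equal(unname(cl$sizes[1]), 60)
  ph <- cl$phi$phi
  expect_true(all(abs(ph - 0.6) < 0.05))
})

test_that("two well-separated clusters are recovered exactly with accurate phi", {
  withr::local_seed(302)
  sim <- sim_observations(c(0.9, 0.3), c(0.9, 0.05), n_per_cluster = 40,
                          depth = 500, purity = 1)
  cl <- cluster_mutations(sim$obs, purity = c(pre = 1, post = 1), seed = 19)
  est <- cl$assignments$cluster
  expect_equal(adjusted_rand(est, sim$truth), 1)
  ph <- tidyr::pivot_wider(cl$phi, names_from = "sample", values_from = "phi")
  truth_phi <- tibble::tibble(pre = c(0.9, 0.3), post = c(0.9, 0.05))
  # match recovered clusters to truth by majority membership
  for (k in 1:2) {
    rec <- unique(est[sim$truth == k])
    expect_length(rec, 1)
    expect_lt(abs(ph$pre[ph$cluster == rec] - truth_phi$pre[k]), 0.05)
    expect_lt(abs(ph$post[ph$cluster == rec] - truth_phi$post[k]), 0.05)
  }
})

test_that("identical seed and input reproduce the result exactly", {
  withr::local_seed(303)
  sim <- sim_observations(c(0.8, 0.4), c(0.2, 0.6), n_per_cluster = 20,
                          depth = 300, purity = 0.9)
  a <- cluster_mutations(sim$obs, purity = c(pre = 0.9, post = 0.9), seed = 23)
  b <- cluster_mutations(sim$obs, purity = c(pre = 0.9, post = 0.9), seed = 23)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$phi, b$phi)
  expect_identical(a$coassign, b$coassign)
  expect_identical(a$diagnostics$k_trace, b$diagnostics$k_trace)
})

test_that("a mutation with zero depth in every sample is rejected by name", {
  obs <- tibble::tibble(id = c("m1", "m1", "m2", "m2"),
                        sample = rep(c("pre", "post"), 2),
                        alt = c(10, 10, 0, 0), depth = c(50, 50, 0, 0))
  expect_error(cluster_mutations(obs, c(pre = 1, post = 1), seed = 1), "m2")
})

test_that("a mutation missing from one sample stays in the model", {
  withr::local_seed(304)
  sim <- sim_observations(c(0.9, 0.3), c(0.9, 0.3), n_per_cluster = 15,
                          depth = 400, purity = 1)
  obs <- sim$obs
  # delete the pre-sample observation of one mutation entirely
  obs <- obs[!(obs$id == "c1_m1" & obs$sample == "pre"), ]
  cl <- cluster_mutations(obs, purity = c(pre = 1, post = 1), seed = 29)
  expect_true("c1_m1" %in% cl$assignments$id)
})

test_that("filter_clusters drops small clusters and keeps ids stable", {
  withr::local_seed(305)
  # engineer sizes {5, 1, 3}: two separated clusters plus one outlier mutation
  sim <- sim_observations(c(0.9, 0.25), c(0.9, 0.25), n_per_cluster = 5,
                          depth = 1000, purity = 1)
  obs <- sim$obs[!(sim$obs$id %in% paste0("c2_m", 4:5)), ]
  out <- tibble::tibble(id = "lone", sample = c("pre", "post"),
                        alt = c(580, 40), depth = 1000)
  cl <- cluster_mutations(dplyr::bind_rows(obs, out),
                          purity = c(pre = 1, post = 1), seed = 31)
  expect_setequal(unname(cl$sizes), c(5, 3, 1))
  kept <- filter_clusters(cl, min_mutations = 2)
  expect_setequal(unname(kept$sizes), c(5, 3))
  expect_equal(sum(is.na(kept$assignments$cluster)), 1)
  expect_setequal(names(kept$sizes),
                  intersect(names(cl$sizes), names(kept$sizes)))
  # retaining everything or using min_mutations = 1 is the identity
  expect_equal(filter_clusters(cl, min_mutations = 1), cl)
})

test_that("fitted assignment beats random assignments in model log-likelihood", {
  withr::local_seed(306)
  for (i in 1:3) {
    k <- sample(2:3, 1)
    phi_pre <- seq(0.9, 0.2, length.out = k)
    phi_post <- rev(phi_pre)
    sim <- sim_observations(phi_pre, phi_post, n_per_cluster = 15,
                            depth = 500, purity = 0.8)
    cl <- cluster_mutations(sim$obs, purity = c(pre = 0.8, post = 0.8),
                            seed = 100 + i)
    ll_fit <- assignment_loglik(sim$obs, c(pre = 0.8, post = 0.8),
                                cl$assignments$cluster)
    ll_rand <- assignment_loglik(sim$obs, c(pre = 0.8, post = 0.8),
                                 sample(cl$assignments$cluster))
    expect_gte(ll_fit, ll_rand)
  }
})

test_that("posterior mean prevalence approaches the moment estimate (grid limit)", {
  # one mutation, one cluster: phi_hat ~ VAF * ((1-t)c_n + t*C_t) / (t*m)
  cases <- tibble::tribble(
    ~alt, ~depth, ~t, ~cn, ~m,
    1200, 4000, 0.8, 2, 1,
    900, 3000, 1.0, 2, 1,
    800, 4000, 0.8, 3, 1)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    obs <- tibble::tibble(id = "m", sample = "s", alt = cs$alt,
                          depth = cs$depth, tumor_cn = cs$cn,
                          multiplicity = cs$m)
    cl <- cluster_mutations(obs, purity = c(s = cs$t), seed = 5)
    vaf <- cs$alt / cs$depth
    moment <- min(1, vaf * ((1 - cs$t) * 2 + cs$t * cs$cn) / (cs$t * cs$m))
    expect_lt(abs(cl$phi$phi - moment), 1 / 100)
  }
})

test_that("downstream metrics are invariant to cluster relabeling", {
  withr::local_seed(307)
  sim <- sim_observations(c(0.9, 0.5, 0.2), c(0.9, 0.1, 0.4),
                          n_per_cluster = 20, depth = 500, purity = 0.8)
  cl <- cluster_mutations(sim$obs, purity = c(pre = 0.8, post = 0.8), seed = 41)
  cl <- filter_clusters(cl)
  relabeled <- cl
  ids <- sort(unique(relabeled$assignments$cluster))
  perm <- setNames(rev(ids), ids)
  relabeled$assignments$cluster <- unname(perm[as.character(relabeled$assignments$cluster)])
  relabeled$phi$cluster <- unname(perm[as.character(relabeled$phi$cluster)])
  names(relabeled$sizes) <- as.character(perm[names(relabeled$sizes)])

  for (s in c("pre", "post")) {
    expect_equal(compute_ith(relabeled, s), compute_ith(cl, s))
  }
  a <- classify_evolution_model(cl)
  b <- classify_evolution_model(relabeled)
  expect_equal(b$label, a$label)
  expect_equal(b$main_phi_pre, a$main_phi_pre)
  expect_setequal(unname(perm[as.character(a$resistant[[1]])]),
                  b$resistant[[1]])
})
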