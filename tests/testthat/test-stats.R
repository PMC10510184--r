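test_that("exact rank-sum p-values come from full enumeration", {
  res <- wilcoxon_rank_sum_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 2 / 20)  # 2 extreme assignments of C(6,3)=20
  expect_equal(res$statistic, 6)
  expect_equal(res$method, "exact")
  # identical multisets: maximal symmetry
  expect_equal(wilcoxon_rank_sum_exact(c(2, 5, 9), c(2, 5, 9))$p_value, 1)
  # n = m = 1: both assignments are extreme
  expect_equal(wilcoxon_rank_sum_exact(4, 7)$p_value, 1)
  expect_error(wilcoxon_rank_sum_exact(numeric(0), 1), "non-empty")
})

test_that("exact p matches the enumeration oracle on random small samples", {
  withr::local_seed(501)
  for (i in 1:50) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    # draw from a small integer range so ties are frequent
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, m, replace = TRUE)
    res <- wilcoxon_rank_sum_exact(x, y)
    expect_equal(res$p_value, wilcoxon_oracle(x, y), tolerance = 1e-12)
    # symmetry in the two groups
    expect_equal(wilcoxon_rank_sum_exact(y, x)$p_value, res$p_value)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("exact p agrees with the classical distribution when there are no ties", {
  withr::local_seed(502)
  for (i in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- sample(1:100, n); y <- setdiff(sample(1:100, n + m), x)[seq_len(m)]
    ours <- wilcoxon_rank_sum_exact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("compare_pre_post runs every metric against the enumeration oracle", {
  profiles <- tibble::tibble(
    patient = rep(paste0("P", 1:5), 2),
    timepoint = rep(c("pre", "post"), each = 5),
    cna_burden = c(6.99, 4.88, 17.05, 11.90, 20.78,
                   11.25, 0.08, 2.05, 1.21, 7.98),
    tmb = c(4.34, 3.03, 16.32, 4.66, 5.82, 1.05, 2.32, 1.13, 4.53, 1.00),
    ith = c(4, 1, 2, 6, 2, 4, 4, 7, 6, 2),
    sdi = c(0.66, 0.46, 0.23, 1.03, 0.14, 0.91, 0.0, 1.02, 1.08, 0.22),
    wgii = c(0.24, 0.11, 0.09, 0.01, 1.00, 0.14, 0.35, 0.23, 0.44, 0.90),
    math = c(44.77, 61.48, 74.22, 34.12, 46.28,
             48.46, 35.47, 31.71, 34.42, 49.32))
  tab <- compare_pre_post(profiles)
  expect_equal(nrow(tab), 6)
  for (i in seq_len(nrow(tab))) {
    m <- tab$metric[i]
    expect_equal(tab$p_value[i],
                 wilcoxon_oracle(profiles[[m]][profiles$timepoint == "pre"],
                                 profiles[[m]][profiles$timepoint == "post"]),
                 tolerance = 1e-12, info = m)
  }
  # identical pre and post lists give p = 1
  same <- profiles
  same[same$timepoint == "post", 3:8] <- same[same$timepoint == "pre", 3:8]
  expect_true(all(compare_pre_post(same)$p_value == 1))
  # single patient runs with n = m = 1
  one <- profiles[profiles$patient == "P1", ]
  expect_true(all(compare_pre_post(one)$p_value == 1))
  # missing metric named in the error
  expect_error(compare_pre_post(profiles[, -4]), "tmb")
})

test_that("gene partitions follow set algebra and reconstruct their inputs", {
  p <- partition_genes(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(p$pre_only, "A")
  expect_equal(p$shared, c("B", "C"))
  expect_equal(p$post_only, "D")
  expect_equal(partition_genes(c("A"), c("B"))$shared, character(0))
  same <- partition_genes(c("A", "B"), c("B", "A"))
  expect_equal(same$pre_only, character(0))
  expect_equal(same$post_only, character(0))
  # empty symbols dropped; case-insensitive
  p2 <- partition_genes(tibble::tibble(gene = c("tp53", "", NA)),
                        tibble::tibble(gene = "TP53"))
  expect_equal(p2$shared, "TP53")
  expect_equal(p2$pre_only, character(0))

  withr::local_seed(601)
  for (i in 1:20) {
    pre <- sample(LETTERS, sample(0:15, 1))
    post <- sample(LETTERS, sample(0:15, 1))
    part <- partition_genes(pre, post)
    expect_length(intersect(part$pre_only, part$shared), 0)
    expect_length(intersect(part$pre_only, part$post_only), 0)
    expect_length(intersect(part$shared, part$post_only), 0)
    expect_setequal(c(part$pre_only, part$shared), unique(pre))
    expect_setequal(c(part$post_only, part$shared), unique(post))
  }
})

test_that("cross-patient intersections find the shared repaired and new genes", {
  parts <- list(
    P1 = partition_genes(c("MUC7", "MUC5B", "FLG", "AX1"), c("ZNF1")),
    P2 = partition_genes(c("MUC7", "MUC5B", "TTN"), c("ZNF2")),
    P3 = partition_genes(c("MUC7", "MUC5B", "OBSCN"), c("ZNF3")),
    P4 = partition_genes(c("KRAS"), c("ZNF91", "EP400")),
    P5 = partition_genes(c("BRAF"), c("ZNF91", "NPW")))
  expect_equal(shared_across_patients(parts, c("P1", "P2", "P3"), "pre_only"),
               c("MUC5B", "MUC7"))
  expect_equal(shared_across_patients(parts, c("P4", "P5"), "post_only"),
               "ZNF91")
  expect_equal(shared_across_patients(parts, names(parts), "pre_only"),
               character(0))
  expect_error(shared_across_patients(parts, "P9", "pre_only"), "P9")
  # monotone non-increasing as patients are added
  withr::local_seed(602)
  for (i in 1:10) {
    rp <- lapply(1:4, function(j) partition_genes(sample(LETTERS, 10), "ZZ"))
    names(rp) <- paste0("Q", 1:4)
    prev <- NULL
    for (k in 1:4) {
      cur <- shared_across_patients(rp, paste0("Q", 1:k), "pre_only")
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("driver annotation is case-insensitive and handles empty lists", {
  ann <- annotate_drivers(c("TP53", "MUC7"), c("TP53"))
  expect_equal(ann$is_driver, c(TRUE, FALSE))
  expect_equal(annotate_drivers(c("tp53"), c("TP53"))$is_driver, TRUE)
  expect_false(any(annotate_drivers(c("TP53"), character(0))$is_driver))
  path <- tempfile()
  writeLines(c("# drivers", " tp53 ", "AR"), path)
  ann2 <- annotate_drivers(c("TP53", "AR", "PTEN"), path)
  expect_equal(ann2$is_driver, c(TRUE, TRUE, FALSE))
  expect_error(annotate_drivers("TP53", file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("median dichotomization is strict so the median element falls low", {
  lab <- dichotomize_by_median(c(1, 2, 3, 4))
  expect_equal(unclass(lab)[1:4], c("low", "low", "high", "high"),
               ignore_attr = TRUE)
  expect_equal(attr(lab, "cutoff"), 2.5)
  expect_true(all(dichotomize_by_median(rep(7, 5)) == "low"))
  expect_equal(as.character(dichotomize_by_median(5)), "low")
  expect_error(dichotomize_by_median(numeric(0)), "empty")
})
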