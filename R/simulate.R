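# Synthetic paired pre/post tumor cohorts with known ground truth. Each
# patient is a random rooted clone tree whose pre-treatment prevalences are
# drawn top-down under the subclonal sum rule; the treatment scenario decides
# the post-treatment prevalences (homogeneous: the main clone persists with
# perturbed subclones; heterogeneous: the main clone is eradicated and a
# non-main lineage expands). Read counts are binomial at negative-binomial
# depths through the purity/copy-number VAF model, and germline contaminants
# and common polymorphisms are injected with filter-failing properties so the
# variant filters are exercised end to end.

#' Settings for the synthetic cohort generator
#'
#' Defaults emulate a small paired-exome treatment cohort: 5 patients, two
#' timepoints, mean coverage 500x, purity around 0.8, 4 subclones of ~10
#' mutations each, a fifth of the genome copy-number deviated, and a handful
#' of germline/polymorphism contaminants per patient for filter testing.
#'
#' @param n_patients Number of patients; default 5.
#' @param prop_homogeneous Fraction of patients generated under the
#'   homogeneous (main clone persists) scenario; default 0.4, i.e. 2 of 5.
#' @param k_clusters Subclone count per patient before treatment-induced
#'   additions, in 2..6; default 4.
#' @param mutations_per_cluster Mean mutations per subclone (Poisson, min 2);
#'   default 10.
#' @param purity Tumor purity of generated samples (jittered by up to 0.03
#'   per sample and recorded in the manifest); default 0.8.
#' @param mean_depth Mean sequencing depth; default 500.
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   distribution; default 50.
#' @param cn_deviated_fraction Fraction of copy-number segments deviating
#'   from diploid; default 0.2.
#' @param n_germline_contaminants Germline-heterozygous contaminant variants
#'   injected per patient (fail the germline-support filter); default 5.
#' @param n_polymorphisms Common-polymorphism variants injected per patient
#'   (fail the population-frequency filter); default 5.
#' @param capture_size_mb Capture footprint recorded for TMB; default 38.
#' @param presence_threshold Prevalence above which a clone counts as
#'   present; default 0.10.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_patients = 5, prop_homogeneous = 0.4,
                              k_clusters = 4, mutations_per_cluster = 10,
                              purity = 0.8, mean_depth = 500,
                              depth_dispersion = 50,
                              cn_deviated_fraction = 0.2,
                              n_germline_contaminants = 5,
                              n_polymorphisms = 5, capture_size_mb = 38,
                              presence_threshold = 0.10) {
  stopifnot(n_patients >= 0, prop_homogeneous >= 0, prop_homogeneous <= 1,
            k_clusters >= 2, k_clusters <= 6, mutations_per_cluster >= 2,
            purity > 0, purity <= 1, mean_depth > 0, depth_dispersion > 0,
            cn_deviated_fraction >= 0, cn_deviated_fraction <= 1,
            n_germline_contaminants >= 0, n_polymorphisms >= 0,
            capture_size_mb > 0, presence_threshold > 0)
  structure(as.list(environment()), class = "sim_config")
}

# bundled realistic symbols for generated mutations
symbol_pool <- function() {
  path <- system.file("extdata", "gene_symbols.txt", package = "clonevo")
  readLines(path, warn = FALSE)
}

# integer copy number at a position from a segment table (2 outside segments)
locate_cn <- function(segments, chrom, pos) {
  hit <- segments$total_cn[normalize_chrom(segments$chrom) == normalize_chrom(chrom) &
                             segments$start <= pos & segments$end >= pos]
  if (length(hit) >= 1) hit[1] else 2
}

# random non-overlapping integer-CN segments over the autosomes
sim_segments <- function(cn_deviated_fraction, sample_id) {
  rows <- list()
  for (chr in 1:22) {
    n_seg <- sample(2:4, 1)
    cuts <- sort(sample(seq(2e6, 118e6, by = 1e6), n_seg - 1))
    bounds <- c(1, cuts, 120e6)
    for (k in seq_len(n_seg)) {
      dev <- runif(1) < cn_deviated_fraction
      rows[[length(rows) + 1L]] <- tibble(
        sample = sample_id, chrom = as.character(chr),
        start = bounds[k] + (k > 1), end = bounds[k + 1],
        total_cn = if (dev) sample(c(1L, 3L, 4L), 1) else 2L)
    }
  }
  seg <- dplyr::bind_rows(rows)
  seg$length <- seg$end - seg$start + 1
  seg
}

# draw children prevalences under the sum rule, top-down over a parent vector
draw_phis_topdown <- function(parent, root_phi) {
  K <- length(parent)
  phi <- numeric(K)
  root <- which(parent == 0L)
  phi[root] <- root_phi
  # process nodes in an order where parents come first
  depth_order <- order(vapply(seq_len(K), function(v) {
    d <- 0L
    while (parent[v] != 0L) { v <- parent[v]; d <- d + 1L }
    d
  }, integer(1)))
  for (v in depth_order) {
    ch <- which(parent == v)
    if (length(ch) == 0) next
    budget <- phi[v] * runif(1, 0.55, 0.9)
    w <- runif(length(ch), 0.4, 1)
    phi[ch] <- budget * w / sum(w)
  }
  phi
}

# random clone-tree design for one patient under a scenario
sim_design <- function(config, scenario) {
  K <- config$k_clusters
  parent <- integer(K)
  for (k in seq(2, K)) parent[k] <- sample.int(k - 1, 1)
  phi_pre <- draw_phis_topdown(parent, runif(1, 0.85, 0.98))
  n_new <- sample(1:2, 1)
  if (scenario == "homogeneous") {
    phi_post <- draw_phis_topdown(parent, runif(1, 0.8, 0.95))
    new_parent <- 1L
    budget <- max(phi_post[new_parent] - sum(phi_post[parent == new_parent]), 0.15)
  } else {
    phi_post <- numeric(K)
    expanded <- sample(seq(2, K), 1)
    phi_post[expanded] <- runif(1, 0.6, 0.9)
    # nested prevalences for the expanded lineage's descendants
    desc <- function(v) {
      ch <- which(parent == v)
      for (w in ch) {
        phi_post[w] <<- phi_post[v] * runif(1, 0.2, 0.5)
        desc(w)
      }
    }
    desc(expanded)
    new_parent <- expanded
    budget <- 0.45 * phi_post[expanded]
  }
  new_phi <- sort(runif(n_new, 0.12, max(0.13, budget)), decreasing = TRUE)
  clusters <- tibble(
    cluster = seq_len(K + n_new),
    parent = c(parent, rep(new_parent, n_new)),
    phi_pre = c(phi_pre, rep(0, n_new)),
    phi_post = c(phi_post, new_phi),
    n_mutations = pmax(2L, stats::rpois(K + n_new, config$mutations_per_cluster)),
    is_new = c(rep(FALSE, K), rep(TRUE, n_new))
  )
  clusters
}

# core generator: turns an explicit cluster design into MAF/SEG tables plus
# ground truth. gene_inject maps cluster id -> character vector of symbols
# forced into that cluster.
sim_patient_core <- function(patient_id, clusters, config, scenario,
                             purity_pre, purity_post, gene_inject = list(),
                             min_retained_size = NULL) {
  seg_pre <- sim_segments(config$cn_deviated_fraction, paste0(patient_id, "_pre"))
  seg_post <- sim_segments(config$cn_deviated_fraction, paste0(patient_id, "_post"))

  pool <- sample(symbol_pool())
  pool <- setdiff(pool, c(unlist(gene_inject), "MUC7", "MUC5B", "ZNF91"))
  pool <- paste0(pool, "_", patient_id)  # patient-private symbols
  gene_cursor <- 0L

  rows <- list()
  truth_assign <- list()
  for (ci in seq_len(nrow(clusters))) {
    cl <- clusters[ci, ]
    inj <- gene_inject[[as.character(cl$cluster)]] %||% character(0)
    n_mut <- max(cl$n_mutations, length(inj))
    genes <- c(inj, pool[gene_cursor + seq_len(n_mut - length(inj))])
    gene_cursor <- gene_cursor + n_mut - length(inj)
    for (k in seq_len(n_mut)) {
      chrom <- as.character(sample(1:22, 1))
      pos <- sample.int(119e6, 1)
      alleles <- sample(c("A", "C", "G", "T"), 2)
      cn_pre <- locate_cn(seg_pre, chrom, pos)
      cn_post <- locate_cn(seg_post, chrom, pos)
      d_pre <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
      d_post <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
      d_n <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
      b_pre <- rbinom(1, d_pre, expected_vaf(cl$phi_pre, purity_pre, cn_pre))
      b_post <- rbinom(1, d_post, expected_vaf(cl$phi_post, purity_post, cn_post))
      id <- sprintf("%s:%d:%s:%s", chrom, pos, alleles[1], alleles[2])
      rows[[length(rows) + 1L]] <- tibble(
        id = id, chrom = chrom, pos = pos, ref = alleles[1], alt = alleles[2],
        gene = genes[k],
        consequence = if (runif(1) < 0.75) "nonsynonymous" else "other",
        t_ref_pre = d_pre - b_pre, t_alt_pre = b_pre,
        t_ref_post = d_post - b_post, t_alt_post = b_post,
        n_ref = d_n, n_alt = 0, pop_freq = NA_real_,
        cluster = cl$cluster, kind = "somatic")
      truth_assign[[length(truth_assign) + 1L]] <- tibble(
        id = id, gene = genes[k], cluster = cl$cluster)
    }
  }

  inject_contaminant <- function(kind) {
    chrom <- as.character(sample(1:22, 1))
    pos <- sample.int(119e6, 1)
    alleles <- sample(c("A", "C", "G", "T"), 2)
    d_pre <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
    d_post <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
    d_n <- max(1, rnbinom(1, mu = config$mean_depth, size = config$depth_dispersion))
    if (kind == "germline") {
      # heterozygous germline leakage: ~50% VAF in normal and both tumors
      b_pre <- rbinom(1, d_pre, 0.5)
      b_post <- rbinom(1, d_post, 0.5)
      n_alt <- max(rbinom(1, d_n, 0.5), 6)  # guaranteed above the <=5 cutoff
      pf <- NA_real_
    } else {
      # common polymorphism: somatic-looking counts, high population frequency
      b_pre <- rbinom(1, d_pre, 0.3)
      b_post <- rbinom(1, d_post, 0.3)
      n_alt <- sample(0:2, 1)
      pf <- runif(1, 0.011, 0.4)
    }
    tibble(
      id = sprintf("%s:%d:%s:%s", chrom, pos, alleles[1], alleles[2]),
      chrom = chrom, pos = pos, ref = alleles[1], alt = alleles[2],
      gene = paste0("CONTAM", sample.int(9999, 1), "_", patient_id),
      consequence = "other",
      t_ref_pre = d_pre - b_pre, t_alt_pre = b_pre,
      t_ref_post = d_post - b_post, t_alt_post = b_post,
      n_ref = d_n - n_alt, n_alt = n_alt, pop_freq = pf,
      cluster = NA_integer_, kind = kind)
  }
  for (i in seq_len(config$n_germline_contaminants)) {
    rows[[length(rows) + 1L]] <- inject_contaminant("germline")
  }
  for (i in seq_len(config$n_polymorphisms)) {
    rows[[length(rows) + 1L]] <- inject_contaminant("polymorphism")
  }
  all_rows <- dplyr::bind_rows(rows)

  make_variants <- function(tp) {
    tibble(
      chrom = all_rows$chrom, pos = all_rows$pos,
      ref = all_rows$ref, alt = all_rows$alt, gene = all_rows$gene,
      consequence = all_rows$consequence,
      t_ref = all_rows[[paste0("t_ref_", tp)]],
      t_alt = all_rows[[paste0("t_alt_", tp)]],
      n_ref = all_rows$n_ref, n_alt = all_rows$n_alt,
      pop_freq = all_rows$pop_freq)
  }
  variants_pre <- make_variants("pre")
  variants_post <- make_variants("post")

  # independent bookkeeping of which rows survive the four filter criteria
  passes <- function(v) {
    (v$t_ref + v$t_alt) >= 20 & (v$n_ref + v$n_alt) >= 20 &
      v$n_alt <= 5 & v$t_alt >= 5 & dplyr::coalesce(v$pop_freq, 0) < 0.01
  }
  thr <- config$presence_threshold
  retained <- clusters$n_mutations >= 2  # subclone counts use retained clusters
  truth <- list(
    patient = patient_id, scenario = scenario,
    clusters = clusters,
    assignment = dplyr::bind_rows(truth_assign),
    filter_fail = tibble(id = all_rows$id[all_rows$kind != "somatic"],
                         kind = all_rows$kind[all_rows$kind != "somatic"]),
    n_kept_pre = sum(passes(variants_pre)),
    n_kept_post = sum(passes(variants_post)),
    ith_pre = sum(clusters$phi_pre >= thr & retained),
    ith_post = sum(clusters$phi_post >= thr & retained),
    purity = c(pre = purity_pre, post = purity_post)
  )
  list(variants_pre = variants_pre, variants_post = variants_post,
       segments_pre = seg_pre, segments_post = seg_post, truth = truth)
}

#' Simulate one paired pre/post patient
#'
#' @param config A [simulation_config()].
#' @param scenario `"homogeneous"` (main clone persists after treatment) or
#'   `"heterogeneous"` (main clone eradicated, a non-main lineage expands).
#' @param seed Integer RNG seed; required.
#' @param patient_id Identifier used in file names and gene symbols.
#' @param out_dir If non-`NULL`, MAF and SEG files for both timepoints are
#'   written there.
#' @return A list with `variants_pre`, `variants_post` (MAF-layout tibbles;
#'   each contains the union of the patient's variants with per-timepoint
#'   allelic counts), `segments_pre`, `segments_post`, `truth` (scenario,
#'   cluster design, mutation assignment, injected filter-failing variants,
#'   per-sample kept counts and purities) and, when written, `files`.
#' @export
simulate_patient <- function(config, scenario = c("homogeneous", "heterogeneous"),
                             seed, patient_id = "P1", out_dir = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) abort("simulate_patient: seed is required")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  purity_pre <- min(1, max(0.3, config$purity + runif(1, -0.03, 0.03)))
  purity_post <- min(1, max(0.3, config$purity + runif(1, -0.03, 0.03)))
  clusters <- sim_design(config, scenario)
  res <- sim_patient_core(patient_id, clusters, config, scenario,
                          purity_pre, purity_post)
  if (!is.null(out_dir)) {
    res$files <- write_patient_files(res, patient_id, out_dir)
  }
  res
}

write_patient_files <- function(res, patient_id, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    maf_pre = file.path(out_dir, paste0(patient_id, "_pre.maf")),
    maf_post = file.path(out_dir, paste0(patient_id, "_post.maf")),
    seg_pre = file.path(out_dir, paste0(patient_id, "_pre.seg")),
    seg_post = file.path(out_dir, paste0(patient_id, "_post.seg")))
  write_maf(res$variants_pre, files["maf_pre"])
  write_maf(res$variants_post, files["maf_post"])
  write_segments(res$segments_pre, files["seg_pre"])
  write_segments(res$segments_post, files["seg_post"])
  files
}

cohort_manifest_row <- function(patient_id, tp, purity, pfs, files) {
  tibble(patient = patient_id, sample = paste0(patient_id, "_", tp),
         timepoint = tp, purity = purity, pfs_months = pfs,
         maf = basename(files[[paste0("maf_", tp)]]),
         seg = basename(files[[paste0("seg_", tp)]]))
}

#' Simulate a full paired cohort
#'
#' Generates `n_patients` independent patients (scenario labels split by
#' `prop_homogeneous`, homogeneous patients first), writes their MAF/SEG
#' files and a cohort manifest to `out_dir`, and returns the ground truth.
#' Per-patient seeds are derived deterministically from `seed`, so the same
#' seed reproduces the directory byte for byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (error if it exists non-empty, unless
#'   `force`).
#' @param seed Master integer seed; required.
#' @param force Overwrite a non-empty `out_dir`; default `FALSE`.
#' @return List with `manifest_path`, `manifest` (tibble) and `truth`
#'   (per-patient ground-truth list plus a `labels` tibble).
#' @export
simulate_cohort <- function(config, out_dir, seed, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) abort("simulate_cohort: seed is required")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s exists and is not empty", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_patients
  n_hom <- round(n * config$prop_homogeneous)
  scenarios <- c(rep("homogeneous", n_hom), rep("heterogeneous", n - n_hom))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pfs <- ifelse(scenarios == "homogeneous", runif(n, 2, 6), runif(n, 6, 24))
  manifest <- list()
  truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%02d", i)
    pseed <- (as.integer(seed) + 104729L * i) %% 2147483647L
    res <- simulate_patient(config, scenarios[i], seed = pseed,
                            patient_id = pid, out_dir = out_dir)
    truth[[pid]] <- res$truth
    manifest[[length(manifest) + 1L]] <-
      cohort_manifest_row(pid, "pre", res$truth$purity[["pre"]], pfs[i], res$files)
    manifest[[length(manifest) + 1L]] <-
      cohort_manifest_row(pid, "post", res$truth$purity[["post"]], pfs[i], res$files)
  }
  manifest <- if (n == 0) {
    tibble(patient = character(), sample = character(), timepoint = character(),
           purity = numeric(), pfs_months = numeric(), maf = character(),
           seg = character())
  } else {
    dplyr::bind_rows(manifest)
  }
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  labels <- tibble(patient = sprintf("P%02d", seq_len(n)), scenario = scenarios)
  list(manifest_path = manifest_path, manifest = manifest,
       truth = c(truth, list(labels = labels)))
}

# fixed cluster designs for the five-patient worked example: prevalence
# patterns chosen so per-sample subclone counts are pre 4,1,2,6,2 and post
# 4,4,7,6,2, with the main clone persisting for patients 4 and 5 only
worked_example_designs <- function() {
  tb <- function(...) tibble::tribble(...)
  list(
    P1 = list(scenario = "heterogeneous", pfs = 23, inject = list(`1` = c("MUC7", "MUC5B")),
      clusters = tb(
        ~cluster, ~parent, ~phi_pre, ~phi_post, ~n_mutations, ~is_new,
        1L, 0L, 0.95, 0.00, 8L, FALSE,
        2L, 1L, 0.45, 0.85, 8L, FALSE,
        3L, 1L, 0.30, 0.00, 7L, FALSE,
        4L, 1L, 0.20, 0.00, 6L, FALSE,
        5L, 2L, 0.00, 0.40, 7L, TRUE,
        6L, 2L, 0.00, 0.25, 6L, TRUE,
        7L, 2L, 0.00, 0.15, 5L, TRUE)),
    P2 = list(scenario = "heterogeneous", pfs = 11.6, inject = list(`1` = c("MUC7", "MUC5B")),
      clusters = tb(
        ~cluster, ~parent, ~phi_pre, ~phi_post, ~n_mutations, ~is_new,
        1L, 0L, 0.90, 0.00, 10L, FALSE,
        2L, 1L, 0.00, 0.60, 8L, TRUE,
        3L, 1L, 0.00, 0.38, 7L, TRUE,
        4L, 1L, 0.00, 0.22, 6L, TRUE,
        5L, 1L, 0.00, 0.12, 6L, TRUE)),
    P3 = list(scenario = "heterogeneous", pfs = 7.3, inject = list(`1` = c("MUC7", "MUC5B")),
      clusters = tb(
        ~cluster, ~parent, ~phi_pre, ~phi_post, ~n_mutations, ~is_new,
        1L, 0L, 0.92, 0.00, 9L, FALSE,
        2L, 1L, 0.35, 0.80, 8L, FALSE,
        3L, 2L, 0.00, 0.55, 7L, TRUE,
        4L, 2L, 0.00, 0.45, 7L, TRUE,
        5L, 2L, 0.00, 0.34, 6L, TRUE,
        6L, 2L, 0.00, 0.25, 6L, TRUE,
        7L, 2L, 0.00, 0.17, 5L, TRUE,
        8L, 2L, 0.00, 0.11, 5L, TRUE)),
    P4 = list(scenario = "homogeneous", pfs = 2.4, inject = list(`7` = "ZNF91"),
      clusters = tb(
        ~cluster, ~parent, ~phi_pre, ~phi_post, ~n_mutations, ~is_new,
        1L, 0L, 0.95, 0.88, 9L, FALSE,
        2L, 1L, 0.45, 0.40, 8L, FALSE,
        3L, 1L, 0.30, 0.28, 7L, FALSE,
        4L, 2L, 0.20, 0.18, 6L, FALSE,
        5L, 2L, 0.12, 0.00, 6L, FALSE,
        6L, 3L, 0.14, 0.13, 6L, FALSE,
        7L, 2L, 0.00, 0.18, 5L, TRUE)),
    P5 = list(scenario = "homogeneous", pfs = 2.9, inject = list(`3` = "ZNF91"),
      clusters = tb(
        ~cluster, ~parent, ~phi_pre, ~phi_post, ~n_mutations, ~is_new,
        1L, 0L, 0.90, 0.85, 12L, FALSE,
        2L, 1L, 0.35, 0.30, 10L, FALSE,
        3L, 2L, 0.00, 0.15, 1L, TRUE))
  )
}

#' Generate the fixed five-patient worked-example cohort
#'
#' A deterministic paired cohort mirroring a reported five-patient androgen-deprivation cohort: two
#' homogeneous-scenario patients (PFS 2.4 and 2.9 months) and three
#' heterogeneous-scenario patients (PFS 23, 11.6 and 7.3 months), with
#' per-sample subclone counts of 4, 1, 2, 6, 2 before and 4, 4, 7, 6, 2
#' after treatment. The three heterogeneous patients carry `MUC7` and
#' `MUC5B` mutations only before treatment (the "repaired" genes); the two
#' homogeneous patients gain a `ZNF91` mutation only after treatment. All
#' other gene symbols are patient-private.
#'
#' @param out_dir Directory to write MAF/SEG files and the manifest to.
#' @param seed Integer seed for read sampling; required.
#' @return As [simulate_cohort()].
#' @export
worked_example_cohort <- function(out_dir, seed) {
  if (missing(seed) || is.null(seed)) abort("worked_example_cohort: seed is required")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0) {
    abort(sprintf("output directory %s exists and is not empty", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # deep coverage so the configured subclone structure is identifiable:
  # adjacent post-treatment clusters in this design sit ~0.03 apart in VAF
  config <- simulation_config(mean_depth = 2000)
  designs <- worked_example_designs()
  manifest <- list()
  truth <- list()
  for (i in seq_along(designs)) {
    pid <- names(designs)[i]
    des <- designs[[i]]
    set.seed((as.integer(seed) + 104729L * i) %% 2147483647L)
    res <- sim_patient_core(pid, des$clusters, config, des$scenario,
                            purity_pre = 0.80, purity_post = 0.85,
                            gene_inject = des$inject)
    res$files <- write_patient_files(res, pid, out_dir)
    truth[[pid]] <- res$truth
    manifest[[length(manifest) + 1L]] <-
      cohort_manifest_row(pid, "pre", 0.80, des$pfs, res$files)
    manifest[[length(manifest) + 1L]] <-
      cohort_manifest_row(pid, "post", 0.85, des$pfs, res$files)
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  labels <- tibble(
    patient = names(designs),
    scenario = vapply(designs, function(d) d$scenario, character(1)))
  list(manifest_path = manifest_path, manifest = manifest,
       truth = c(truth, list(labels = labels)))
}
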