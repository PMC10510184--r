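# End-to-end orchestration: manifest -> filter -> metrics -> subclonal
# clustering -> clone tree -> evolution-model classification -> cohort
# statistics -> report files. Every number in the emitted reports is
# reproducible by calling the underlying module functions directly; the
# pipeline only sequences them. A single seed drives the sampler (one
# derived seed per patient); all other stages are deterministic.

variant_key <- function(v) sprintf("%s:%d:%s:%s", v$chrom, v$pos, v$ref, v$alt)

# joint pre/post observations for one patient: union of the per-sample kept
# variants, with allelic counts looked up in both samples' full variant
# tables (zero depth where a variant was not reported) and locus copy number
# from the per-sample segments
build_observations <- function(kept_pre, kept_post, all_pre, all_post,
                               seg_pre, seg_post) {
  keys <- union(variant_key(kept_pre), variant_key(kept_post))
  lookup <- function(all_v, keys) {
    idx <- match(keys, variant_key(all_v))
    tibble(
      alt = ifelse(is.na(idx), 0, all_v$t_alt[idx]),
      depth = ifelse(is.na(idx), 0, all_v$t_alt[idx] + all_v$t_ref[idx]))
  }
  parts <- strsplit(keys, ":")
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.numeric(vapply(parts, `[`, "", 2))
  cn_for <- function(seg) {
    vapply(seq_along(keys), function(i) locate_cn(seg, chrom[i], pos[i]),
           numeric(1))
  }
  pre <- lookup(all_pre, keys)
  post <- lookup(all_post, keys)
  dplyr::bind_rows(
    tibble(id = keys, sample = "pre", alt = pre$alt, depth = pre$depth,
           tumor_cn = cn_for(seg_pre), multiplicity = 1),
    tibble(id = keys, sample = "post", alt = post$alt, depth = post$depth,
           tumor_cn = cn_for(seg_post), multiplicity = 1))
}

analyze_patient <- function(pid, rows, filter_cfg, cluster_cfg, seed_patient,
                            capture_size_mb, ploidy, neutral_cn,
                            log2_threshold, presence_threshold, seg_dialect) {
  pre_row <- rows[rows$timepoint == "pre", ]
  post_row <- rows[rows$timepoint == "post", ]
  all_pre <- read_maf(pre_row$maf)
  all_post <- read_maf(post_row$maf)
  seg_pre <- read_segments(pre_row$seg, dialect = seg_dialect)
  seg_post <- read_segments(post_row$seg, dialect = seg_dialect)

  filt_pre <- apply_filters(all_pre, filter_cfg)
  filt_post <- apply_filters(all_post, filter_cfg)

  obs <- build_observations(filt_pre$kept, filt_post$kept, all_pre, all_post,
                            seg_pre, seg_post)
  purity <- c(pre = pre_row$purity, post = post_row$purity)
  clusters <- cluster_mutations(obs, purity, cluster_cfg, seed = seed_patient)
  retained <- filter_clusters(clusters, min_mutations = 2)

  tree <- tryCatch(infer_best_tree(retained), error = function(e) {
    inform(sprintf("patient %s: clone tree skipped (%s)", pid, conditionMessage(e)))
    NULL
  })
  call <- classify_evolution_model(retained, presence_threshold,
                                   patient = pid,
                                   pfs_months = pre_row$pfs_months)
  profiles <- dplyr::bind_rows(
    heterogeneity_profile(pid, "pre", filt_pre$kept, seg_pre, retained,
                          sample_name = "pre",
                          capture_size_mb = capture_size_mb, ploidy = ploidy,
                          neutral_cn = neutral_cn,
                          log2_threshold = log2_threshold,
                          presence_threshold = presence_threshold),
    heterogeneity_profile(pid, "post", filt_post$kept, seg_post, retained,
                          sample_name = "post",
                          capture_size_mb = capture_size_mb, ploidy = ploidy,
                          neutral_cn = neutral_cn,
                          log2_threshold = log2_threshold,
                          presence_threshold = presence_threshold))
  partition <- partition_genes(filt_pre$kept, filt_post$kept)
  list(patient = pid, profiles = profiles, clusters = retained, tree = tree,
       call = call, partition = partition,
       filter_reports = list(pre = filt_pre$report, post = filt_post$report))
}

#' Run the full paired-cohort analysis pipeline
#'
#' Reads the cohort manifest, then per patient: applies the four variant
#' filters to each timepoint, builds joint pre/post observations from the
#' union of kept variants (with copy number from the per-sample segments),
#' clusters them into subclones, retains clusters of two or more mutations,
#' infers the clone tree (skipped with a message when more than 7 clusters
#' remain), classifies the evolution model, computes the six heterogeneity
#' indices per sample and the repaired/shared/new gene partition. Cohort
#' level, it compares the metrics pre versus post and groups PFS by
#' evolution model, then writes all report files to `out_dir`.
#'
#' @param manifest_path Cohort manifest TSV (see [read_manifest()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer master seed (per-patient sampler seeds are derived
#'   from it); required.
#' @param filter_cfg A [filter_config()].
#' @param cluster_cfg A [cluster_config()].
#' @param capture_size_mb,ploidy,neutral_cn,log2_threshold,presence_threshold
#'   Metric parameters (see the het-metric functions).
#' @param seg_dialect Segment file dialect, `"integer"` or `"log2"`.
#' @param driver_list Optional driver-gene list (path or character vector);
#'   when given, per-sample driver counts are written.
#' @return Invisibly, a list with `profiles`, `calls`, `comparison`,
#'   `pfs_by_model`, `partitions`, `patients` (per-patient detail) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(manifest_path, out_dir, seed,
                         filter_cfg = filter_config(),
                         cluster_cfg = cluster_config(),
                         capture_size_mb = 38, ploidy = 2, neutral_cn = 2,
                         log2_threshold = 0.25, presence_threshold = 0.10,
                         seg_dialect = "integer", driver_list = NULL) {
  if (missing(seed) || is.null(seed)) abort("run_pipeline: seed is required")
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  patients <- unique(manifest$patient[manifest$timepoint %in% c("pre", "post")])
  results <- list()
  for (i in seq_along(patients)) {
    pid <- patients[i]
    rows <- manifest[manifest$patient == pid, ]
    pseed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    results[[pid]] <- analyze_patient(
      pid, rows, filter_cfg, cluster_cfg, pseed, capture_size_mb, ploidy,
      neutral_cn, log2_threshold, presence_threshold, seg_dialect)
  }
  profiles <- dplyr::bind_rows(lapply(results, `[[`, "profiles"))
  calls <- dplyr::bind_rows(lapply(results, `[[`, "call"))
  comparison <- compare_pre_post(profiles)
  pfs_by_model <- group_pfs_by_model(calls)
  partitions <- lapply(results, `[[`, "partition")

  files <- write_pipeline_outputs(out_dir, seed, results, profiles, calls,
                                  comparison, pfs_by_model, partitions,
                                  driver_list)
  invisible(list(profiles = profiles, calls = calls, comparison = comparison,
                 pfs_by_model = pfs_by_model, partitions = partitions,
                 patients = results, files = files))
}

write_pipeline_outputs <- function(out_dir, seed, results, profiles, calls,
                                   comparison, pfs_by_model, partitions,
                                   driver_list) {
  files <- c(
    heterogeneity = file.path(out_dir, "heterogeneity.tsv"),
    comparison = file.path(out_dir, "comparison.tsv"),
    calls = file.path(out_dir, "evolution_calls.json"),
    trees = file.path(out_dir, "clone_trees.json"),
    partitions = file.path(out_dir, "gene_partitions.json"),
    log = file.path(out_dir, "run_log.json"))
  write_heterogeneity_report(profiles, files["heterogeneity"])
  con <- file(files["comparison"], "w", encoding = "UTF-8")
  writeLines("# clonevo pre/post comparison v1", con)
  close(con)
  readr::write_tsv(comparison, files["comparison"], append = TRUE,
                   col_names = TRUE, progress = FALSE)

  calls_json <- lapply(seq_len(nrow(calls)), function(i) {
    list(patient = calls$patient[i], label = calls$label[i],
         main_clone = calls$main_clone[i],
         main_phi_pre = calls$main_phi_pre[i],
         main_phi_post = calls$main_phi_post[i],
         resistant = calls$resistant[[i]],
         pfs_months = calls$pfs_months[i])
  })
  jsonlite::write_json(calls_json, files["calls"], auto_unbox = TRUE,
                       digits = NA)

  trees_json <- lapply(results, function(r) {
    if (is.null(r$tree)) return(list(skipped = TRUE))
    list(nodes = r$tree$nodes, root = r$tree$root,
         parent = as.list(setNames(
           ifelse(is.na(r$tree$parent), "root", as.character(r$tree$parent)),
           names(r$tree$parent))),
         phi = apply(r$tree$phi, 2, identity, simplify = FALSE),
         violation_score = r$tree$score)
  })
  jsonlite::write_json(trees_json, files["trees"], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(lapply(partitions, unclass), files["partitions"],
                       auto_unbox = FALSE, digits = NA)

  per_patient_clusters <- lapply(names(results), function(pid) {
    f <- file.path(out_dir, paste0("clusters_", pid, ".tsv"))
    con <- file(f, "w", encoding = "UTF-8")
    writeLines("# clonevo cluster assignments v1", con)
    close(con)
    readr::write_tsv(tidy(results[[pid]]$clusters), f, append = TRUE,
                     col_names = TRUE, progress = FALSE)
    f
  })
  files <- c(files, setNames(unlist(per_patient_clusters),
                             paste0("clusters_", names(results))))

  if (!is.null(driver_list)) {
    drv <- dplyr::bind_rows(lapply(names(results), function(pid) {
      p <- partitions[[pid]]
      genes <- unique(c(p$pre_only, p$shared, p$post_only))
      ann <- annotate_drivers(genes, driver_list)
      tibble(patient = pid,
             n_drivers_pre = sum(ann$is_driver &
                                   ann$gene %in% c(p$pre_only, p$shared)),
             n_drivers_post = sum(ann$is_driver &
                                    ann$gene %in% c(p$post_only, p$shared)))
    }))
    f <- file.path(out_dir, "driver_counts.tsv")
    readr::write_tsv(drv, f, progress = FALSE)
    files <- c(files, drivers = f)
  }

  log <- list(
    package = "clonevo",
    version = as.character(utils::packageVersion("clonevo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    n_patients = length(results),
    filter_reports = lapply(results, function(r) {
      lapply(r$filter_reports, as.list)
    }))
  jsonlite::write_json(log, files["log"], auto_unbox = TRUE, digits = NA)
  files
}
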