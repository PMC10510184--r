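# Somatic-variant filtering: four criteria applied as a conjunction, with a
# per-criterion attrition report. Attribution is sequential in the fixed
# order depth -> germline support -> tumor support -> population frequency
# (each removed variant is charged to the first criterion it fails), so the
# report is deterministic; the kept set itself is order-free.

#' Filter thresholds for somatic variant calls
#'
#' Defaults follow the standard paired tumor/normal post-calling filter:
#' sequencing depth of at least 20 in both tumor and normal, at most 5
#' alternate reads in the germline sample, at least 5 alternate reads in the
#' tumor sample, and a population allele frequency strictly below 1%.
#' "Depth" is the sum of reference and alternate allelic counts.
#'
#' @param min_depth_both Minimum depth required in both tumor and normal
#'   (inclusive). Default 20.
#' @param max_germline_alt Maximum alternate reads allowed in the normal
#'   (inclusive). Default 5.
#' @param min_tumor_alt Minimum alternate reads required in the tumor
#'   (inclusive). Default 5.
#' @param max_pop_freq Population-frequency cutoff (strict `<`). Default 0.01.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth_both = 20, max_germline_alt = 5,
                          min_tumor_alt = 5, max_pop_freq = 0.01) {
  stopifnot(min_depth_both >= 0, max_germline_alt >= 0, min_tumor_alt >= 0,
            max_pop_freq >= 0, max_pop_freq <= 1)
  structure(
    list(min_depth_both = min_depth_both, max_germline_alt = max_germline_alt,
         min_tumor_alt = min_tumor_alt, max_pop_freq = max_pop_freq),
    class = "filter_config")
}

#' Apply the four somatic-variant filter criteria
#'
#' Keeps variants with tumor and normal depth at or above
#' `min_depth_both`, at most `max_germline_alt` alternate reads in the
#' normal, at least `min_tumor_alt` alternate reads in the tumor, and a
#' population frequency strictly below `max_pop_freq`. Variants without a
#' population-frequency annotation are treated as frequency 0 (an
#' un-annotated variant cannot exceed the cutoff). Input order is preserved.
#'
#' @param variants Variant tibble (see [read_maf()]).
#' @param config A [filter_config()].
#' @return A list of class `filter_result` with elements `kept` (tibble, the
#'   surviving variants in input order) and `report` (one-row tibble:
#'   `input_count`, `removed_by_depth`, `removed_by_germline_support`,
#'   `removed_by_tumor_support`, `removed_by_pop_freq`, `kept_count`).
#' @export
apply_filters <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(variants)
  if (n == 0) {
    report <- tibble(input_count = 0L, removed_by_depth = 0L,
                     removed_by_germline_support = 0L,
                     removed_by_tumor_support = 0L,
                     removed_by_pop_freq = 0L, kept_count = 0L)
    return(structure(list(kept = variants, report = report),
                     class = "filter_result"))
  }
  fail_depth <- (variants$t_ref + variants$t_alt) < config$min_depth_both |
    (variants$n_ref + variants$n_alt) < config$min_depth_both
  fail_germ <- variants$n_alt > config$max_germline_alt
  fail_tum <- variants$t_alt < config$min_tumor_alt
  pf <- dplyr::coalesce(variants$pop_freq, 0)
  fail_pf <- pf >= config$max_pop_freq
  first_fail <- dplyr::case_when(
    fail_depth ~ "depth",
    fail_germ ~ "germline",
    fail_tum ~ "tumor",
    fail_pf ~ "pop_freq",
    TRUE ~ "kept"
  )
  report <- tibble(
    input_count = n,
    removed_by_depth = sum(first_fail == "depth"),
    removed_by_germline_support = sum(first_fail == "germline"),
    removed_by_tumor_support = sum(first_fail == "tumor"),
    removed_by_pop_freq = sum(first_fail == "pop_freq"),
    kept_count = sum(first_fail == "kept")
  )
  structure(list(kept = variants[first_fail == "kept", , drop = FALSE],
                 report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<filter_result> %d in, %d kept (removed: depth %d, germline %d, tumor %d, pop_freq %d)\n",
    r$input_count, r$kept_count, r$removed_by_depth,
    r$removed_by_germline_support, r$removed_by_tumor_support,
    r$removed_by_pop_freq))
  invisible(x)
}

#' @export
tidy.filter_result <- function(x, ...) {
  tidyr::pivot_longer(x$report, dplyr::everything(),
                      names_to = "quantity", values_to = "count")
}

#' @export
glance.filter_result <- function(x, ...) x$report
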