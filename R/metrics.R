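# The six per-sample heterogeneity indices: TMB, CNA burden, wGII, MATH,
# Shannon diversity of subclone sizes (SDI), and the subclone count (ITH).

#' Tumor mutational burden
#'
#' Nonsynonymous somatic mutations per megabase of captured coding sequence:
#' `n_nonsynonymous / capture_size_mb`. Counting only nonsynonymous-coding
#' variants is the caller's responsibility (see [read_maf()]'s `consequence`
#' column).
#'
#' @param n_nonsynonymous Count of nonsynonymous coding mutations.
#' @param capture_size_mb Capture footprint in megabases; default 38 (a
#'   typical whole-exome capture).
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(n_nonsynonymous, capture_size_mb = 38) {
  if (!is.numeric(capture_size_mb) || capture_size_mb <= 0) {
    abort("capture_size_mb must be > 0")
  }
  stopifnot(n_nonsynonymous >= 0)
  n_nonsynonymous / capture_size_mb
}

segment_dialect <- function(segments) {
  if ("total_cn" %in% names(segments)) "integer"
  else if ("log2_ratio" %in% names(segments)) "log2"
  else abort("segments carry neither 'total_cn' nor 'log2_ratio'")
}

segment_deviated <- function(segments, neutral_cn = 2, log2_threshold = 0.25) {
  switch(segment_dialect(segments),
         integer = segments$total_cn != neutral_cn,
         log2 = abs(segments$log2_ratio) > log2_threshold)
}

#' Copy-number alteration burden
#'
#' Percentage of copy-number segments deviating from neutral among all
#' detected segments. A segment is deviated when `total_cn != neutral_cn`
#' (integer dialect) or `|log2_ratio| > log2_threshold` (log2 dialect).
#'
#' @param segments Segment tibble (see [read_segments()]).
#' @param neutral_cn Neutral integer copy number; default 2.
#' @param log2_threshold Deviation cutoff for the log2 dialect; default 0.25.
#' @return Percent in \[0, 100\].
#' @export
compute_cna_burden <- function(segments, neutral_cn = 2, log2_threshold = 0.25) {
  if (nrow(segments) == 0) abort("CNA burden is undefined for an empty segment list")
  dev <- segment_deviated(segments, neutral_cn, log2_threshold)
  100 * sum(dev) / nrow(segments)
}

AUTOSOMES <- as.character(1:22)

#' Weighted genome instability index
#'
#' For each autosome with segment coverage, the fraction of covered length
#' lying in segments whose integer copy number differs from `round(ploidy)`;
#' wGII is the unweighted mean of these per-chromosome fractions (length-
#' weighted within a chromosome, equally weighted across chromosomes; sex
#' chromosomes are excluded).
#'
#' @param segments Segment tibble with integer copy numbers (`total_cn`).
#' @param ploidy Average sample ploidy; default 2.
#' @return Fraction in \[0, 1\].
#' @export
compute_wgii <- function(segments, ploidy = 2) {
  stopifnot(ploidy > 0)
  if (segment_dialect(segments) != "integer") {
    abort("wGII requires integer copy numbers (total_cn)")
  }
  seg <- segments[normalize_chrom(segments$chrom) %in% AUTOSOMES, , drop = FALSE]
  if (nrow(seg) == 0) abort("wGII is undefined without autosomal segments")
  seg$length <- seg$end - seg$start + 1
  seg$dev <- seg$total_cn != round(ploidy)
  frac <- seg |>
    dplyr::group_by(chrom = normalize_chrom(.data$chrom)) |>
    dplyr::summarise(
      frac = sum(.data$length[.data$dev]) / sum(.data$length),
      .groups = "drop")
  mean(frac$frac)
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' `100 * 1.4826 * median(|vaf - median(vaf)|) / median(vaf)`: the median
#' absolute deviation of the variant allele fractions, scaled by the usual
#' 1.4826 normal-consistency constant, as a percentage of the median VAF.
#'
#' @param vafs Numeric vector of variant allele fractions in (0, 1], length
#'   at least 2.
#' @return Dimensionless score, 0 when all VAFs are equal.
#' @export
compute_math <- function(vafs) {
  if (length(vafs) < 2) abort("MATH requires at least 2 VAFs")
  if (any(is.na(vafs)) || any(vafs <= 0) || any(vafs > 1)) {
    abort("VAFs must lie in (0, 1]")
  }
  med <- median(vafs)
  if (med <= 0) abort("MATH is undefined when the median VAF is 0")
  100 * 1.4826 * median(abs(vafs - med)) / med
}

#' Shannon diversity index of subclone sizes
#'
#' Entropy (natural log) of the cluster-size distribution: with
#' `p_k = size_k / sum(sizes)`, returns `-sum(p_k * log(p_k))`. Zero for a
#' single cluster.
#'
#' @param cluster_sizes Positive integer vector of mutations per cluster.
#' @return Entropy in nats.
#' @export
compute_sdi <- function(cluster_sizes) {
  if (length(cluster_sizes) == 0) abort("SDI requires at least one cluster")
  if (any(cluster_sizes < 1)) abort("cluster sizes must be >= 1")
  p <- cluster_sizes / sum(cluster_sizes)
  s <- -sum(p * log(p))
  if (s == 0) s <- 0  # avoid IEEE negative zero for a single cluster
  s
}

#' Intratumor heterogeneity as the subclone count
#'
#' Number of retained clusters present in a sample, where presence means a
#' cellular prevalence at or above `presence_threshold`.
#'
#' @param phis Numeric vector of per-cluster cellular prevalences in one
#'   sample (or a [cluster_mutations()] result together with `sample`).
#' @param sample When `phis` is a `clone_clusters` object, the sample whose
#'   prevalences to use.
#' @param presence_threshold Minimum prevalence to count a cluster as present;
#'   default 0.10.
#' @return Integer subclone count (0 when no cluster is present).
#' @export
compute_ith <- function(phis, sample = NULL, presence_threshold = 0.10) {
  if (inherits(phis, "clone_clusters")) {
    stopifnot(!is.null(sample))
    phis <- cluster_phis(phis, sample)
  }
  sum(phis >= presence_threshold)
}

#' Assemble one heterogeneity-report row for a tumor sample
#'
#' Convenience constructor combining the six indices into the report layout
#' used by [write_heterogeneity_report()].
#'
#' @param patient,timepoint Identifiers for the row.
#' @param kept_variants Filtered variant tibble for the sample.
#' @param segments Segment tibble for the sample.
#' @param clusters A retained [cluster_mutations()] result for the patient,
#'   or `NULL` (ITH/SDI become 0).
#' @param sample_name Sample column in `clusters` for this timepoint.
#' @param capture_size_mb,ploidy,neutral_cn,log2_threshold,presence_threshold
#'   Metric parameters (see the individual metric functions).
#' @return One-row tibble: patient, timepoint, cna_burden, tmb, ith, sdi,
#'   wgii, math.
#' @export
heterogeneity_profile <- function(patient, timepoint, kept_variants, segments,
                                  clusters = NULL, sample_name = timepoint,
                                  capture_size_mb = 38, ploidy = 2,
                                  neutral_cn = 2, log2_threshold = 0.25,
                                  presence_threshold = 0.10) {
  n_nonsyn <- sum(kept_variants$consequence == "nonsynonymous")
  vafs <- with(kept_variants, t_alt / (t_alt + t_ref))
  vafs <- vafs[!is.na(vafs) & vafs > 0]
  math <- if (length(vafs) >= 2 && median(vafs) > 0) compute_math(vafs) else 0
  ith <- 0L
  sdi <- 0
  if (!is.null(clusters)) {
    phis <- cluster_phis(clusters, sample_name)
    present <- phis >= presence_threshold
    ith <- sum(present)
    sizes <- cluster_sizes(clusters)[names(phis)[present]]
    if (length(sizes) > 0) sdi <- compute_sdi(sizes)
  }
  tibble(
    patient = patient, timepoint = timepoint,
    cna_burden = compute_cna_burden(segments, neutral_cn, log2_threshold),
    tmb = compute_tmb(n_nonsyn, capture_size_mb),
    ith = as.integer(ith), sdi = sdi,
    wgii = compute_wgii(segments, ploidy),
    math = math
  )
}
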