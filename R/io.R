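# Readers and writers for every external representation the pipeline touches:
# MAF variant tables, paired VCF, SEG copy-number segments, cohort manifests
# and the heterogeneity report. All files are UTF-8, tab-delimited, with '#'
# comment lines ignored. Coordinates are 1-based inclusive throughout (MAF/SEG
# convention); chromosome names are normalized by stripping a "chr" prefix so
# variant and segment files join regardless of style.

MAF_REQUIRED <- c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
  "Tumor_Seq_Allele2", "Variant_Classification",
  "t_ref_count", "t_alt_count", "n_ref_count", "n_alt_count"
)

# population-frequency annotation columns; pop_freq = max over those present
MAF_POPFREQ <- c("ExAC_AF", "ESP6500_AF", "gnomAD_AF", "pop_freq")

# MAF nonsilent classes counted as nonsynonymous coding (TMB numerator)
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins",
  "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site"
)

normalize_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, col_types = readr::cols(.default = "c"), ...)
}

to_count <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric value '%s' in column '%s' of %s (data row %d)",
                  x[bad[1]], col, path, bad[1]))
  }
  out
}

#' Read somatic variants from a MAF file
#'
#' Reads the subset of MAF columns the pipeline needs and returns one row per
#' variant in file order. Variant classifications in the standard nonsilent
#' set (missense, nonsense, frameshift, splice-site, nonstop,
#' translation-start) are mapped to consequence `"nonsynonymous"`; everything
#' else is `"other"`. The population frequency is the maximum over the
#' annotation columns present (`ExAC_AF`, `ESP6500_AF`, `gnomAD_AF`,
#' `pop_freq`); `NA` when no annotation column exists.
#'
#' @param path Path to a tab-delimited MAF file (`#` lines are comments).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `t_ref`, `t_alt`, `n_ref`, `n_alt`, `pop_freq`.
#' @export
#' @examples
#' maf <- file.path(tempdir(), "tiny.maf")
#' writeLines(c(
#'   paste(c("Hugo_Symbol","Chromosome","Start_Position","Reference_Allele",
#'           "Tumor_Seq_Allele2","Variant_Classification","t_ref_count",
#'           "t_alt_count","n_ref_count","n_alt_count"), collapse = "\t"),
#'   "TP53\t17\t7578406\tC\tT\tMissense_Mutation\t40\t10\t50\t0"), maf)
#' read_maf(maf)
read_maf <- function(path) {
  if (!file.exists(path)) abort(sprintf("MAF file not found: %s", path))
  df <- read_tsv_quiet(path)
  missing <- setdiff(MAF_REQUIRED, names(df))
  if (length(missing) > 0) {
    abort(sprintf("MAF %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  counts <- lapply(c("Start_Position", "t_ref_count", "t_alt_count",
                     "n_ref_count", "n_alt_count"),
                   function(cn) to_count(df[[cn]], cn, path))
  names(counts) <- c("pos", "t_ref", "t_alt", "n_ref", "n_alt")
  pf_cols <- intersect(MAF_POPFREQ, names(df))
  pop_freq <- if (length(pf_cols) == 0) rep(NA_real_, nrow(df)) else {
    pf <- vapply(seq_len(nrow(df)), function(i) {
      v <- suppressWarnings(as.numeric(unlist(df[i, pf_cols])))
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
    pf
  }
  out <- tibble(
    chrom = normalize_chrom(df$Chromosome),
    pos = counts$pos,
    ref = df$Reference_Allele,
    alt = df$Tumor_Seq_Allele2,
    gene = dplyr::coalesce(df$Hugo_Symbol, ""),
    consequence = ifelse(df$Variant_Classification %in% NONSYNONYMOUS_CLASSES,
                         "nonsynonymous", "other"),
    t_ref = counts$t_ref, t_alt = counts$t_alt,
    n_ref = counts$n_ref, n_alt = counts$n_alt,
    pop_freq = pop_freq
  )
  validate_variants(out, path)
  out
}

validate_variants <- function(v, path = "<variants>") {
  cnts <- c("t_ref", "t_alt", "n_ref", "n_alt")
  for (cn in cnts) {
    if (any(is.na(v[[cn]])) || any(v[[cn]] < 0)) {
      abort(sprintf("negative or missing %s in %s", cn, path))
    }
  }
  if (any(v$pos < 1, na.rm = TRUE)) abort(sprintf("position < 1 in %s", path))
  pf <- v$pop_freq[!is.na(v$pop_freq)]
  if (any(pf < 0 | pf > 1)) abort(sprintf("pop_freq outside [0,1] in %s", path))
  invisible(v)
}

#' Write variants to a MAF file
#'
#' Inverse of [read_maf()]; writes the column subset this package reads, so a
#' write-then-read round-trip preserves all fields.
#'
#' @param variants Tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  validate_variants(variants)
  df <- tibble(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Classification = ifelse(variants$consequence == "nonsynonymous",
                                    "Missense_Mutation", "Silent"),
    t_ref_count = variants$t_ref, t_alt_count = variants$t_alt,
    n_ref_count = variants$n_ref, n_alt_count = variants$n_alt,
    pop_freq = variants$pop_freq
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read paired tumor/normal variants from a VCF file
#'
#' Builds variant records from per-sample allelic depths (`AD`) of the two
#' named samples. Multi-allelic sites are split into one record per alternate
#' allele. Sites where either sample lacks an allelic-depth value are skipped
#' and counted in the `skipped` attribute of the result. Gene symbol and
#' consequence are not taken from the VCF (no annotation parsing); records are
#' returned with an empty gene and consequence `"other"`.
#'
#' @param path Path to a VCF 4.x file with a per-sample `AD` FORMAT field.
#' @param tumor_sample,normal_sample Sample names as they appear in the VCF
#'   header.
#' @return A tibble in the same layout as [read_maf()], with attribute
#'   `skipped` giving the number of sites dropped for missing allelic depths.
#' @export
read_vcf_paired <- function(path, tumor_sample, normal_sample) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(tumor_sample, normal_sample)) {
    if (!s %in% samples) {
      abort(sprintf("sample '%s' not in VCF %s; available: %s",
                    s, path, paste(samples, collapse = ", ")))
    }
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, dimnames = list(NULL, names(ad)))
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ad_t <- ad[i, tumor_sample]
    ad_n <- ad[i, normal_sample]
    if (is.na(ad_t) || is.na(ad_n) || ad_t == "." || ad_n == ".") {
      skipped <- skipped + 1L
      next
    }
    adt <- suppressWarnings(as.numeric(strsplit(ad_t, ",")[[1]]))
    adn <- suppressWarnings(as.numeric(strsplit(ad_n, ",")[[1]]))
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    if (any(is.na(adt)) || any(is.na(adn)) ||
        length(adt) < length(alts) + 1 || length(adn) < length(alts) + 1) {
      skipped <- skipped + 1L
      next
    }
    for (a in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = normalize_chrom(fix[i, "CHROM"]),
        pos = as.numeric(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        gene = "", consequence = "other",
        t_ref = adt[1], t_alt = adt[a + 1],
        n_ref = adn[1], n_alt = adn[a + 1],
        pop_freq = NA_real_
      )
    }
  }
  out <- if (length(rows) == 0) {
    tibble(chrom = character(), pos = numeric(), ref = character(),
           alt = character(), gene = character(), consequence = character(),
           t_ref = numeric(), t_alt = numeric(), n_ref = numeric(),
           n_alt = numeric(), pop_freq = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  validate_variants(out, path)
  attr(out, "skipped") <- skipped
  out
}

#' Read copy-number segments from a SEG file
#'
#' @param path Tab-delimited SEG-style file with columns `chrom`, `start`,
#'   `end` (1-based inclusive) and one value column: `total_cn` for the
#'   integer dialect or `log2_ratio` (also recognized: `seg.mean`) for the
#'   log2-ratio dialect. A `sample` column is carried through if present.
#' @param dialect `"integer"` or `"log2"`; the file must contain the matching
#'   value column.
#' @return A tibble sorted by chromosome then start, with columns `chrom`,
#'   `start`, `end`, `length` and `total_cn` or `log2_ratio`. Overlapping
#'   segments on a chromosome are an error.
#' @export
read_segments <- function(path, dialect = c("integer", "log2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("SEG file not found: %s", path))
  df <- read_tsv_quiet(path)
  names(df) <- tolower(names(df))
  ren <- c(chromosome = "chrom", loc.start = "start", loc.end = "end",
           "seg.mean" = "log2_ratio", log2 = "log2_ratio", cn = "total_cn",
           copy_number = "total_cn", id = "sample")
  for (old in names(ren)) {
    if (old %in% names(df) && !ren[[old]] %in% names(df)) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  for (cn in c("chrom", "start", "end")) {
    if (!cn %in% names(df)) abort(sprintf("SEG %s is missing column '%s'", path, cn))
  }
  value_col <- if (dialect == "integer") "total_cn" else "log2_ratio"
  if (!value_col %in% names(df)) {
    abort(sprintf(
      "SEG %s has no '%s' column required by the %s dialect (columns: %s)",
      path, value_col, dialect, paste(names(df), collapse = ", ")))
  }
  seg <- tibble(
    chrom = normalize_chrom(df$chrom),
    start = to_count(df$start, "start", path),
    end = to_count(df$end, "end", path)
  )
  if ("sample" %in% names(df)) seg$sample <- df$sample
  seg[[value_col]] <- to_count(df[[value_col]], value_col, path)
  if (dialect == "integer" && any(seg$total_cn != round(seg$total_cn))) {
    abort(sprintf("SEG %s: non-integer copy number under the integer dialect", path))
  }
  validate_segments(seg, path)
}

validate_segments <- function(seg, path = "<segments>") {
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0) {
    abort(sprintf("segment with start > end in %s (row %d)", path, bad[1]))
  }
  seg <- dplyr::arrange(seg, .data$chrom, .data$start)
  by_chr <- split(seq_len(nrow(seg)), seg$chrom)
  for (idx in by_chr) {
    if (length(idx) < 2) next
    s <- seg[idx, ]
    ovl <- which(s$start[-1] <= s$end[-nrow(s)])
    if (length(ovl) > 0) {
      i <- ovl[1]
      abort(sprintf(
        "overlapping segments in %s: %s:%d-%d and %s:%d-%d",
        path, s$chrom[i], s$start[i], s$end[i],
        s$chrom[i + 1], s$start[i + 1], s$end[i + 1]))
    }
  }
  seg$length <- seg$end - seg$start + 1
  seg
}

#' Write copy-number segments to a SEG file
#'
#' @param segments Tibble as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- intersect(c("sample", "chrom", "start", "end", "total_cn", "log2_ratio"),
                    names(segments))
  readr::write_tsv(segments[cols], path, progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV with one row per sample: `patient`, `sample`,
#' `timepoint` (`pre`/`post`), `purity`, `pfs_months`, `maf`, `seg`. File
#' paths are resolved relative to the manifest's directory. Every patient
#' must have exactly one `pre` and one `post` sample, with purity in (0, 1].
#'
#' @param path Manifest TSV path.
#' @return A validated tibble with `maf` and `seg` resolved to full paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- read_tsv_quiet(path)
  need <- c("patient", "sample", "timepoint", "purity", "pfs_months", "maf", "seg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("manifest %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df$purity <- to_count(df$purity, "purity", path)
  df$pfs_months <- to_count(df$pfs_months, "pfs_months", path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  df$maf <- resolve(df$maf)
  df$seg <- resolve(df$seg)
  validate_manifest(tibble::as_tibble(df))
}

validate_manifest <- function(manifest) {
  tumor <- manifest[manifest$timepoint %in% c("pre", "post"), ]
  bad_tp <- setdiff(unique(manifest$timepoint), c("pre", "post", "normal"))
  if (length(bad_tp) > 0) {
    abort(sprintf("unknown timepoint(s): %s", paste(bad_tp, collapse = ", ")))
  }
  for (p in unique(tumor$patient)) {
    tp <- tumor$timepoint[tumor$patient == p]
    if (sum(tp == "pre") != 1 || sum(tp == "post") != 1) {
      abort(sprintf(
        "patient %s must have exactly one pre and one post sample (has %s)",
        p, paste(sort(tp), collapse = ", ")))
    }
  }
  if (any(is.na(tumor$purity)) || any(tumor$purity <= 0 | tumor$purity > 1)) {
    abort("tumor sample purity must be present and in (0, 1]")
  }
  if (any(is.na(tumor$pfs_months)) || any(tumor$pfs_months < 0)) {
    abort("pfs_months must be present and >= 0 for tumor samples")
  }
  manifest
}

#' Write a cohort manifest
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

REPORT_COLUMNS <- c("patient", "timepoint", "CNA_burden", "TMB", "ITH",
                    "SDI", "wGII", "MATH")

#' Write the per-sample heterogeneity report
#'
#' One row per tumor sample with the six heterogeneity indices, in the layout
#' patient, timepoint, CNA_burden, TMB, ITH, SDI, wGII, MATH. Values are
#' written with six decimal places, so a write-then-read round-trip preserves
#' them to 1e-6.
#'
#' @param profiles Tibble with columns `patient`, `timepoint`, `cna_burden`,
#'   `tmb`, `ith`, `sdi`, `wgii`, `math`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_heterogeneity_report <- function(profiles, path) {
  if (nrow(profiles) > 0 &&
      anyDuplicated(profiles[c("patient", "timepoint")]) > 0) {
    abort("duplicate (patient, timepoint) in heterogeneity profiles")
  }
  num <- function(x) sprintf("%.6f", x)
  df <- tibble(
    patient = as.character(profiles$patient),
    timepoint = as.character(profiles$timepoint),
    CNA_burden = num(profiles$cna_burden),
    TMB = num(profiles$tmb),
    ITH = as.integer(profiles$ith),
    SDI = num(profiles$sdi),
    wGII = num(profiles$wgii),
    MATH = num(profiles$math)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# clonevo heterogeneity report v1", con)
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(as.list(df), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a heterogeneity report written by [write_heterogeneity_report()]
#' @param path Report TSV path.
#' @return Tibble with lower-case metric columns.
#' @export
read_heterogeneity_report <- function(path) {
  df <- read_tsv_quiet(path)
  missing <- setdiff(REPORT_COLUMNS, names(df))
  if (length(missing) > 0) {
    abort(sprintf("report %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  tibble(
    patient = df$patient, timepoint = df$timepoint,
    cna_burden = as.numeric(df$CNA_burden), tmb = as.numeric(df$TMB),
    ith = as.integer(df$ITH), sdi = as.numeric(df$SDI),
    wgii = as.numeric(df$wGII), math = as.numeric(df$MATH)
  )
}

#' Read a driver-gene list
#'
#' Newline-delimited gene symbols; blank lines and `#` comments ignored.
#' Symbols are upper-cased and trimmed for case-insensitive matching.
#'
#' @param path Text file path.
#' @return Character vector of normalized symbols.
#' @export
read_driver_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("driver list not found: %s", path))
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[x != "" & !startsWith(x, "#")]
  unique(toupper(x))
}
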