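# Shared fixtures and independent brute-force oracles. Oracles re-evaluate
# the definitional formulas literally and are kept separate from the package
# implementation paths they check.

maf_header <- paste(c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
  "Tumor_Seq_Allele2", "Variant_Classification", "t_ref_count",
  "t_alt_count", "n_ref_count", "n_alt_count"), collapse = "\t")

write_maf_fixture <- function(rows, header = maf_header) {
  path <- tempfile(fileext = ".maf")
  writeLines(c(header, rows), path)
  path
}

write_seg_fixture <- function(rows,
                              header = "sample\tchrom\tstart\tend\ttotal_cn") {
  path <- tempfile(fileext = ".seg")
  writeLines(c(header, rows), path)
  path
}

rand_variants <- function(n) {
  tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = paste0("G", seq_len(n)),
    consequence = sample(c("nonsynonymous", "other"), n, replace = TRUE),
    t_ref = sample(0:200, n, replace = TRUE),
    t_alt = sample(0:60, n, replace = TRUE),
    n_ref = sample(0:200, n, replace = TRUE),
    n_alt = sample(0:10, n, replace = TRUE),
    pop_freq = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 0.05)))
}

rand_segments <- function(n_chr = 4, segs_per_chr = 3) {
  rows <- list()
  for (chr in seq_len(n_chr)) {
    bounds <- sort(sample.int(1e6, segs_per_chr + 1))
    for (k in seq_len(segs_per_chr)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = as.character(chr), start = bounds[k] + (k > 1),
        end = bounds[k + 1], total_cn = sample(0:4, 1))
    }
  }
  seg <- dplyr::bind_rows(rows)
  seg$length <- seg$end - seg$start + 1
  seg
}

# --- definitional oracles -------------------------------------------------

math_oracle <- function(v) {
  m <- sort(v)[ceiling(length(v) / 2)]
  if (length(v) %% 2 == 0) {
    s <- sort(v)
    m <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  }
  dev <- abs(v - m)
  s <- sort(dev)
  mad_raw <- if (length(v) %% 2 == 0) {
    (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  } else {
    s[ceiling(length(v) / 2)]
  }
  100 * 1.4826 * mad_raw / m
}

sdi_oracle <- function(sizes) {
  total <- sum(sizes)
  acc <- 0
  for (s in sizes) acc <- acc - (s / total) * log(s / total)
  acc
}

wgii_oracle <- function(seg, ploidy = 2) {
  chrs <- unique(seg$chrom[seg$chrom %in% as.character(1:22)])
  fr <- vapply(chrs, function(ch) {
    s <- seg[seg$chrom == ch, ]
    len <- s$end - s$start + 1
    sum(len[s$total_cn != round(ploidy)]) / sum(len)
  }, numeric(1))
  mean(fr)
}

cna_oracle <- function(seg, neutral = 2) {
  100 * sum(seg$total_cn != neutral) / nrow(seg)
}

tmb_oracle <- function(n, mb) n / mb

# exact two-sided rank-sum p by explicit enumeration of group assignments
wilcoxon_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n)])
  EW <- n * (N + 1) / 2
  hits <- 0L; total <- 0L
  for (pick in utils::combn(N, n, simplify = FALSE)) {
    total <- total + 1L
    if (abs(sum(r[pick]) - EW) >= abs(W_obs - EW) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# count labeled trees on K nodes rooted at `root` by brute force over all
# parent vectors (independent of the Pruefer-based enumeration)
count_rooted_trees_bruteforce <- function(K, root = 1) {
  if (K == 1) return(1L)
  slots <- setdiff(seq_len(K), root)
  grids <- expand.grid(rep(list(seq_len(K)), K - 1))
  count <- 0L
  for (r in seq_len(nrow(grids))) {
    parent <- integer(K)
    parent[slots] <- as.integer(grids[r, ])
    if (any(parent[slots] == slots)) next
    ok <- TRUE
    for (v in slots) {
      seen <- logical(K); cur <- v
      while (cur != root) {
        if (seen[cur]) { ok <- FALSE; break }
        seen[cur] <- TRUE
        cur <- parent[cur]
      }
      if (!ok) break
    }
    if (ok) count <- count + 1L
  }
  count
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# joint pre/post observations for simulated reads from given prevalences
sim_observations <- function(phi_pre, phi_post, n_per_cluster, depth, purity) {
  stopifnot(length(phi_pre) == length(phi_post))
  rows <- list()
  truth <- integer(0)
  for (k in seq_along(phi_pre)) {
    for (j in seq_len(n_per_cluster)) {
      id <- sprintf("c%d_m%d", k, j)
      xp <- clonevo::expected_vaf(phi_pre[k], purity)
      xq <- clonevo::expected_vaf(phi_post[k], purity)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, sample = c("pre", "post"),
        alt = c(rbinom(1, depth, xp), rbinom(1, depth, xq)),
        depth = depth)
      truth <- c(truth, k)
    }
  }
  list(obs = dplyr::bind_rows(rows), truth = truth)
}
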