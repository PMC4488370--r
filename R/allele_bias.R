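## Allele-biased expression of duplicate gene copies.
##
## Sites called heterozygous in an inbred line are read as sites that
## segregate between two collapsed duplicate copies.  Comparing the
## minor allele's frequency in genomic versus RNA-seq reads per gene
## tests whether one copy is transcriptionally silent.

#' Filter candidate copy-segregating sites
#'
#' Keeps sites with `site_quality >= min_quality`, `het_support >
#' min_het_support` (sites without an FQ-like score are dropped), DNA and
#' RNA depth both `>= min_cov`, and (when `genes` is given) located
#' within an annotated gene, which also fills/overrides `gene_id`.
#'
#' @param sites site data.frame (see [simulate_segregating_sites()] for
#'   the column contract).
#' @param min_quality minimum phred-like site quality (default 20).
#' @param min_het_support exclusive lower bound on the heterozygosity
#'   support score (default 0).
#' @param min_cov minimum DNA and RNA depth (default 10).
#' @param genes optional gene-model data.frame for the containment rule.
#' @return the retained sites.
#' @export
select_segregating_sites <- function(sites, min_quality = 20,
                                     min_het_support = 0, min_cov = 10,
                                     genes = NULL) {
  dna <- sites$dna_count_a + sites$dna_count_b
  rna <- sites$rna_count_a + sites$rna_count_b
  keep <- !is.na(sites$het_support) &
    sites$site_quality >= min_quality &
    sites$het_support > min_het_support &
    dna >= min_cov & rna >= min_cov
  out <- sites[keep, , drop = FALSE]
  if (!is.null(genes)) {
    gid <- rep(NA_character_, nrow(out))
    for (i in seq_len(nrow(genes)))
      gid[out$contig == genes$contig[i] & out$pos >= genes$start[i] &
            out$pos < genes$end[i]] <- genes$gene_id[i]
    out$gene_id <- gid
    out <- out[!is.na(out$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Minor-allele frequencies of one or many sites
#'
#' The minor allele is decided once, from the DNA counts (smaller count;
#' ties broken towards the lexicographically smaller nucleotide), and the
#' same allele's frequency is reported in both data types, so a biased
#' RNA frequency is interpretable as silence of that copy.
#'
#' @param sites site data.frame with positive DNA and RNA depth.
#' @return data.frame minor_allele, dna_freq, rna_freq along `sites`.
#' @export
minor_allele_freqs <- function(sites) {
  dna <- sites$dna_count_a + sites$dna_count_b
  rna <- sites$rna_count_a + sites$rna_count_b
  if (any(dna == 0) || any(rna == 0))
    stop("all sites must have positive DNA and RNA depth")
  a_minor <- sites$dna_count_a < sites$dna_count_b |
    (sites$dna_count_a == sites$dna_count_b &
       sites$allele_a < sites$allele_b)
  data.frame(
    minor_allele = ifelse(a_minor, sites$allele_a, sites$allele_b),
    dna_freq = ifelse(a_minor, sites$dna_count_a, sites$dna_count_b) / dna,
    rna_freq = ifelse(a_minor, sites$rna_count_a, sites$rna_count_b) / rna)
}

#' Two-sample rank-sum test of a gene's DNA vs RNA frequencies
#'
#' Exact permutation p-value (doubled smaller tail of the rank-sum
#' statistic over all group assignments, midranks for ties) when the
#' total number of sites is at most `exact_max`; normal approximation
#' with ties correction and continuity correction beyond that.  A paired
#' signed-rank variant is available but with the typical 2-5 sites per
#' gene it cannot reach p < 0.05, which is why the two-sample reading is
#' the default.
#'
#' @param dna_freqs,rna_freqs per-site minor-allele frequencies.
#' @param paired use the signed-rank test instead.
#' @param exact_max largest total n for exact enumeration (default 20).
#' @return two-sided p-value.
#' @export
gene_bias_test <- function(dna_freqs, rna_freqs, paired = FALSE,
                           exact_max = 20) {
  if (length(dna_freqs) < 2 || length(rna_freqs) < 2)
    stop("need at least 2 sites per group")
  if (paired) {
    stopifnot(length(dna_freqs) == length(rna_freqs))
    return(suppressWarnings(
      wilcox.test(dna_freqs, rna_freqs, paired = TRUE)$p.value))
  }
  m <- length(dna_freqs); n <- length(rna_freqs)
  if (m + n <= exact_max) {
    r <- rank(c(dna_freqs, rna_freqs))
    w_obs <- sum(r[seq_len(m)])
    combs <- .combn_cache(m + n, m)
    w_all <- colSums(matrix(r[combs], nrow = m))
    eps <- 1e-9
    p <- 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps))
    return(min(1, p))
  }
  suppressWarnings(
    wilcox.test(dna_freqs, rna_freqs, exact = FALSE, correct = TRUE)$p.value)
}

# subset enumeration is reused heavily in per-gene loops: memoize
.combn_env <- new.env(parent = emptyenv())
.combn_cache <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.combn_env[[key]]))
    .combn_env[[key]] <- utils::combn(n, k)
  .combn_env[[key]]
}

#' Benjamini-Hochberg FDR adjustment
#' @param p_values numeric vector in `[0,1]`.
#' @return adjusted p-values (same order as input).
#' @export
fdr_correct <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Per-gene allele-bias analysis
#'
#' Runs the site filter, the minor-allele frequency extraction and the
#' per-gene rank-sum test, then adjusts across genes with
#' Benjamini-Hochberg.  Genes with fewer than 2 usable sites are skipped
#' (listed in the `skipped` attribute).
#'
#' @param sites site data.frame.
#' @param fdr significance level on adjusted p-values (default 0.05).
#' @param min_quality,min_het_support,min_cov passed to
#'   [select_segregating_sites()].
#' @param genes optional gene models for the containment rule.
#' @param paired use the paired signed-rank variant.
#' @return data.frame gene_id, n_sites, median_dna_freq,
#'   median_rna_freq, p_raw, p_fdr, biased.
#' @export
allele_bias <- function(sites, fdr = 0.05, min_quality = 20,
                        min_het_support = 0, min_cov = 10, genes = NULL,
                        paired = FALSE) {
  sel <- select_segregating_sites(sites, min_quality, min_het_support,
                                  min_cov, genes)
  empty <- data.frame(gene_id = character(), n_sites = integer(),
                      median_dna_freq = numeric(),
                      median_rna_freq = numeric(), p_raw = numeric(),
                      p_fdr = numeric(), biased = logical())
  if (nrow(sel) == 0) return(empty)
  fr <- cbind(sel["gene_id"], minor_allele_freqs(sel))
  counts <- table(fr$gene_id)
  skipped <- names(counts)[counts < 2]
  if (length(skipped) > 0)
    message(length(skipped), " gene(s) skipped with < 2 usable sites")
  keep <- names(counts)[counts >= 2]
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(g) {
    f <- fr[fr$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, n_sites = nrow(f),
               median_dna_freq = median(f$dna_freq),
               median_rna_freq = median(f$rna_freq),
               p_raw = gene_bias_test(f$dna_freq, f$rna_freq,
                                      paired = paired))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_correct(out$p_raw)
  out$biased <- out$p_fdr < fdr
  attr(out, "skipped") <- skipped
  out
}
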