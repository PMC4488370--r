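## Enrichment / depletion of SV-affected genes across homology classes,
## protein-domain gene families, and diversity strata.

#' Homology-class depletion / enrichment among SV-affected genes
#'
#' Per class, a two-sided Fisher's exact test of (in class vs not) by
#' (SV-affected vs not) over the gene universe.
#'
#' @param sv_genes character vector of SV-affected gene ids (subset of
#'   `classes$gene_id`).
#' @param classes data.frame gene_id, class covering the universe.
#' @return data.frame class, n_sv, n_class, odds_ratio, p_value,
#'   direction ("depleted"/"enriched"/"none").
#' @export
class_depletion <- function(sv_genes, classes) {
  if (!all(sv_genes %in% classes$gene_id))
    stop("sv_genes must be a subset of the classified gene universe")
  in_sv <- classes$gene_id %in% sv_genes
  out <- lapply(unique(classes$class), function(cl) {
    in_cl <- classes$class == cl
    if (!any(in_cl)) return(NULL)
    tab <- matrix(c(sum(in_cl & in_sv), sum(!in_cl & in_sv),
                    sum(in_cl & !in_sv), sum(!in_cl & !in_sv)), 2)
    ft <- fisher.test(tab)
    or <- unname(ft$estimate)
    data.frame(class = cl, n_sv = sum(in_cl & in_sv), n_class = sum(in_cl),
               odds_ratio = or, p_value = ft$p.value,
               direction = if (or < 1) "depleted"
                           else if (or > 1) "enriched" else "none")
  })
  do.call(rbind, out)
}

#' Protein-domain family enrichment among SV-affected genes
#'
#' Families are genes sharing a PFAM accession.  Per domain: k = SV
#' genes with the domain, K = background genes with it, n = |sv_genes|,
#' N = |background|; upper-tail hypergeometric
#' `p = P(X >= k), X ~ Hypergeom(N, K, n)`, Benjamini-Hochberg across
#' domains.  A gene with several domains counts once per domain, so the
#' per-domain tests are not independent (the BH correction is a
#' pragmatic, not exact, control).
#'
#' @param domains data.frame gene_id, domain_id covering the background.
#' @param sv_genes,background character vectors of gene ids
#'   (`sv_genes` a subset of `background`).
#' @param min_family_size smallest background family tested (default 2).
#' @param n_perm if > 0, also compute a label-permutation p per domain
#'   (that many draws, seeded by `perm_seed`).
#' @param perm_seed RNG seed for the permutation alternative.
#' @return data.frame domain_id, k, K, n, N, p_value, p_fdr (and
#'   p_perm when requested).
#' @export
family_enrichment <- function(domains, sv_genes, background,
                              min_family_size = 2, n_perm = 0,
                              perm_seed = 1L) {
  stopifnot(all(sv_genes %in% background))
  domains <- domains[domains$gene_id %in% background, , drop = FALSE]
  domains <- unique(domains[, c("gene_id", "domain_id")])
  N <- length(unique(background))
  n <- length(unique(sv_genes))
  fam <- split(domains$gene_id, domains$domain_id)
  fam <- fam[lengths(fam) >= min_family_size]
  if (length(fam) == 0)
    return(data.frame(domain_id = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p_value = numeric(), p_fdr = numeric()))
  out <- data.frame(
    domain_id = names(fam),
    k = vapply(fam, function(g) sum(g %in% sv_genes), 0L),
    K = lengths(fam), n = n, N = N)
  out$p_value <- phyper(out$k - 1, out$K, N - out$K, n, lower.tail = FALSE)
  out$p_fdr <- fdr_correct(out$p_value)
  if (n_perm > 0) {
    out$p_perm <- withr::with_seed(perm_seed, {
      bg <- unique(background)
      perm_k <- matrix(0L, n_perm, length(fam))
      for (b in seq_len(n_perm)) {
        draw <- sample(bg, n)
        perm_k[b, ] <- vapply(fam, function(g) sum(g %in% draw), 0L)
      }
      vapply(seq_along(fam), function(j)
        (sum(perm_k[, j] >= out$k[j]) + 1) / (n_perm + 1), 0)
    })
  }
  rownames(out) <- NULL
  out
}

#' Nucleotide diversity in windows with vs without SVs
#'
#' Partitions the 100 kb windows by any-SV overlap and compares the two
#' diversity distributions with a two-sided Wilcoxon rank-sum test.
#'
#' @param diversity data.frame contig, start, end, pi.
#' @param calls SV call data.frame.
#' @return list: median_with, median_without, ratio (with/without),
#'   p_value, n_with, n_without.
#' @export
diversity_by_sv <- function(diversity, calls) {
  has_sv <- rep(FALSE, nrow(diversity))
  for (i in seq_len(nrow(calls))) {
    has_sv <- has_sv | (diversity$contig == calls$contig[i] &
                          overlap_len(diversity$start, diversity$end,
                                      calls$start[i], calls$end[i]) > 0)
  }
  if (!any(has_sv) || all(has_sv))
    stop("both window groups (with and without SVs) must be non-empty")
  with_pi <- diversity$pi[has_sv]
  without_pi <- diversity$pi[!has_sv]
  p <- if (length(unique(c(with_pi, without_pi))) == 1) 1 else
    suppressWarnings(wilcox.test(with_pi, without_pi,
                                 exact = FALSE)$p.value)
  list(median_with = median(with_pi), median_without = median(without_pi),
       ratio = median(with_pi) / median(without_pi),
       p_value = p,
       n_with = sum(has_sv), n_without = sum(!has_sv))
}
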