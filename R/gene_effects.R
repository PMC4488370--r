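## SV-to-gene assignment and expression-impact tests.

#' Assign SV status to genes
#'
#' Complete mode: a gene is deleted/duplicated only if its whole span
#' (first to last exon) lies inside a single call of that type — the
#' conservative rule that tolerates imprecise read-coverage breakpoints.
#' Half mode (deletions only): a gene is `partially_deleted` if deletions
#' cover at least half of its span.
#'
#' @param calls SV call data.frame.
#' @param genes gene-model data.frame.
#' @param mode "complete" or "half".
#' @return data.frame gene_id, status
#'   (deleted/duplicated/partially_deleted/unaffected), mode.
#' @export
assign_sv_genes <- function(calls, genes, mode = c("complete", "half")) {
  mode <- match.arg(mode)
  status <- rep("unaffected", nrow(genes))
  if (mode == "complete") {
    for (i in seq_len(nrow(calls))) {
      inside <- genes$contig == calls$contig[i] &
        genes$start >= calls$start[i] & genes$end <= calls$end[i]
      # deletions win over duplications on (impossible) overlap ties
      upd <- inside & (status == "unaffected" | calls$sv_type[i] == "deletion")
      status[upd] <- if (calls$sv_type[i] == "deletion") "deleted"
                     else "duplicated"
    }
  } else {
    dels <- calls[calls$sv_type == "deletion", , drop = FALSE]
    cov <- numeric(nrow(genes))
    if (nrow(dels) > 0) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        dels$contig, IRanges::IRanges(dels$start + 1, dels$end)))
      red <- as.data.frame(gr)
      for (i in seq_len(nrow(red))) {
        sel <- genes$contig == red$seqnames[i]
        cov[sel] <- cov[sel] + overlap_len(genes$start[sel], genes$end[sel],
                                           red$start[i] - 1, red$end[i])
      }
    }
    status[cov >= 0.5 * (genes$end - genes$start)] <- "partially_deleted"
  }
  data.frame(gene_id = genes$gene_id, status = status, mode = mode)
}

#' Expression classes in FPKM
#'
#' Bins FPKM into `{zero, (0,1], (1,10], (10,100], >100}`: zero means
#' complete lack of expression evidence, the other classes roughly span
#' orders of magnitude.  Interior edges are closed on the right (an FPKM
#' of exactly 100 falls in (10,100]).
#'
#' @param fpkm numeric vector of non-negative FPKM values.
#' @param breaks interior bin edges (default `c(1, 10, 100)`).
#' @return ordered factor of class labels.
#' @export
expression_class <- function(fpkm, breaks = c(1, 10, 100)) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be >= 0")
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  labs <- ifelse(is.infinite(hi), paste0(">", lo),
                 paste0("(", lo, ",", hi, "]"))
  cls <- character(length(fpkm))
  cls[fpkm == 0] <- "zero"
  nz <- which(fpkm > 0)
  # index = number of interior edges strictly below the value, plus one
  cls[nz] <- labs[findInterval(fpkm[nz], breaks, left.open = TRUE) + 1]
  factor(cls, levels = c("zero", labs), ordered = TRUE)
}

#' Loss-of-expression test (Fisher's exact)
#'
#' 2x2 table of (zero vs nonzero FPKM in the test strain) against
#' (SV-affected vs background genes); two-sided Fisher's exact test.
#'
#' @param affected,background disjoint character vectors of gene ids.
#' @param expression named numeric vector of test-strain FPKM covering
#'   both sets.
#' @return list: odds_ratio (conditional MLE), p_value, table.
#' @export
loss_of_expression_test <- function(affected, background, expression) {
  if (length(affected) == 0 || length(background) == 0)
    stop("both gene sets must be non-empty")
  if (length(intersect(affected, background)) > 0)
    stop("gene sets must be disjoint")
  miss <- setdiff(c(affected, background), names(expression))
  if (length(miss) > 0)
    stop("no expression value for ", length(miss), " gene(s), e.g. ",
         miss[1])
  tab <- rbind(affected = table(factor(expression[affected] == 0,
                                       levels = c(TRUE, FALSE))),
               background = table(factor(expression[background] == 0,
                                         levels = c(TRUE, FALSE))))
  colnames(tab) <- c("zero", "nonzero")
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Dosage fold-change test (Wilcoxon rank-sum)
#'
#' Compares log2(test/ref) expression ratios of duplicated genes against
#' unaffected genes; only genes expressed (FPKM > 0) in both samples
#' enter.
#'
#' @param duplicated,unaffected character vectors of gene ids.
#' @param expr_ref,expr_test named numeric vectors of FPKM.
#' @return list: p_value, n_dup, n_unaff, median_shift (difference of
#'   group median log2 ratios).
#' @export
dosage_fold_change_test <- function(duplicated, unaffected,
                                    expr_ref, expr_test) {
  usable <- function(g) g[expr_ref[g] > 0 & expr_test[g] > 0 &
                            !is.na(expr_ref[g]) & !is.na(expr_test[g])]
  d <- usable(duplicated); u <- usable(unaffected)
  if (length(d) < 3 || length(u) < 3)
    stop("need at least 3 expressed genes per group (have ",
         length(d), " and ", length(u), ")")
  lfc <- function(g) log2(expr_test[g] / expr_ref[g])
  wt <- suppressWarnings(wilcox.test(lfc(d), lfc(u), exact = FALSE))
  list(p_value = wt$p.value, n_dup = length(d), n_unaff = length(u),
       median_shift = median(lfc(d)) - median(lfc(u)))
}

#' Spearman correlation between two transcriptomes
#'
#' @param expr_A,expr_B named numeric FPKM vectors over the same genes.
#' @return Spearman's rho.
#' @export
transcriptome_correlation <- function(expr_A, expr_B) {
  genes <- intersect(names(expr_A), names(expr_B))
  if (length(genes) < 3) stop("need at least 3 shared genes")
  cor(expr_A[genes], expr_B[genes], method = "spearman")
}

#' Genes affected in both strains (shared events)
#' @param status_a,status_b outputs of [assign_sv_genes()] for two
#'   strains; `what` the status of interest.
#' @param what status value to intersect on.
#' @return character vector of gene ids with that status in both.
#' @export
shared_events <- function(status_a, status_b, what = "deleted") {
  intersect(status_a$gene_id[status_a$status == what],
            status_b$gene_id[status_b$status == what])
}
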