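## Differential read-coverage SV calling.
##
## The coverage model: window counts in the two libraries are Poisson;
## conditioning on their sum turns the rate comparison into an exact
## binomial test of count_test ~ Binomial(n, q) with q the test library's
## share of total reads.  Two-sided p-values use the minimum-likelihood
## convention (sum of outcome probabilities <= the observed one), the
## same convention as stats::binom.test.

#' Tile (sliding) windows over an assembly
#'
#' @param assembly genome assembly data.frame (`contig`, `length`).
#' @param window_size window width in bases.
#' @param step step between window starts; `step = window_size` gives a
#'   non-overlapping tiling.  A final partial window is kept if it is at
#'   least `step` long; contigs shorter than one window yield a single
#'   truncated window.
#' @return data.frame contig, start, end.
#' @export
make_windows <- function(assembly, window_size, step = window_size %/% 2) {
  if (window_size <= 0) stop("window_size must be > 0")
  if (step <= 0 || step > window_size)
    stop("step must satisfy 0 < step <= window_size")
  out <- lapply(seq_len(nrow(assembly)), function(i) {
    L <- assembly$length[i]
    if (L <= window_size)
      return(data.frame(contig = assembly$contig[i], start = 0, end = L))
    starts <- seq(0, L - 1, by = step)
    ends <- pmin(starts + window_size, L)
    # full windows always; a trailing partial only if longer than one step
    keep <- (ends - starts == window_size) | (ends - starts > step)
    data.frame(contig = assembly$contig[i], start = starts[keep],
               end = ends[keep])
  })
  do.call(rbind, out)
}

#' Exact conditional coverage test for one or many windows
#'
#' Given Poisson counts `count_ref` (control) and `count_test` and the
#' library totals, computes the log2 fold change
#' `log2(((count_test + 0.5)/total_test) / ((count_ref + 0.5)/total_ref))`
#' (pseudocount 0.5 keeps it finite at zero coverage; it never enters the
#' p-value) and the two-sided exact conditional p-value from
#' `count_test ~ Binomial(n, q)`, `n = count_ref + count_test`,
#' `q = total_test / (total_ref + total_test)`.
#'
#' Windows with `n = 0` get `p = 1`, `log2_fc = 0` and `no_data = TRUE`.
#'
#' @param count_ref,count_test integer vectors of window read counts.
#' @param total_ref,total_test library totals (scalars, > 0).
#' @return data.frame log2_fc, p_value, no_data.
#' @export
window_test <- function(count_ref, count_test, total_ref, total_test) {
  stopifnot(total_ref > 0, total_test > 0,
            length(count_ref) == length(count_test))
  q <- total_test / (total_ref + total_test)
  n <- count_ref + count_test
  fc <- log2(((count_test + 0.5) / total_test) /
               ((count_ref + 0.5) / total_ref))
  p <- rep(1, length(n))
  no_data <- n == 0
  fc[no_data] <- 0
  # group by n: the null distribution depends only on n, so compute the
  # minimum-likelihood two-sided p for all k of each n at once
  todo <- which(!no_data)
  for (nn in unique(n[todo])) {
    idx <- todo[n[todo] == nn]
    d <- dbinom(0:nn, nn, q)
    ord <- order(d)
    csum <- cumsum(d[ord])
    # p(k) = sum of all outcome probabilities <= d[k] (with float slack)
    rank_of <- integer(nn + 1)
    rank_of[ord] <- seq_along(ord)
    # extend ties: last position in the ordered vector with d <= d[k]*(1+eps)
    dk <- d[count_test[idx] + 1]
    pk <- vapply(dk, function(x) {
      csum[max(which(d[ord] <= x * (1 + 1e-7)))]
    }, 0)
    p[idx] <- pmin(1, pk)
  }
  data.frame(log2_fc = fc, p_value = p, no_data = no_data)
}

#' Compute window statistics from a counts table
#'
#' @param counts data.frame contig, start, end, count_ref, count_test.
#' @param total_ref,total_test optional library totals; default the
#'   column sums (the windowed genome is then the library universe).
#' @return the counts data.frame with log2_fc, p_value, no_data added.
#' @export
window_stats <- function(counts, total_ref = sum(counts$count_ref),
                         total_test = sum(counts$count_test)) {
  cbind(counts, window_test(counts$count_ref, counts$count_test,
                            total_ref, total_test))
}

#' Per-strain, per-type threshold policy
#'
#' The four calibrated cutoff pairs of the original strains ship as
#' [paper_threshold_policies()].  Deletion policies must have a negative
#' fold-change cutoff, duplication policies a positive one.
#'
#' @param strain strain label.
#' @param sv_type "deletion" or "duplication".
#' @param fc_cutoff log2 fold-change cutoff (sign must match the type).
#' @param p_cutoff p-value cutoff (windows with `p < p_cutoff` pass).
#' @return one-row data.frame of class `threshold_policy`.
#' @export
threshold_policy <- function(strain, sv_type, fc_cutoff, p_cutoff) {
  sv_type <- match.arg(sv_type, c("deletion", "duplication"))
  if (sv_type == "deletion" && fc_cutoff >= 0)
    stop("deletion policies need fc_cutoff < 0")
  if (sv_type == "duplication" && fc_cutoff <= 0)
    stop("duplication policies need fc_cutoff > 0")
  structure(data.frame(strain = strain, sv_type = sv_type,
                       fc_cutoff = fc_cutoff, p_cutoff = p_cutoff),
            class = c("threshold_policy", "data.frame"))
}

#' The four published strain/type cutoff pairs
#' @return data.frame of four threshold policies.
#' @export
paper_threshold_policies <- function() {
  rbind(threshold_policy("RS5410", "duplication", 1.01, 1e-15),
        threshold_policy("RS5410", "deletion", -1.66, 1e-5),
        threshold_policy("RS5200", "duplication", 0.74, 1e-15),
        threshold_policy("RS5200", "deletion", -1.63, 1e-5))
}

#' Filter window statistics by a threshold policy
#'
#' Keeps windows with `p_value < p_cutoff` and `log2_fc >= fc_cutoff`
#' (duplications) or `log2_fc <= fc_cutoff` (deletions).
#'
#' @param stats window-stat data.frame from [window_stats()].
#' @param policy a [threshold_policy()] row.
#' @return the retained windows.
#' @export
apply_thresholds <- function(stats, policy) {
  if (policy$sv_type == "deletion" && policy$fc_cutoff >= 0 ||
      policy$sv_type == "duplication" && policy$fc_cutoff <= 0)
    stop("policy sign inconsistent with sv_type")
  keep <- stats$p_value < policy$p_cutoff &
    (if (policy$sv_type == "duplication") stats$log2_fc >= policy$fc_cutoff
     else stats$log2_fc <= policy$fc_cutoff)
  stats[keep, , drop = FALSE]
}

#' Merge significant windows into SV calls
#'
#' Overlapping or bookended windows of the same type merge into one call
#' spanning their union; calls shorter than `min_size` are dropped.
#' `min_p` is the smallest and `mean_log2_fc` the mean over member
#' windows.
#'
#' @param significant retained windows (one sv_type).
#' @param sv_type the type of the windows.
#' @param strain strain label for the calls.
#' @param min_size minimum call span in bases (default 2000).
#' @return SV call data.frame.
#' @export
merge_calls <- function(significant, sv_type, strain = "test",
                        min_size = 2000) {
  if (nrow(significant) == 0)
    return(sv_calls(character(), numeric(), numeric(), character(),
                    min_size = min_size)[0, ])
  gr <- GenomicRanges::GRanges(
    significant$contig,
    IRanges::IRanges(significant$start + 1, significant$end))
  merged <- GenomicRanges::reduce(gr)   # merges overlapping + bookended
  hits <- GenomicRanges::findOverlaps(gr, merged)
  idx <- S4Vectors::subjectHits(hits)
  min_p <- tapply(significant$p_value[S4Vectors::queryHits(hits)], idx, min)
  mean_fc <- tapply(significant$log2_fc[S4Vectors::queryHits(hits)], idx,
                    mean)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1,
                    end = GenomicRanges::end(merged),
                    sv_type = sv_type, strain = strain,
                    min_p = as.numeric(min_p),
                    mean_log2_fc = as.numeric(mean_fc), polarized = NA)
  out <- out[out$end - out$start >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call SVs of both types from window statistics
#'
#' @param stats window-stat data.frame.
#' @param policies data.frame of threshold policies (one per sv_type),
#'   e.g. two rows of [paper_threshold_policies()] for one strain.
#' @param min_size minimum call span (default 2000).
#' @return SV call data.frame (both types).
#' @export
call_svs <- function(stats, policies, min_size = 2000) {
  out <- lapply(seq_len(nrow(policies)), function(i) {
    pol <- policies[i, ]
    merge_calls(apply_thresholds(stats, pol), pol$sv_type,
                strain = pol$strain, min_size = min_size)
  })
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Label calls against a truth set
#'
#' A call is a true positive if it overlaps any truth interval of the
#' same type by at least `min_overlap` bases.
#'
#' @param calls SV call data.frame.
#' @param truth truth SV data.frame (contig, start, end, sv_type).
#' @param min_overlap minimum overlap in bases (default 1).
#' @return calls with a `label` column ("true_positive"/"false_positive").
#' @export
label_calls <- function(calls, truth, min_overlap = 1) {
  lab <- rep("false_positive", nrow(calls))
  for (i in seq_len(nrow(truth))) {
    sel <- calls$contig == truth$contig[i] &
      calls$sv_type == truth$sv_type[i] &
      overlap_len(calls$start, calls$end,
                  truth$start[i], truth$end[i]) >= min_overlap
    lab[sel] <- "true_positive"
  }
  cbind(calls, label = lab)
}

#' ROC over p-value and fold-change cutoff grids
#'
#' For every `(p_cutoff, fc_cutoff)` pair, a labelled call is retained if
#' `min_p < p_cutoff` and its `mean_log2_fc` passes `fc_cutoff` in the
#' direction of `sv_type`.  TPR is the retained fraction of true
#' positives, FPR of false positives.
#'
#' @param labeled labelled call data.frame (needs both labels present).
#' @param p_grid,fc_grid cutoff grids.
#' @param sv_type orientation of the fold-change cutoff.
#' @return data.frame p_cutoff, fc_cutoff, tpr, fpr sorted by fpr.
#' @export
roc_curve <- function(labeled, p_grid, fc_grid,
                      sv_type = c("deletion", "duplication")) {
  sv_type <- match.arg(sv_type)
  is_tp <- labeled$label == "true_positive"
  if (!any(is_tp) || all(is_tp))
    stop("labelled set must contain both true and false positives")
  grid <- expand.grid(p_cutoff = p_grid, fc_cutoff = fc_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    keep <- labeled$min_p < grid$p_cutoff[i] &
      (if (sv_type == "duplication")
         labeled$mean_log2_fc >= grid$fc_cutoff[i]
       else labeled$mean_log2_fc <= grid$fc_cutoff[i])
    data.frame(p_cutoff = grid$p_cutoff[i], fc_cutoff = grid$fc_cutoff[i],
               tpr = sum(keep & is_tp) / sum(is_tp),
               fpr = sum(keep & !is_tp) / sum(!is_tp))
  })
  out <- do.call(rbind, res)
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Pick an operating point from a ROC
#'
#' Maximizes TPR subject to `fpr <= max_fpr`; ties broken by smaller
#' FPR, then by more stringent (smaller) p cutoff.
#'
#' @param roc ROC data.frame from [roc_curve()].
#' @param max_fpr admissible false-positive rate.
#' @param strain,sv_type labels for the returned policy.
#' @return a [threshold_policy()].
#' @export
pick_operating_point <- function(roc, max_fpr = 0.05, strain = "test",
                                 sv_type = c("deletion", "duplication")) {
  sv_type <- match.arg(sv_type)
  ok <- roc[roc$fpr <= max_fpr, , drop = FALSE]
  if (nrow(ok) == 0)
    stop("no ROC point satisfies fpr <= ", max_fpr,
         "; try a larger max_fpr")
  ok <- ok[order(-ok$tpr, ok$fpr, ok$p_cutoff), , drop = FALSE]
  threshold_policy(strain, sv_type, ok$fc_cutoff[1], ok$p_cutoff[1])
}

#' Per-window genome fraction deleted / duplicated
#'
#' Tiles the assembly in non-overlapping windows (default 100 kb) and
#' reports, per window, the fraction of bases covered by the union of
#' calls of each type; duplications positive, deletions negative (the
#' plotting convention).
#'
#' @param calls SV call data.frame.
#' @param assembly genome assembly data.frame.
#' @param window window width in bases (default 100000).
#' @return data.frame contig, start, end, frac_duplicated, frac_deleted
#'   (negative), with the fraction denominators the true window lengths.
#' @export
genome_fraction <- function(calls, assembly, window = 1e5) {
  wins <- make_windows(assembly, window, window)
  frac_of <- function(type) {
    sub <- calls[calls$sv_type == type, , drop = FALSE]
    if (nrow(sub) == 0) return(rep(0, nrow(wins)))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$contig, IRanges::IRanges(sub$start + 1, sub$end)))
    red <- as.data.frame(gr)
    f <- numeric(nrow(wins))
    for (i in seq_len(nrow(red))) {
      sel <- wins$contig == red$seqnames[i]
      f[sel] <- f[sel] + overlap_len(wins$start[sel], wins$end[sel],
                                     red$start[i] - 1, red$end[i])
    }
    f / (wins$end - wins$start)
  }
  data.frame(wins, frac_duplicated = frac_of("duplication"),
             frac_deleted = -frac_of("deletion"))
}

#' Calibrate policies on labelled calls and re-filter
#'
#' The formalized version of the published threshold choice: generate
#' permissive candidate calls, label them against a truth/curation set,
#' run a ROC per type, pick the operating point with FPR at most
#' `max_fpr`, and keep the candidate calls that pass the chosen policy.
#'
#' @param stats window-stat data.frame.
#' @param truth truth SV data.frame.
#' @param strain strain label.
#' @param max_fpr admissible FPR for the operating point.
#' @param min_size minimum call size.
#' @param p_grid,fc_grid calibration grids.
#' @return list: `calls` (final), `policies`, `candidates` (labelled).
#' @export
calibrate_and_call <- function(stats, truth, strain = "test",
                               max_fpr = 0.05, min_size = 2000,
                               p_grid = 10^-c(2, 3, 5, 10, 15, 20, 30),
                               fc_grid = c(0.3, 0.5, 0.74, 1.01, 1.5, 2)) {
  out <- list(calls = NULL, policies = NULL, candidates = NULL)
  for (type in c("deletion", "duplication")) {
    sgn <- if (type == "deletion") -1 else 1
    loose <- threshold_policy(strain, type, sgn * min(abs(fc_grid)),
                              max(p_grid))
    cand <- merge_calls(apply_thresholds(stats, loose), type,
                        strain = strain, min_size = min_size)
    lab <- label_calls(cand, truth)
    if (!all(c("true_positive", "false_positive") %in% lab$label)) {
      # degenerate labelling: keep the loose policy
      pol <- loose
    } else {
      roc <- roc_curve(lab, p_grid, sgn * abs(fc_grid), sv_type = type)
      pol <- pick_operating_point(roc, max_fpr, strain, type)
    }
    keep <- lab$min_p < pol$p_cutoff &
      (if (type == "duplication") lab$mean_log2_fc >= pol$fc_cutoff
       else lab$mean_log2_fc <= pol$fc_cutoff)
    out$calls <- rbind(out$calls,
                       lab[keep, setdiff(names(lab), "label"), drop = FALSE])
    out$policies <- rbind(out$policies, pol)
    out$candidates <- rbind(out$candidates, lab)
  }
  out$calls <- out$calls[order(out$calls$contig, out$calls$start), ,
                         drop = FALSE]
  rownames(out$calls) <- NULL
  out
}

#' Recovery metrics of calls against a truth set
#'
#' @param calls final SV calls; `truth` planted truth.
#' @param truth truth SV data.frame.
#' @return data.frame per sv_type: tpr (truth intervals hit by a call of
#'   the same type) and fdr (calls hitting no truth interval).
#' @export
recovery_metrics <- function(calls, truth) {
  out <- lapply(c("deletion", "duplication"), function(type) {
    tr <- truth[truth$sv_type == type, , drop = FALSE]
    cl <- calls[calls$sv_type == type, , drop = FALSE]
    hit_truth <- vapply(seq_len(nrow(tr)), function(i)
      any(cl$contig == tr$contig[i] &
            overlap_len(cl$start, cl$end, tr$start[i], tr$end[i]) > 0),
      TRUE)
    call_tp <- vapply(seq_len(nrow(cl)), function(i)
      any(tr$contig == cl$contig[i] &
            overlap_len(tr$start, tr$end, cl$start[i], cl$end[i]) > 0),
      TRUE)
    data.frame(sv_type = type,
               n_truth = nrow(tr), n_calls = nrow(cl),
               tpr = if (nrow(tr)) mean(hit_truth) else NA_real_,
               fdr = if (nrow(cl)) mean(!call_tp) else NA_real_)
  })
  do.call(rbind, out)
}
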