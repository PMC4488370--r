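## Perfect collinearity between two genomes and SV polarization.
##
## The outgroup alignment regime of interest uses gap/mismatch penalties
## so high that any break ends an alignment, which reduces scored gene-
## order alignment to exact maximal-run detection: a block is a maximal
## run of ortholog pairs whose positions advance by +1 in both genomes
## (or by -1 throughout in genome B, for inversions).

#' Find perfectly collinear gene-order blocks
#'
#' @param order_A gene ids of genome A in genomic order.
#' @param order_B gene ids of genome B in genomic order.
#' @param ortholog_map named character vector mapping A ids to B ids
#'   (one-to-one over the genes considered; coverage-1 holds by
#'   construction since maximal runs partition the shared genes).
#' @param min_len minimum block length in genes (default 2).
#' @param allow_reversed count whole-run inversions as collinear
#'   (default TRUE).
#' @param genes_A optional gene-model data.frame for A; if given, each
#'   block gets a `span_A` attribute (contig, start of first gene, end of
#'   last gene).
#' @return list of blocks; each block is a data.frame with columns
#'   `gene_a`, `gene_b` and attributes `orientation` ("same"/"reversed")
#'   and, when `genes_A` is given, `span_A`.
#' @export
collinear_blocks <- function(order_A, order_B, ortholog_map, min_len = 2,
                             allow_reversed = TRUE, genes_A = NULL) {
  if (anyDuplicated(order_A)) stop("duplicate gene in order_A")
  if (anyDuplicated(order_B)) stop("duplicate gene in order_B")
  shared <- order_A[order_A %in% names(ortholog_map) &
                      ortholog_map[order_A] %in% order_B]
  if (length(shared) == 0) return(list())
  pos_B <- match(ortholog_map[shared], order_B)
  pos_A <- match(shared, order_A)  # a non-shared interposed gene breaks a run
  runs <- .maximal_runs(pos_B, pos_A)
  blocks <- lapply(runs, function(r) {
    if (!allow_reversed && r$orientation == "reversed") {
      # split a reversed run into its singleton pairs (none survive
      # min_len >= 2, matching the orientation-blind regime)
      return(lapply(r$idx, function(i) {
        b <- data.frame(gene_a = shared[i],
                        gene_b = unname(ortholog_map[shared[i]]))
        attr(b, "orientation") <- "same"
        b
      }))
    }
    b <- data.frame(gene_a = shared[r$idx],
                    gene_b = unname(ortholog_map[shared[r$idx]]))
    attr(b, "orientation") <- r$orientation
    list(b)
  })
  blocks <- unlist(blocks, recursive = FALSE)
  blocks <- Filter(function(b) nrow(b) >= min_len, blocks)
  if (!is.null(genes_A)) {
    blocks <- lapply(blocks, function(b) {
      g <- genes_A[match(b$gene_a, genes_A$gene_id), , drop = FALSE]
      attr(b, "span_A") <- data.frame(contig = g$contig[1],
                                      start = min(g$start),
                                      end = max(g$end))
      b
    })
  }
  blocks
}

#' Block spans as a BED-like data.frame
#' @param blocks output of [collinear_blocks()] run with `genes_A`.
#' @return data.frame contig, start, end, n_genes, orientation.
#' @export
block_spans <- function(blocks) {
  if (length(blocks) == 0)
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), n_genes = integer(),
                      orientation = character()))
  do.call(rbind, lapply(blocks, function(b) {
    sp <- attr(b, "span_A")
    if (is.null(sp)) stop("blocks carry no span_A; pass genes_A to ",
                          "collinear_blocks()")
    data.frame(sp, n_genes = nrow(b), orientation = attr(b, "orientation"))
  }))
}

#' Polarize SV calls by overlap with collinear blocks
#'
#' A call is polarized (interpretable as a derived event, the outgroup
#' carrying the ancestral state) if it overlaps the union of block spans
#' by at least `min_overlap` bases (default 1, the published "overlapped"
#' rule) or, if `min_overlap_frac > 0`, by that fraction of its length.
#'
#' @param calls SV call data.frame.
#' @param blocks list of blocks with `span_A` attributes, or a
#'   data.frame of spans from [block_spans()].
#' @param min_overlap minimum overlap in bases.
#' @param min_overlap_frac optional minimum overlap as fraction of call
#'   length (0 disables).
#' @return calls with the `polarized` flag set for every row.
#' @export
polarize_svs <- function(calls, blocks, min_overlap = 1,
                         min_overlap_frac = 0) {
  spans <- if (is.data.frame(blocks)) blocks else block_spans(blocks)
  ov <- numeric(nrow(calls))
  if (nrow(spans) > 0) {
    # overlap with the union: reduce spans first so shared bases are not
    # double counted
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      spans$contig, IRanges::IRanges(spans$start + 1, spans$end)))
    red <- as.data.frame(gr)
    for (i in seq_len(nrow(red)))
      ov <- ov + ifelse(calls$contig == red$seqnames[i],
                        overlap_len(calls$start, calls$end,
                                    red$start[i] - 1, red$end[i]), 0)
  }
  need <- pmax(min_overlap, min_overlap_frac * (calls$end - calls$start))
  calls$polarized <- ov >= need
  calls
}
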