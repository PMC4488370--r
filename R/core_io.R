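## Domain containers and readers/writers.
##
## Every container is a plain data.frame with a documented column contract
## (the data.table/limma style); constructors validate invariants once so
## downstream code can assume them.

#' Genome assembly backbone
#'
#' @param contig character vector of unique contig identifiers.
#' @param length integer vector of contig lengths in bases (> 0).
#' @return data.frame with columns `contig`, `length`.
#' @export
genome_assembly <- function(contig, length) {
  stopifnot(length(contig) == base::length(length))
  if (anyDuplicated(contig)) stop("contig ids must be unique")
  length <- as.numeric(length)
  if (any(length <= 0)) stop("contig lengths must be > 0")
  data.frame(contig = as.character(contig), length = length)
}

#' Gene model table
#'
#' One row per gene; the gene span runs from the first exon start to the
#' last exon end (introns included).  `exons` is a list-column of
#' two-column data.frames (`start`, `end`), 0-based half-open, sorted and
#' non-overlapping.
#'
#' @param gene_id,contig,start,end,strand vectors, one element per gene.
#' @param exons optional list of data.frames with `start`,`end`; defaults
#'   to a single exon spanning the whole gene.
#' @return validated data.frame of gene models.
#' @export
gene_models <- function(gene_id, contig, start, end, strand = "+",
                        exons = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("gene start must be < end")
  if (is.null(exons)) {
    exons <- Map(function(s, e) data.frame(start = s, end = e), start, end)
  }
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gm <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   start = start, end = end, strand = strand)
  gm$exons <- lapply(exons, function(ex) {
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    rownames(ex) <- NULL
    ex
  })
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  for (i in seq_len(nrow(gm))) {
    ex <- gm$exons[[i]]
    if (any(ex$start >= ex$end))
      stop("gene ", gm$gene_id[i], ": exon start must be < end")
    if (any(ex$start < gm$start[i]) || any(ex$end > gm$end[i]))
      stop("gene ", gm$gene_id[i], ": exon outside gene span")
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("gene ", gm$gene_id[i], ": exons overlap")
  }
  invisible(gm)
}

#' SV call table constructor
#'
#' @param contig,start,end call interval (0-based half-open).
#' @param sv_type "deletion" or "duplication".
#' @param strain strain label.
#' @param min_p smallest member-window p-value.
#' @param mean_log2_fc mean member-window log2 fold change.
#' @param polarized logical or NA (unknown).
#' @param min_size minimum call length in bases (default 2000).
#' @return validated data.frame of SV calls.
#' @export
sv_calls <- function(contig, start, end, sv_type, strain = "test",
                     min_p = NA_real_, mean_log2_fc = NA_real_,
                     polarized = NA, min_size = 2000) {
  if (!all(sv_type %in% c("deletion", "duplication")))
    stop("sv_type must be 'deletion' or 'duplication'")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end - start < min_size))
    stop("SV calls must span at least ", min_size, " bases")
  data.frame(contig = as.character(contig), start = start, end = end,
             sv_type = as.character(sv_type),
             strain = rep_len(as.character(strain), length(contig)),
             min_p = rep_len(as.numeric(min_p), length(contig)),
             mean_log2_fc = rep_len(as.numeric(mean_log2_fc), length(contig)),
             polarized = rep_len(as.logical(polarized), length(contig)))
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features and converts the GFF3 1-based closed
#' coordinates to the package's 0-based half-open convention.  Exons are
#' attached to genes by the `Parent`/`ID` attributes (transcript levels,
#' if present, are traversed); genes without annotated exons get a single
#' exon spanning the gene.
#'
#' @param path GFF3 file.
#' @return gene-model data.frame (see [gene_models()]).
#' @export
read_gff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0) {
    return(gene_models(character(), character(), numeric(), numeric())[0, ])
  }
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) return(gene_models(character(), character(),
                                           numeric(), numeric())[0, ])
  # map every feature to its ancestral gene id
  parent_of <- function(x) vapply(x, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]), "")
  df$parent <- parent_of(df$Parent)
  id2gene <- setNames(genes$ID, genes$ID)
  # one indirection level (gene -> mRNA -> exon) is enough for GFF3 here
  mids <- df$ID[!is.na(df$parent) & df$parent %in% genes$ID & df$type != "exon"]
  id2gene <- c(id2gene, setNames(
    df$parent[match(mids, df$ID)], mids))
  ex <- df[df$type == "exon", , drop = FALSE]
  ex$gene <- id2gene[ex$parent]
  exon_list <- lapply(genes$ID, function(g) {
    e <- ex[!is.na(ex$gene) & ex$gene == g, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    data.frame(start = e$start - 1, end = e$end)  # 1-closed -> 0-half-open
  })
  gm <- gene_models(
    gene_id = ifelse(is.na(genes$ID), paste0("gene", seq_len(nrow(genes))),
                     genes$ID),
    contig = as.character(genes$seqnames),
    start = genes$start - 1, end = genes$end,
    strand = ifelse(as.character(genes$strand) == "-", "-", "+"),
    exons = Map(function(e, s, en) if (is.null(e))
      data.frame(start = s, end = en) else e,
      exon_list, genes$start - 1, genes$end))
  gm
}

#' Read biallelic SNV sites from a VCF
#'
#' Keeps biallelic SNV records; multiallelic records are skipped with a
#' warning.  `site_quality` is the QUAL column and `het_support` the
#' FQ-like INFO field (samtools consensus quality); records without an FQ
#' field get `het_support = NA` and are excluded by the downstream site
#' filter.  Positions are converted to 0-based.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @return data.frame with columns contig, pos, allele_a, allele_b,
#'   site_quality, het_support.
#' @export
read_vcf_sites <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  empty <- data.frame(contig = character(), pos = numeric(),
                      allele_a = character(), allele_b = character(),
                      site_quality = numeric(), het_support = numeric())
  if (nrow(vcf) == 0) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  ref <- as.character(VariantAnnotation::ref(vcf))
  multi <- n_alt != 1
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) skipped")
  alt1 <- rep(NA_character_, nrow(vcf))
  alt1[!multi] <- as.character(unlist(alt[!multi]))
  snv <- !multi & nchar(ref) == 1 & nchar(alt1) == 1 &
    alt1 %in% c("A", "C", "G", "T")
  info <- VariantAnnotation::info(vcf)
  fq <- if ("FQ" %in% colnames(info)) as.numeric(info$FQ) else
    rep(NA_real_, nrow(vcf))
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1,
    allele_a = ref, allele_b = alt1,
    site_quality = as.numeric(rr$QUAL),
    het_support = fq)[snv, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SV calls as BED6
#'
#' Columns: contig, start, end, name = sv_type, score = -10*log10(min_p)
#' (phred style, capped at the BED maximum of 1000), strand ".".  A
#' header comment line records the column contract so empty files are
#' self-describing.
#'
#' @param calls SV call data.frame (see [sv_calls()]).
#' @param path output file.
#' @export
write_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#contig\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(calls) == 0) return(invisible(path))
  score <- -10 * log10(calls$min_p)
  score[!is.finite(score) | score > 1000] <- 1000
  score[is.na(calls$min_p)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.", calls$contig,
                   as.integer(calls$start), as.integer(calls$end),
                   calls$sv_type, score)
  writeLines(lines, con)
  invisible(path)
}

#' Read SV calls from a BED6 written by [write_bed()]
#' @param path BED file; `strain` strain label to attach.
#' @param strain strain label for the resulting calls.
#' @return SV call data.frame (min_p reconstructed from the score column).
#' @export
read_bed_calls <- function(path, strain = "test") {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("contig", "start", "end", "name",
                                "score", "strand"))
  if (nrow(d) == 0)
    return(sv_calls(character(), numeric(), numeric(), character())[0, ])
  sv_calls(d$contig, d$start, d$end, d$name, strain = strain,
           min_p = 10^(-d$score / 10))
}

#' Tabular readers/writers (TSV with header)
#'
#' Thin wrappers that fix `sep`/`quote`/`stringsAsFactors` once so every
#' table in the pipeline round-trips exactly.
#'
#' @param x data.frame; `path` file path.
#' @rdname tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv
#' @param path file path.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

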