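## Seeded synthetic-data generator with planted ground truth.
##
## Each simulate_* step draws from its own RNG stream (a fixed offset of
## the master seed) so adding or reordering steps never perturbs the
## others; a fixed seed gives byte-identical output everywhere.

#' Simulation configuration
#'
#' Defaults state the scenario the pipeline is built for: a 16X control
#' library against a 12X test library of 100 bp reads, deletions and
#' duplications of 2-75 kb, homozygous events only (copy factors 0 and 2;
#' the strains are inbred lines), and log-normal baseline expression.
#'
#' @param seed master RNG seed (integer).
#' @param genome_length total assembly length in bases.
#' @param n_contigs number of contigs the length is split over.
#' @param n_genes number of non-overlapping genes to place.
#' @param n_deletions,n_duplications number of planted SVs per type.
#' @param sv_size_range SV length range in bases.
#' @param depth_ref,depth_test mean read coverage of the control and the
#'   strain of interest.
#' @param read_length read length in bases (coverage-to-count constant).
#' @param window_size analysis window in bases.
#' @param dispersion negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson counts.
#' @param dup_expression_scenario "silent_copy" (one copy transcribed,
#'   FPKM unchanged) or "additive_dosage" (FPKM doubled).
#' @param bias_fraction fraction of duplicated genes whose minor copy is
#'   transcriptionally silent.
#' @param sites_per_dup_gene copy-segregating sites per duplicated gene.
#' @param dna_depth,rna_depth read depth at segregating sites.
#' @param n_rearrangements inversions/translocations applied to the
#'   outgroup gene order.
#' @param diversity_ratio median nucleotide-diversity ratio of SV-bearing
#'   to SV-free 100 kb windows.
#' @param expr_meanlog,expr_sdlog,expr_noise_sdlog log-normal baseline
#'   FPKM parameters and per-sample multiplicative noise (log scale).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e7,
                       n_contigs = 5L,
                       n_genes = 500L,
                       n_deletions = 50L,
                       n_duplications = 30L,
                       sv_size_range = c(2000, 75000),
                       depth_ref = 16,
                       depth_test = 12,
                       read_length = 100,
                       window_size = 2000,
                       dispersion = Inf,
                       dup_expression_scenario = c("silent_copy",
                                                   "additive_dosage"),
                       bias_fraction = 0.5,
                       sites_per_dup_gene = 5L,
                       dna_depth = 30L,
                       rna_depth = 30L,
                       n_rearrangements = 5L,
                       diversity_ratio = 10,
                       expr_meanlog = log(10),
                       expr_sdlog = 1.2,
                       expr_noise_sdlog = 0.15) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_contigs = as.integer(n_contigs), n_genes = as.integer(n_genes),
              n_deletions = as.integer(n_deletions),
              n_duplications = as.integer(n_duplications),
              sv_size_range = sv_size_range,
              depth_ref = depth_ref, depth_test = depth_test,
              read_length = read_length, window_size = window_size,
              dispersion = dispersion,
              dup_expression_scenario = match.arg(dup_expression_scenario),
              bias_fraction = bias_fraction,
              sites_per_dup_gene = as.integer(sites_per_dup_gene),
              dna_depth = as.integer(dna_depth),
              rna_depth = as.integer(rna_depth),
              n_rearrangements = as.integer(n_rearrangements),
              diversity_ratio = diversity_ratio,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              expr_noise_sdlog = expr_noise_sdlog)
  stopifnot(cfg$sv_size_range[1] >= 2000,
            cfg$sv_size_range[1] <= cfg$sv_size_range[2],
            cfg$bias_fraction >= 0, cfg$bias_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# component RNG streams: fixed offsets of the master seed (kept < 2^31)
.sim_seed <- function(cfg, component) {
  offsets <- c(genome = 11L, svs = 23L, counts = 37L, expr = 41L,
               sites = 53L, homology = 61L, orders = 71L, diversity = 83L)
  (cfg$seed %% 2000000000L) + offsets[[component]]
}

#' Simulate an assembly and non-overlapping gene models
#'
#' Genes of 1-10 exons are packed uniformly without overlap; infeasible
#' packings (too many genes for the genome) raise an error.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `assembly` (see [genome_assembly()]) and
#'   `genes` (see [gene_models()]).
#' @export
simulate_genome <- function(cfg) {
  withr::with_seed(.sim_seed(cfg, "genome"), {
    len <- rep(floor(cfg$genome_length / cfg$n_contigs), cfg$n_contigs)
    len[1] <- len[1] + cfg$genome_length - sum(len)
    asm <- genome_assembly(sprintf("contig%02d", seq_len(cfg$n_contigs)), len)
    if (cfg$n_genes == 0)
      return(list(assembly = asm,
                  genes = gene_models(character(), character(), numeric(),
                                      numeric())[0, ]))
    # allot genes to contigs proportional to length, then pack each contig
    n_per <- as.vector(table(factor(
      sample.int(cfg$n_contigs, cfg$n_genes, replace = TRUE,
                 prob = len / sum(len)), levels = seq_len(cfg$n_contigs))))
    gid <- 0L
    rows <- list()
    for (ci in seq_len(cfg$n_contigs)) {
      n <- n_per[ci]
      if (n == 0) next
      glen <- pmin(round(rlnorm(n, log(3000), 0.6)) + 200, 20000)
      gap_total <- len[ci] - sum(glen)
      if (gap_total < n + 1)
        stop("infeasible gene packing: too many genes for contig ", ci)
      gaps <- as.vector(stats::rmultinom(1, gap_total, rep(1, n + 1)))
      starts <- cumsum(c(0, glen)) [seq_len(n)] + cumsum(gaps[seq_len(n)])
      for (k in seq_len(n)) {
        gid <- gid + 1L
        s <- starts[k]; e <- s + glen[k]
        n_ex <- sample.int(10L, 1L)
        cuts <- sort(sample(seq(s + 1, e - 1), min(2 * n_ex - 2, e - s - 2)))
        # alternate exon/intron segments; guarantee >= 1 exon
        bounds <- unique(c(s, cuts, e))
        seg <- cbind(head(bounds, -1), tail(bounds, -1))
        take <- seq(1, nrow(seg), by = 2)
        rows[[gid]] <- list(gene_id = sprintf("g%04d", gid),
                            contig = asm$contig[ci], start = s, end = e,
                            strand = sample(c("+", "-"), 1),
                            exons = data.frame(start = seg[take, 1],
                                               end = seg[take, 2]))
      }
    }
    genes <- gene_models(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      contig = vapply(rows, `[[`, "", "contig"),
      start = vapply(rows, `[[`, 0, "start"),
      end = vapply(rows, `[[`, 0, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      exons = lapply(rows, `[[`, "exons"))
    list(assembly = asm, genes = genes)
  })
}

#' Plant non-overlapping deletions and duplications
#'
#' @param cfg a [sim_config()].
#' @param assembly genome assembly data.frame.
#' @return data.frame of truth SVs: contig, start, end, sv_type,
#'   copy_factor (0 for deletions, 2 for duplications).
#' @export
plant_svs <- function(cfg, assembly) {
  withr::with_seed(.sim_seed(cfg, "svs"), {
    n <- cfg$n_deletions + cfg$n_duplications
    if (n == 0)
      return(data.frame(contig = character(), start = numeric(),
                        end = numeric(), sv_type = character(),
                        copy_factor = numeric()))
    types <- c(rep("deletion", cfg$n_deletions),
               rep("duplication", cfg$n_duplications))
    placed <- data.frame(contig = character(), start = numeric(),
                         end = numeric())
    out <- vector("list", n)
    for (i in seq_len(n)) {
      size <- round(runif(1, cfg$sv_size_range[1], cfg$sv_size_range[2]))
      ok <- FALSE
      for (try in 1:1000) {
        ci <- sample.int(nrow(assembly), 1,
                         prob = assembly$length / sum(assembly$length))
        if (assembly$length[ci] < size) next
        s <- floor(runif(1, 0, assembly$length[ci] - size))
        same <- placed[placed$contig == assembly$contig[ci], , drop = FALSE]
        if (nrow(same) == 0 ||
            all(overlap_len(s, s + size, same$start, same$end) == 0)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place SV ", i, " without overlap; ",
                    "reduce the number or size of SVs")
      placed <- rbind(placed, data.frame(contig = assembly$contig[ci],
                                         start = s, end = s + size))
      out[[i]] <- data.frame(contig = assembly$contig[ci], start = s,
                             end = s + size, sv_type = types[i],
                             copy_factor = if (types[i] == "deletion") 0 else 2)
    }
    truth <- do.call(rbind, out)
    truth <- truth[order(truth$contig, truth$start), ]
    rownames(truth) <- NULL
    truth
  })
}

# length-weighted copy factor of a window given the truth set
.window_copy_factor <- function(contig, start, end, truth) {
  f <- rep(1, length(start))
  for (i in seq_len(nrow(truth))) {
    sel <- contig == truth$contig[i]
    if (!any(sel)) next
    ov <- overlap_len(start[sel], end[sel], truth$start[i], truth$end[i])
    f[sel] <- f[sel] + (truth$copy_factor[i] - 1) * ov / (end[sel] - start[sel])
  }
  f
}

#' Simulate per-window read counts
#'
#' Window counts are Poisson with mean `depth * window / read_length`,
#' scaled in the test sample by the local copy factor (0 inside
#' deletions, 2 inside duplications, length-weighted across breakpoints).
#' Setting `dispersion` to a finite value draws negative-binomial counts
#' instead (real coverage is overdispersed).
#'
#' @param cfg a [sim_config()]; `assembly` the assembly; `truth` planted
#'   SVs; `windows` optional window tiling (defaults to non-overlapping
#'   `window_size` tiles).
#' @param assembly genome assembly data.frame.
#' @param truth planted SV data.frame from [plant_svs()].
#' @param windows optional data.frame contig/start/end.
#' @return data.frame contig, start, end, count_ref, count_test.
#' @export
simulate_window_counts <- function(cfg, assembly, truth, windows = NULL) {
  if (is.null(windows))
    windows <- make_windows(assembly, cfg$window_size, cfg$window_size)
  withr::with_seed(.sim_seed(cfg, "counts"), {
    w <- windows$end - windows$start
    mu_ref <- cfg$depth_ref * w / cfg$read_length
    cf <- .window_copy_factor(windows$contig, windows$start, windows$end,
                              truth)
    mu_test <- cfg$depth_test * w / cfg$read_length * cf
    draw <- function(mu) {
      if (is.finite(cfg$dispersion))
        stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu)
      else rpois(length(mu), mu)
    }
    data.frame(contig = windows$contig, start = windows$start,
               end = windows$end,
               count_ref = draw(mu_ref), count_test = draw(mu_test))
  })
}

#' Simulate gene expression for two samples
#'
#' A shared log-normal baseline with independent multiplicative noise per
#' sample; genes fully inside deletions get test FPKM 0, genes fully
#' inside duplications are doubled under `additive_dosage` and unchanged
#' under `silent_copy`.
#'
#' @param cfg a [sim_config()].
#' @param genes gene-model data.frame.
#' @param truth planted SV data.frame.
#' @return data.frame gene_id, sample ("ref"/"test"), fpkm (long format).
#' @export
simulate_expression <- function(cfg, genes, truth) {
  withr::with_seed(.sim_seed(cfg, "expr"), {
    n <- nrow(genes)
    base <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    noise_ref <- rlnorm(n, 0, cfg$expr_noise_sdlog)
    noise_test <- rlnorm(n, 0, cfg$expr_noise_sdlog)
    status <- gene_truth_status(genes, truth)
    fpkm_ref <- base * noise_ref
    fpkm_test <- base * noise_test
    fpkm_test[status == "deleted"] <- 0
    if (cfg$dup_expression_scenario == "additive_dosage")
      fpkm_test[status == "duplicated"] <- 2 * fpkm_test[status == "duplicated"]
    rbind(data.frame(gene_id = genes$gene_id, sample = "ref",
                     fpkm = fpkm_ref),
          data.frame(gene_id = genes$gene_id, sample = "test",
                     fpkm = fpkm_test))
  })
}

#' Truth status of each gene (full containment in a planted SV)
#' @param genes gene-model data.frame; `truth` planted SVs.
#' @param truth planted SV data.frame.
#' @return character vector along `genes`: deleted/duplicated/unaffected.
#' @export
gene_truth_status <- function(genes, truth) {
  status <- rep("unaffected", nrow(genes))
  for (i in seq_len(nrow(truth))) {
    inside <- genes$contig == truth$contig[i] &
      genes$start >= truth$start[i] & genes$end <= truth$end[i]
    status[inside] <- if (truth$sv_type[i] == "deletion") "deleted"
                      else "duplicated"
  }
  status
}

#' Simulate copy-segregating sites of duplicated genes
#'
#' Each duplicated gene carries `sites_per_dup_gene` apparent
#' heterozygous sites.  DNA minor-allele counts are Binomial(depth, 0.5)
#' (the two collapsed copies contribute equally to genomic reads); RNA
#' counts are Binomial(depth, 0.5) for unbiased genes and Binomial(depth,
#' 0) — i.e. exactly zero — for the `bias_fraction` of genes whose minor
#' copy is silent.  Truth labels are attached.
#'
#' @param cfg a [sim_config()].
#' @param dup_genes gene-model data.frame of duplicated genes.
#' @return data.frame of sites: contig, pos, gene_id, allele_a, allele_b,
#'   dna_count_a/b, rna_count_a/b, site_quality, het_support, true_biased.
#' @export
simulate_segregating_sites <- function(cfg, dup_genes) {
  if (nrow(dup_genes) == 0 || cfg$sites_per_dup_gene == 0)
    return(data.frame(contig = character(), pos = numeric(),
                      gene_id = character(), allele_a = character(),
                      allele_b = character(), dna_count_a = integer(),
                      dna_count_b = integer(), rna_count_a = integer(),
                      rna_count_b = integer(), site_quality = numeric(),
                      het_support = numeric(), true_biased = logical()))
  withr::with_seed(.sim_seed(cfg, "sites"), {
    biased <- runif(nrow(dup_genes)) < cfg$bias_fraction
    per_gene <- lapply(seq_len(nrow(dup_genes)), function(i) {
      g <- dup_genes[i, ]
      m <- cfg$sites_per_dup_gene
      pos <- sort(sample(seq(g$start, g$end - 1), m))
      nts <- c("A", "C", "G", "T")
      aa <- sample(nts, m, replace = TRUE)
      ab <- vapply(aa, function(a) sample(setdiff(nts, a), 1), "")
      dna_b <- rbinom(m, cfg$dna_depth, 0.5)
      dna_a <- cfg$dna_depth - dna_b
      # the silent copy of a biased gene carries the genomic minor
      # allele (same identity rule as the analysis: smaller DNA count,
      # ties to the lexicographically smaller nucleotide)
      a_minor <- dna_a < dna_b | (dna_a == dna_b & aa < ab)
      rna_minor <- rbinom(m, cfg$rna_depth, if (biased[i]) 0 else 0.5)
      rna_a <- ifelse(a_minor, rna_minor, cfg$rna_depth - rna_minor)
      data.frame(contig = g$contig, pos = pos, gene_id = g$gene_id,
                 allele_a = aa, allele_b = ab,
                 dna_count_a = dna_a, dna_count_b = dna_b,
                 rna_count_a = rna_a, rna_count_b = cfg$rna_depth - rna_a,
                 site_quality = round(runif(m, 30, 60)),
                 het_support = round(runif(m, 5, 60)),
                 true_biased = biased[i])
    })
    out <- do.call(rbind, per_gene)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a two-species protein hit table with planted homology classes
#'
#' Focal-species genes are assigned one of five classes (one-to-one
#' ortholog, one-to-many singleton with homologs, conserved with
#' paralogs, orphan singleton, orphan with paralogs) and a hit table is
#' emitted whose reciprocal-best/inparalog structure realizes exactly
#' those classes.
#'
#' @param cfg a [sim_config()].
#' @param n_genes focal-species genes to simulate (default `cfg$n_genes`).
#' @param class_probs sampling weights of the five classes.
#' @param focal,other species labels.
#' @return list: `hits` (data.frame query_id, subject_id, query_species,
#'   subject_species, bitscore, evalue), `truth` (data.frame gene_id,
#'   class), `genes` (all focal gene ids).
#' @export
simulate_homology <- function(cfg, n_genes = cfg$n_genes,
                              class_probs = c(one_to_one = 0.3,
                                              singleton_with_homologs = 0.2,
                                              with_paralogs_conserved = 0.2,
                                              orphan_singleton = 0.15,
                                              orphan_with_paralogs = 0.15),
                              focal = "Ppa", other = "Cel") {
  withr::with_seed(.sim_seed(cfg, "homology"), {
    hits <- list(); truth <- list(); k <- 0L; bi <- 0L
    add_hit <- function(q, s, qs, ss, bits) {
      k <<- k + 1L
      hits[[k]] <<- data.frame(query_id = q, subject_id = s,
                               query_species = qs, subject_species = ss,
                               bitscore = bits, evalue = 10^-(bits / 10))
    }
    gid <- function(i) sprintf("%s_g%04d", focal, i)
    i <- 1L
    while (i <= n_genes) {
      cl <- sample(names(class_probs), 1, prob = class_probs)
      paired <- cl %in% c("with_paralogs_conserved", "orphan_with_paralogs")
      if (paired && i == n_genes)  # no room for a partner: fall back
        cl <- if (cl == "orphan_with_paralogs") "orphan_singleton"
              else "singleton_with_homologs"
      paired <- cl %in% c("with_paralogs_conserved", "orphan_with_paralogs")
      g <- gid(i)
      bi <- bi + 1L
      b <- sprintf("%s_g%04d", other, bi)
      if (cl == "one_to_one") {
        add_hit(g, b, focal, other, 200)
        add_hit(b, g, other, focal, 200)
      } else if (cl == "singleton_with_homologs") {
        # one-to-many: the subject has an inparalog scoring above its
        # best inter-species hit, so no one-to-one pair can be emitted
        b2 <- sprintf("%s_g%04d_ip", other, bi)
        add_hit(g, b, focal, other, 200)
        add_hit(b, g, other, focal, 200)
        add_hit(b, b2, other, other, 250)
        add_hit(b2, b, other, other, 250)
      } else if (cl == "with_paralogs_conserved") {
        g2 <- gid(i + 1L)
        add_hit(g, g2, focal, focal, 150)
        add_hit(g2, g, focal, focal, 150)
        add_hit(g, b, focal, other, 200)
        add_hit(b, g, other, focal, 200)
        add_hit(g2, b, focal, other, 195)
        add_hit(b, g2, other, focal, 195)
      } else if (cl == "orphan_with_paralogs") {
        g2 <- gid(i + 1L)
        add_hit(g, g2, focal, focal, 150)
        add_hit(g2, g, focal, focal, 150)
      } # orphan_singleton: no hits at all
      truth[[i]] <- data.frame(gene_id = g, class = cl)
      if (paired) {
        truth[[i + 1L]] <- data.frame(gene_id = gid(i + 1L), class = cl)
        i <- i + 2L
      } else i <- i + 1L
    }
    truth <- do.call(rbind, truth)
    hits <- if (k > 0) do.call(rbind, hits) else
      data.frame(query_id = character(), subject_id = character(),
                 query_species = character(), subject_species = character(),
                 bitscore = numeric(), evalue = numeric())
    rownames(truth) <- rownames(hits) <- NULL
    list(hits = hits, truth = truth, genes = truth$gene_id)
  })
}

#' Simulate a rearranged outgroup gene order with known collinear blocks
#'
#' Starts from the focal gene order, applies `n_rearrangements` random
#' inversions or translocations of contiguous runs, and reports the truth
#' blocks (maximal unbroken runs) alongside.
#'
#' @param cfg a [sim_config()].
#' @param genes gene-model data.frame sorted by position.
#' @return list: `order_A` and `order_B` (gene-id vectors), `ortholog_map`
#'   (named character vector A -> B ids), `truth_blocks` (list of
#'   data.frames with columns gene_a, gene_b, plus attr "orientation").
#' @export
simulate_gene_orders <- function(cfg, genes) {
  ord <- order(genes$contig, genes$start)
  order_A <- genes$gene_id[ord]
  n <- length(order_A)
  withr::with_seed(.sim_seed(cfg, "orders"), {
    perm <- seq_len(n)
    for (r in seq_len(cfg$n_rearrangements)) {
      if (n < 4) break
      i <- sort(sample.int(n, 2))
      if (i[2] - i[1] < 1) next
      if (runif(1) < 0.5) {
        perm[i[1]:i[2]] <- rev(perm[i[1]:i[2]])        # inversion
      } else {                                          # translocation
        block <- perm[i[1]:i[2]]
        rest <- perm[-(i[1]:i[2])]
        at <- sample.int(length(rest) + 1, 1) - 1
        perm <- append(rest, block, after = at)
      }
    }
    order_B <- paste0("B_", order_A[perm])
    ortholog_map <- setNames(paste0("B_", order_A), order_A)
    # truth blocks: maximal runs of consecutive A-indices in B order
    pos_in_B <- match(paste0("B_", order_A), order_B)
    truth_blocks <- .maximal_runs(pos_in_B)
    truth_blocks <- lapply(truth_blocks, function(b) {
      df <- data.frame(gene_a = order_A[b$idx],
                       gene_b = paste0("B_", order_A[b$idx]))
      attr(df, "orientation") <- b$orientation
      df
    })
    list(order_A = order_A, order_B = order_B,
         ortholog_map = ortholog_map, truth_blocks = truth_blocks)
  })
}

# maximal runs of ortholog pairs: genome-A indices advance by exactly +1
# while genome-B indices advance by +1 (same) or -1 (reversed) throughout
.maximal_runs <- function(pos_b, pos_a = seq_along(pos_b)) {
  n <- length(pos_b)
  if (n == 0) return(list())
  runs <- list(); start <- 1L; dir <- 0L
  flush <- function(s, e, d) {
    runs[[length(runs) + 1L]] <<- list(
      idx = s:e, orientation = if (d < 0) "reversed" else "same")
  }
  if (n == 1) { flush(1L, 1L, 0L); return(runs) }
  for (i in seq_len(n - 1)) {
    step_b <- pos_b[i + 1] - pos_b[i]
    contig_a <- pos_a[i + 1] - pos_a[i] == 1
    if (contig_a && abs(step_b) == 1 && (dir == 0L || step_b == dir)) {
      if (dir == 0L) dir <- step_b
      next
    }
    flush(start, i, dir); start <- i + 1L; dir <- 0L
  }
  flush(start, n, dir)
  runs
}

#' Simulate per-window nucleotide diversity stratified by SV overlap
#'
#' Windows overlapping any SV call draw pi from a log-normal whose median
#' is `diversity_ratio` times that of SV-free windows (background
#' selection keeps SV-free regions depauperate).
#'
#' @param cfg a [sim_config()].
#' @param windows data.frame contig/start/end (the 100 kb tiling).
#' @param calls SV call (or truth) data.frame with contig/start/end.
#' @return data.frame contig, start, end, pi, has_sv.
#' @export
simulate_diversity <- function(cfg, windows, calls) {
  withr::with_seed(.sim_seed(cfg, "diversity"), {
    has_sv <- rep(FALSE, nrow(windows))
    for (i in seq_len(nrow(calls))) {
      sel <- windows$contig == calls$contig[i] &
        overlap_len(windows$start, windows$end,
                    calls$start[i], calls$end[i]) > 0
      has_sv <- has_sv | sel
    }
    base_median <- 5e-4
    meanlog <- ifelse(has_sv, log(base_median * cfg$diversity_ratio),
                      log(base_median))
    data.frame(contig = windows$contig, start = windows$start,
               end = windows$end,
               pi = rlnorm(nrow(windows), meanlog, 0.5),
               has_sv = has_sv)
  })
}

#' Write a complete synthetic data set to disk
#'
#' Emits the same formats the readers consume (GFF3 genes, TSV counts and
#' expression, VCF-free site TSV, hits/domain TSVs) plus a
#' `truth.json` sidecar with every planted truth object.
#'
#' @param cfg a [sim_config()]; `dir` output directory.
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(cfg)
  truth <- plant_svs(cfg, gen$assembly)
  counts <- simulate_window_counts(cfg, gen$assembly, truth)
  expr <- simulate_expression(cfg, gen$genes, truth)
  status <- gene_truth_status(gen$genes, truth)
  dup_genes <- gen$genes[status == "duplicated", , drop = FALSE]
  sites <- simulate_segregating_sites(cfg, dup_genes)
  hom <- simulate_homology(cfg)
  orders <- simulate_gene_orders(cfg, gen$genes)
  write_tsv(gen$assembly, file.path(dir, "assembly.tsv"))
  write_gff(gen$genes, file.path(dir, "genes.gff3"))
  write_tsv(counts, file.path(dir, "window_counts.tsv"))
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(sites, file.path(dir, "sites.tsv"))
  write_tsv(hom$hits, file.path(dir, "hits.tsv"))
  jsonlite::write_json(
    list(svs = truth, gene_status = data.frame(gene_id = gen$genes$gene_id,
                                               status = status),
         homology = hom$truth),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  invisible(list(assembly = gen$assembly, genes = gen$genes, truth = truth,
                 counts = counts, expression = expr, sites = sites,
                 homology = hom, orders = orders))
}

#' Write gene models as GFF3
#' @param genes gene-model data.frame; `path` output file.
#' @param path output file.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start + 1, g$end, g$strand, g$gene_id), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$contig, ex$start[j] + 1, ex$end[j], g$strand,
                         g$gene_id, j, g$gene_id), con)
  }
  invisible(path)
}
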