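cfg_small <- sim_config(seed = 11, genome_length = 2e6, n_contigs = 2,
                        n_genes = 80, n_deletions = 6, n_duplications = 6,
                        sv_size_range = c(2000, 40000))

test_that("simulate_genome packs the requested genes without overlap, deterministically", {
  gen <- simulate_genome(cfg_small)
  g <- gen$genes
  expect_equal(nrow(g), 80)
  for (ct in unique(g$contig)) {
    s <- g[g$contig == ct, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  gen2 <- simulate_genome(cfg_small)
  expect_identical(gen$genes$start, gen2$genes$start)
  # n_genes = 0 gives an assembly with no genes
  empty <- simulate_genome(sim_config(seed = 1, genome_length = 1e5,
                                      n_contigs = 1, n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
})

test_that("plant_svs places disjoint >=2kb intervals of both types", {
  gen <- simulate_genome(cfg_small)
  truth <- plant_svs(cfg_small, gen$assembly)
  expect_equal(sum(truth$sv_type == "deletion"), 6)
  expect_equal(sum(truth$sv_type == "duplication"), 6)
  expect_true(all(truth$end - truth$start >= 2000))
  for (ct in unique(truth$contig)) {
    s <- truth[truth$contig == ct, ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # degenerate size range pins all lengths
  cfg1 <- sim_config(seed = 3, genome_length = 1e6, n_contigs = 1,
                     n_genes = 0, n_deletions = 10, n_duplications = 0,
                     sv_size_range = c(2000, 2000))
  tr1 <- plant_svs(cfg1, simulate_genome(cfg1)$assembly)
  expect_true(all(tr1$end - tr1$start == 2000))
  expect_identical(plant_svs(cfg_small, gen$assembly), truth)
})

test_that("window counts follow the planted copy factors", {
  # dedicated large single-deletion/duplication genome for tight means
  cfg <- sim_config(seed = 21, genome_length = 6e6, n_contigs = 1,
                    n_genes = 0, n_deletions = 1, n_duplications = 1,
                    sv_size_range = c(75000, 75000), window_size = 1000)
  gen <- simulate_genome(cfg)
  truth <- plant_svs(cfg, gen$assembly)
  cnt <- simulate_window_counts(cfg, gen$assembly, truth)
  cf <- svmicroevo:::.window_copy_factor(cnt$contig, cnt$start, cnt$end,
                                         truth)
  neutral <- cnt$count_test[cf == 1]
  inside_del <- cnt$count_test[cf == 0]
  inside_dup <- cnt$count_test[cf == 2]
  expect_gt(length(inside_del), 50)
  expect_gt(length(inside_dup), 50)
  expect_lt(mean(inside_del), 0.01 * mean(neutral))
  # duplication windows: sample mean within 3 SE of twice the neutral mean
  mu <- 2 * cfg$depth_test * cfg$window_size / cfg$read_length
  se <- sqrt(mu / length(inside_dup))
  expect_lt(abs(mean(inside_dup) - mu), 3 * se)
  # zero-depth test sample
  cfg0 <- sim_config(seed = 21, genome_length = 1e5, n_contigs = 1,
                     n_genes = 0, n_deletions = 0, n_duplications = 0,
                     depth_test = 0)
  cnt0 <- simulate_window_counts(cfg0, simulate_genome(cfg0)$assembly,
                                 plant_svs(cfg0, simulate_genome(cfg0)$assembly))
  expect_true(all(cnt0$count_test == 0))
})

test_that("breakpoint-straddling windows get the length-weighted factor", {
  truth <- data.frame(contig = "c", start = 1000, end = 3000,
                      sv_type = "duplication", copy_factor = 2)
  f <- svmicroevo:::.window_copy_factor("c", 500, 1500, truth)
  expect_equal(f, 1 + 0.5)  # half inside a x2 interval
  f0 <- svmicroevo:::.window_copy_factor("c", 3000, 4000, truth)
  expect_equal(f0, 1)
})

test_that("expression honours deletion zeroing and the duplication scenarios", {
  gen <- simulate_genome(cfg_small)
  truth <- plant_svs(cfg_small, gen$assembly)
  status <- gene_truth_status(gen$genes, truth)
  expr_sc <- simulate_expression(cfg_small, gen$genes, truth)
  test_fpkm <- expr_sc$fpkm[expr_sc$sample == "test"]
  expect_true(all(test_fpkm[status == "deleted"] == 0))
  # additive dosage doubles duplicated genes: median log2 ratio near 1
  cfg_ad <- sim_config(seed = 31, genome_length = 4e6, n_contigs = 1,
                       n_genes = 400, n_deletions = 0, n_duplications = 25,
                       sv_size_range = c(30000, 75000),
                       dup_expression_scenario = "additive_dosage")
  gen2 <- simulate_genome(cfg_ad)
  tr2 <- plant_svs(cfg_ad, gen2$assembly)
  st2 <- gene_truth_status(gen2$genes, tr2)
  expect_gt(sum(st2 == "duplicated"), 30)
  e2 <- simulate_expression(cfg_ad, gen2$genes, tr2)
  r <- e2$fpkm[e2$sample == "test"] / e2$fpkm[e2$sample == "ref"]
  expect_lt(abs(median(log2(r[st2 == "duplicated"])) - 1), 0.2)
  expect_lt(abs(median(log2(r[st2 == "unaffected"]))), 0.2)
  # silent copy leaves duplicated genes at baseline
  e3 <- simulate_expression(cfg_ad2 <- sim_config(
    seed = 31, genome_length = 4e6, n_contigs = 1, n_genes = 400,
    n_deletions = 0, n_duplications = 25,
    sv_size_range = c(30000, 75000)), gen2$genes, tr2)
  r3 <- e3$fpkm[e3$sample == "test"] / e3$fpkm[e3$sample == "ref"]
  expect_lt(abs(median(log2(r3[st2 == "duplicated"]))), 0.2)
})

test_that("segregating sites realize the stated binomial model", {
  cfg <- sim_config(seed = 41, genome_length = 2e6, n_contigs = 1,
                    n_genes = 400, n_deletions = 0, n_duplications = 0,
                    bias_fraction = 0, sites_per_dup_gene = 5,
                    dna_depth = 50, rna_depth = 50)
  gen <- simulate_genome(cfg)
  sites <- simulate_segregating_sites(cfg, gen$genes)
  expect_equal(nrow(sites), 400 * 5)
  fr <- minor_allele_freqs(sites)
  # folded-binomial mean: 0.5 - E|X/n - 0.5| for X ~ Bin(50, .5)
  x <- 0:50
  folded_mean <- sum(pmin(x, 50 - x) / 50 * dbinom(x, 50, 0.5))
  se <- sd(fr$dna_freq) / sqrt(nrow(sites))
  expect_lt(abs(mean(fr$dna_freq) - folded_mean), 3 * se)
  # biased genes have RNA minor counts exactly 0
  cfg_b <- sim_config(seed = 41, genome_length = 2e6, n_contigs = 1,
                      n_genes = 50, n_deletions = 0, n_duplications = 0,
                      bias_fraction = 1, sites_per_dup_gene = 4)
  sb <- simulate_segregating_sites(cfg_b, simulate_genome(cfg_b)$genes)
  frb <- minor_allele_freqs(sb)
  expect_true(all(frb$rna_freq == 0))
  # no sites requested -> empty
  cfg0 <- sim_config(seed = 1, sites_per_dup_gene = 0)
  expect_equal(nrow(simulate_segregating_sites(cfg0, gen$genes)), 0)
})

test_that("simulated hit tables realize the planted homology structure", {
  cfg <- sim_config(seed = 51)
  hom <- simulate_homology(cfg, n_genes = 60)
  # planted one-to-one pairs are reciprocal best hits with no intra hits
  o2o <- hom$truth$gene_id[hom$truth$class == "one_to_one"]
  for (g in head(o2o, 3)) {
    mine <- hom$hits[hom$hits$query_id == g, ]
    expect_equal(nrow(mine), 1)
    expect_equal(mine$subject_species, "Cel")
  }
  orphans <- hom$truth$gene_id[hom$truth$class == "orphan_singleton"]
  expect_false(any(hom$hits$query_id %in% orphans |
                     hom$hits$subject_id %in% orphans))
  expect_identical(simulate_homology(cfg, n_genes = 60)$hits, hom$hits)
})

test_that("gene orders: no rearrangement gives one block, an interior inversion three", {
  cfg0 <- sim_config(seed = 61, genome_length = 1e6, n_contigs = 1,
                     n_genes = 30, n_deletions = 0, n_duplications = 0,
                     n_rearrangements = 0)
  gen <- simulate_genome(cfg0)
  ord <- simulate_gene_orders(cfg0, gen$genes)
  expect_equal(length(ord$truth_blocks), 1)
  expect_equal(nrow(ord$truth_blocks[[1]]), 30)
  # hand-built interior inversion via the run finder used by the simulator
  runs <- svmicroevo:::.maximal_runs(c(1, 2, 5, 4, 3, 6, 7))
  expect_equal(length(runs), 3)
  expect_equal(runs[[2]]$orientation, "reversed")
  expect_identical(simulate_gene_orders(cfg0, gen$genes)$order_B,
                   ord$order_B)
})

test_that("diversity medians scale by the configured ratio", {
  cfg <- sim_config(seed = 71, genome_length = 1e7, n_contigs = 1)
  wins <- make_windows(genome_assembly("c1", 4e7), 1e5, 1e5)
  calls <- data.frame(contig = "c1",
                      start = seq(0, 2e7 - 1, by = 1e5)[1:200],
                      end = seq(0, 2e7 - 1, by = 1e5)[1:200] + 5e4)
  div <- simulate_diversity(cfg, wins, calls)
  expect_gte(sum(div$has_sv), 200)
  expect_gte(sum(!div$has_sv), 200)
  ratio <- median(div$pi[div$has_sv]) / median(div$pi[!div$has_sv])
  expect_lt(abs(ratio - 10) / 10, 0.2)
  # no calls -> everything in the "without" group
  div0 <- simulate_diversity(cfg, wins, calls[0, ])
  expect_false(any(div0$has_sv))
})

test_that("simulate_dataset writes a consistent set of text files", {
  dir <- file.path(tempdir(), "simds")
  cfg <- sim_config(seed = 81, genome_length = 1e6, n_contigs = 1,
                    n_genes = 40, n_deletions = 3, n_duplications = 3,
                    sv_size_range = c(2000, 30000))
  ds <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "assembly.tsv", "genes.gff3", "window_counts.tsv", "expression.tsv",
    "sites.tsv", "hits.tsv", "truth.json")))))
  cnt <- read_tsv(file.path(dir, "window_counts.tsv"))
  expect_identical(cnt$count_ref, ds$counts$count_ref)
  genes_back <- read_gff(file.path(dir, "genes.gff3"))
  expect_setequal(genes_back$gene_id, ds$genes$gene_id)
})
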