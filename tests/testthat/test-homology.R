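hit <- function(q, s, qs, ss, bits, ev = 1e-20)
  data.frame(query_id = q, subject_id = s, query_species = qs,
             subject_species = ss, bitscore = bits, evalue = ev)

test_that("build_hit_graph filters by e-value and collapses redundant pairs", {
  hits <- rbind(hit("a1", "b1", "A", "B", 80),
                hit("b1", "a1", "B", "A", 95),
                hit("a1", "a2", "A", "A", 50, ev = 0.01),  # above cutoff
                hit("a1", "a1", "A", "A", 500))            # self hit
  g <- build_hit_graph(hits, genes = data.frame(
    gene_id = c("a1", "a2", "b1"), species = c("A", "A", "B")))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 95)
  expect_equal(igraph::vcount(g), 3)  # a2 kept as isolated vertex
  g0 <- build_hit_graph(hits[0, ], genes = data.frame(
    gene_id = c("x", "y"), species = "A"))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 2)
})

test_that("find_inparalogs applies the intra >= best-inter rule", {
  hits <- rbind(hit("a1", "b1", "A", "B", 100),
                hit("a2", "b1", "A", "B", 90),
                hit("a1", "a2", "A", "A", 95))
  g <- build_hit_graph(hits)
  ip <- find_inparalogs(g, c("A", "B"))
  expect_equal(ip[["a2"]], "a1")  # 95 >= min(100, 90)
  expect_equal(ip[["a1"]], "a2")  # the relation is symmetric
  # strict mode demands > at equality of intra and best-inter scores
  hits2 <- rbind(hit("a1", "b1", "A", "B", 95),
                 hit("a2", "b1", "A", "B", 95),
                 hit("a1", "a2", "A", "A", 95))
  ip2 <- find_inparalogs(build_hit_graph(hits2), c("A", "B"))
  expect_equal(ip2[["a1"]], "a2")
  ip2s <- find_inparalogs(build_hit_graph(hits2), c("A", "B"),
                          strict = TRUE)
  expect_null(ip2s[["a1"]])
  # no inter-species hit: s = -Inf, every intra partner qualifies
  hits3 <- hit("a1", "a2", "A", "A", 40)
  ip3 <- find_inparalogs(build_hit_graph(hits3), c("A", "B"))
  expect_equal(ip3[["a1"]], "a2")
  expect_equal(ip3[["a2"]], "a1")
})

test_that("one_to_one_orthologs demands unique reciprocal bests and no inparalogs", {
  clean <- rbind(hit("a1", "b1", "A", "B", 100))
  expect_equal(one_to_one_orthologs(build_hit_graph(clean), c("A", "B")),
               data.frame(gene_a = "a1", gene_b = "b1"))
  # inparalog on the A side blocks the pair
  blocked <- rbind(hit("a1", "b1", "A", "B", 100),
                   hit("a2", "b1", "A", "B", 90),
                   hit("a1", "a2", "A", "A", 95))
  expect_equal(nrow(one_to_one_orthologs(build_hit_graph(blocked),
                                         c("A", "B"))), 0)
  # bitscore tie for the top hit breaks reciprocity
  tie <- rbind(hit("a1", "b1", "A", "B", 100),
               hit("a1", "b2", "A", "B", 100))
  expect_equal(nrow(one_to_one_orthologs(build_hit_graph(tie),
                                         c("A", "B"))), 0)
})

test_that("classify_genes covers the five classes and partitions the gene set", {
  hits <- rbind(
    hit("one1", "cel1", "Ppa", "Cel", 200),
    hit("cel1", "one1", "Cel", "Ppa", 200),
    hit("par1", "par2", "Ppa", "Ppa", 150),
    hit("par1", "cel2", "Ppa", "Cel", 200),
    hit("par2", "cel2", "Ppa", "Cel", 195),
    hit("orp1", "orp2", "Ppa", "Ppa", 120))
  genes <- data.frame(gene_id = c("one1", "par1", "par2", "orp1", "orp2",
                                  "lone", "cel1", "cel2"),
                      species = c(rep("Ppa", 6), "Cel", "Cel"))
  cls <- classify_homology(hits, genes, "Ppa", "Cel")
  got <- setNames(cls$class, cls$gene_id)
  expect_equal(unname(got["one1"]), "one_to_one")
  expect_equal(unname(got["par1"]), "with_paralogs_conserved")
  expect_equal(unname(got["par2"]), "with_paralogs_conserved")
  expect_equal(unname(got["orp1"]), "orphan_with_paralogs")
  expect_equal(unname(got["orp2"]), "orphan_with_paralogs")
  expect_equal(unname(got["lone"]), "orphan_singleton")
  expect_equal(sum(is.na(got)), 0)
  expect_equal(nrow(cls), 6)  # every focal gene classified exactly once
})

test_that("classifier agrees with brute-force rule application on random graphs", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      n_a <- sample(3:25, 1); n_b <- sample(2:25, 1)
      genes <- data.frame(
        gene_id = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
        species = c(rep("A", n_a), rep("B", n_b)))
      n_hit <- sample(0:40, 1)
      if (n_hit == 0) {
        hits <- hit("x", "y", "A", "B", 1)[0, ]
      } else {
        qi <- sample(genes$gene_id, n_hit, replace = TRUE)
        si <- sample(genes$gene_id, n_hit, replace = TRUE)
        hits <- data.frame(
          query_id = qi, subject_id = si,
          query_species = genes$species[match(qi, genes$gene_id)],
          subject_species = genes$species[match(si, genes$gene_id)],
          bitscore = sample(10:100, n_hit, replace = TRUE),
          evalue = 10^-sample(4:30, n_hit, replace = TRUE))
        hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
      }
      got <- classify_homology(hits, genes, "A", "B")
      want <- oracle_classify(hits, genes, "A", "B")
      expect_equal(setNames(got$class, got$gene_id)[names(want)], want,
                   info = paste("replicate", rep))
    }
  })
})

test_that("planted classes are recovered exactly and row order does not matter", {
  cfg <- sim_config(seed = 91)
  hom <- simulate_homology(cfg, n_genes = 500)
  genes <- data.frame(gene_id = hom$genes, species = "Ppa")
  cls <- classify_homology(hom$hits, genes, "Ppa", "Cel")
  expect_equal(setNames(cls$class, cls$gene_id)[hom$truth$gene_id],
               setNames(hom$truth$class, hom$truth$gene_id))
  # permute hit rows
  withr::with_seed(5, shuf <- hom$hits[sample.int(nrow(hom$hits)), ])
  cls2 <- classify_homology(shuf, genes, "Ppa", "Cel")
  expect_equal(cls2[order(cls2$gene_id), ], cls[order(cls$gene_id), ],
               ignore_attr = TRUE)
})
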