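## Homology classification from protein hit tables.
##
## Five exhaustive, mutually exclusive classes over the focal species:
## one-to-one orthologs with the designated ortholog species (reciprocal
## best hits without inparalogs), one-to-many ("singleton with
## homologs"), many-to-X ("with paralogs, conserved"), orphan singletons
## and orphans with paralogs.  "Best" and "more closely related" are
## ordered by bitscore, which does not saturate the way e-values do.

#' Build the hit graph
#'
#' Undirected weighted graph over all genes; hits with
#' `evalue < max_evalue` become edges with weight the maximum bitscore
#' over redundant pairs (A-B and B-A records collapse to one edge).
#' Self-hits are dropped.
#'
#' @param hits data.frame query_id, subject_id, query_species,
#'   subject_species, bitscore, evalue.
#' @param genes optional data.frame gene_id, species for vertices with
#'   no hits (isolated genes must exist in the graph to be classified).
#' @param max_evalue e-value cutoff (default 0.001, exclusive).
#' @return igraph object with vertex attribute `species` and edge
#'   attribute `weight`.
#' @export
build_hit_graph <- function(hits, genes = NULL, max_evalue = 0.001) {
  hits <- hits[hits$evalue < max_evalue &
                 hits$query_id != hits$subject_id, , drop = FALSE]
  verts <- unique(rbind(
    data.frame(gene_id = hits$query_id, species = hits$query_species),
    data.frame(gene_id = hits$subject_id, species = hits$subject_species),
    if (!is.null(genes)) genes[, c("gene_id", "species")]))
  verts <- verts[!duplicated(verts$gene_id), , drop = FALSE]
  if (nrow(hits) == 0) {
    g <- igraph::make_empty_graph(n = nrow(verts), directed = FALSE)
    igraph::V(g)$name <- verts$gene_id
    igraph::V(g)$species <- verts$species
    return(g)
  }
  # collapse redundant pairs to the max bitscore
  key <- ifelse(hits$query_id < hits$subject_id,
                paste(hits$query_id, hits$subject_id),
                paste(hits$subject_id, hits$query_id))
  w <- tapply(hits$bitscore, key, max)
  ends <- do.call(rbind, strsplit(names(w), " ", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1], to = ends[, 2], weight = as.numeric(w)),
    directed = FALSE, vertices = verts)
  g
}

# best (maximum) edge weight from each vertex into a vertex subset;
# -Inf where there is no such edge
.best_weight_to <- function(g, into) {
  out <- setNames(rep(-Inf, igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::ecount(g) == 0) return(out)
  el <- igraph::as_data_frame(g, what = "edges")
  for (side in 1:2) {
    from <- el[[side]]; to <- el[[3 - side]]
    sel <- to %in% into
    if (any(sel)) {
      mx <- tapply(el$weight[sel], from[sel], max)
      out[names(mx)] <- pmax(out[names(mx)], mx)
    }
  }
  out
}

#' Find inparalogs within a species pair
#'
#' An intra-species pair (g, h) is an inparalog pair when its bitscore
#' reaches either member's best inter-species bitscore, i.e.
#' `weight(g,h) >= min(s(g), s(h))` — the two genes are then more closely
#' related to each other than at least one of them is to anything in the
#' other species (permissive `>=` reading; `strict = TRUE` uses `>`).
#' Genes with no inter-species hit have s = -Inf, so all their intra
#' partners qualify.
#'
#' @param graph hit graph from [build_hit_graph()].
#' @param species_pair character vector of the two species.
#' @param strict require strictly greater intra-species weight.
#' @return named list mapping gene_id to character vector of inparalogs
#'   (only genes with at least one inparalog appear).
#' @export
find_inparalogs <- function(graph, species_pair, strict = FALSE) {
  sp <- igraph::V(graph)$species
  names(sp) <- igraph::V(graph)$name
  in_pair <- names(sp)[sp %in% species_pair]
  best_inter <- lapply(species_pair, function(s)
    .best_weight_to(graph, into = names(sp)[sp == s]))
  names(best_inter) <- species_pair
  s_of <- function(gene) {
    other <- setdiff(species_pair, sp[gene])
    best_inter[[other]][gene]
  }
  res <- list()
  if (igraph::ecount(graph) == 0) return(res)
  el <- igraph::as_data_frame(graph, what = "edges")
  intra <- el[sp[el$from] == sp[el$to] & sp[el$from] %in% species_pair, ,
              drop = FALSE]
  cmp <- if (strict) `>` else `>=`
  for (i in seq_len(nrow(intra))) {
    a <- intra$from[i]; b <- intra$to[i]; w <- intra$weight[i]
    if (cmp(w, min(s_of(a), s_of(b)))) {
      res[[a]] <- c(res[[a]], b)
      res[[b]] <- c(res[[b]], a)
    }
  }
  res
}

#' One-to-one orthologs between a species pair
#'
#' Pairs (a, b) such that b is a's unique best inter-species hit and vice
#' versa (a bitscore tie for either top hit breaks reciprocity — no pair)
#' and neither member has an inparalog.
#'
#' @param graph hit graph.
#' @param species_pair the two species (first is the focal side of the
#'   returned data.frame).
#' @param strict passed to [find_inparalogs()].
#' @return data.frame gene_a, gene_b.
#' @export
one_to_one_orthologs <- function(graph, species_pair, strict = FALSE) {
  empty <- data.frame(gene_a = character(), gene_b = character())
  if (igraph::ecount(graph) == 0) return(empty)
  sp <- igraph::V(graph)$species
  names(sp) <- igraph::V(graph)$name
  el <- igraph::as_data_frame(graph, what = "edges")
  inter <- el[sp[el$from] %in% species_pair & sp[el$to] %in% species_pair &
                sp[el$from] != sp[el$to], , drop = FALSE]
  if (nrow(inter) == 0) return(empty)
  # orient: a = species_pair[1]
  a <- ifelse(sp[inter$from] == species_pair[1], inter$from, inter$to)
  b <- ifelse(sp[inter$from] == species_pair[1], inter$to, inter$from)
  inter <- data.frame(a = a, b = b, weight = inter$weight)
  top_unique <- function(from, to, w) {
    # unique best partner of each `from` gene; NA on ties
    vapply(split(seq_along(from), from), function(idx) {
      mx <- max(w[idx])
      best <- to[idx][w[idx] == mx]
      if (length(best) == 1) best else NA_character_
    }, "")
  }
  best_a <- top_unique(inter$a, inter$b, inter$weight)
  best_b <- top_unique(inter$b, inter$a, inter$weight)
  ip <- find_inparalogs(graph, species_pair, strict = strict)
  cand <- names(best_a)[!is.na(best_a)]
  keep <- vapply(cand, function(g) {
    partner <- best_a[[g]]
    !is.na(best_b[partner] %||% NA_character_) &&
      identical(unname(best_b[[partner]]), g) &&
      is.null(ip[[g]]) && is.null(ip[[partner]])
  }, TRUE)
  out <- data.frame(gene_a = cand[keep],
                    gene_b = unname(best_a[cand[keep]]))
  rownames(out) <- NULL
  out
}

#' Classify focal-species genes into homology classes
#'
#' Focal genes with any above-threshold hit to another species are
#' "conserved", otherwise "orphan".  Connected components of the
#' intra-focal subgraph split each group into "with paralogs" (component
#' size > 1) and singletons; conserved singletons that are one-to-one
#' pairs with the ortholog species become `one_to_one`, the remaining
#' conserved singletons `singleton_with_homologs`.
#'
#' @param graph hit graph containing all focal genes (isolated vertices
#'   included; pass `genes` to [build_hit_graph()]).
#' @param pairs one-to-one pair data.frame from [one_to_one_orthologs()].
#' @param focal_species focal species label.
#' @return data.frame gene_id, class.
#' @export
classify_genes <- function(graph, pairs, focal_species) {
  sp <- igraph::V(graph)$species
  names(sp) <- igraph::V(graph)$name
  focal <- names(sp)[sp == focal_species]
  conserved <- setNames(rep(FALSE, length(focal)), focal)
  comp_size <- setNames(rep(1L, length(focal)), focal)
  if (igraph::ecount(graph) > 0) {
    el <- igraph::as_data_frame(graph, what = "edges")
    inter <- el[xor(sp[el$from] == focal_species,
                    sp[el$to] == focal_species), , drop = FALSE]
    hit_out <- unique(c(inter$from[sp[inter$from] == focal_species],
                        inter$to[sp[inter$to] == focal_species]))
    conserved[hit_out] <- TRUE
    # the induced focal subgraph keeps exactly the intra-focal edges
    sub <- igraph::induced_subgraph(graph, focal)
    comp <- igraph::components(sub)
    comp_size[igraph::V(sub)$name] <- comp$csize[comp$membership]
  }
  is_121 <- focal %in% pairs$gene_a
  cls <- ifelse(conserved,
                ifelse(comp_size > 1, "with_paralogs_conserved",
                       ifelse(is_121, "one_to_one",
                              "singleton_with_homologs")),
                ifelse(comp_size > 1, "orphan_with_paralogs",
                       "orphan_singleton"))
  data.frame(gene_id = focal, class = unname(cls))
}

#' Full homology classification from a hit table
#'
#' @param hits hit data.frame; `genes` data.frame gene_id, species
#'   covering all focal genes; `focal_species`, `ortholog_species`
#'   labels; `max_evalue` e-value cutoff; `strict` inparalog comparison.
#' @param genes data.frame gene_id, species (all genes incl. hitless).
#' @param focal_species focal species label.
#' @param ortholog_species designated one-to-one partner species.
#' @param max_evalue hit e-value cutoff.
#' @param strict strict inparalog comparison.
#' @return data.frame gene_id, class.
#' @export
classify_homology <- function(hits, genes, focal_species,
                              ortholog_species, max_evalue = 0.001,
                              strict = FALSE) {
  g <- build_hit_graph(hits, genes = genes, max_evalue = max_evalue)
  pairs <- one_to_one_orthologs(g, c(focal_species, ortholog_species),
                                strict = strict)
  classify_genes(g, pairs, focal_species)
}
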