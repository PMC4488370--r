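# Independent oracles used across test files.  Each is a deliberately
# naive, brute-force formulation kept separate from the package's code
# paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..m as a list of integer vectors
combinat_perms <- function(m) {
  if (m == 1) return(list(1L))
  sub <- combinat_perms(m - 1)
  out <- list()
  for (p in sub) for (i in 0:(m - 1))
    out[[length(out) + 1]] <- append(p, m, after = i)
  out
}

# two-sided minimum-likelihood binomial p by exhaustive enumeration
oracle_binom_p <- function(k, n, q) {
  d <- dbinom(0:n, n, q)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# maximal collinear runs by exhaustive enumeration: every interval [i,j]
# with a constant +1/-1 step that cannot be extended on either side.
# In a permutation such runs are pairwise disjoint, so together with the
# uncovered singletons they partition the positions.
oracle_runs <- function(order_A, order_B) {
  m <- length(order_A)
  pos <- match(order_A, order_B)
  valid <- function(i, j, dir) all(diff(pos[i:j]) == dir)
  runs <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) for (dir in c(1, -1)) {
    if (j <= i) next
    if (!valid(i, j, dir)) next
    if (i > 1 && valid(i - 1, j, dir)) next
    if (j < m && valid(i, j + 1, dir)) next
    runs[[length(runs) + 1]] <- i:j
  }
  covered <- unlist(runs)
  for (i in setdiff(seq_len(m), covered))
    runs[[length(runs) + 1]] <- i
  runs[order(vapply(runs, min, 0))]
}

# exact two-sided (doubled-tail) rank-sum p over all subset assignments
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(combn(length(r), m), 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# upper-tail hypergeometric by direct summation of the pmf (log scale to
# survive large N)
oracle_hyper_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  j <- j[n - j <= N - K]
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# brute-force homology classification by direct rule application on a
# hit table (no graph library)
oracle_classify <- function(hits, genes, focal, ortho, max_evalue = 0.001) {
  h <- hits[hits$evalue < max_evalue & hits$query_id != hits$subject_id, ]
  # symmetric max-bitscore weight table
  pair_w <- new.env(parent = emptyenv())
  pkey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (i in seq_len(nrow(h))) {
    k <- pkey(h$query_id[i], h$subject_id[i])
    pair_w[[k]] <- max(pair_w[[k]] %||% -Inf, h$bitscore[i])
  }
  sp <- setNames(genes$species, genes$gene_id)
  W <- function(a, b) pair_w[[pkey(a, b)]] %||% -Inf
  ids <- genes$gene_id
  neighbors <- function(g) unique(c(
    h$subject_id[h$query_id == g], h$query_id[h$subject_id == g]))
  best_to <- function(g, species) {
    cand <- ids[sp[ids] == species & ids != g]
    w <- vapply(cand, function(x) W(g, x), 0)
    if (!any(is.finite(w))) return(NULL)
    mx <- max(w)
    list(score = mx, genes = cand[w == mx])
  }
  has_inpara <- function(g, other_species) {
    bg <- best_to(g, other_species)
    sg <- if (is.null(bg)) -Inf else bg$score
    intra <- ids[sp[ids] == sp[g] & ids != g]
    any(vapply(intra, function(x) {
      w <- W(g, x)
      if (!is.finite(w)) return(FALSE)
      bx <- best_to(x, other_species)
      sx <- if (is.null(bx)) -Inf else bx$score
      w >= min(sg, sx)
    }, TRUE))
  }
  one21 <- character(0)
  for (g in ids[sp[ids] == focal]) {
    bg <- best_to(g, ortho)
    if (is.null(bg) || length(bg$genes) != 1) next
    b <- bg$genes
    bb <- best_to(b, focal)
    if (is.null(bb) || length(bb$genes) != 1 || bb$genes != g) next
    if (has_inpara(g, ortho) || has_inpara(b, focal)) next
    one21 <- c(one21, g)
  }
  # connected components of intra-focal hits
  focal_ids <- ids[sp[ids] == focal]
  comp <- setNames(seq_along(focal_ids), focal_ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(h))) {
      a <- h$query_id[i]; b <- h$subject_id[i]
      if (a %in% focal_ids && b %in% focal_ids && comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  csize <- table(comp)
  vapply(focal_ids, function(g) {
    conserved <- any(sp[neighbors(g)] != focal)
    multi <- csize[as.character(comp[g])] > 1
    if (conserved) {
      if (multi) "with_paralogs_conserved"
      else if (g %in% one21) "one_to_one"
      else "singleton_with_homologs"
    } else {
      if (multi) "orphan_with_paralogs" else "orphan_singleton"
    }
  }, "")
}
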