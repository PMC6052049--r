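# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (choose() enumeration, recursive DFS/BFS
# over accessor-level edges) rather than reusing the package's DP passes.

# exhaustive two-sided Fisher P from binomial coefficients
fisherOracle <- function(k, n, K, N) {
  if (n == 0 || K == 0 || K == N) return(1)
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  probs <- vapply(lo:hi, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1))
  obs <- probs[k - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# hand-formula corrections (step-up/step-down written out explicitly)
bonferroniOracle <- function(p) pmin(1, length(p) * p)
sidakOracle <- function(p) pmin(1, 1 - (1 - p)^length(p))
holmOracle <- function(p) {
  m <- length(p); o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m); out[o] <- adj
  out
}
stepUpOracle <- function(p, mult = 1) {
  m <- length(p); o <- order(p)
  q <- pmin(1, mult * m / seq_len(m) * p[o])
  adj <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- adj
  out
}
bhOracle <- function(p) stepUpOracle(p, 1)
byOracle <- function(p) stepUpOracle(p, sum(1 / seq_along(p)))

# parent edges of every term, via the public accessor only
oracleParentEdges <- function(graph, edgeTypes = character()) {
  ids <- goTerms(graph)
  ids <- ids$id[!ids$obsolete]
  stats::setNames(lapply(ids, function(id)
    goParents(graph, id, edgeTypes)), ids)
}

# longest/shortest root path by memoised recursion over parent edges
oracleDepthLevel <- function(graph, edgeTypes = character()) {
  pm <- oracleParentEdges(graph, edgeTypes)
  roots <- unname(goRoots(graph))
  dMemo <- new.env(); lMemo <- new.env()
  depth <- function(id) {
    if (!is.null(dMemo[[id]])) return(dMemo[[id]])
    v <- if (id %in% roots) 0L else
      1L + max(vapply(pm[[id]], depth, integer(1)))
    dMemo[[id]] <- v; v
  }
  level <- function(id) {
    if (!is.null(lMemo[[id]])) return(lMemo[[id]])
    v <- if (id %in% roots) 0L else
      1L + min(vapply(pm[[id]], level, integer(1)))
    lMemo[[id]] <- v; v
  }
  ids <- names(pm)
  data.frame(id = ids,
             depth = vapply(ids, depth, integer(1)),
             level = vapply(ids, level, integer(1)),
             stringsAsFactors = FALSE)
}

# descendant set by plain BFS over inverted parent edges
oracleDescendants <- function(graph, term, edgeTypes = character()) {
  pm <- oracleParentEdges(graph, edgeTypes)
  child <- rep(names(pm), lengths(pm))
  parent <- unlist(pm, use.names = FALSE)
  seen <- character(); frontier <- term
  while (length(frontier)) {
    kids <- setdiff(child[parent %in% frontier], seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  setdiff(seen, term)
}

# inclusive ancestor set by plain BFS up
oracleAncestors <- function(graph, term, edgeTypes = character(),
                            inclusive = TRUE) {
  pm <- oracleParentEdges(graph, edgeTypes)
  seen <- character(); frontier <- term
  while (length(frontier)) {
    up <- setdiff(unique(unlist(pm[frontier], use.names = FALSE)), seen)
    seen <- c(seen, up)
    frontier <- up
  }
  if (inclusive) unique(c(term, seen)) else seen
}

# a small hand-assembled diamond graph used in several tests:
# root <- x <- z, root <- z  (z has two paths of length 1 and 2)
diamondGraph <- function() {
  ids <- sprintf("GO:%07d", 1:3)
  isa <- stats::setNames(list(character(), ids[1], c(ids[1], ids[2])), ids)
  new("OntologyGraph",
      terms = data.frame(id = ids, name = c("root", "x", "z"),
                         namespace = "biological_process",
                         obsolete = FALSE, stringsAsFactors = FALSE),
      isaParents = isa,
      relParents = data.frame(child = character(), type = character(),
                              parent = character(),
                              stringsAsFactors = FALSE),
      keptRelationships = character(),
      roots = c(biological_process = ids[1]),
      altIndex = stats::setNames(character(), character()),
      meta = list(format_version = "1.2", data_version = "test"))
}

# chain root <- t2 <- ... <- tn within one namespace
chainGraph <- function(n, namespace = "biological_process") {
  ids <- sprintf("GO:%07d", seq_len(n))
  isa <- stats::setNames(c(list(character()),
                           lapply(seq_len(n - 1), function(i) ids[i])), ids)
  new("OntologyGraph",
      terms = data.frame(id = ids, name = paste("chain", seq_len(n)),
                         namespace = namespace, obsolete = FALSE,
                         stringsAsFactors = FALSE),
      isaParents = isa,
      relParents = data.frame(child = character(), type = character(),
                              parent = character(),
                              stringsAsFactors = FALSE),
      keptRelationships = character(),
      roots = stats::setNames(ids[1], namespace),
      altIndex = stats::setNames(character(), character()),
      meta = list(format_version = "1.2", data_version = "test"))
}

# association from a plain named list, for hand-built cases
assocFromList <- function(g2t, namespace = "biological_process",
                          propagated = FALSE) {
  GOgrouper:::.newAssociation(g2t, namespace, propagated)
}
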