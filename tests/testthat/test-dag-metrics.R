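test_that("depth and level follow the longest/shortest path definitions", {
  g <- diamondGraph()  # root -> x -> z and root -> z
  dl <- computeDepthLevel(g)
  z <- dl[dl$id == "GO:0000003", ]
  expect_equal(z$level, 1)
  expect_equal(z$depth, 2)
  # a 17-term chain puts its deepest term at depth 16
  ch <- chainGraph(17)
  dlc <- computeDepthLevel(ch)
  expect_equal(max(dlc$depth), 16)
  expect_equal(dlc$depth, dlc$level)  # single path: depth == level
})

test_that("depth/level match the recursive oracle on random DAGs", {
  for (seed in 1:5) {
    g <- makeToyDag(sample(50:200, 1), seed = seed, pRelationship = 0.15)
    for (et in list(character(), "part_of")) {
      dl <- computeDepthLevel(g, et)
      o <- oracleDepthLevel(g, et)
      m <- match(dl$id, o$id)
      expect_equal(dl$depth, o$depth[m])
      expect_equal(dl$level, o$level[m])
      expect_true(all(dl$level <= dl$depth))
    }
  }
})

test_that("descendant counts equal brute-force reachability", {
  ch <- chainGraph(3)
  expect_equal(descendantCount(ch, "GO:0000001"), 2)
  expect_equal(descendantCount(ch, "GO:0000003"), 0)  # leaf
  expect_error(descendantCount(ch, "GO:0009999"), "unknown")
  g <- makeToyDag(120, seed = 8, pRelationship = 0.2)
  ids <- sample(goTerms(g)$id, 25)
  for (et in list(character(), "part_of")) {
    dcnt <- GOgrouper:::.allDcnt(g, et)
    for (id in ids) {
      o <- oracleDescendants(g, id, et)
      expect_equal(descendantCount(g, id, et), length(o))
      expect_equal(unname(dcnt[id]), length(o))
      # child descendant sets are strict subsets of the parent's
      for (ch2 in goChildren(g, id, et))
        expect_true(all(oracleDescendants(g, ch2, et) %in% o))
    }
  }
})

test_that("depth-01 aliases are assigned by descending dcnt with id ties", {
  # two depth-01 terms with dcnt 5 and 1
  ids <- sprintf("GO:%07d", 1:9)
  isa <- stats::setNames(c(list(character()), as.list(c(
    ids[1], ids[1], ids[2], ids[2], ids[2], ids[4], ids[5], ids[3]))), ids)
  g <- GOgrouper:::.graphFromEdges(ids, paste("t", 1:9),
                                   rep("biological_process", 9), isa)
  al <- assignD1Aliases(g)
  expect_equal(unname(al["A"]), ids[2])  # dcnt 5
  expect_equal(unname(al["B"]), ids[3])  # dcnt 1
  # equal dcnts break alphabetically
  ids2 <- sprintf("GO:%07d", 1:3)
  isa2 <- stats::setNames(list(character(), ids2[1], ids2[1]), ids2)
  g2 <- GOgrouper:::.graphFromEdges(ids2, paste("t", 1:3),
                                    rep("biological_process", 3), isa2)
  al2 <- assignD1Aliases(g2)
  expect_equal(unname(al2), ids2[2:3])
})

test_that("alias strings collect all depth-01 ancestors, sorted", {
  g <- makeToyDag(100, seed = 21, pRelationship = 0.1)
  al <- assignD1Aliases(g)
  dl <- computeDepthLevel(g, c("part_of", "regulates"))
  d1 <- dl$id[dl$depth == 1]
  for (id in sample(goTerms(g)$id, 20)) {
    anc <- oracleAncestors(g, id, c("part_of", "regulates"))
    want <- sort(names(al)[al %in% intersect(anc, d1)])
    expect_equal(aliasString(g, id, al), paste(want, collapse = ""))
  }
  # a depth-01 term is its own single letter
  expect_equal(aliasString(g, al[["A"]], al), "A")
})

test_that("term counts are descendant-inclusive with root total", {
  ch <- chainGraph(3)
  # all genes annotated to root only: frequency 1, tinfo 0
  tc <- termCounts(assocFromList(list(g1 = "GO:0000001",
                                      g2 = "GO:0000001")), ch)
  expect_equal(unname(tc$tinfo["GO:0000001"]), 0)
  expect_error(termCounts(assocFromList(list()), ch), "empty")
  # counts equal brute-force descendant-gene unions; parent >= child
  g <- makeToyDag(40, seed = 17)
  set.seed(17)
  ids <- goTerms(g)$id
  g2t <- lapply(stats::setNames(1:20, paste0("gene", 1:20)), function(i)
    sample(ids, sample(1:3, 1)))
  a <- assocFromList(g2t)
  tc2 <- termCounts(a, g)
  pairsGene <- rep(names(g2t), lengths(g2t))
  pairsTerm <- unlist(g2t, use.names = FALSE)
  for (t in names(tc2$counts)) {
    below <- c(t, oracleDescendants(g, t))
    expect_equal(unname(tc2$counts[t]),
                 length(unique(pairsGene[pairsTerm %in% below])))
    for (ch2 in goChildren(g, t)) {
      if (ch2 %in% names(tc2$counts))
        expect_true(tc2$counts[t] >= tc2$counts[ch2])
    }
  }
  expect_true(all(tc2$tinfo >= 0))
})

test_that("a normalized count of e^-5 gives an information content of 5", {
  # 148 genes ~ e^5 of them annotated to the root, 1 to a specific leaf
  ch <- chainGraph(2)
  genes <- paste0("gene", seq_len(148))
  g2t <- stats::setNames(rep(list("GO:0000001"), 148), genes)
  g2t[["gene1"]] <- c("GO:0000001", "GO:0000002")
  tc <- termCounts(assocFromList(g2t), ch)
  expect_equal(unname(tc$tinfo["GO:0000002"]), -log(1 / 148))
  expect_equal(unname(tc$tinfo["GO:0000002"]), 5, tolerance = 0.01)
})

test_that("Resnik and Lin similarities match the common-ancestor scan", {
  g <- makeToyDag(60, seed = 23)
  set.seed(23)
  ids <- goTerms(g)$id
  g2t <- lapply(stats::setNames(1:30, paste0("gene", 1:30)), function(i)
    sample(ids, sample(1:3, 1)))
  tc <- termCounts(assocFromList(g2t), g)
  have <- names(tc$tinfo)
  pairs <- matrix(sample(have, 30, replace = TRUE), ncol = 2)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    common <- intersect(oracleAncestors(g, a), oracleAncestors(g, b))
    common <- intersect(common, have)
    want <- if (length(common)) max(tc$tinfo[common]) else 0
    expect_equal(resnikSimilarity(a, b, tc, g), want)
    expect_equal(resnikSimilarity(b, a, tc, g),
                 resnikSimilarity(a, b, tc, g))  # symmetry
    l <- linSimilarity(a, b, tc, g)
    expect_true(l >= 0 && l <= 1 + 1e-12)
  }
  # identity: lin(t, t) = 1 for informative terms
  t1 <- have[which(tc$tinfo[have] > 0)[1]]
  expect_equal(linSimilarity(t1, t1, tc, g), 1)
  # only common ancestor is the root with tinfo 0
  root <- goRoots(g)[[1]]
  expect_equal(resnikSimilarity(root, root, tc, g), 0)
  # different namespaces are an error
  g2 <- makeToyDag(6, nRoots = 2, seed = 2)
  tids <- goTerms(g2)
  expect_error(resnikSimilarity(tids$id[1], tids$id[4], tc, g2),
               "namespace")
})

test_that("slim mapping returns path-aware direct and full ancestor sets", {
  # chain root(slim) <- a(slim) <- b
  ch <- chainGraph(3)
  slim <- c("GO:0000001", "GO:0000002")
  expect_equal(mapToSlim(ch, "GO:0000003", slim, "direct"), "GO:0000002")
  expect_setequal(mapToSlim(ch, "GO:0000003", slim, "all"), slim)
  expect_equal(mapToSlim(ch, "GO:0000002", slim, "direct"), "GO:0000002")
  expect_equal(mapToSlim(ch, "GO:0000001", slim, "all"), "GO:0000001")
  # no slim ancestor -> empty
  expect_equal(mapToSlim(ch, "GO:0000003", character(), "all"),
               character())
  # random DAG/slim vs brute-force path analysis
  g <- makeToyDag(80, seed = 29)
  set.seed(29)
  slim2 <- sample(goTerms(g)$id, 12)
  pm <- oracleParentEdges(g)
  firstSlimOracle <- function(id) {
    if (id %in% slim2) return(id)
    unique(unlist(lapply(pm[[id]], firstSlimOracle), use.names = FALSE))
  }
  for (id in sample(goTerms(g)$id, 20)) {
    expect_setequal(mapToSlim(g, id, slim2, "all"),
                    intersect(oracleAncestors(g, id), slim2))
    expect_setequal(mapToSlim(g, id, slim2, "direct"),
                    as.character(unique(firstSlimOracle(id))))
  }
})
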