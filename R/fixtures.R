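## Deterministic generators for toy ontologies and skewed synthetic
## associations, so that every analysis path is testable without downloads.

.goId <- function(i) sprintf("GO:%07d", i)

# run code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# assemble an OntologyGraph from parallel vectors without OBO text
.graphFromEdges <- function(ids, names, namespaces, isaParents,
                            relParents = data.frame(child = character(),
                                                    type = character(),
                                                    parent = character(),
                                                    stringsAsFactors = FALSE),
                            keptRelationships = c("part_of", "regulates")) {
  terms <- data.frame(id = ids, name = names, namespace = namespaces,
                      obsolete = FALSE, stringsAsFactors = FALSE)
  roots <- character()
  for (ns in unique(namespaces)) {
    inNs <- ids[namespaces == ns]
    parentless <- inNs[lengths(isaParents[inNs]) == 0L]
    stopifnot(length(parentless) == 1L)
    roots[[ns]] <- parentless
  }
  g <- new("OntologyGraph", terms = terms, isaParents = isaParents,
           relParents = relParents, keptRelationships = keptRelationships,
           roots = roots, altIndex = stats::setNames(character(),
                                                     character()),
           meta = list(format_version = "1.2", data_version = "synthetic"))
  stopifnot(validateAcyclic(g, c("part_of", "regulates")))
  g
}

#' Generate a random toy ontology DAG
#'
#' Terms are created in id order and each non-root term draws 1 to
#' \code{maxParents} parents uniformly from the earlier terms of its
#' namespace, so the graph is acyclic by construction and a pure function
#' of the seed. With \code{nRoots > 1} (up to 3) the terms are split over
#' that many namespaces, each with its own root.
#'
#' @param nTerms total number of terms.
#' @param nRoots number of namespaces/roots (1 to 3).
#' @param maxParents maximum parents per term.
#' @param pRelationship probability that a drawn edge is emitted as a
#'   \code{part_of} relationship instead of \code{is_a} (each term keeps at
#'   least one \code{is_a} parent).
#' @param seed integer seed.
#' @return an [OntologyGraph-class].
#' @export
makeToyDag <- function(nTerms, nRoots = 1, maxParents = 3,
                       pRelationship = 0, seed = 1) {
  stopifnot(nTerms >= nRoots, nRoots >= 1, nRoots <= 3)
  .withSeed(seed, {
    nss <- GO_NAMESPACES[sort(rep_len(seq_len(nRoots), nTerms))]
    ids <- .goId(seq_len(nTerms))
    isa <- stats::setNames(vector("list", nTerms), ids)
    relC <- character(); relP <- character()
    for (ns in unique(nss)) {
      inNs <- which(nss == ns)
      isa[[ids[inNs[1]]]] <- character()
      for (j in seq_along(inNs)[-1]) {
        i <- inNs[j]
        pool <- ids[inNs[seq_len(j - 1L)]]
        nPar <- sample(seq_len(min(maxParents, length(pool))), 1L)
        parents <- sample(pool, nPar)
        asRel <- stats::runif(nPar) < pRelationship
        asRel[1] <- FALSE  # guarantee one is_a parent
        isa[[ids[i]]] <- parents[!asRel]
        if (any(asRel)) {
          relC <- c(relC, rep(ids[i], sum(asRel)))
          relP <- c(relP, parents[asRel])
        }
      }
    }
    rel <- data.frame(child = relC, type = rep("part_of", length(relC)),
                      parent = relP, stringsAsFactors = FALSE)
    .graphFromEdges(ids, paste("term", seq_len(nTerms)), nss, isa, rel)
  })
}

#' Fixed toy DAG reproducing the header re-routing scenario
#'
#' A small biological-process DAG whose candidate-header descendant counts
#' reproduce, as order statistics, the situation where a leaf term
#' ("germinal center formation" analog) sits under both a developmental
#' branch and an immune branch: the initially chosen header is the
#' smallest-dcnt morphogenesis header, and adding an "immune response"
#' header with a still smaller dcnt re-routes the leaf into the immune
#' section. The leaf has level 3 and depth 5.
#'
#' @return list with \code{graph} (an [OntologyGraph-class]), \code{target}
#'   (the leaf id), \code{defaultHeaders} (the five initial candidate
#'   header ids), \code{addedHeader} (the immune-response analog),
#'   \code{initialChoice} and \code{reroutedChoice}.
#' @export
makeFig2Dag <- function() {
  ids <- .goId(1:21)
  nm <- c("biological_process",                         # 1 root
          "developmental process",                      # 2
          "response to stimulus",                       # 3
          "immune system process",                      # 4
          "anatomical structure formation involved in morphogenesis", # 5
          "immune response",                            # 6
          "leukocyte activation",                       # 7  (depth 3)
          "B cell activation",                          # 8  (depth 4)
          "germinal center formation",                  # 9  target leaf
          paste("filler term", 10:21))                  # padding
  ns <- rep("biological_process", 21)
  isa <- stats::setNames(vector("list", 21), ids)
  P <- function(i, parents) isa[[ids[i]]] <<- ids[parents]
  P(1, integer())
  P(2, 1); P(3, 1); P(4, 1)
  P(5, 2)                    # morphogenesis under development
  P(6, c(3, 4))              # immune response under response & immune sys
  P(7, 6); P(8, 7)
  P(9, c(5, 8))              # target: via dev (level 3) and immune (depth 5)
  P(10, 2); P(11, 2); P(12, 2); P(13, 2)    # dev padding
  P(14, 5); P(15, 5); P(16, 5)              # morphogenesis padding
  P(17, 3); P(18, 3); P(19, 3)              # response padding
  P(20, 4); P(21, 4)                        # immune-system padding
  graph <- .graphFromEdges(ids, nm, ns, isa)
  list(graph = graph,
       target = ids[9],
       defaultHeaders = ids[c(1, 2, 3, 4, 5)],
       addedHeader = ids[6],
       initialChoice = ids[5],
       reroutedChoice = ids[6])
}

#' Generate a skewed synthetic gene association
#'
#' Emulates the shape of real model-organism annotation sets: per-term gene
#' counts follow a heavy-tailed mixture (a geometric bulk with median about
#' 3 genes/term plus a lognormal heavy tail), a fixed number of broad terms
#' each annotate more than \code{broadMinGenes} genes, and a designated
#' cluster of terms coherently annotates a target gene pool (the truly
#' enriched genes for simulations). Regular terms draw their genes from the
#' whole population; broad terms draw from the background only (the
#' coherent pool is depleted for broad functions, which is what makes
#' those terms under-represented in target-heavy studies); cluster terms
#' annotate target genes only. Deterministic per seed.
#'
#' @param graph an [OntologyGraph-class] (single-namespace).
#' @param nGenes population size.
#' @param nBroad number of broad terms.
#' @param broadMinGenes every broad term annotates more than this many
#'   genes.
#' @param clusterTerms term ids annotating the target pool (leaves
#'   recommended); when \code{NULL}, the \code{nClusterTerms}
#'   highest-numbered leaf terms are used.
#' @param nClusterTerms number of cluster terms when \code{clusterTerms} is
#'   \code{NULL}.
#' @param clusterSize size of the target gene pool.
#' @param seed integer seed.
#' @return list with \code{assoc} (a [GeneAssociation-class]),
#'   \code{genes}, \code{targetPool}, \code{backgroundPool},
#'   \code{broadTerms} and \code{clusterTerms}.
#' @export
makeSkewedAssociation <- function(graph, nGenes = 20000, nBroad = 30,
                                  broadMinGenes = 1000,
                                  clusterTerms = NULL, nClusterTerms = 8,
                                  clusterSize = 124, seed = 1) {
  stopifnot(broadMinGenes < nGenes)
  ns <- names(graph@roots)[1]
  root <- graph@roots[[ns]]
  live <- goTerms(graph)
  live <- live$id[!live$obsolete & live$namespace == ns]
  if (is.null(clusterTerms)) {
    cm <- .childMap(graph, character())
    leaves <- live[vapply(live, function(t) length(cm[[t]] %||%
                                                     character()) == 0L,
                          logical(1))]
    if (length(leaves) < nClusterTerms)
      stop("not enough leaf terms for the requested cluster")
    clusterTerms <- utils::tail(sort(leaves), nClusterTerms)
  }
  # the cluster's ancestors stay clean so target annotations propagate
  # through a branch that annotates only target genes
  clusterAnc <- unique(unlist(lapply(clusterTerms, function(t)
    goAncestors(graph, t, inclusive = TRUE)), use.names = FALSE))
  candidates <- setdiff(live, c(root, clusterAnc))
  if (length(candidates) < nBroad)
    stop("not enough terms for ", nBroad, " broad terms")
  .withSeed(seed, {
    genes <- sprintf("gene%05d", seq_len(nGenes))
    targetPool <- sort(sample(genes, clusterSize))
    backgroundPool <- setdiff(genes, targetPool)
    # broad terms: prefer shallow terms so the broad signal is structural
    dl <- computeDepthLevel(graph)
    cand <- candidates[order(dl$depth[match(candidates, dl$id)],
                             candidates)]
    broadTerms <- cand[seq_len(nBroad)]
    regular <- setdiff(candidates, broadTerms)

    geneChunks <- list(); termChunks <- list()
    # regular terms: geometric bulk (median ~3) plus a 5% lognormal heavy
    # tail scaled to the broad threshold, so that most genes keep at least
    # one non-broad annotation (as in real annotation sets, where gene
    # coverage hardly depends on the few very broad terms)
    nReg <- length(regular)
    counts <- 1L + stats::rgeom(nReg, prob = 0.25)
    tail_i <- stats::runif(nReg) < 0.05
    tailScale <- max(10, 0.35 * broadMinGenes)
    counts[tail_i] <- pmax(counts[tail_i],
                           1L + round(stats::rlnorm(sum(tail_i),
                                                    meanlog =
                                                      log(tailScale),
                                                    sdlog = 0.6)))
    # regular terms always stay strictly below the broad threshold
    counts <- pmin(counts, max(1L, broadMinGenes - 1L), nGenes)
    for (i in seq_len(nReg)) {
      geneChunks[[length(geneChunks) + 1L]] <- sample(genes, counts[i])
      termChunks[[length(termChunks) + 1L]] <- rep(regular[i], counts[i])
    }
    # broad terms: log-uniform between 1.5x and 6x the broad threshold
    if (nBroad > 0) {
      bc <- round(exp(stats::runif(nBroad, log(1.5 * broadMinGenes),
                                   log(min(6 * broadMinGenes,
                                           length(backgroundPool))))))
      for (i in seq_len(nBroad)) {
        geneChunks[[length(geneChunks) + 1L]] <- sample(backgroundPool,
                                                        bc[i])
        termChunks[[length(termChunks) + 1L]] <- rep(broadTerms[i], bc[i])
      }
    }
    # cluster terms: each target gene gets 1-3 cluster terms
    for (g in targetPool) {
      ts <- sample(clusterTerms, min(sample(1:3, 1L),
                                     length(clusterTerms)))
      geneChunks[[length(geneChunks) + 1L]] <- rep(g, length(ts))
      termChunks[[length(termChunks) + 1L]] <- ts
    }
    pairsGene <- unlist(geneChunks, use.names = FALSE)
    pairsTerm <- unlist(termChunks, use.names = FALSE)
    g2t <- lapply(split(pairsTerm, pairsGene), unique)
    assoc <- .newAssociation(g2t, ns)
    list(assoc = assoc, genes = genes, targetPool = targetPool,
         backgroundPool = backgroundPool, broadTerms = broadTerms,
         clusterTerms = sort(clusterTerms))
  })
}

#' One-call simulation fixture: DAG plus skewed association
#'
#' Builds the study conditions used by the simulation framework: a
#' single-root biological-process DAG with a dedicated depth-1 parent for
#' the coherent cluster terms (so target annotations propagate through a
#' clean branch), and a skewed association over it.
#'
#' @param nTerms terms in the DAG (cluster terms included).
#' @param nGenes population size.
#' @param nBroad,broadMinGenes,nClusterTerms,clusterSize passed to
#'   [makeSkewedAssociation()].
#' @param seed integer seed.
#' @return list with \code{graph} plus everything returned by
#'   [makeSkewedAssociation()].
#' @export
makeSimulationFixture <- function(nTerms = 2000, nGenes = 20000,
                                  nBroad = 30, broadMinGenes = 1000,
                                  nClusterTerms = 8, clusterSize = 124,
                                  seed = 1) {
  stopifnot(nTerms > nClusterTerms + nBroad + 2)
  nBody <- nTerms - nClusterTerms - 1L
  # branched body DAG: root -> branch heads -> within-branch sub-DAGs.
  # Bounded branch sizes keep ancestor-propagated gene counts of
  # non-broad terms below the broad threshold, mirroring the real GO
  # where only a handful of terms annotate very many genes.
  nBranch <- max(2L, min(16L, (nBody - 1L) %/% 8L))
  bodyIds <- .goId(seq_len(nBody))
  isa <- stats::setNames(vector("list", nBody), bodyIds)
  isa[[bodyIds[1]]] <- character()
  .withSeed(seed, {
    branchOf <- integer(nBody)
    heads <- 1L + seq_len(nBranch)
    branchOf[heads] <- seq_len(nBranch)
    for (h in heads) isa[[bodyIds[h]]] <- bodyIds[1]
    if (nBody > 1L + nBranch) {
      rest <- (2L + nBranch):nBody
      branchOf[rest] <- sample(rep_len(seq_len(nBranch), length(rest)))
      for (i in rest) {
        pool <- bodyIds[which(branchOf == branchOf[i])]
        pool <- pool[pool < bodyIds[i]]
        isa[[bodyIds[i]]] <- sample(pool, min(length(pool),
                                              sample(1:2, 1L)))
      }
    }
  })
  # append a dedicated cluster parent under the root plus leaf cluster terms
  ids <- c(bodyIds, .goId(nBody + seq_len(nClusterTerms + 1L)))
  nm <- c("biological_process", paste("body term", seq_len(nBody - 1L) + 1L),
          "humoral-style coherent process",
          paste("cluster term", seq_len(nClusterTerms)))
  ns <- rep("biological_process", length(ids))
  parentId <- .goId(nBody + 1L)
  isa[[parentId]] <- bodyIds[1]
  for (k in seq_len(nClusterTerms))
    isa[[.goId(nBody + 1L + k)]] <- parentId
  graph <- .graphFromEdges(ids, nm, ns, isa)
  clusterTerms <- .goId(nBody + 1L + seq_len(nClusterTerms))
  fx <- makeSkewedAssociation(graph, nGenes = nGenes, nBroad = nBroad,
                              broadMinGenes = broadMinGenes,
                              clusterTerms = clusterTerms,
                              clusterSize = clusterSize, seed = seed + 1L)
  c(list(graph = graph), fx)
}
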