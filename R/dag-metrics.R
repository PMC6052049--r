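## Per-term structural and information metrics: depth, level, descendant
## counts, depth-01 aliases, information content, semantic similarity and
## GO-slim mapping.

#' Depth and level of every term
#'
#' Depth is the maximum number of edges on a path from the namespace root
#' down to the term; level is the minimum. Roots have depth = level = 0.
#'
#' @param graph an [OntologyGraph-class].
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return data.frame with columns \code{id}, \code{namespace},
#'   \code{depth}, \code{level}.
#' @export
computeDepthLevel <- function(graph, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  ord <- .topoOrder(pm)
  if (is.null(ord)) stop("graph is cyclic over the selected edge set")
  depth <- stats::setNames(rep(NA_integer_, length(ord)), ord)
  level <- depth
  roots <- unname(graph@roots)
  depth[roots] <- 0L; level[roots] <- 0L
  for (id in ord) {
    if (id %in% roots) next
    ps <- pm[[id]]
    if (!length(ps) || anyNA(depth[ps]))
      stop("term has no path to its namespace root: ", id)
    depth[[id]] <- max(depth[ps]) + 1L
    level[[id]] <- min(level[ps]) + 1L
  }
  data.frame(id = ord,
             namespace = goNamespace(graph, ord),
             depth = unname(depth), level = unname(level),
             stringsAsFactors = FALSE)
}

#' Number of distinct descendants of a term
#'
#' Leaf terms have a descendant count (dcnt) of zero; the count excludes the
#' term itself. Broader edge sets (e.g. including \code{part_of}) can only
#' add descendants.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a primary GO id.
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return integer.
#' @export
descendantCount <- function(graph, term, edgeTypes = character()) {
  length(goDescendants(graph, term, edgeTypes))
}

# dcnt for every non-obsolete term in one reverse-topological DP pass;
# descendant sets are kept as integer index vectors
.allDcnt <- function(graph, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  ord <- .topoOrder(pm)
  if (is.null(ord)) stop("graph is cyclic over the selected edge set")
  cm <- .childMap(graph, edgeTypes)
  idx <- stats::setNames(seq_along(ord), ord)
  desc <- vector("list", length(ord))
  dcnt <- stats::setNames(integer(length(ord)), ord)
  for (id in rev(ord)) {
    kids <- cm[[id]]
    if (is.null(kids) || !length(kids)) {
      desc[[idx[[id]]]] <- integer()
    } else {
      ki <- unname(idx[kids])
      desc[[idx[[id]]]] <- unique(c(ki, unlist(desc[ki], use.names = FALSE)))
    }
    dcnt[[id]] <- length(desc[[idx[[id]]]])
  }
  dcnt
}

#' Assign alias letters to depth-01 terms
#'
#' Depth-01 terms of a namespace are sorted by descendant count, largest
#' first (ties broken by term id), and assigned the letters A, B, C, ...;
#' past 26 terms the aliases continue with lowercase letters.
#'
#' @param graph an [OntologyGraph-class].
#' @param namespace the namespace whose depth-01 terms are labelled.
#' @param edgeTypes relationship types used for both depth and dcnt
#'   (default \code{part_of} + \code{regulates}, the convention for
#'   descendant-count reporting).
#' @return named character vector: alias letter -> term id.
#' @export
assignD1Aliases <- function(graph, namespace = "biological_process",
                            edgeTypes = c("part_of", "regulates")) {
  dl <- computeDepthLevel(graph, edgeTypes)
  d1 <- dl$id[dl$namespace == namespace & dl$depth == 1L]
  if (!length(d1)) return(stats::setNames(character(), character()))
  dcnt <- .allDcnt(graph, edgeTypes)[d1]
  ord <- order(-dcnt, d1)
  letters_all <- c(LETTERS, letters)
  if (length(d1) > length(letters_all))
    stop("more depth-01 terms than available alias letters")
  stats::setNames(d1[ord], letters_all[seq_along(d1)])
}

#' Alias string of a term's depth-01 ancestors
#'
#' Concatenates, in ascending order, the alias letters of every depth-01
#' ancestor of the term (the term itself included when it is at depth 01),
#' giving its general location in the DAG.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a primary GO id.
#' @param aliases named character vector from [assignD1Aliases()].
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return a string of alias letters.
#' @export
aliasString <- function(graph, term, aliases,
                        edgeTypes = c("part_of", "regulates")) {
  anc <- goAncestors(graph, term, edgeTypes, inclusive = TRUE)
  hit <- names(aliases)[aliases %in% anc]
  paste(sort(hit), collapse = "")
}

#' Descendant-inclusive annotation counts and information content
#'
#' For every term, counts the distinct genes annotated to the term or to any
#' of its \code{is_a} descendants. The branch total is the count at the
#' namespace root (so the root's annotation frequency is 1) and the
#' information content is \code{tinfo = -log(count / total)} (natural log),
#' defined only for terms with a non-zero count.
#'
#' @param assoc a [GeneAssociation-class].
#' @param graph an [OntologyGraph-class].
#' @return an object of class \code{TermCountsTable}: a list with
#'   \code{counts} (named integer), \code{total} (integer) and \code{tinfo}
#'   (named numeric, terms with zero counts absent).
#' @export
termCounts <- function(assoc, graph) {
  if (!length(assoc@gene2terms)) stop("empty association")
  closed <- if (assoc@propagated) assoc else propagateCounts(assoc, graph)
  counts <- lengths(closed@term2genes)
  root <- graph@roots[[assoc@namespace]]
  total <- if (root %in% names(counts)) counts[[root]] else
    length(closed@gene2terms)
  tinfo <- -log(counts / total)
  structure(list(counts = counts, total = total, tinfo = tinfo,
                 namespace = assoc@namespace),
            class = "TermCountsTable")
}

#' @export
print.TermCountsTable <- function(x, ...) {
  cat("TermCountsTable (", x$namespace, "): ", length(x$counts),
      " terms, branch total ", x$total, " genes\n", sep = "")
  invisible(x)
}

.tinfoOf <- function(tc, id) {
  if (!id %in% names(tc$tinfo))
    stop("no information content defined for ", id)
  tc$tinfo[[id]]
}

#' Resnik semantic similarity of two terms
#'
#' The maximum information content over the common \code{is_a} ancestors of
#' the two terms (the terms themselves included).
#'
#' @param a,b primary GO ids in the same namespace.
#' @param tctable a \code{TermCountsTable} from [termCounts()].
#' @param graph an [OntologyGraph-class].
#' @return numeric similarity (0 when the only informative common ancestor
#'   is the root).
#' @export
resnikSimilarity <- function(a, b, tctable, graph) {
  if (goNamespace(graph, a) != goNamespace(graph, b))
    stop("terms are in different namespaces")
  common <- intersect(goAncestors(graph, a, inclusive = TRUE),
                      goAncestors(graph, b, inclusive = TRUE))
  common <- intersect(common, names(tctable$tinfo))
  if (!length(common)) return(0)
  max(tctable$tinfo[common])
}

#' Lin semantic similarity of two terms
#'
#' \code{2 * resnik(a, b) / (tinfo(a) + tinfo(b))}, defined as 0 when the
#' denominator is 0 (both terms uninformative).
#'
#' @inheritParams resnikSimilarity
#' @return numeric in [0, 1] when both terms have positive information
#'   content.
#' @export
linSimilarity <- function(a, b, tctable, graph) {
  denom <- .tinfoOf(tctable, a) + .tinfoOf(tctable, b)
  if (denom == 0) return(0)
  2 * resnikSimilarity(a, b, tctable, graph) / denom
}

#' Map a term onto a GO-slim subset
#'
#' \code{mode = "all"} returns every slim ancestor of the term (the term
#' itself included when it is in the slim). \code{mode = "direct"} returns
#' the slim terms first encountered on upward paths from the term: a slim
#' ancestor is excluded when every path to it passes through another slim
#' term.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a primary GO id.
#' @param slimIds character set of slim term ids (must be graph terms).
#' @param mode \code{"direct"} or \code{"all"}.
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return character vector of slim ids (possibly empty).
#' @export
mapToSlim <- function(graph, term, slimIds, mode = c("direct", "all"),
                      edgeTypes = character()) {
  mode <- match.arg(mode)
  stopifnot(all(slimIds %in% graph@terms$id))
  pm <- .parentMap(graph, edgeTypes)
  if (!term %in% names(pm)) stop("unknown or obsolete term: ", term)
  if (mode == "all") {
    anc <- .ancestorsOf(pm, term, inclusive = TRUE)
    return(sort(intersect(anc, slimIds)))
  }
  # first slim term reachable on each upward path, by memoised DP
  memo <- new.env(parent = emptyenv())
  firstSlim <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- if (id %in% slimIds) id else {
      ps <- pm[[id]]
      if (!length(ps)) character()
      else unique(unlist(lapply(ps, firstSlim), use.names = FALSE))
    }
    memo[[id]] <- res
    res
  }
  sort(firstSlim(term))
}
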