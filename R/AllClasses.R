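GO_ID_REGEX <- "^GO:[0-9]{7}$"
GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")
RELATION_TYPES <- c("part_of", "regulates", "positively_regulates",
                    "negatively_regulates")

#' Ontology stored as a directed acyclic graph
#'
#' An \code{OntologyGraph} holds the parsed ontology: one row per term with
#' its attributes, the \code{is_a} parent edges, typed relationship edges
#' (\code{part_of}, \code{regulates} and its signed subtypes), the namespace
#' roots, and an index from alternative (merged) identifiers to primary ones.
#' Obsolete terms are retained so that lookups can resolve them, but they
#' carry no edges and are excluded from every traversal.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}, \code{obsolete}.
#' @slot isaParents named list: term id -> character vector of \code{is_a}
#'   parent ids.
#' @slot relParents data.frame with columns \code{child}, \code{type},
#'   \code{parent}; only relationship types requested at parse time are kept,
#'   with the signed \code{regulates} subtypes preserved verbatim.
#' @slot keptRelationships character: relationship types requested at parse
#'   time (after folding signed subtypes into \code{"regulates"}).
#' @slot roots named character: namespace -> root term id.
#' @slot altIndex named character: alternative id -> primary id.
#' @slot meta list with \code{format_version} and \code{data_version}.
#'
#' @seealso [readObo()], [makeToyDag()], [goTerms()], [goParents()]
#' @export
setClass("OntologyGraph",
  representation(
    terms = "data.frame",
    isaParents = "list",
    relParents = "data.frame",
    keptRelationships = "character",
    roots = "character",
    altIndex = "character",
    meta = "list"
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  tr <- object@terms
  need <- c("id", "name", "namespace", "obsolete")
  if (!all(need %in% names(tr)))
    return(paste("terms must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tr$id))
    msg <- c(msg, "duplicated term ids")
  bad <- tr$id[!grepl(GO_ID_REGEX, tr$id)]
  if (length(bad))
    msg <- c(msg, paste("malformed term id:", bad[1]))
  if (length(object@altIndex) &&
      any(names(object@altIndex) %in% tr$id))
    msg <- c(msg, "alt ids overlap primary ids")
  obs <- tr$id[tr$obsolete]
  if (length(obs)) {
    if (any(obs %in% unlist(object@isaParents, use.names = FALSE)))
      msg <- c(msg, "obsolete term used as a parent")
    if (any(lengths(object@isaParents[obs]) > 0))
      msg <- c(msg, "obsolete term has parents")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn OntologyGraph compact summary of the graph.
#' @param object an \code{OntologyGraph}.
#' @export
setMethod("show", "OntologyGraph", function(object) {
  tr <- object@terms
  cat("OntologyGraph with", nrow(tr), "terms (",
      sum(tr$obsolete), "obsolete )\n")
  for (ns in names(object@roots)) {
    cat("  ", ns, ": root ", object@roots[[ns]], ", ",
        sum(tr$namespace == ns & !tr$obsolete), " terms\n", sep = "")
  }
  if (nrow(object@relParents))
    cat("  relationship edges:",
        paste(sprintf("%s (%d)", names(table(object@relParents$type)),
                      as.integer(table(object@relParents$type))),
              collapse = ", "), "\n")
  if (length(object@altIndex))
    cat("  alt ids:", length(object@altIndex), "\n")
})

#' Gene-to-term association for one namespace
#'
#' A \code{GeneAssociation} is the bipartite map between gene products and
#' the GO terms annotated to them, restricted to a single namespace. The
#' inverse index (\code{term2genes}) is derived at construction and kept in
#' exact correspondence with \code{gene2terms}. When \code{propagated} is
#' \code{TRUE} every gene's term set is closed under \code{is_a} ancestors.
#'
#' @slot namespace one of \code{biological_process},
#'   \code{molecular_function}, \code{cellular_component}.
#' @slot gene2terms named list: gene -> character vector of term ids.
#' @slot term2genes named list: term id -> character vector of genes.
#' @slot nAnnotations integer: total number of distinct gene-term pairs.
#' @slot propagated logical.
#'
#' @seealso [buildAssociation()], [propagateCounts()], [gene2Terms()]
#' @export
setClass("GeneAssociation",
  representation(
    namespace = "character",
    gene2terms = "list",
    term2genes = "list",
    nAnnotations = "integer",
    propagated = "logical"
  )
)

setValidity("GeneAssociation", function(object) {
  msg <- character()
  if (!object@namespace %in% GO_NAMESPACES)
    msg <- c(msg, "unknown namespace")
  n1 <- sum(lengths(object@gene2terms))
  n2 <- sum(lengths(object@term2genes))
  if (n1 != n2)
    msg <- c(msg, "gene2terms and term2genes disagree in size")
  if (object@nAnnotations != n1)
    msg <- c(msg, "nAnnotations does not match gene2terms")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn GeneAssociation compact summary of the association.
#' @param object a \code{GeneAssociation}.
#' @export
setMethod("show", "GeneAssociation", function(object) {
  cat("GeneAssociation (", object@namespace, ")\n", sep = "")
  cat("  genes: ", length(object@gene2terms),
      "  terms: ", length(object@term2genes),
      "  annotations: ", object@nAnnotations, "\n", sep = "")
  cat("  propagated:", object@propagated, "\n")
})

# internal constructor: builds the inverse index from gene2terms
.newAssociation <- function(gene2terms, namespace, propagated = FALSE) {
  gene2terms <- gene2terms[lengths(gene2terms) > 0]
  gene2terms <- lapply(gene2terms, function(x) sort(unique(x)))
  genes <- rep(names(gene2terms), lengths(gene2terms))
  terms <- unlist(gene2terms, use.names = FALSE)
  term2genes <- if (length(terms)) {
    lapply(split(genes, terms), function(g) sort(unique(g)))
  } else list()
  new("GeneAssociation",
      namespace = namespace,
      gene2terms = gene2terms,
      term2genes = term2genes,
      nAnnotations = length(terms),
      propagated = propagated)
}
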