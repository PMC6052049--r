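## OBO 1.2 (go-basic dialect) parsing, writing and DAG validation.

# strip a trailing "! comment" from an id-bearing OBO value
.stripOboComment <- function(x) sub("\\s*!.*$", "", x)

# fold signed regulates subtypes into "regulates" for traversal purposes
.foldRelType <- function(type) {
  if (!length(type)) return(character())
  ifelse(type %in% c("positively_regulates", "negatively_regulates"),
         "regulates", type)
}

#' Read an OBO 1.2 ontology into an OntologyGraph
#'
#' Parses \code{[Term]} stanzas of a go-basic-dialect OBO file. \code{is_a}
#' edges are always kept; \code{relationship} edges are kept only for the
#' types in \code{keepRelationships} (\code{"regulates"} covers the signed
#' subtypes, which are preserved verbatim on the record). \code{[Typedef]}
#' stanzas are ignored. Obsolete terms are loaded but carry no edges and are
#' excluded from traversals. The graph restricted to the kept edges is
#' checked to be acyclic; cross-namespace edges are rejected.
#'
#' @param path path to an OBO file, or a character vector of lines.
#' @param keepRelationships character subset of
#'   \code{c("part_of", "regulates")} (signed subtypes may be named
#'   explicitly); default keeps none, so the graph has \code{is_a} edges only.
#' @return an [OntologyGraph-class].
#' @examples
#' obo <- c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'          "name: root", "namespace: biological_process", "", "[Term]",
#'          "id: GO:0000002", "name: child", "namespace: biological_process",
#'          "is_a: GO:0000001 ! root")
#' g <- readObo(obo)
#' goChildren(g, "GO:0000001")
#' @export
readObo <- function(path, keepRelationships = character()) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  keepFolded <- unique(.foldRelType(keepRelationships))
  bad <- setdiff(keepFolded, c("part_of", "regulates"))
  if (length(bad))
    stop("unknown relationship type(s): ", paste(bad, collapse = ", "))

  meta <- list(format_version = "1.2", data_version = "")
  stanzaStart <- grep("^\\[", lines)
  headerEnd <- if (length(stanzaStart)) stanzaStart[1] - 1L else length(lines)
  for (ln in lines[seq_len(headerEnd)]) {
    if (startsWith(ln, "format-version:"))
      meta$format_version <- trimws(sub("^format-version:", "", ln))
    if (startsWith(ln, "data-version:"))
      meta$data_version <- trimws(sub("^data-version:", "", ln))
  }

  ids <- character(); nms <- character(); nss <- character()
  obs <- logical()
  isa <- list()
  relChild <- character(); relType <- character(); relParent <- character()
  altFrom <- character(); altTo <- character()

  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) != "[Term]") { i <- i + 1L; next }
    at <- i; i <- i + 1L
    id <- NA_character_; name <- ""; ns <- NA_character_
    obsolete <- FALSE
    myIsa <- character(); myRelT <- character(); myRelP <- character()
    myAlt <- character()
    while (i <= n && !grepl("^\\[", lines[i])) {
      ln <- lines[i]; i <- i + 1L
      if (!nzchar(trimws(ln)) || startsWith(ln, "!")) next
      colon <- regexpr(":", ln, fixed = TRUE)
      if (colon < 0)
        stop("malformed stanza line ", i - 1L, ": ", ln)
      key <- substr(ln, 1L, colon - 1L)
      val <- trimws(substr(ln, colon + 1L, nchar(ln)))
      switch(key,
        id = { id <- .stripOboComment(val) },
        name = { name <- val },
        namespace = { ns <- .stripOboComment(val) },
        is_a = { myIsa <- c(myIsa, .stripOboComment(val)) },
        alt_id = { myAlt <- c(myAlt, .stripOboComment(val)) },
        is_obsolete = { obsolete <- identical(.stripOboComment(val), "true") },
        relationship = {
          parts <- strsplit(.stripOboComment(val), "\\s+")[[1]]
          if (length(parts) != 2L)
            stop("malformed relationship at line ", i - 1L, ": ", ln)
          myRelT <- c(myRelT, parts[1]); myRelP <- c(myRelP, parts[2])
        },
        NULL)
    }
    if (is.na(id) || !grepl(GO_ID_REGEX, id))
      stop("malformed stanza starting at line ", at, ": missing or bad id")
    if (is.na(ns))
      stop("malformed stanza starting at line ", at, " (", id,
           "): missing namespace")
    if (!ns %in% GO_NAMESPACES)
      stop("unknown namespace '", ns, "' for ", id)
    ids <- c(ids, id); nms <- c(nms, name); nss <- c(nss, ns)
    obs <- c(obs, obsolete)
    isa[[id]] <- if (obsolete) character() else unique(myIsa)
    if (!obsolete && length(myRelT)) {
      keep <- .foldRelType(myRelT) %in% keepFolded
      relChild <- c(relChild, rep(id, sum(keep)))
      relType <- c(relType, myRelT[keep])
      relParent <- c(relParent, myRelP[keep])
    }
    if (length(myAlt)) {
      altFrom <- c(altFrom, myAlt); altTo <- c(altTo, rep(id, length(myAlt)))
    }
  }
  if (!length(ids)) stop("no [Term] stanzas found")

  terms <- data.frame(id = ids, name = nms, namespace = nss, obsolete = obs,
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL

  # drop edges that point at obsolete or unknown terms
  obsSet <- ids[obs]
  isa <- lapply(isa, function(p) setdiff(p, obsSet))
  unknown <- setdiff(unlist(isa, use.names = FALSE), ids)
  if (length(unknown))
    stop("is_a edge to unknown term: ", unknown[1])
  keepRel <- !(relParent %in% obsSet)
  relChild <- relChild[keepRel]; relType <- relType[keepRel]
  relParent <- relParent[keepRel]
  unknown <- setdiff(relParent, ids)
  if (length(unknown))
    stop("relationship edge to unknown term: ", unknown[1])

  nsOf <- stats::setNames(nss, ids)
  # cross-namespace edges are errors
  for (child in names(isa)) {
    p <- isa[[child]]
    if (length(p) && any(nsOf[p] != nsOf[child]))
      stop("cross-namespace is_a edge from ", child)
  }
  if (length(relChild) && any(nsOf[relParent] != nsOf[relChild]))
    stop("cross-namespace relationship edge from ",
         relChild[which(nsOf[relParent] != nsOf[relChild])[1]])

  alt <- stats::setNames(altTo, altFrom)
  alt <- alt[!names(alt) %in% ids]

  relParents <- data.frame(child = relChild, type = relType,
                           parent = relParent, stringsAsFactors = FALSE)

  # roots: exactly one parentless non-obsolete term per namespace
  roots <- character()
  for (ns in unique(nss[!obs])) {
    inNs <- ids[nss == ns & !obs]
    parentless <- inNs[lengths(isa[inNs]) == 0L]
    if (length(parentless) != 1L)
      stop("namespace ", ns, " has ", length(parentless),
           " root terms; expected exactly 1")
    roots[[ns]] <- parentless
  }

  g <- new("OntologyGraph", terms = terms, isaParents = isa,
           relParents = relParents, keptRelationships = keepFolded,
           roots = roots, altIndex = alt, meta = meta)
  cyc <- .findCycleMember(g, c("part_of", "regulates"))
  if (!is.na(cyc))
    stop("ontology graph is cyclic; cycle includes ", cyc)
  g
}

#' Write an OntologyGraph as canonical OBO text
#'
#' Emits a deterministic OBO 1.2 rendering (terms sorted by id, fields in a
#' fixed order) so that write/read/write round trips are byte-identical.
#'
#' @param graph an [OntologyGraph-class].
#' @param path output file path; if \code{NULL} the lines are returned.
#' @return invisibly (or visibly when \code{path} is \code{NULL}) the lines.
#' @export
writeObo <- function(graph, path = NULL) {
  out <- c(paste0("format-version: ", graph@meta$format_version))
  if (nzchar(graph@meta$data_version))
    out <- c(out, paste0("data-version: ", graph@meta$data_version))
  tr <- graph@terms[order(graph@terms$id), , drop = FALSE]
  rel <- graph@relParents
  for (k in seq_len(nrow(tr))) {
    id <- tr$id[k]
    out <- c(out, "", "[Term]", paste0("id: ", id),
             paste0("name: ", tr$name[k]),
             paste0("namespace: ", tr$namespace[k]))
    alts <- sort(names(graph@altIndex)[graph@altIndex == id])
    out <- c(out, sprintf("alt_id: %s", alts))
    out <- c(out, sprintf("is_a: %s", sort(graph@isaParents[[id]])))
    if (nrow(rel)) {
      mine <- rel[rel$child == id, , drop = FALSE]
      mine <- mine[order(mine$type, mine$parent), , drop = FALSE]
      out <- c(out, sprintf("relationship: %s %s", mine$type, mine$parent))
    }
    if (tr$obsolete[k]) out <- c(out, "is_obsolete: true")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Resolve a GO identifier to its primary id
#'
#' @param graph an [OntologyGraph-class].
#' @param id a primary or alternative GO id (vectorised).
#' @return the primary id(s); identity for primary ids.
#' @export
resolveId <- function(graph, id) {
  out <- id
  isAlt <- id %in% names(graph@altIndex)
  out[isAlt] <- unname(graph@altIndex[id[isAlt]])
  unknown <- !(out %in% graph@terms$id)
  if (any(unknown))
    stop("unknown GO id: ", paste(unique(id[unknown]), collapse = ", "))
  out
}

## ---- edge-set helpers -----------------------------------------------------

# named list id -> parents over is_a plus the selected relationship types;
# obsolete terms excluded. edgeTypes uses folded names ("regulates" selects
# the signed subtypes too).
.parentMap <- function(graph, edgeTypes = character()) {
  pm <- graph@isaParents
  live <- graph@terms$id[!graph@terms$obsolete]
  pm <- pm[live]
  edgeTypes <- unique(.foldRelType(edgeTypes))
  if (length(edgeTypes) && nrow(graph@relParents)) {
    rel <- graph@relParents
    rel <- rel[.foldRelType(rel$type) %in% edgeTypes, , drop = FALSE]
    if (nrow(rel)) {
      extra <- split(rel$parent, rel$child)
      for (child in names(extra))
        pm[[child]] <- unique(c(pm[[child]], extra[[child]]))
    }
  }
  pm
}

# exact inverse of .parentMap
.childMap <- function(graph, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  child <- rep(names(pm), lengths(pm))
  parent <- unlist(pm, use.names = FALSE)
  cm <- stats::setNames(vector("list", length(pm)), names(pm))
  if (length(child)) {
    sp <- split(child, parent)
    cm[names(sp)] <- sp
  }
  cm
}

# Kahn topological order (parents before children); returns ids, or NULL if
# a cycle exists
.topoOrder <- function(pm) {
  ids <- names(pm)
  idx <- stats::setNames(seq_along(ids), ids)
  nParent <- lengths(pm)
  childList <- vector("list", length(ids))
  for (ci in seq_along(ids)) {
    for (p in pm[[ci]]) {
      pi <- idx[[p]]
      childList[[pi]] <- c(childList[[pi]], ci)
    }
  }
  queue <- which(nParent == 0L)
  order <- integer(0)
  nP <- nParent
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ci in childList[[v]]) {
      nP[ci] <- nP[ci] - 1L
      if (nP[ci] == 0L) queue <- c(queue, ci)
    }
  }
  if (length(order) != length(ids)) return(NULL)
  ids[order]
}

# returns NA if acyclic, else the id of one term on a cycle
.findCycleMember <- function(graph, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  if (!is.null(.topoOrder(pm))) return(NA_character_)
  # strip terms whose parents have all been stripped; leftovers feed cycles
  repeat {
    removable <- names(pm)[vapply(pm, function(p) !any(p %in% names(pm)),
                                  logical(1))]
    if (!length(removable) || !length(pm)) break
    pm <- pm[!names(pm) %in% removable]
  }
  # walk parent edges inside the leftover set until a node repeats
  cur <- names(pm)[1]
  seen <- character()
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    cur <- intersect(pm[[cur]], names(pm))[1]
  }
  cur
}

#' Check a graph for acyclicity over a chosen edge set
#'
#' @param graph an [OntologyGraph-class].
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return \code{TRUE} iff no directed cycle exists over the selected edges.
#' @export
validateAcyclic <- function(graph, edgeTypes = character()) {
  !is.null(.topoOrder(.parentMap(graph, edgeTypes)))
}

## ---- traversal ------------------------------------------------------------

# ancestors of id over the chosen edge set (BFS up); optionally inclusive
.ancestorsOf <- function(pm, id, inclusive = FALSE) {
  seen <- character(); frontier <- id
  while (length(frontier)) {
    parents <- unique(unlist(pm[frontier], use.names = FALSE))
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  if (inclusive) unique(c(id, seen)) else seen
}

.descendantsOf <- function(cm, id, inclusive = FALSE) {
  .ancestorsOf(cm, id, inclusive)  # same BFS on the inverted map
}

#' Ancestor terms of a GO term
#'
#' @param graph an [OntologyGraph-class].
#' @param id a primary GO id.
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @param inclusive include \code{id} itself.
#' @return character vector of ancestor ids.
#' @export
goAncestors <- function(graph, id, edgeTypes = character(),
                        inclusive = FALSE) {
  pm <- .parentMap(graph, edgeTypes)
  if (!id %in% names(pm)) stop("unknown or obsolete term: ", id)
  .ancestorsOf(pm, id, inclusive)
}

#' Descendant terms of a GO term
#'
#' @inheritParams goAncestors
#' @return character vector of descendant ids.
#' @export
goDescendants <- function(graph, id, edgeTypes = character(),
                          inclusive = FALSE) {
  cm <- .childMap(graph, edgeTypes)
  if (!id %in% names(cm)) stop("unknown or obsolete term: ", id)
  .descendantsOf(cm, id, inclusive)
}

## ---- accessors ------------------------------------------------------------

#' Term table of an ontology graph
#' @param graph an [OntologyGraph-class].
#' @return data.frame with columns id, name, namespace, obsolete.
#' @export
goTerms <- function(graph) graph@terms

#' Namespace roots
#' @param graph an [OntologyGraph-class].
#' @return named character vector, namespace -> root id.
#' @export
goRoots <- function(graph) graph@roots

#' Direct parents of a term
#' @inheritParams goAncestors
#' @return character vector of parent ids.
#' @export
goParents <- function(graph, id, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  if (!id %in% names(pm)) stop("unknown or obsolete term: ", id)
  pm[[id]]
}

#' Direct children of a term
#' @inheritParams goAncestors
#' @return character vector of child ids.
#' @export
goChildren <- function(graph, id, edgeTypes = character()) {
  cm <- .childMap(graph, edgeTypes)
  if (!id %in% names(cm)) stop("unknown or obsolete term: ", id)
  cm[[id]] %||% character()
}

#' Human-readable name of a term
#' @param graph an [OntologyGraph-class].
#' @param id primary GO id(s).
#' @return character vector of names.
#' @export
goName <- function(graph, id) {
  m <- match(id, graph@terms$id)
  if (anyNA(m)) stop("unknown GO id: ", id[which(is.na(m))[1]])
  graph@terms$name[m]
}

#' Namespace of a term
#' @param graph an [OntologyGraph-class].
#' @param id primary GO id(s).
#' @return character vector of namespaces.
#' @export
goNamespace <- function(graph, id) {
  m <- match(id, graph@terms$id)
  if (anyNA(m)) stop("unknown GO id: ", id[which(is.na(m))[1]])
  graph@terms$namespace[m]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
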