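## Annotation readers (GAF 2.x, NCBI gene2go, GPAD) and association building.

# canonical empty record frame; qualifiers is a list-column of character sets
.emptyRecords <- function() {
  data.frame(gene = character(), go_id = character(),
             evidence = character(), aspect = character(),
             taxon = integer(), stringsAsFactors = FALSE)
}

.recordsFrame <- function(gene, go_id, qualifiers, evidence, aspect, taxon) {
  out <- data.frame(gene = gene, go_id = go_id, evidence = evidence,
                    aspect = aspect, taxon = taxon, stringsAsFactors = FALSE)
  out$qualifiers <- qualifiers
  out
}

.splitQualifiers <- function(x) {
  lapply(x, function(q) {
    if (is.na(q) || !nzchar(q) || q == "-") character()
    else strsplit(q, "|", fixed = TRUE)[[1]]
  })
}

#' Read a GAF 2.x annotation file
#'
#' Expects the 17-column tab-separated GO Annotation Format; lines starting
#' with \code{"!"} are comments. Columns mapped: 2 (DB Object ID), 4
#' (Qualifier, pipe-separated), 5 (GO ID), 7 (Evidence), 9 (Aspect) and 13
#' (Taxon, first \code{taxon:NNNN} entry).
#'
#' @param path file path or character vector of lines.
#' @return data.frame of annotation records with columns \code{gene},
#'   \code{go_id}, \code{evidence}, \code{aspect}, \code{taxon} and a
#'   list-column \code{qualifiers}.
#' @export
readGaf <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.emptyRecords())
  # sentinel keeps trailing empty fields that strsplit would drop
  fields <- lapply(strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nf <- lengths(fields)
  if (any(nf != 17L))
    stop("GAF line ", lineNo[which(nf != 17L)[1]], " has ",
         nf[which(nf != 17L)[1]], " columns; expected 17")
  m <- do.call(rbind, fields)
  taxon <- vapply(strsplit(m[, 13], "|", fixed = TRUE), function(tx) {
    tx <- tx[startsWith(tx, "taxon:")]
    if (!length(tx)) NA_integer_ else as.integer(sub("^taxon:", "", tx[1]))
  }, integer(1))
  .recordsFrame(gene = m[, 2], go_id = m[, 5],
                qualifiers = .splitQualifiers(m[, 4]),
                evidence = m[, 7], aspect = m[, 9], taxon = taxon)
}

#' Write annotation records as canonical GAF 2.2 text
#'
#' Unknown GAF columns are filled with fixed defaults so that
#' write/read/write round trips are byte-identical.
#'
#' @param records data.frame as returned by [readGaf()].
#' @param path output path; if \code{NULL} the lines are returned.
#' @param db database label for column 1.
#' @return invisibly the lines written.
#' @export
writeGaf <- function(records, path = NULL, db = "DB") {
  hdr <- "!gaf-version: 2.2"
  qual <- vapply(records$qualifiers, function(q)
    if (length(q)) paste(q, collapse = "|") else "involved_in", character(1))
  taxon <- ifelse(is.na(records$taxon), "taxon:0",
                  paste0("taxon:", records$taxon))
  rows <- paste(db, records$gene, records$gene, qual, records$go_id,
                "GO_REF:0000000", records$evidence, "", records$aspect,
                "", "", "protein", taxon, "20180101", db, "", "",
                sep = "\t")
  out <- c(hdr, rows)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read an NCBI gene2go annotation file
#'
#' Expects the 8-column tab format with header
#' \code{#tax_id GeneID GO_ID Evidence Qualifier GO_term PubMed Category}.
#' The Category values Process/Function/Component map to aspects P/F/C and
#' the Qualifier \code{"-"} maps to the empty set.
#'
#' @param path file path or character vector of lines.
#' @param taxonFilter optional integer: keep only records for this taxon.
#' @return data.frame of annotation records (see [readGaf()]).
#' @export
readGene2go <- function(path, taxonFilter = NULL) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.emptyRecords())
  fields <- lapply(strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop("gene2go line ", lineNo[which(nf < 8L)[1]],
         " has fewer than 8 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:8))
  aspect <- c(Process = "P", Function = "F", Component = "C")[m[, 8]]
  rec <- .recordsFrame(gene = m[, 2], go_id = m[, 3],
                       qualifiers = .splitQualifiers(m[, 5]),
                       evidence = m[, 4],
                       aspect = ifelse(is.na(aspect), "", aspect),
                       taxon = as.integer(m[, 1]))
  if (!is.null(taxonFilter))
    rec <- rec[!is.na(rec$taxon) & rec$taxon == taxonFilter, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Read a GPAD annotation file
#'
#' Supports GPAD 1.1 (12 tab-separated columns; columns 2/3/4/6 give the
#' object id, qualifier, GO id and ECO evidence code) and GPAD 2.0
#' (header-declared; column 1 holds \code{DB:ObjectID}). The aspect is left
#' blank and inferred from the graph when the association is built.
#'
#' @param path file path or character vector of lines.
#' @return data.frame of annotation records (see [readGaf()]).
#' @export
readGpad <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  version <- "1.1"
  hdr <- lines[startsWith(lines, "!")]
  verLine <- grep("^!\\s*(gpa|gpad)-version:", hdr, value = TRUE)
  if (length(verLine)) {
    v <- trimws(sub("^!\\s*(gpa|gpad)-version:", "", verLine[1]))
    if (grepl("^1\\.", v)) version <- "1.1"
    else if (grepl("^2\\.", v)) version <- "2.0"
    else stop("unknown GPAD version header: ", v)
  }
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.emptyRecords())
  fields <- lapply(strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  nf <- lengths(fields)
  minCols <- if (version == "1.1") 10L else 9L
  if (any(nf < minCols))
    stop("GPAD line ", lineNo[which(nf < minCols)[1]], " is too short")
  if (version == "1.1") {
    gene <- vapply(fields, `[`, character(1), 2L)
    qual <- vapply(fields, `[`, character(1), 3L)
    goid <- vapply(fields, `[`, character(1), 4L)
    evid <- vapply(fields, `[`, character(1), 6L)
  } else {
    obj <- vapply(fields, `[`, character(1), 1L)
    gene <- sub("^[^:]+:", "", obj)
    qual <- vapply(fields, `[`, character(1), 3L)
    goid <- vapply(fields, `[`, character(1), 4L)
    evid <- vapply(fields, `[`, character(1), 6L)
  }
  .recordsFrame(gene = gene, go_id = goid,
                qualifiers = .splitQualifiers(qual),
                evidence = evid, aspect = "", taxon = NA_integer_)
}

#' Build a GeneAssociation from annotation records
#'
#' Filters records (NOT-qualified annotations, excluded evidence codes,
#' terms outside the requested namespace), resolves alternative ids against
#' the graph and builds the gene/term indexes with set semantics.
#'
#' @param records data.frame of annotation records (see [readGaf()]).
#' @param graph an [OntologyGraph-class].
#' @param namespace the namespace to keep.
#' @param evidenceExclude evidence codes to drop (default: keep all,
#'   including IEA).
#' @param dropNot drop records whose qualifiers contain \code{"NOT"}
#'   (default \code{TRUE}).
#' @param strict error (instead of warn-and-drop) on unresolvable GO ids.
#' @param warnAlt emit a warning when alternative ids are silently resolved.
#' @return a [GeneAssociation-class].
#' @export
buildAssociation <- function(records, graph,
                             namespace = "biological_process",
                             evidenceExclude = character(),
                             dropNot = TRUE, strict = FALSE,
                             warnAlt = FALSE) {
  stopifnot(namespace %in% GO_NAMESPACES)
  if (!nrow(records))
    return(.newAssociation(list(), namespace))
  keep <- rep(TRUE, nrow(records))
  if (dropNot && !is.null(records$qualifiers))
    keep <- keep & !vapply(records$qualifiers, function(q) "NOT" %in% q,
                           logical(1))
  if (length(evidenceExclude))
    keep <- keep & !(records$evidence %in% evidenceExclude)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records))
    return(.newAssociation(list(), namespace))

  ids <- records$go_id
  isAlt <- ids %in% names(graph@altIndex)
  if (any(isAlt)) {
    if (warnAlt)
      warning(sum(isAlt), " annotation(s) used alternative GO ids; resolved")
    ids[isAlt] <- unname(graph@altIndex[ids[isAlt]])
  }
  known <- ids %in% graph@terms$id
  if (any(!known)) {
    bad <- unique(records$go_id[!known])
    if (strict)
      stop("unresolvable GO id(s) in annotations: ",
           paste(utils::head(bad, 5), collapse = ", "))
    warning("dropping ", sum(!known), " annotation(s) with unresolvable ",
            "GO ids (e.g. ", bad[1], ")")
  }
  records <- records[known, , drop = FALSE]
  ids <- ids[known]
  m <- match(ids, graph@terms$id)
  obsolete <- graph@terms$obsolete[m]
  if (any(obsolete)) {
    warning("dropping ", sum(obsolete), " annotation(s) to obsolete terms")
    records <- records[!obsolete, , drop = FALSE]
    ids <- ids[!obsolete]; m <- m[!obsolete]
  }
  nsOk <- graph@terms$namespace[m] == namespace
  # aspect/namespace conflicts resolve in favour of the graph's namespace
  if (!is.null(records$aspect)) {
    asp <- c(biological_process = "P", molecular_function = "F",
             cellular_component = "C")[[namespace]]
    conflict <- nsOk & nzchar(records$aspect) & records$aspect != asp
    if (any(conflict))
      warning(sum(conflict), " record(s) had an aspect conflicting with ",
              "the term namespace; the graph's namespace wins")
  }
  records <- records[nsOk, , drop = FALSE]
  ids <- ids[nsOk]
  g2t <- lapply(split(ids, records$gene), unique)
  .newAssociation(g2t, namespace)
}

#' Close every gene's term set under is_a ancestors
#'
#' Augments the association so that each gene is annotated to every ancestor
#' (up to and including the namespace root) of its directly annotated terms.
#' The input association is unmodified; propagation is idempotent by
#' construction and refused on an already-propagated association.
#'
#' @param assoc a [GeneAssociation-class] with \code{propagated = FALSE}.
#' @param graph an [OntologyGraph-class].
#' @return a propagated [GeneAssociation-class].
#' @export
propagateCounts <- function(assoc, graph) {
  if (assoc@propagated)
    stop("association is already propagated")
  ancIncl <- .ancestorClosureMap(graph)
  g2t <- lapply(assoc@gene2terms, function(ts)
    unique(unlist(ancIncl[ts], use.names = FALSE)))
  .newAssociation(g2t, assoc@namespace, propagated = TRUE)
}

# inclusive is_a ancestor closure for every non-obsolete term, via one DP
# pass over a topological order
.ancestorClosureMap <- function(graph) {
  pm <- .parentMap(graph, character())
  ord <- .topoOrder(pm)
  anc <- stats::setNames(vector("list", length(ord)), ord)
  for (id in ord) {
    ps <- pm[[id]]
    anc[[id]] <- if (length(ps))
      unique(c(id, unlist(anc[ps], use.names = FALSE))) else id
  }
  anc
}

#' Remove all annotations of selected (typically very broad) terms
#'
#' @param assoc a [GeneAssociation-class].
#' @param termIds terms whose gene-term pairs are removed from both
#'   directions of the index; ids not present are ignored.
#' @return a [GeneAssociation-class].
#' @export
pruneBroadTerms <- function(assoc, termIds) {
  if (!length(termIds)) return(assoc)
  g2t <- lapply(assoc@gene2terms, function(ts) setdiff(ts, termIds))
  .newAssociation(g2t, assoc@namespace, propagated = assoc@propagated)
}

## ---- accessors ------------------------------------------------------------

#' Gene-to-term map of an association
#' @param assoc a [GeneAssociation-class].
#' @return named list gene -> character vector of term ids.
#' @export
gene2Terms <- function(assoc) assoc@gene2terms

#' Term-to-gene map of an association
#' @param assoc a [GeneAssociation-class].
#' @return named list term id -> character vector of genes.
#' @export
term2Genes <- function(assoc) assoc@term2genes

#' Number of distinct gene-term pairs
#' @param assoc a [GeneAssociation-class].
#' @return integer.
#' @export
nAnnotations <- function(assoc) assoc@nAnnotations

#' Has the association been closed under ancestors?
#' @param assoc a [GeneAssociation-class].
#' @return logical.
#' @export
isPropagated <- function(assoc) assoc@propagated
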