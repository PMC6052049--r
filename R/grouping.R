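## Two-step grouping of GOEA results: broad GO headers first, then
## researcher-named sections; plus the sections-file workflow, hierarchy
## reports and DOT export.

#' Build a header-candidate set for grouping
#'
#' @param graph an [OntologyGraph-class].
#' @param candidates character vector of candidate header term ids.
#' @param metric \code{"dcnt"} (descendant count; species- and
#'   annotation-agnostic) or \code{"tinfo"} (information content; requires
#'   \code{tctable}).
#' @param tctable a \code{TermCountsTable} from [termCounts()], required for
#'   the \code{tinfo} metric; candidates without a defined information
#'   content rank last.
#' @param edgeTypes relationship types used for the grouping hierarchy and
#'   the dcnt metric (default \code{part_of} + \code{regulates}).
#' @return an object of class \code{HeaderSet}.
#' @export
headerSet <- function(graph, candidates, metric = c("dcnt", "tinfo"),
                      tctable = NULL,
                      edgeTypes = c("part_of", "regulates")) {
  metric <- match.arg(metric)
  candidates <- unique(candidates)
  stopifnot(all(candidates %in% graph@terms$id))
  obs <- graph@terms$obsolete[match(candidates, graph@terms$id)]
  candidates <- candidates[!obs]
  dcnt <- .allDcnt(graph, edgeTypes)
  dl <- computeDepthLevel(graph, edgeTypes)
  depth <- stats::setNames(dl$depth, dl$id)
  mv <- if (metric == "dcnt") {
    as.numeric(dcnt[candidates])
  } else {
    if (is.null(tctable))
      stop("the tinfo metric requires an association-derived TermCountsTable")
    ti <- tctable$tinfo[candidates]
    ifelse(is.na(ti), Inf, as.numeric(ti))
  }
  structure(list(candidates = candidates, metric = metric,
                 metricValues = stats::setNames(mv, candidates),
                 dcnt = dcnt, depth = depth, edgeTypes = edgeTypes),
            class = "HeaderSet")
}

#' @export
print.HeaderSet <- function(x, ...) {
  cat("HeaderSet:", length(x$candidates), "candidate headers, metric",
      x$metric, "\n")
  invisible(x)
}

#' Default header candidates: GO slims plus all depth-01 terms
#'
#' The default first-step headers are the GO-slim terms (if any) together
#' with every depth-01 term of the graph, plus any user-supplied headers;
#' obsolete terms are excluded.
#'
#' @param graph an [OntologyGraph-class].
#' @param slimIds GO-slim term ids (e.g. read from goslim_generic.obo).
#' @param userHeaders additional headers, typically from a sections file.
#' @inheritParams headerSet
#' @return a \code{HeaderSet}.
#' @export
defaultHeaders <- function(graph, slimIds = character(),
                           userHeaders = character(),
                           metric = c("dcnt", "tinfo"), tctable = NULL,
                           edgeTypes = c("part_of", "regulates")) {
  dl <- computeDepthLevel(graph, edgeTypes)
  d1 <- dl$id[dl$depth == 1L]
  headerSet(graph, unique(c(slimIds, d1, userHeaders)), metric = metric,
            tctable = tctable, edgeTypes = edgeTypes)
}

#' Choose the most specific header for a term
#'
#' Among the candidate headers that are the term itself or one of its
#' ancestors (over the grouping edge set), returns the one with the minimal
#' metric value (smallest dcnt or tinfo, i.e. the most specific). Ties break
#' by smaller dcnt, then greater depth, then lexicographic id.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a primary GO id.
#' @param headers a \code{HeaderSet}.
#' @return the chosen header id, or \code{NA_character_} when no candidate
#'   is an ancestor of the term.
#' @export
chooseHeader <- function(graph, term, headers) {
  pm <- .parentMap(graph, headers$edgeTypes)
  if (!term %in% names(pm)) stop("unknown or obsolete term: ", term)
  anc <- .ancestorsOf(pm, term, inclusive = TRUE)
  cand <- intersect(headers$candidates, anc)
  if (!length(cand)) return(NA_character_)
  ord <- order(headers$metricValues[cand], headers$dcnt[cand],
               -headers$depth[cand], cand)
  cand[ord[1]]
}

#' Sections specification
#'
#' An ordered list of researcher-named sections, each holding an ordered
#' list of GO header ids. The implicit final section \code{"Misc."} holds
#' everything unassigned and is never user-declared.
#'
#' @param sections named list: section name -> character vector of header
#'   ids, in display order.
#' @return an object of class \code{SectionsSpec}.
#' @export
sectionsSpec <- function(sections = list()) {
  if (length(sections)) {
    if (is.null(names(sections)) || any(!nzchar(names(sections))))
      stop("every section needs a non-empty name")
    if ("Misc." %in% names(sections))
      stop("'Misc.' is implicit and may not be declared")
    all_ids <- unlist(sections, use.names = FALSE)
    if (anyDuplicated(all_ids))
      stop("header ids must be unique across sections")
  }
  structure(list(sections = sections), class = "SectionsSpec")
}

#' @export
print.SectionsSpec <- function(x, ...) {
  cat("SectionsSpec with", length(x$sections), "sections\n")
  for (nm in names(x$sections))
    cat("  ", nm, ": ", length(x$sections[[nm]]), " headers\n", sep = "")
  invisible(x)
}

# section name of each header under a spec (first match wins), "Misc."
# when unlisted
.sectionOfHeader <- function(spec, headerIds) {
  out <- rep("Misc.", length(headerIds))
  names(out) <- headerIds
  for (nm in names(spec$sections)) {
    hit <- headerIds %in% spec$sections[[nm]] & out == "Misc."
    out[hit] <- nm
  }
  # first-match rule: earlier sections claimed first because later loops
  # only fill ids still at "Misc."
  out
}

#' Group GO terms (or enrichment records) under headers and sections
#'
#' The first grouping step assigns every term to its most specific candidate
#' header ([chooseHeader()]); the second assigns each header to the first
#' section that lists it, or to the implicit \code{"Misc."} section. All
#' input terms are retained: terms with no candidate ancestor header appear
#' in the \code{ungrouped} component (inside \code{Misc.} in reports).
#'
#' @param x a character vector of GO ids, or a data.frame of enrichment
#'   records with a \code{GO} column (e.g. from [runGoea()]).
#' @param graph an [OntologyGraph-class].
#' @param headers a \code{HeaderSet}.
#' @param sections a \code{SectionsSpec} (default: empty, everything under
#'   \code{Misc.}).
#' @param sortKey column of \code{x} used to order members within a header,
#'   ascending (default: the first \code{p_}-prefixed column when \code{x}
#'   is a record frame, else descendant count descending then id).
#' @return an object of class \code{GroupedReport}: a list with
#'   \code{entries} (data.frame: \code{section}, \code{header}, \code{GO},
#'   any record columns), \code{ungrouped} (same shape, header \code{NA}),
#'   and \code{sections}.
#' @export
groupTerms <- function(x, graph, headers, sections = sectionsSpec(),
                       sortKey = NULL) {
  recs <- if (is.data.frame(x)) x else
    data.frame(GO = unique(x), stringsAsFactors = FALSE)
  if (!"GO" %in% names(recs)) stop("records need a GO column")
  if (anyDuplicated(recs$GO)) stop("duplicate GO ids in input")
  recs$GO <- resolveId(graph, recs$GO)
  if (is.null(sortKey)) {
    pcols <- grep("^p_", names(recs), value = TRUE)
    sortKey <- if (length(pcols)) pcols[1] else NA_character_
  } else if (!sortKey %in% names(recs)) {
    stop("unknown sort key: ", sortKey)
  }
  hdr <- vapply(recs$GO, function(t) chooseHeader(graph, t, headers),
                character(1))
  sec <- rep("Misc.", length(hdr))
  grouped <- !is.na(hdr)
  sec[grouped] <- .sectionOfHeader(sections, hdr[grouped])
  recs$header <- unname(hdr)
  recs$section <- sec

  memberOrd <- function(df) {
    if (!is.na(sortKey)) order(df[[sortKey]], df$GO)
    else order(-headers$dcnt[df$GO], df$GO)
  }
  secNames <- c(names(sections$sections), "Misc.")
  entryList <- list()
  for (nm in secNames) {
    inSec <- recs[recs$section == nm & !is.na(recs$header), , drop = FALSE]
    if (!nrow(inSec)) next
    hdrs <- unique(inSec$header)
    hdrs <- if (nm == "Misc.") {
      hdrs[order(-headers$dcnt[hdrs], hdrs)]
    } else {
      declared <- sections$sections[[nm]]
      c(intersect(declared, hdrs), sort(setdiff(hdrs, declared)))
    }
    for (h in hdrs) {
      mem <- inSec[inSec$header == h, , drop = FALSE]
      entryList[[length(entryList) + 1L]] <- mem[memberOrd(mem), ,
                                                 drop = FALSE]
    }
  }
  entries <- if (length(entryList)) do.call(rbind, entryList) else
    recs[0, , drop = FALSE]
  ungrouped <- recs[is.na(recs$header), , drop = FALSE]
  ungrouped <- ungrouped[memberOrd(ungrouped), , drop = FALSE]
  rownames(entries) <- NULL; rownames(ungrouped) <- NULL
  front <- c("section", "header", "GO")
  entries <- entries[, c(front, setdiff(names(entries), front)),
                     drop = FALSE]
  ungrouped <- ungrouped[, names(entries), drop = FALSE]
  structure(list(entries = entries, ungrouped = ungrouped,
                 sections = sections, headers = headers),
            class = "GroupedReport")
}

#' @export
print.GroupedReport <- function(x, ...) {
  cat("GroupedReport:", nrow(x$entries), "grouped,",
      nrow(x$ungrouped), "ungrouped GO terms\n")
  tab <- table(x$entries$section)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

## ---- sections files -------------------------------------------------------

#' Read a sections file
#'
#' Grammar: section lines \code{"# SECTION: <name>"}; member lines begin
#' with a GO id and everything after \code{"#"} is ignored; blank lines are
#' ignored. A \code{Misc.} section (written by the workflow for unassigned
#' headers) is dropped on read since it is always recalculated.
#'
#' @param path file path or character vector of lines.
#' @return a \code{SectionsSpec}.
#' @export
readSections <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  sections <- list()
  current <- NA_character_
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^#\\s*SECTION:\\s*(.+)$", ln))[[1]]
    if (length(m) == 2L) {
      current <- trimws(m[2])
      if (current != "Misc." && is.null(sections[[current]]))
        sections[[current]] <- character()
      next
    }
    if (grepl("^GO:[0-9]{7}", ln)) {
      id <- sub("^(GO:[0-9]{7}).*$", "\\1", ln)
      if (!is.na(current) && current != "Misc.")
        sections[[current]] <- c(sections[[current]], id)
    }
  }
  sectionsSpec(sections)
}

#' Write a sections specification in canonical plain form
#'
#' @param spec a \code{SectionsSpec}.
#' @param path output path; if \code{NULL} the lines are returned.
#' @return invisibly the lines written.
#' @export
writeSections <- function(spec, path = NULL) {
  out <- character()
  for (nm in names(spec$sections))
    out <- c(out, paste0("# SECTION: ", nm), spec$sections[[nm]])
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

.nsAbbrev <- c(biological_process = "BP", molecular_function = "MF",
               cellular_component = "CC")

# annotated header line: id, namespace, user-GO count, dcnt, level, depth,
# name
.annotatedHeaderLine <- function(graph, id, nUsr, headers, dl) {
  m <- match(id, graph@terms$id)
  d <- dl[match(id, dl$id), ]
  sprintf("%s # %s %5d uGOs %6d L%02d D%02d %s", id,
          .nsAbbrev[[graph@terms$namespace[m]]], nUsr,
          headers$dcnt[[id]], d$level, d$depth, graph@terms$name[m])
}

#' Sections-file workflow: group user GO ids and (re)write report files
#'
#' Runs the two-step grouping of \code{goids} guided by a sections input
#' file. When \code{sectionsIn} does not exist it is first written with
#' every currently active header (the headers chosen for the input GO ids)
#' listed under \code{"# SECTION: Misc."}. \code{sectionsOut} (the input
#' spec with the Misc. area recalculated and every header annotated with
#' its user-GO count, dcnt, level and depth) and \code{groupedOut} (the full
#' grouping) are always written. Console-style summary lines, e.g.
#' \code{"usr GOs(98 in 1 sections, 742 ungrpd)"}, are emitted with
#' \code{message()}.
#'
#' @param goids character vector of user GO ids (or a path readable by
#'   [readGeneList()]).
#' @param graph an [OntologyGraph-class].
#' @param sectionsIn path of the sections input file.
#' @param sectionsOut path of the re-annotated sections file (default
#'   \code{sections.txt} next to \code{sectionsIn}).
#' @param groupedOut path of the grouped report (default
#'   \code{grouped_gos.txt} next to \code{sectionsIn}).
#' @param slimIds optional GO-slim header candidates.
#' @param metric,tctable passed to [defaultHeaders()].
#' @param edgeTypes grouping edge set.
#' @return invisibly a list of summary counts (\code{nGoids},
#'   \code{nGrouped}, \code{nUngrouped}, \code{nSectionHeaders},
#'   \code{nSections}, \code{nUnusedHeaders}) and the written paths.
#' @export
wrSectionsWorkflow <- function(goids, graph, sectionsIn,
                               sectionsOut = file.path(dirname(sectionsIn),
                                                       "sections.txt"),
                               groupedOut = file.path(dirname(sectionsIn),
                                                      "grouped_gos.txt"),
                               slimIds = character(),
                               metric = "dcnt", tctable = NULL,
                               edgeTypes = c("part_of", "regulates")) {
  if (length(goids) == 1L && file.exists(goids))
    goids <- readGeneList(goids)
  if (!length(goids)) stop("no user GO ids given")
  goids <- unique(resolveId(graph, goids))
  dl <- computeDepthLevel(graph, edgeTypes)

  haveIn <- file.exists(sectionsIn)
  spec <- if (haveIn) readSections(sectionsIn) else sectionsSpec()
  userHeaders <- unlist(spec$sections, use.names = FALSE)
  headers <- defaultHeaders(graph, slimIds = slimIds,
                            userHeaders = userHeaders, metric = metric,
                            tctable = tctable, edgeTypes = edgeTypes)
  grouped <- groupTerms(goids, graph, headers, spec)
  ent <- grouped$entries
  usedHeaders <- unique(ent$header)
  usrPerHeader <- table(ent$header)
  inSections <- ent$section != "Misc."
  nGrouped <- sum(inSections)
  nUngrouped <- length(goids) - nGrouped
  sectionHeaders <- unique(ent$header[inSections])
  unusedHeaders <- setdiff(usedHeaders, sectionHeaders)
  nSec <- length(unique(ent$section[inSections]))

  hline <- function(ids) vapply(ids, function(h) {
    cnt <- if (h %in% names(usrPerHeader)) usrPerHeader[[h]] else 0L
    .annotatedHeaderLine(graph, h, cnt, headers, dl)
  }, character(1), USE.NAMES = FALSE)
  miscOrder <- function(ids) ids[order(-headers$dcnt[ids], ids)]

  if (!haveIn) {
    out <- c("# Grouping hints: move headers out of Misc. into named",
             "# sections ('# SECTION: <name>') to group the user GO ids.",
             "# SECTION: Misc.", hline(miscOrder(usedHeaders)))
    writeLines(out, sectionsIn)
    message(sprintf("hdr GOs(0 in 0 sections, %d unused) WROTE: %s",
                    length(usedHeaders), sectionsIn))
  } else {
    message(sprintf("hdr GOs(%d in %d sections, N/A unused) READ: %s",
                    length(sectionHeaders), nSec, sectionsIn))
  }

  out <- character()
  for (nm in names(spec$sections)) {
    out <- c(out, paste0("# SECTION: ", nm))
    for (h in spec$sections[[nm]]) out <- c(out, hline(h))
  }
  out <- c(out, "# SECTION: Misc.", hline(miscOrder(unusedHeaders)))
  writeLines(out, sectionsOut)
  message(sprintf("hdr GOs(%d in %d sections, %d unused) WROTE: %s",
                  length(sectionHeaders), nSec, length(unusedHeaders),
                  sectionsOut))

  gline <- function(df) vapply(seq_len(nrow(df)), function(i) {
    id <- df$GO[i]
    m <- match(id, graph@terms$id)
    d <- dl[match(id, dl$id), ]
    sprintf("%s # %s %6d L%02d D%02d %s", id,
            .nsAbbrev[[graph@terms$namespace[m]]], headers$dcnt[[id]],
            d$level, d$depth, graph@terms$name[m])
  }, character(1))
  gout <- character()
  for (nm in unique(ent$section)) {
    gout <- c(gout, paste0("# SECTION: ", nm))
    inSec <- ent[ent$section == nm, , drop = FALSE]
    for (h in unique(inSec$header)) {
      gout <- c(gout, paste0("# HDR ", hline(h)))
      gout <- c(gout, gline(inSec[inSec$header == h, , drop = FALSE]))
    }
    if (nm == "Misc." && nrow(grouped$ungrouped)) {
      gout <- c(gout, "# UNGROUPED", gline(grouped$ungrouped))
    }
  }
  if (!"Misc." %in% ent$section && nrow(grouped$ungrouped))
    gout <- c(gout, "# SECTION: Misc.", "# UNGROUPED",
              gline(grouped$ungrouped))
  writeLines(gout, groupedOut)
  message(sprintf("usr GOs(%d in %d sections, %d ungrpd) WROTE: %s",
                  nGrouped, nSec, nUngrouped, groupedOut))
  message(sprintf("%d user GO IDs", length(goids)))

  invisible(list(nGoids = length(goids), nGrouped = nGrouped,
                 nUngrouped = nUngrouped,
                 nSectionHeaders = length(sectionHeaders),
                 nSections = nSec, nUnusedHeaders = length(unusedHeaders),
                 sectionsIn = sectionsIn, sectionsOut = sectionsOut,
                 groupedOut = groupedOut, grouped = grouped))
}

## ---- hierarchy report and DOT export --------------------------------------

#' Text report of the hierarchy above or below a term
#'
#' One line per term on the paths between the term and its namespace root
#' (\code{"up"}) or in the sub-DAG below it (\code{"down"}). Lines are
#' indented with one dash per depth level plus one
#' (\code{"- GO:... <dcnt> D<depth> <name>"}); marked terms get a
#' \code{"> "} prefix. Each term is printed once, at its first depth-first
#' encounter; children are visited by descending descendant count.
#'
#' @param graph an [OntologyGraph-class].
#' @param term the query term (primary GO id).
#' @param direction \code{"up"} or \code{"down"}.
#' @param mark terms to prefix with \code{">"} (default the query term).
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return character vector of report lines.
#' @export
hierReport <- function(graph, term, direction = c("up", "down"),
                       mark = term, edgeTypes = character()) {
  direction <- match.arg(direction)
  pm <- .parentMap(graph, edgeTypes)
  if (!term %in% names(pm)) stop("unknown or obsolete term: ", term)
  cm <- .childMap(graph, edgeTypes)
  dl <- computeDepthLevel(graph, edgeTypes)
  depth <- stats::setNames(dl$depth, dl$id)
  dcnt <- .allDcnt(graph, edgeTypes)
  if (direction == "up") {
    keep <- .ancestorsOf(pm, term, inclusive = TRUE)
    start <- graph@roots[[goNamespace(graph, term)]]
  } else {
    keep <- .descendantsOf(cm, term, inclusive = TRUE)
    start <- term
  }
  lines <- character()
  seen <- character()
  visit <- function(id) {
    if (id %in% seen) return(invisible())
    seen <<- c(seen, id)
    prefix <- if (id %in% mark) "> " else ""
    lines <<- c(lines, sprintf("%s%s %s %d D%02d %s", prefix,
                               strrep("-", depth[[id]] + 1L), id,
                               dcnt[[id]], depth[[id]], goName(graph, id)))
    kids <- intersect(cm[[id]] %||% character(), keep)
    for (k in kids[order(-dcnt[kids], kids)]) visit(k)
  }
  visit(start)
  lines
}

#' Export an induced ancestor sub-DAG as DOT text
#'
#' Emits a GraphViz \code{digraph} of the terms and all their ancestors over
#' the chosen edge set. Node labels carry the id, dcnt, level/depth, name
#' and (optionally) section; header terms get a distinct border.
#'
#' @param graph an [OntologyGraph-class].
#' @param termIds terms whose ancestor closure is drawn.
#' @param headers optional \code{HeaderSet}; its candidates present in the
#'   drawing are emphasised.
#' @param sectionOf optional named character: term id -> section name shown
#'   in the label.
#' @param significanceColors optional named character: term id -> fill
#'   colour.
#' @param edgeTypes relationship types to include besides \code{is_a}.
#' @return character vector of DOT lines.
#' @export
exportDot <- function(graph, termIds, headers = NULL, sectionOf = NULL,
                      significanceColors = NULL, edgeTypes = character()) {
  pm <- .parentMap(graph, edgeTypes)
  termIds <- resolveId(graph, unique(termIds))
  nodes <- sort(unique(unlist(lapply(termIds, function(t)
    .ancestorsOf(pm, t, inclusive = TRUE)), use.names = FALSE)))
  dl <- computeDepthLevel(graph, edgeTypes)
  dcnt <- .allDcnt(graph, edgeTypes)
  esc <- function(x) gsub('"', '\\\\"', x)
  out <- c("digraph GO {", "  node [shape=box];")
  for (id in nodes) {
    d <- dl[match(id, dl$id), ]
    lab <- sprintf("%s d%d L%02d D%02d\\n%s", id, dcnt[[id]], d$level,
                   d$depth, esc(goName(graph, id)))
    if (!is.null(sectionOf) && id %in% names(sectionOf))
      lab <- paste0(lab, "\\n", esc(sectionOf[[id]]))
    attrs <- sprintf('label="%s"', lab)
    if (!is.null(headers) && id %in% headers$candidates)
      attrs <- paste0(attrs, ', color=blue, penwidth=2')
    if (!is.null(significanceColors) && id %in% names(significanceColors))
      attrs <- paste0(attrs, sprintf(', style=filled, fillcolor="%s"',
                                     significanceColors[[id]]))
    out <- c(out, sprintf('  "%s" [%s];', id, attrs))
  }
  for (id in nodes) {
    for (p in intersect(pm[[id]], nodes))
      out <- c(out, sprintf('  "%s" -> "%s";', p, id))
  }
  c(out, "}")
}
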