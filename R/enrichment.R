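## Over/under-representation testing: two-sided Fisher's exact test,
## multiple-test corrections, the GOEA driver and report writers.

SUPPORTED_METHODS <- c("bonferroni", "sidak", "holm", "fdr_bh", "fdr_by",
                       "fdr_resampling")

# two-sided Fisher P for vectors of study counts k against a common
# (studyN, popN); K varies per entry. Sums the hypergeometric probabilities
# of all tables with the same margins whose point probability does not
# exceed the observed one (relative tie tolerance 1e-7, the fisher.test
# convention).
.fisherVecSameMargins <- function(k, K, studyN, popN) {
  p <- numeric(length(k))
  degen <- studyN == 0L | K == 0L | K == popN
  p[degen] <- 1
  todo <- which(!degen)
  if (!length(todo)) return(p)
  j <- 0:studyN
  # dhyper recycles over the K's column-wise with outer-style expansion
  M <- outer(j, K[todo], function(jj, KK)
    stats::dhyper(jj, KK, popN - KK, studyN))
  obs <- M[cbind(k[todo] + 1L, seq_along(todo))]
  keep <- M <= rep(obs * (1 + 1e-7), each = length(j))
  p[todo] <- pmin(1, colSums(M * keep))
  p
}

#' Two-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Computes the two-sided Fisher P-value for the table (study genes
#' annotated to a term out of the study size, against population genes
#' annotated out of the population size): the sum of hypergeometric
#' probabilities of all tables with the same margins whose point probability
#' is at most that of the observed table. Degenerate margins (empty study,
#' or a term annotating no or all population genes) give P = 1 by
#' convention. All arguments are vectorised.
#'
#' @param studyCount genes in the study annotated to the term.
#' @param studyN study size.
#' @param popCount population genes annotated to the term.
#' @param popN population size.
#' @return numeric vector of P-values in [0, 1].
#' @examples
#' fisherExactTwoSided(5, 5, 5, 10)  # 2/252
#' @export
fisherExactTwoSided <- function(studyCount, studyN, popCount, popN) {
  n <- max(length(studyCount), length(studyN), length(popCount),
           length(popN))
  studyCount <- rep_len(studyCount, n); studyN <- rep_len(studyN, n)
  popCount <- rep_len(popCount, n); popN <- rep_len(popN, n)
  if (any(studyCount < 0 | studyCount > studyN | popCount < 0 |
          popCount > popN | studyCount > popCount | studyN > popN))
    stop("invalid contingency table")
  out <- numeric(n)
  for (grp in split(seq_len(n), paste(studyN, popN))) {
    out[grp] <- .fisherVecSameMargins(studyCount[grp], popCount[grp],
                                      studyN[grp[1]], popN[grp[1]])
  }
  out
}

#' Direction of an enrichment table
#'
#' \code{'e'} (enriched) iff the study annotation ratio strictly exceeds the
#' population ratio, else \code{'p'} (purified / under-represented); equal
#' ratios are classified \code{'p'} so that \code{'e'} stays conservative.
#'
#' @inheritParams fisherExactTwoSided
#' @return character vector of \code{'e'} / \code{'p'}.
#' @export
classifyDirection <- function(studyCount, studyN, popCount, popN) {
  n <- max(length(studyCount), length(studyN), length(popCount),
           length(popN))
  studyCount <- rep_len(studyCount, n); studyN <- rep_len(studyN, n)
  popCount <- rep_len(popCount, n); popN <- rep_len(popN, n)
  sr <- ifelse(studyN > 0, studyCount / studyN, 0)
  pr <- ifelse(popN > 0, popCount / popN, 0)
  ifelse(sr > pr, "e", "p")
}

#' Multiple-test correction of a P-value vector
#'
#' Supported methods: \code{bonferroni} (\code{min(1, m p)}), \code{sidak}
#' (\code{1 - (1 - p)^m}), \code{holm} (step-down), \code{fdr_bh} and
#' \code{fdr_by} (step-up with enforced monotonicity) and
#' \code{fdr_resampling} (permutation estimate; see Details). The output is
#' order-aligned with the input.
#'
#' @details The resampling FDR draws \code{B} random study sets of the
#' observed study size uniformly from the population, recomputes the
#' uncorrected P-values over the same tested-term rule, and estimates the
#' corrected P for an observed value p0 as the mean over resamples of
#' (number of resample P-values <= p0) divided by the observed number of
#' P-values <= p0 (at least 1), capped at 1. Deterministic given
#' \code{seed}.
#'
#' @param pvals numeric vector of P-values.
#' @param method one of the supported method names.
#' @param alpha significance level (unused by the closed-form methods).
#' @param resampleContext for \code{fdr_resampling}: list with elements
#'   \code{study} (the observed study genes), \code{population},
#'   \code{assoc} (a [GeneAssociation-class]; already propagated if the
#'   analysis was) and optionally \code{universePolicy}.
#' @param seed integer seed for the resampling method.
#' @param B number of resamples (default 500).
#' @return numeric vector, same length and order as \code{pvals}.
#' @export
correctPvalues <- function(pvals, method, alpha = 0.05,
                           resampleContext = NULL, seed = NULL, B = 500) {
  if (!method %in% SUPPORTED_METHODS)
    stop("unknown correction method: ", method)
  m <- length(pvals)
  if (!m) return(numeric())
  switch(method,
    bonferroni = stats::p.adjust(pvals, "bonferroni"),
    holm = stats::p.adjust(pvals, "holm"),
    fdr_bh = stats::p.adjust(pvals, "BH"),
    fdr_by = stats::p.adjust(pvals, "BY"),
    sidak = pmin(1, 1 - (1 - pvals)^m),
    fdr_resampling = .fdrResampling(pvals, resampleContext, seed, B))
}

.fdrResampling <- function(pvals, ctx, seed, B) {
  if (is.null(ctx) || is.null(ctx$study) || is.null(ctx$population) ||
      is.null(ctx$assoc))
    stop("fdr_resampling needs a resampleContext with study, population ",
         "and assoc")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nStudy <- length(ctx$study)
  pop <- ctx$population
  obsLe <- vapply(pvals, function(p0) sum(pvals <= p0), numeric(1))
  acc <- numeric(length(pvals))
  for (b in seq_len(B)) {
    rs <- sample(pop, nStudy)
    pb <- .goeaPvalues(rs, pop, ctx$assoc,
                       ctx$universePolicy %||% "study")$p
    acc <- acc + vapply(pvals, function(p0) sum(pb <= p0), numeric(1))
  }
  pmin(1, (acc / B) / pmax(1, obsLe))
}

# uncorrected p-values for one study draw; the core counting shared by
# runGoea and the resampling FDR. Returns term ids, counts and p.
.goeaPvalues <- function(study, population, assoc, universePolicy) {
  g2t <- assoc@gene2terms
  popN <- length(population)
  studyTerms <- unlist(g2t[intersect(study, names(g2t))], use.names = FALSE)
  counts <- table(studyTerms)
  if (universePolicy == "population") {
    allTerms <- names(assoc@term2genes)
    k <- integer(length(allTerms))
    names(k) <- allTerms
    k[names(counts)] <- as.integer(counts)
    terms <- allTerms
  } else {
    terms <- names(counts)
    k <- as.integer(counts)
    names(k) <- terms
  }
  if (!length(terms))
    return(list(terms = character(), k = integer(), K = integer(),
                p = numeric()))
  K <- lengths(assoc@term2genes[terms])
  p <- fisherExactTwoSided(unname(k), length(study), unname(K), popN)
  list(terms = terms, k = unname(k), K = unname(K), p = p)
}

#' Run a gene ontology enrichment analysis
#'
#' Tests every term annotating at least one study gene (the default tested
#' universe; \code{universePolicy = "population"} tests every
#' population-annotated term) with a two-sided Fisher's exact test, labels
#' each term enriched (\code{'e'}) or purified (\code{'p'}), and applies the
#' requested multiple-test corrections jointly over all tested terms.
#'
#' @param study character vector of study gene ids (a subset of
#'   \code{population}; genes outside it are dropped with a warning, or an
#'   error when \code{strict}).
#' @param population character vector of population gene ids.
#' @param assoc a [GeneAssociation-class]; genes outside the population are
#'   ignored for the population counts.
#' @param graph an [OntologyGraph-class].
#' @param alpha significance level carried in the result attributes.
#' @param methods character vector of correction methods (see
#'   [correctPvalues()]); one result column \code{p_<method>} each.
#' @param propagate close the association under is_a ancestors before
#'   testing (no-op if already propagated).
#' @param universePolicy \code{"study"} (default) or \code{"population"}.
#' @param strict error instead of warn on study genes missing from the
#'   population.
#' @param addMetrics annotate records with term depth and descendant count
#'   (set \code{FALSE} for speed in simulations).
#' @param seed,B passed to the resampling FDR when requested.
#' @return data.frame of enrichment records sorted by uncorrected P then GO
#'   id, with columns \code{GO}, \code{NS}, \code{enrichment}, \code{name},
#'   \code{study_count}, \code{study_n}, \code{pop_count}, \code{pop_n},
#'   \code{p_uncorrected}, \code{depth}, \code{dcnt}, one \code{p_<method>}
#'   column per correction, and a list-column \code{study_items}.
#' @export
runGoea <- function(study, population, assoc, graph, alpha = 0.05,
                    methods = "fdr_bh", propagate = FALSE,
                    universePolicy = c("study", "population"),
                    strict = FALSE, addMetrics = TRUE, seed = NULL,
                    B = 500) {
  universePolicy <- match.arg(universePolicy)
  stopifnot(alpha > 0, alpha < 1)
  bad <- setdiff(methods, SUPPORTED_METHODS)
  if (length(bad)) stop("unknown correction method: ", bad[1])
  study <- unique(study); population <- unique(population)
  missing <- setdiff(study, population)
  if (length(missing)) {
    if (strict) stop(length(missing), " study gene(s) not in the population")
    warning("dropping ", length(missing),
            " study gene(s) not in the population")
    study <- setdiff(study, missing)
  }
  if (propagate && !assoc@propagated)
    assoc <- propagateCounts(assoc, graph)
  # restrict the association to population genes if it covers others
  extra <- setdiff(names(assoc@gene2terms), population)
  if (length(extra))
    assoc <- .newAssociation(assoc@gene2terms[setdiff(
      names(assoc@gene2terms), extra)], assoc@namespace, assoc@propagated)
  res <- .goeaPvalues(study, population, assoc, universePolicy)
  if (!length(res$terms)) {
    out <- data.frame(GO = character(), NS = character(),
                      enrichment = character(), name = character(),
                      study_count = integer(), study_n = integer(),
                      pop_count = integer(), pop_n = integer(),
                      p_uncorrected = numeric(), depth = integer(),
                      dcnt = integer(), stringsAsFactors = FALSE)
    for (mth in methods) out[[paste0("p_", mth)]] <- numeric()
    out$study_items <- list()
    attr(out, "alpha") <- alpha
    return(out)
  }
  studyN <- length(study); popN <- length(population)
  direction <- classifyDirection(res$k, studyN, res$K, popN)
  out <- data.frame(GO = res$terms,
                    NS = assoc@namespace,
                    enrichment = direction,
                    name = NA_character_,
                    study_count = res$k, study_n = studyN,
                    pop_count = unname(res$K), pop_n = popN,
                    p_uncorrected = res$p,
                    depth = NA_integer_, dcnt = NA_integer_,
                    stringsAsFactors = FALSE)
  known <- match(out$GO, graph@terms$id)
  out$name <- ifelse(is.na(known), "", graph@terms$name[known])
  if (addMetrics) {
    dl <- computeDepthLevel(graph)
    dcnt <- .allDcnt(graph)
    m <- match(out$GO, dl$id)
    out$depth <- dl$depth[m]
    out$dcnt <- unname(dcnt[out$GO])
  }
  for (mth in methods) {
    ctx <- if (mth == "fdr_resampling")
      list(study = study, population = population, assoc = assoc,
           universePolicy = universePolicy)
    out[[paste0("p_", mth)]] <- correctPvalues(out$p_uncorrected, mth,
                                               alpha, ctx, seed, B)
  }
  # study items: study genes annotated to each tested term (inverted from
  # the study genes' own term sets, which is cheap)
  sg <- intersect(study, names(assoc@gene2terms))
  g2t <- assoc@gene2terms[sg]
  si <- split(rep(sg, lengths(g2t)), unlist(g2t, use.names = FALSE))
  out$study_items <- lapply(out$GO, function(t) sort(si[[t]] %||% character()))
  ord <- order(out$p_uncorrected, out$GO)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Filter enrichment records for significance
#'
#' @param records data.frame from [runGoea()].
#' @param method correction whose \code{p_<method>} column is compared
#'   (\code{"uncorrected"} uses \code{p_uncorrected}).
#' @param alpha significance level; the comparison is strict (\code{<}).
#' @param directions subset of \code{c("e", "p")} to keep.
#' @return the significant records, input order preserved.
#' @export
significantRecords <- function(records, method = "fdr_bh", alpha = 0.05,
                               directions = c("e", "p")) {
  col <- if (identical(method, "uncorrected")) "p_uncorrected"
         else paste0("p_", method)
  if (!col %in% names(records))
    stop("no column ", col, " in the records; was this method run?")
  keep <- records[[col]] < alpha & records$enrichment %in% directions
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a study or population gene list
#'
#' One gene id per line; \code{"#"} comments (whole-line or trailing) and
#' blank lines are ignored.
#'
#' @param path file path or character vector of lines.
#' @return character vector of unique gene ids, input order.
#' @export
readGeneList <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) &&
               file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Write enrichment records as TSV
#'
#' Pinned column order: GO, NS, enrichment, name, ratio_in_study (k/n),
#' ratio_in_pop (K/N), p_uncorrected, depth, dcnt, one column per correction
#' method present, study_items (comma-joined, sorted).
#'
#' @param records data.frame from [runGoea()].
#' @param path output path; if \code{NULL} the lines are returned.
#' @return invisibly the lines written.
#' @export
writeGoeaTsv <- function(records, path = NULL) {
  pcols <- grep("^p_(?!uncorrected)", names(records), value = TRUE,
                perl = TRUE)
  hdr <- c("GO", "NS", "enrichment", "name", "ratio_in_study",
           "ratio_in_pop", "p_uncorrected", "depth", "dcnt", pcols,
           "study_items")
  rows <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(c(r$GO, r$NS, r$enrichment, r$name,
            sprintf("%d/%d", r$study_count, r$study_n),
            sprintf("%d/%d", r$pop_count, r$pop_n),
            format(r$p_uncorrected, digits = 6),
            as.character(r$depth), as.character(r$dcnt),
            vapply(pcols, function(cn) format(r[[cn]], digits = 6),
                   character(1)),
            paste(sort(r$study_items[[1]]), collapse = ",")),
          collapse = "\t")
  }, character(1))
  out <- c(paste(hdr, collapse = "\t"), rows)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write enrichment records as JSON
#'
#' @param records data.frame from [runGoea()].
#' @param path output path.
#' @return invisibly the path.
#' @export
writeGoeaJson <- function(records, path) {
  recs <- records
  recs$study_items <- vapply(records$study_items, function(g)
    paste(sort(g), collapse = ","), character(1))
  jsonlite::write_json(recs, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
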