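## Stochastic GOEA simulation framework: gene-level FDR, sensitivity and
## specificity over a grid of study sizes and true-null fractions.

#' Parameters for a simulation grid
#'
#' The study gene lists mix two kinds of randomly chosen genes: target
#' genes (a coherent, truly enriched pool; true positives when discovered)
#' and background ("true null") genes (false positives when discovered).
#'
#' @param targetPool character vector of target genes (the truly enriched
#'   pool, e.g. 124 humoral-response genes).
#' @param backgroundPool character vector: the population minus the target
#'   pool. Must be disjoint from \code{targetPool}.
#' @param studySizes integer vector of study-set sizes.
#' @param nullFractions numeric vector in [0, 1]: fraction of each study
#'   drawn from the background pool.
#' @param reps simulated GOEAs per grid cell.
#' @param alpha significance level.
#' @param method multiple-test correction (default Benjamini-Hochberg).
#' @param propagate close the association under is_a ancestors before
#'   testing.
#' @param viewing \code{"enriched_only"} counts a gene as discovered only
#'   through terms with direction \code{'e'}; \code{"both_directions"} also
#'   counts under-represented terms.
#' @param universePolicy tested-term rule handed to [runGoea()]. The
#'   default \code{"population"} corrects over every population-annotated
#'   term, the multiplicity under which gene-level FDR control holds;
#'   \code{"study"} corrects only over terms hit by the study.
#' @param seed integer master seed; per-cell substreams are derived from it
#'   so cells are order-independent.
#' @return an object of class \code{SimParams}.
#' @export
simParams <- function(targetPool, backgroundPool, studySizes = c(4, 16, 64,
                      124), nullFractions = c(0, 0.25, 0.5, 0.75, 1),
                      reps = 100, alpha = 0.05, method = "fdr_bh",
                      propagate = TRUE,
                      viewing = c("enriched_only", "both_directions"),
                      universePolicy = c("population", "study"),
                      seed = 1) {
  viewing <- match.arg(viewing)
  universePolicy <- match.arg(universePolicy)
  stopifnot(reps >= 1, alpha > 0, alpha < 1,
            all(nullFractions >= 0 & nullFractions <= 1),
            method %in% SUPPORTED_METHODS)
  if (length(intersect(targetPool, backgroundPool)))
    stop("target and background pools must be disjoint")
  structure(list(targetPool = targetPool, backgroundPool = backgroundPool,
                 studySizes = as.integer(studySizes),
                 nullFractions = nullFractions, reps = as.integer(reps),
                 alpha = alpha, method = method, propagate = propagate,
                 viewing = viewing, universePolicy = universePolicy,
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' @export
print.SimParams <- function(x, ...) {
  cat("SimParams:", length(x$targetPool), "target /",
      length(x$backgroundPool), "background genes;",
      length(x$studySizes), "sizes x", length(x$nullFractions),
      "fractions x", x$reps, "reps;", x$viewing, "\n")
  invisible(x)
}

#' Draw one simulated study set
#'
#' \code{round(size * nullFraction)} background genes plus the remainder of
#' target genes, each sampled without replacement from its pool.
#'
#' @param params a \code{SimParams}.
#' @param size study size.
#' @param nullFraction fraction of true-null genes.
#' @return list with \code{genes} and logical \code{isNull} labels.
#' @export
drawStudySet <- function(params, size, nullFraction) {
  nNull <- round(size * nullFraction)
  nTarget <- size - nNull
  if (nNull > length(params$backgroundPool))
    stop("requested ", nNull, " null genes but the background pool has ",
         length(params$backgroundPool))
  if (nTarget > length(params$targetPool))
    stop("requested ", nTarget, " target genes but the target pool has ",
         length(params$targetPool))
  genes <- c(if (nTarget) sample(params$targetPool, nTarget),
             if (nNull) sample(params$backgroundPool, nNull))
  list(genes = genes,
       isNull = c(rep(FALSE, nTarget), rep(TRUE, nNull)))
}

#' Gene-level confusion counts for one simulated GOEA
#'
#' A study gene is "discovered" iff it appears among the study items of at
#' least one significant record (the caller filters records by direction
#' and significance first). Targets discovered are true positives; nulls
#' discovered are false positives.
#'
#' @param genes study genes.
#' @param isNull logical labels aligned with \code{genes}.
#' @param sigRecords significant records (from [significantRecords()]).
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
geneConfusion <- function(genes, isNull, sigRecords) {
  discovered <- genes %in% unique(unlist(sigRecords$study_items,
                                         use.names = FALSE))
  c(TP = sum(discovered & !isNull), FP = sum(discovered & isNull),
    TN = sum(!discovered & isNull), FN = sum(!discovered & !isNull))
}

#' Run the full simulation grid
#'
#' For every (study size, null fraction) cell, draws \code{reps} study
#' sets, runs a GOEA on each (two-sided Fisher, the configured correction),
#' filters significant records by the viewing rule and aggregates the
#' per-rep gene-level false discovery rate (\code{FP / (FP + TP)}, with
#' 0/0 counted as 0), sensitivity and specificity. Sensitivity is reported
#' as \code{NA} for all-null cells and specificity as \code{NA} for
#' no-null cells. Fully deterministic given the seed; cells use derived
#' substreams so their order does not matter.
#'
#' @param params a \code{SimParams}.
#' @param assoc a [GeneAssociation-class] covering both pools.
#' @param graph an [OntologyGraph-class].
#' @return data.frame with one row per cell: \code{size}, \code{null_frac},
#'   mean and standard error of \code{fdr}, \code{sensitivity},
#'   \code{specificity}, the mean discovery count and \code{reps}.
#' @export
runGrid <- function(params, assoc, graph) {
  if (params$propagate && !assoc@propagated)
    assoc <- propagateCounts(assoc, graph)
  population <- c(params$targetPool, params$backgroundPool)
  directions <- if (params$viewing == "enriched_only") "e" else c("e", "p")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  cells <- expand.grid(size = params$studySizes,
                       null_frac = params$nullFractions,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  for (ci in seq_len(nrow(cells))) {
    size <- cells$size[ci]; frac <- cells$null_frac[ci]
    cellSeed <- (params$seed %% 100000L) * 20011L + size * 101L +
      round(frac * 1000) * 7L
    set.seed(cellSeed %% 2147483647L)
    fdr <- sens <- spc <- disc <- numeric(params$reps)
    for (r in seq_len(params$reps)) {
      draw <- drawStudySet(params, size, frac)
      recs <- runGoea(draw$genes, population, assoc, graph,
                      alpha = params$alpha, methods = params$method,
                      propagate = FALSE,
                      universePolicy = params$universePolicy,
                      addMetrics = FALSE)
      sig <- significantRecords(recs, params$method, params$alpha,
                                directions)
      cf <- geneConfusion(draw$genes, draw$isNull, sig)
      fdr[r] <- if (cf[["TP"]] + cf[["FP"]] == 0L) 0 else
        cf[["FP"]] / (cf[["TP"]] + cf[["FP"]])
      sens[r] <- if (cf[["TP"]] + cf[["FN"]] == 0L) NA_real_ else
        cf[["TP"]] / (cf[["TP"]] + cf[["FN"]])
      spc[r] <- if (cf[["TN"]] + cf[["FP"]] == 0L) NA_real_ else
        cf[["TN"]] / (cf[["TN"]] + cf[["FP"]])
      disc[r] <- cf[["TP"]] + cf[["FP"]]
    }
    sensOk <- sens[!is.na(sens)]; spcOk <- spc[!is.na(spc)]
    rows[[ci]] <- data.frame(
      size = size, null_frac = frac,
      fdr_mean = mean(fdr), fdr_se = se(fdr),
      sensitivity_mean = if (length(sensOk)) mean(sensOk) else NA_real_,
      sensitivity_se = if (length(sensOk)) se(sensOk) else NA_real_,
      specificity_mean = if (length(spcOk)) mean(spcOk) else NA_real_,
      specificity_se = if (length(spcOk)) se(spcOk) else NA_real_,
      discoveries_mean = mean(disc), reps = params$reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shuffle the associations of true-null genes
#'
#' Randomly permutes the term-sets held by the given null genes among those
#' same genes (a stress test: the multiset of annotation profiles is
#' preserved exactly); all other genes are untouched.
#'
#' @param assoc a [GeneAssociation-class].
#' @param nullGenes genes whose term sets are permuted.
#' @return a [GeneAssociation-class].
#' @export
shuffleTrueNullAssociations <- function(assoc, nullGenes) {
  g2t <- assoc@gene2terms
  present <- intersect(nullGenes, names(g2t))
  if (length(present) > 1L)
    g2t[present] <- g2t[sample(present)]
  .newAssociation(g2t, assoc@namespace, propagated = assoc@propagated)
}

#' Write a simulation grid as TSV
#'
#' Long format: one row per cell and metric, columns size, null_frac,
#' metric, mean, se, reps.
#'
#' @param grid data.frame from [runGrid()].
#' @param path output path; if \code{NULL} the lines are returned.
#' @return invisibly the lines written.
#' @export
writeGridTsv <- function(grid, path = NULL) {
  out <- "size\tnull_frac\tmetric\tmean\tse\treps"
  for (i in seq_len(nrow(grid))) {
    for (metric in c("fdr", "sensitivity", "specificity")) {
      out <- c(out, sprintf("%d\t%g\t%s\t%s\t%s\t%d", grid$size[i],
                            grid$null_frac[i], metric,
                            format(grid[[paste0(metric, "_mean")]][i],
                                   digits = 6),
                            format(grid[[paste0(metric, "_se")]][i],
                                   digits = 6),
                            grid$reps[i]))
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
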