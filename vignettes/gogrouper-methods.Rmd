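---
title: "GOgrouper: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GOgrouper: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOgrouper)
```

GOgrouper does three things: it runs gene ontology enrichment analyses
(GOEAs), it organizes their results with a two-step grouping method, and it
validates GOEA behaviour with a stochastic simulation framework that
measures *gene-level* error rates. This vignette explains the statistical
model behind each part, the parameters that matter, and the design choices
that were genuinely open.

## The ontology model

An ontology is parsed from OBO 1.2 text into an `OntologyGraph`: a directed
acyclic graph with one node per term and typed edges. `is_a` edges are
always kept; `part_of` and `regulates` edges (the signed
`positively_regulates`/`negatively_regulates` subtypes fold into
`regulates` for traversal, but are preserved on the record) are opt-in per
call site. The two conventions coexist deliberately:

* **annotation propagation and term counts use `is_a` only** — an
  annotation to a part does not imply an annotation to the whole, so
  gene-count semantics stay conservative;
* **descendant counts and grouping default to
  `is_a + part_of + regulates`** — when judging how *broad* a term is, all
  hierarchy edges carry information.

Both are exposed as `edgeTypes` arguments. Obsolete terms are loaded (so
lookups resolve) but carry no edges and are excluded from every traversal
and candidate set. Cross-namespace edges are rejected as parse errors, and
each namespace must have exactly one root.

Per-term structural metrics follow the usual definitions: *depth* is the
longest edge path from the namespace root down to the term, *level* the
shortest, and *dcnt* the number of distinct descendants (0 for leaves).
Depth-01 terms receive alias letters A, B, C, ... in order of decreasing
dcnt (ties by id; lowercase letters past 26), and a term's alias string
concatenates the letters of all its depth-01 ancestors — a compact "where
in the DAG" signature.

Given an association, a term's *information content* is
`tinfo = -log(frequency)` with the natural log, where frequency is the
descendant-inclusive count of distinct genes annotated to the term divided
by the count at the namespace root. Choosing the root count as the branch
total makes the root's frequency exactly 1 and its `tinfo` 0, which is the
behaviour wanted from an "uninformative" term; terms with no annotations
have no defined `tinfo` and rank last when used as a grouping metric.
Resnik similarity is the maximum `tinfo` over common `is_a` ancestors
(terms included), and Lin similarity is `2*resnik/(tinfo(a)+tinfo(b))`,
defined 0 when the denominator is 0.

## The enrichment test

For a study set of $n$ genes from a population of $N$, a term annotating
$K$ population genes and $k$ study genes is tested with the two-sided
Fisher's exact test: the sum of hypergeometric point probabilities, over
all tables with the same margins, that do not exceed the observed table's
point probability. Ties are compared with a relative tolerance of $10^{-7}$
(the convention of `stats::fisher.test`, against which the implementation
is cross-checked); the implementation itself enumerates `dhyper` mass
vectorized over terms, which is what makes thousands of simulated GOEAs
per minute feasible. Degenerate margins ($n = 0$, $K = 0$ or $K = N$) give
$P = 1$ by convention — notably the namespace root under propagated
annotations.

A term is labelled enriched (`'e'`) iff $k/n > K/N$ strictly, else purified
(`'p'`); the tie goes to `'p'` so that `'e'` stays conservative.

Multiple-test corrections: Bonferroni, Holm, Benjamini-Hochberg and
Benjamini-Yekutieli delegate to `stats::p.adjust`; Sidak
($1-(1-p)^m$) and a resampling FDR are implemented here. The resampling
FDR draws $B$ (default 500) random study sets of the observed size
uniformly from the population, recomputes the uncorrected P-values under
the same tested-term rule, and estimates the corrected value for an
observed $p_0$ as the mean over resamples of the count of resample
P-values $\le p_0$, divided by the observed count $\le p_0$ (at least 1),
capped at 1 — a standard plug-in estimate of expected false over observed
discoveries, deterministic given a seed.

**The tested universe** is a real modelling choice. By default `runGoea`
tests every term annotating at least one study gene and corrects jointly
over that set (across namespaces, if several are tested in one run; a
per-namespace run is just a separate call). The alternative,
`universePolicy = "population"`, tests every population-annotated term.
The difference matters for *gene-level* error rates: under the study-only
universe, the multiplicity $m$ shrinks to the handful of terms the study
happens to touch, and Benjamini-Hochberg's step-up lets a single
null-gene term with a moderate P-value become significant by riding on the
truly enriched terms' tiny P-values. The simulation framework therefore
corrects over the population universe (see below), which is also what
mature GOEA tools do when they compute a record for every annotated term.
Comparisons against alpha are strict (`<`) everywhere.

## The two-step grouping method

A GOEA can return hundreds of significant terms in a flat list. Grouping
rearranges — never filters — that list in two steps:

1. **headers**: every result term is assigned to its *most specific*
   candidate header, i.e. the candidate that is the term itself or an
   ancestor (over the grouping edge set) with the minimal metric value.
   The candidate set defaults to the GO-slim terms plus *all* depth-01
   terms, plus any user-added headers. The metric is `dcnt`
   (annotation-independent) or `tinfo` (requires an association; requesting
   it without one is an error). Metric ties break by smaller dcnt, then
   greater depth, then id — three deterministic, documented levels, since
   ties must resolve the same way on every run.
2. **sections**: each header is assigned to the first researcher-named
   section that lists it; unlisted headers fall into the implicit final
   `Misc.` section. Terms with no candidate ancestor at all are reported as
   "ungrouped" inside `Misc.` rather than erroring, so the output always
   conserves the input exactly once.

Within a header, members sort by P-value when the records carry one, else
by descending dcnt then id. The sections file dialect is plain text:
`# SECTION: <name>` lines followed by member lines that begin with a GO id;
everything after `#` on a member line is ignored on read, so the writer can
annotate headers with user-GO counts, dcnt, level and depth without
breaking round trips. The `wrSectionsWorkflow` function reproduces the
iterative workflow: on a first run it writes a `sections_in.txt` skeleton
with every active header under `Misc.`; the researcher moves headers into
named sections and re-runs; `sections.txt` and `grouped_gos.txt` are
always rewritten deterministically. The exact column layout of the
annotated files is this package's own (self-consistent and stable), not
claimed byte-compatible with any other tool's.

`hierReport` prints the paths between a term and its root (or the sub-DAG
below it) one line per term, dash-indented by depth, each term once at its
first depth-first encounter with children visited by descending dcnt; query
terms are marked with a leading `"> "`. `exportDot` emits the induced
ancestor sub-DAG as GraphViz DOT with headers emphasised — a placement aid
for header decisions, not a figure renderer.

## The stochastic simulation framework

The framework asks: *if I run a GOEA on a study set with a known truth,
how often are individual genes falsely implicated?* Study sets mix
`round(size * nullFraction)` background ("true null") genes with target
genes from a coherent pool. After the GOEA, a study gene counts as
**discovered** if it is annotated to at least one significant term that
passes the viewing rule (`enriched_only` or `both_directions`). Discovered
targets are true positives, discovered nulls false positives; per
replicate, FDR is $FP/(FP+TP)$ with $0/0 := 0$ (no discoveries means no
false discoveries), sensitivity $TP/(TP+FN)$ (not applicable in all-null
cells, reported `NA` rather than 0), specificity $TN/(TN+FP)$. Cell means
and standard errors aggregate over replicates; the per-rep mean (rather
than pooling counts across reps) is the headline statistic, since each
replicate is one analyst's GOEA.

A single master seed derives one substream per grid cell, so cells are
reproducible independently of evaluation order.

### What the synthetic association emulates — and what it does not

`makeSkewedAssociation` (and the one-call `makeSimulationFixture`)
generates the study conditions:

* population of 20,000 genes over a ~2,000-term single-root DAG;
* per-term gene counts from a heavy-tailed mixture: a geometric bulk with
  sample median about 3 genes/term and a 5% lognormal tail (scaled to
  ~0.35 of the broad threshold, capped just below it), giving a mean of
  ~20 and standard deviation of ~100 — the skew profile of real
  model-organism annotation sets, where the median is small but the mean
  and variance are dominated by a few large terms;
* exactly 30 **broad terms**, each annotating 1,500–6,000 genes
  (log-uniform above the 1,000-gene threshold), drawn from the background
  pool only;
* a **coherent cluster** of 8 leaf terms under a dedicated depth-1 parent
  annotating a 124-gene target pool (each target gets 1–3 cluster terms);
  regular terms draw from the whole population, so targets also carry
  ordinary annotations.

Two structural choices matter and are deliberate. First, the DAG is
*branched* (a root with ~16 branch heads; terms attach within their
branch), which bounds how many genes any non-broad term accumulates under
ancestor propagation: as in the real ontology, only the designated broad
terms and the root end up annotating more than 1,000 genes. Second, broad
terms draw their genes from the background only: a coherent pool of
same-process genes is depleted for most broad functions, and that
depletion is exactly what makes broad terms *under-represented* in
target-heavy studies.

What the generator does **not** emulate: correlated annotations between
related genes beyond the single cluster, evidence-code structure,
multi-namespace annotations, term-term annotation correlations along the
DAG (except through propagation), or the real GO's depth distribution.
Passing simulations therefore show that the analysis machinery controls
gene-level error under the stated skew and coherence conditions — not that
any particular real dataset will behave identically.

### The two regimes the grid demonstrates

With annotations propagated (`propagate = TRUE`, the configuration that
maximizes sensitivity for small studies) and **enriched-only viewing**, the
grid over study sizes {4, 16, 64, 124} and null fractions {0, 0.5, 1.0}
(100 reps/cell at desk scale; the scale is a parameter) keeps the
empirical gene-level FDR within `alpha + 2*SE` in every cell, specificity
at 0.95 or better, and sensitivity non-decreasing in study size —
propagation never costs sensitivity at size 16 with 25% nulls.

Counting **both directions** breaks this: in target-heavy cells the broad
terms become strongly under-represented (the targets lack them), every
null gene annotated to a significant broad term counts as discovered, and
the null-gene discovery ratio rises far above alpha (maximum cell means
around 0.5). Pruning just the 30 broad terms from the association restores
control even under both-direction viewing. That is the practical lesson
the framework encodes: a handful of very broad terms, better represented
by their many specific descendants, can dominate gene-level error.

## Numerical and interface choices

* Fisher tie tolerance $10^{-7}$ relative (see above); all P-values capped
  at 1.
* `round()` (banker's rounding, R default) fixes the null-gene count per
  draw.
* Degenerate inputs: empty studies yield empty results; study genes absent
  from the population warn and are dropped (`strict = TRUE` errors);
  annotations to unknown or obsolete terms warn and are dropped;
  an already-propagated association refuses a second propagation (the
  closure is a fixed point, so nothing would change).
* Report columns (TSV) are pinned: GO, NS, enrichment, name,
  ratio_in_study, ratio_in_pop, p_uncorrected, depth, dcnt, one column per
  correction, study_items.
* Problem sizes used by the test suite: the exact-test oracle covers every
  table with population size up to 12; the DAG oracles use 100 random DAGs
  of 20–200 terms; the simulation grids run 100 replicates per cell on the
  20,000-gene fixture. These are the desk-scale defaults of the study
  conditions; all of them are parameters.

## Known limitations

* The resampling FDR is a plug-in estimator pinned by this package's
  documentation; other tools implement different resampling schemes.
* GPAD support covers the columns needed to build associations (object id,
  qualifier, GO id, ECO evidence), not the full annotation-extension
  grammar.
* Sections files are self-consistent but not byte-compatible with other
  tools' dialects.
* The CLI's `go_plot` emits DOT text; rendering to an image is left to
  GraphViz.
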