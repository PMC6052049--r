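test_that("default header candidates are slims plus depth-01 terms", {
  g <- makeToyDag(60, seed = 41)
  dl <- computeDepthLevel(g, c("part_of", "regulates"))
  d1 <- dl$id[dl$depth == 1]
  hs <- defaultHeaders(g)
  expect_setequal(hs$candidates, d1)
  # slims that are a subset of depth-01 add nothing
  expect_setequal(defaultHeaders(g, slimIds = d1[1])$candidates, d1)
  # disjoint user headers extend the set
  extra <- setdiff(goTerms(g)$id, d1)[1:3]
  expect_setequal(defaultHeaders(g, userHeaders = extra)$candidates,
                  c(d1, extra))
})

test_that("the most specific candidate header is chosen (re-routing)", {
  fx <- makeFig2Dag()
  hs <- headerSet(fx$graph, fx$defaultHeaders)
  # dcnt ordering mirrors the published scenario: the morphogenesis-like
  # header is the smallest of the five candidates
  dcnts <- sort(hs$dcnt[fx$defaultHeaders])
  expect_equal(names(dcnts)[1], fx$initialChoice)
  expect_equal(chooseHeader(fx$graph, fx$target, hs), fx$initialChoice)
  # adding an immune-response header with a smaller dcnt pulls the term over
  hs2 <- headerSet(fx$graph, c(fx$defaultHeaders, fx$addedHeader))
  expect_lt(hs2$dcnt[[fx$addedHeader]], hs2$dcnt[[fx$initialChoice]])
  expect_equal(chooseHeader(fx$graph, fx$target, hs2), fx$reroutedChoice)
  # the target term sits at level 3 / depth 5
  dl <- computeDepthLevel(fx$graph)
  expect_equal(dl$level[dl$id == fx$target], 3)
  expect_equal(dl$depth[dl$id == fx$target], 5)
  # a term that is itself a header chooses itself
  expect_equal(chooseHeader(fx$graph, fx$addedHeader, hs2), fx$addedHeader)
  # re-routing only affects descendants of the new header
  other <- setdiff(goTerms(fx$graph)$id,
                   c(goDescendants(fx$graph, fx$addedHeader,
                                   inclusive = TRUE)))
  for (t in other)
    expect_equal(chooseHeader(fx$graph, t, hs2),
                 chooseHeader(fx$graph, t, hs))
})

test_that("tinfo metric needs an association and ranks by specificity", {
  fx <- makeFig2Dag()
  expect_error(headerSet(fx$graph, fx$defaultHeaders, metric = "tinfo"),
               "TermCountsTable")
  set.seed(43)
  ids <- goTerms(fx$graph)$id
  g2t <- lapply(stats::setNames(1:40, paste0("gene", 1:40)), function(i)
    sample(ids, sample(1:3, 1)))
  tc <- termCounts(assocFromList(g2t), fx$graph)
  hs <- headerSet(fx$graph, fx$defaultHeaders, metric = "tinfo",
                  tctable = tc)
  ch <- chooseHeader(fx$graph, fx$target, hs)
  expect_true(ch %in% fx$defaultHeaders)
})

test_that("grouping conserves every input exactly once", {
  for (seed in c(51, 52, 53)) {
    g <- makeToyDag(120, seed = seed, pRelationship = 0.1)
    set.seed(seed)
    ids <- sample(goTerms(g)$id, 40)
    hs <- defaultHeaders(g, userHeaders = sample(goTerms(g)$id, 6))
    cand <- hs$candidates
    spec <- sectionsSpec(list(one = cand[1], two = cand[2:3]))
    gr <- groupTerms(ids, g, hs, spec)
    got <- c(gr$entries$GO, gr$ungrouped$GO)
    expect_setequal(got, ids)
    expect_equal(length(got), length(ids))   # no duplicates
    expect_equal(anyDuplicated(got), 0)
    # section order follows the spec, Misc. last
    secs <- unique(gr$entries$section)
    expect_equal(secs, intersect(c("one", "two", "Misc."), secs))
    # grouping is invariant to input order
    gr2 <- groupTerms(rev(ids), g, hs, spec)
    expect_identical(gr2$entries, gr$entries)
  }
})

test_that("members sort by p-value when records carry one", {
  fx <- makeFig2Dag()
  hs <- headerSet(fx$graph, fx$defaultHeaders)
  ids <- goTerms(fx$graph)$id[-1]
  set.seed(3)
  recs <- data.frame(GO = ids, p_fdr_bh = stats::runif(length(ids)),
                     stringsAsFactors = FALSE)
  gr <- groupTerms(recs, fx$graph, hs)
  for (h in unique(gr$entries$header)) {
    ps <- gr$entries$p_fdr_bh[gr$entries$header == h]
    expect_true(!is.unsorted(ps))
  }
  # unknown sort key errors
  expect_error(groupTerms(recs, fx$graph, hs, sortKey = "nope"),
               "sort key")
})

test_that("a header listed in two sections goes to the first", {
  fx <- makeFig2Dag()
  hs <- headerSet(fx$graph, c(fx$defaultHeaders, fx$addedHeader))
  spec <- sectionsSpec(list(alpha = fx$initialChoice,
                            beta = fx$addedHeader))
  # duplicate declarations are rejected at spec construction
  expect_error(sectionsSpec(list(a = "GO:0000005", b = "GO:0000005")),
               "unique")
  gr <- groupTerms(fx$target, fx$graph, hs, spec)
  expect_equal(gr$entries$section, "beta")   # header is the added one
  # empty sections: everything grouped by header under Misc.
  gr2 <- groupTerms(fx$target, fx$graph, hs)
  expect_equal(gr2$entries$section, "Misc.")
})

test_that("sections files round trip byte-identically", {
  spec <- sectionsSpec(list(immune = c("GO:0000004", "GO:0000006"),
                            development = "GO:0000002"))
  lines1 <- writeSections(spec)
  spec2 <- readSections(lines1)
  expect_equal(spec2, spec)
  expect_identical(writeSections(spec2), lines1)
  # annotated member lines and Misc. sections are handled on read
  annotated <- c("# SECTION: immune",
                 "GO:0000004 # BP    12 uGOs    34 L01 D01 immune-ish",
                 "", "# SECTION: Misc.",
                 "GO:0000001 # BP ignored")
  spec3 <- readSections(annotated)
  expect_equal(names(spec3$sections), "immune")
  expect_equal(spec3$sections$immune, "GO:0000004")
})

test_that("the wr_sections workflow writes and reuses its three files", {
  fx <- makeFig2Dag()
  dir <- withr::local_tempdir()
  goids <- setdiff(goTerms(fx$graph)$id, "GO:0000001")
  sIn <- file.path(dir, "sections_in.txt")
  res1 <- suppressMessages(
    wrSectionsWorkflow(goids, fx$graph, sectionsIn = sIn))
  # first run: the input file is created, nothing grouped yet
  expect_true(file.exists(sIn))
  expect_true(file.exists(res1$sectionsOut))
  expect_true(file.exists(res1$groupedOut))
  expect_equal(res1$nGrouped, 0)
  expect_equal(res1$nUngrouped, length(goids))
  # second run with unchanged files is byte-identical
  s1 <- readLines(res1$sectionsOut); g1 <- readLines(res1$groupedOut)
  res2 <- suppressMessages(
    wrSectionsWorkflow(goids, fx$graph, sectionsIn = sIn))
  expect_identical(readLines(res2$sectionsOut), s1)
  expect_identical(readLines(res2$groupedOut), g1)
  # moving a header into a named section groups its member terms
  hdr <- fx$initialChoice
  nBelow <- sum(vapply(goids, function(t)
    identical(chooseHeader(fx$graph, t,
                           defaultHeaders(fx$graph,
                                          userHeaders = hdr)), hdr),
    logical(1)))
  writeLines(c("# SECTION: development", hdr, "# SECTION: Misc."), sIn)
  res3 <- suppressMessages(
    wrSectionsWorkflow(goids, fx$graph, sectionsIn = sIn))
  expect_equal(res3$nGrouped, nBelow)
  expect_equal(res3$nUngrouped, length(goids) - nBelow)
  expect_equal(res3$nSections, 1)
})

test_that("hierarchy reports are dash-indented, marked and deduplicated", {
  ch <- chainGraph(5)
  up <- hierReport(ch, "GO:0000005", "up")
  expect_equal(length(up), 5)
  expect_equal(substr(up[1], 1, 2), "- ")
  expect_match(up[1], "^- GO:0000001 4 D00 chain 1$")
  expect_match(up[5], "^> ----- GO:0000005 0 D04 chain 5$")
  # up from the root is a single line
  expect_equal(length(hierReport(ch, "GO:0000001", "up")), 1)
  # a diamond prints each term once despite two paths
  dg <- diamondGraph()
  down <- hierReport(dg, "GO:0000001", "down")
  expect_equal(length(down), 3)
  expect_equal(sum(grepl("GO:0000003", down)), 1)
})

test_that("DOT export draws the induced ancestor sub-DAG", {
  ch <- chainGraph(3)
  dot1 <- exportDot(ch, "GO:0000001")
  expect_equal(sum(grepl("->", dot1, fixed = TRUE)), 0)
  dot3 <- exportDot(ch, "GO:0000003")
  expect_equal(sum(grepl("->", dot3, fixed = TRUE)), 2)
  expect_match(dot3[1], "^digraph")
  expect_equal(dot3[length(dot3)], "}")
  # structural validity: every node/edge line is well-formed and quoted
  body <- dot3[-c(1, 2, length(dot3))]
  ok <- grepl('^  "GO:[0-9]{7}" \\[label=.*\\];$', body) |
    grepl('^  "GO:[0-9]{7}" -> "GO:[0-9]{7}";$', body)
  expect_true(all(ok))
  # headers and significance colours add attributes
  hs <- headerSet(ch, "GO:0000002", edgeTypes = character())
  dotH <- exportDot(ch, "GO:0000003", headers = hs,
                    significanceColors = c(`GO:0000003` = "red"))
  expect_true(any(grepl("penwidth", dotH)))
  expect_true(any(grepl('fillcolor="red"', dotH)))
})
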