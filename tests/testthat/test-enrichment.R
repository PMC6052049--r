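test_that("two-sided Fisher matches enumeration and fisher.test", {
  # study 5/5 annotated vs population 5/10: only the two extreme tables
  # have point probability <= the observed one
  expect_equal(fisherExactTwoSided(5, 5, 5, 10), 2 / 252,
               tolerance = 1e-12)
  # study identical to population
  expect_equal(fisherExactTwoSided(3, 7, 3, 7), 1)
  # degenerate margins
  expect_equal(fisherExactTwoSided(0, 0, 2, 10), 1)
  expect_equal(fisherExactTwoSided(0, 3, 0, 10), 1)
  expect_equal(fisherExactTwoSided(3, 3, 10, 10), 1)
  # random tables against stats::fisher.test (independent implementation)
  set.seed(1)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    k <- sample(lo:hi, 1)
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2)
    expect_equal(fisherExactTwoSided(k, n, K, N),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("direction classification uses the strict ratio rule", {
  expect_equal(classifyDirection(4, 10, 10, 100), "e")
  expect_equal(classifyDirection(1, 10, 50, 100), "p")
  expect_equal(classifyDirection(1, 10, 10, 100), "p")  # tie -> 'p'
  expect_equal(classifyDirection(c(4, 1), 10, c(10, 50), 100), c("e", "p"))
})

test_that("corrections match hand formulas and basic properties", {
  expect_error(correctPvalues(0.5, "nope"), "unknown")
  # a single p is unchanged by every closed-form method
  for (m in c("bonferroni", "sidak", "holm", "fdr_bh", "fdr_by"))
    expect_equal(correctPvalues(0.037, m), 0.037)
  expect_equal(correctPvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(correctPvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh"),
               rep(0.04, 4))
  set.seed(99)
  for (i in 1:25) {
    p <- stats::runif(sample(2:50, 1))
    expect_equal(correctPvalues(p, "bonferroni"), bonferroniOracle(p))
    expect_equal(correctPvalues(p, "sidak"), sidakOracle(p))
    expect_equal(correctPvalues(p, "holm"), holmOracle(p))
    expect_equal(correctPvalues(p, "fdr_bh"), bhOracle(p))
    expect_equal(correctPvalues(p, "fdr_by"), byOracle(p))
    # every correction >= input; bonferroni/sidak preserve order
    for (m in c("bonferroni", "sidak", "holm", "fdr_bh", "fdr_by")) {
      q <- correctPvalues(p, m)
      expect_true(all(q >= p - 1e-12))
      expect_true(all(q <= 1))
    }
    # monotone in p: sorting by corrected p never inverts strict order
    o <- order(p)
    expect_true(all(diff(correctPvalues(p, "bonferroni")[o]) >= -1e-12))
    expect_true(all(diff(correctPvalues(p, "sidak")[o]) >= -1e-12))
  }
})

test_that("the resampling FDR is seed-deterministic and converges", {
  g <- makeToyDag(25, seed = 4)
  set.seed(4)
  pop <- paste0("gene", 1:60)
  g2t <- lapply(stats::setNames(seq_along(pop), pop), function(i)
    sample(goTerms(g)$id, sample(1:3, 1)))
  a <- assocFromList(g2t)
  study <- pop[1:8]
  r1 <- runGoea(study, pop, a, g, methods = "fdr_resampling", seed = 7,
                B = 60, addMetrics = FALSE)
  r2 <- runGoea(study, pop, a, g, methods = "fdr_resampling", seed = 7,
                B = 60, addMetrics = FALSE)
  expect_identical(r1$p_fdr_resampling, r2$p_fdr_resampling)
  expect_true(all(r1$p_fdr_resampling >= 0 & r1$p_fdr_resampling <= 1))
  # standard error across seed replicates shrinks as B grows
  est <- function(B, seeds) vapply(seeds, function(s)
    runGoea(study, pop, a, g, methods = "fdr_resampling", seed = s,
            B = B, addMetrics = FALSE)$p_fdr_resampling[1], numeric(1))
  sdSmall <- stats::sd(est(10, 1:8))
  sdBig <- stats::sd(est(160, 1:8))
  expect_lt(sdBig, sdSmall + 1e-9)
})

test_that("runGoea reconstructs per-term tables faithfully", {
  g <- makeToyDag(30, seed = 15)
  set.seed(15)
  pop <- paste0("gene", 1:80)
  g2t <- lapply(stats::setNames(seq_along(pop), pop), function(i)
    sample(goTerms(g)$id, sample(1:4, 1)))
  a <- assocFromList(g2t)
  study <- sample(pop, 12)
  r <- runGoea(study, pop, a, g, methods = c("fdr_bh", "bonferroni"))
  # each record's p equals a direct Fisher call on its reconstructed table
  for (i in seq_len(nrow(r))) {
    expect_equal(r$p_uncorrected[i],
                 fisherExactTwoSided(r$study_count[i], r$study_n[i],
                                     r$pop_count[i], r$pop_n[i]))
    expect_equal(r$study_count[i], length(r$study_items[[i]]))
    expect_equal(r$pop_count[i],
                 length(term2Genes(a)[[r$GO[i]]]))
  }
  # tested universe: exactly the terms hit by >= 1 study gene
  expect_setequal(r$GO, unique(unlist(gene2Terms(a)[study])))
  # propagation can only widen the tested universe
  rp <- runGoea(study, pop, a, g, propagate = TRUE)
  expect_true(all(r$GO %in% rp$GO))
  # population universe covers every annotated term
  rpop <- runGoea(study, pop, a, g, universePolicy = "population")
  expect_setequal(rpop$GO, names(term2Genes(a)))
  # corrections are joint over the tested set
  expect_equal(r$p_bonferroni,
               pmin(1, r$p_uncorrected * nrow(r)))
  # metrics annotated
  expect_false(any(is.na(r$depth)))
  expect_false(any(is.na(r$dcnt)))
})

test_that("degenerate GOEAs behave by convention", {
  g <- makeToyDag(10, seed = 2)
  pop <- paste0("gene", 1:20)
  a <- assocFromList(lapply(stats::setNames(seq_along(pop), pop),
                            function(i) goTerms(g)$id[1 + i %% 9]))
  # study == population: nothing can be enriched
  r <- runGoea(pop, pop, a, g, addMetrics = FALSE)
  expect_true(all(r$p_uncorrected > 1 - 1e-12))
  # empty study
  expect_equal(nrow(runGoea(character(), pop, a, g)), 0)
  # study genes outside the population warn and are dropped
  expect_warning(runGoea(c(pop[1], "alien"), pop, a, g), "dropping")
  expect_error(runGoea(c(pop[1], "alien"), pop, a, g, strict = TRUE),
               "not in the population")
  # a single annotated study gene in a 1-gene-term population
  g1 <- chainGraph(2)
  a1 <- assocFromList(c(list(gene1 = "GO:0000002"),
                        stats::setNames(rep(list("GO:0000001"), 99),
                                        paste0("bg", 1:99))))
  r1 <- runGoea("gene1", c("gene1", paste0("bg", 1:99)), a1, g1,
                addMetrics = FALSE)
  rec <- r1[r1$GO == "GO:0000002", ]
  expect_equal(rec$study_count, 1)
  expect_equal(rec$pop_count, 1)
  expect_equal(rec$enrichment, "e")
})

test_that("significance filtering respects method, alpha and direction", {
  recs <- data.frame(GO = sprintf("GO:%07d", 1:6),
                     enrichment = c("e", "p", "e", "p", "e", "p"),
                     p_uncorrected = c(0.001, 0.002, 0.2, 0.01, 0.04, 0.9),
                     stringsAsFactors = FALSE)
  recs$p_fdr_bh <- correctPvalues(recs$p_uncorrected, "fdr_bh")
  recs$study_items <- as.list(letters[1:6])
  sigBoth <- significantRecords(recs, "fdr_bh", 0.05)
  sigE <- significantRecords(recs, "fdr_bh", 0.05, "e")
  expect_true(all(sigE$GO %in% sigBoth$GO))
  expect_true(all(sigE$enrichment == "e"))
  # hand filter agreement
  expect_equal(sigBoth$GO,
               recs$GO[recs$p_fdr_bh < 0.05])
  # alpha = 1 keeps every direction match (strict comparison)
  expect_equal(nrow(significantRecords(recs, "uncorrected", 1)), 6)
  expect_error(significantRecords(recs, "holm"), "method")
})

test_that("gene list reading and report writers are stable", {
  lines <- c("# comment", "geneA", "geneB # trailing", "", "geneA")
  expect_equal(readGeneList(lines), c("geneA", "geneB"))
  g <- makeToyDag(15, seed = 6)
  set.seed(6)
  pop <- paste0("gene", 1:40)
  a <- assocFromList(lapply(stats::setNames(seq_along(pop), pop),
                            function(i) sample(goTerms(g)$id, 2)))
  r <- runGoea(pop[1:6], pop, a, g)
  tsv <- writeGoeaTsv(r)
  expect_match(tsv[1], "^GO\\tNS\\tenrichment\\tname\\tratio_in_study")
  expect_equal(length(tsv), nrow(r) + 1)
  expect_match(tsv[2], "\\d+/6\\t\\d+/40")
  jsonPath <- tempfile(fileext = ".json")
  writeGoeaJson(r, jsonPath)
  back <- jsonlite::read_json(jsonPath)
  expect_equal(length(back), nrow(r))
  expect_equal(back[[1]]$GO, r$GO[1])
})
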