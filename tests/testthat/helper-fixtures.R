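# Shared heavy fixture for the simulation tests: built once per test run.
# The generator parameters are the study conditions (20,000 genes, ~2,000
# terms, 30 broad terms, a 124-gene coherent target pool); only the seed is
# fixed here so the suite is deterministic.

.simCache <- new.env(parent = emptyenv())

getSimFixture <- function() {
  if (is.null(.simCache$fx))
    .simCache$fx <- makeSimulationFixture(seed = 42)
  .simCache$fx
}

getPropagatedAssoc <- function() {
  if (is.null(.simCache$prop)) {
    fx <- getSimFixture()
    .simCache$prop <- propagateCounts(fx$assoc, fx$graph)
  }
  .simCache$prop
}

# a tiny OBO fixture shared by io tests
tinyOboLines <- function() {
  c("format-version: 1.2",
    "data-version: releases/2026-01-01",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: branch a",
    "namespace: biological_process",
    "alt_id: GO:0000090",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: leaf b",
    "namespace: biological_process",
    "is_a: GO:0000002 ! branch a",
    "relationship: part_of GO:0000001 ! root",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true")
}
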