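test_that("libraries load from CSV with eager validation", {
  td <- withr::local_tempdir()
  ft <- file.path(td, "templates.csv")
  ff <- file.path(td, "fragments.csv")
  utils::write.csv(data.frame(
    id = c("fa", "fb", "gc"),
    smiles = c("F", "Cl", "C"),
    category = c("R1", "R1", "R2")
  ), ff, row.names = FALSE)
  utils::write.csv(data.frame(
    id = "t1", family = "toy", scaffold = "c1cc({R2a})cc({R1a})c1",
    slots = "R1a:R1;R2a:R2", symmetric_groups = ""
  ), ft, row.names = FALSE)

  lib <- load_library(ft, ff)
  expect_length(lib$fragments, 3)
  expect_equal(sort(names(lib$by_category)), c("R1", "R2"))
  expect_equal(length(lib$by_category$R1), 2)

  # scaffold lacking a declared placeholder names the missing token
  utils::write.csv(data.frame(
    id = "t1", family = "toy", scaffold = "c1ccc({R1a})cc1",
    slots = "R1a:R1;R2a:R2", symmetric_groups = ""
  ), ft, row.names = FALSE)
  expect_error(load_library(ft, ff), "R2a")

  # unknown category and bad SMILES are row errors
  utils::write.csv(data.frame(
    id = "fa", smiles = "F", category = "R9"
  ), ff, row.names = FALSE)
  utils::write.csv(data.frame(
    id = "t1", family = "toy", scaffold = "c1ccc({R1a})cc1",
    slots = "R1a:R1", symmetric_groups = ""
  ), ft, row.names = FALSE)
  expect_error(load_library(ft, ff), "category")
  utils::write.csv(data.frame(
    id = "fa", smiles = "xx$%", category = "R1"
  ), ff, row.names = FALSE)
  expect_error(load_library(ft, ff), "row 1")
})

test_that("round-tripping a library through CSV preserves it", {
  lib <- toy_library_symmetric()
  td <- withr::local_tempdir()
  write_library(lib, file.path(td, "t.csv"), file.path(td, "f.csv"))
  lib2 <- load_library(file.path(td, "t.csv"), file.path(td, "f.csv"))
  expect_equal(names(lib2$templates), names(lib$templates))
  expect_equal(names(lib2$fragments), names(lib$fragments))
  expect_equal(lib2$templates$t2$symmetric_groups, lib$templates$t2$symmetric_groups)
})

test_that("assembly substitutes fragments and canonicalizes deterministically", {
  tpl <- catalyst_template("t", "toy", "c1ccc({R1a})cc1", c(R1a = "R1"))
  lib <- catalyst_library(list(tpl), list(catalyst_fragment("f", "F", "R1")))
  cand <- assemble(tpl, list(R1a = "f"), lib)
  expect_equal(cand$smiles, canonical_smiles("Fc1ccccc1"))

  # symmetric slots demand identical fragments
  lib2 <- toy_library_symmetric()
  sym <- lib2$templates$t2
  r3 <- lib2$by_category$R3
  ok <- assemble(sym, stats::setNames(list(r3[1], r3[1]), c("R3a", "R3b")), lib2)
  expect_true(is_valid_smiles(ok$smiles))
  expect_error(
    assemble(sym, stats::setNames(list(r3[1], r3[2]), c("R3a", "R3b")), lib2),
    "symmetric"
  )

  # category mismatch and missing slot are assembly errors
  lib3 <- toy_library()
  tpl3 <- lib3$templates$t1
  expect_error(assemble(tpl3, list(R1a = "g_me", R2a = "g_et"), lib3), "category")
  expect_error(assemble(tpl3, list(R1a = "f_f"), lib3), "misses slot")

  # determinism under repeated invocation of a random assignment
  set.seed(42)
  asg <- list(R1a = sample(lib3$by_category$R1, 1),
              R2a = sample(lib3$by_category$R2, 1))
  expect_identical(assemble(tpl3, asg, lib3)$smiles,
                   assemble(tpl3, asg, lib3)$smiles)
})

test_that("enumerate_count follows the product rule and matches brute force", {
  lib <- toy_library()
  expect_equal(enumerate_count(lib), 3 * 4)

  lib_sym <- toy_library_symmetric()
  expect_equal(enumerate_count(lib_sym), 12 + 5)

  all_cands <- enumerate_all(lib_sym)
  expect_length(all_cands, 17)
  smiles <- vapply(all_cands, `[[`, character(1), "smiles")
  expect_equal(length(unique(smiles)), 17)  # assembly is injective here

  # the symmetry constraint strictly reduces the count
  free <- catalyst_template("t2f", "toy", "O=C(N{R3a})N{R3b}",
                            c(R3a = "R3", R3b = "R3"))
  lib_free <- catalyst_library(
    c(lib_sym$templates[c("t1")], list(free)),
    lib_sym$fragments
  )
  expect_gt(enumerate_count(lib_free), enumerate_count(lib_sym))
  expect_equal(enumerate_count(lib_free), 12 + 25)
})

test_that("random candidate draws are uniform over the assignment space", {
  lib <- toy_library()

  set.seed(0)
  a <- sample_candidate(lib)
  set.seed(0)
  b <- sample_candidate(lib)
  expect_identical(a$smiles, b$smiles)

  set.seed(1)
  draws <- sample_candidate(lib, 6000)
  smiles <- vapply(draws, `[[`, character(1), "smiles")
  counts <- table(smiles)
  expect_length(counts, 12)           # every candidate observed
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  # degenerate single-candidate space
  lib1 <- catalyst_library(
    list(catalyst_template("t", "toy", "c1ccc({R1a})cc1", c(R1a = "R1"))),
    list(catalyst_fragment("f", "F", "R1"))
  )
  set.seed(2)
  expect_identical(sample_candidate(lib1)$smiles, canonical_smiles("Fc1ccccc1"))
})

test_that("every assembly from the benchmark library parses", {
  lib <- make_landscape(seed = 1, n_sub_a = 4, n_sub_b = 4)$library
  set.seed(3)
  draws <- sample_candidate(lib, 1000)
  smiles <- vapply(draws, `[[`, character(1), "smiles")
  expect_true(all(nzchar(smiles)))
  expect_true(all(is_valid_smiles(smiles)))
})
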