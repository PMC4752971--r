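benzene <- canonicalize_smiles("c1ccccc1")

test_that("Murcko scaffold strips side chains, keeps exocyclic double bonds", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), benzene)       # toluene
  expect_equal(murcko_scaffold("c1ccccc1"), benzene)        # fixed point
  expect_equal(murcko_scaffold("CC(=O)c1ccccc1"), benzene)  # acetophenone
  # cyclohexanone: the ring carbonyl is part of the scaffold
  expect_equal(murcko_scaffold("O=C1CCCCC1"), canonicalize_smiles("O=C1CCCCC1"))
  expect_true(is.na(murcko_scaffold("CCO")))                # acyclic
})

test_that("parent removal terminates at one ring and respects priorities", {
  expect_true(is.na(scaffold_parent("c1ccccc1")))
  expect_equal(scaffold_parent("c1ccc(-c2ccccc2)cc1"), benzene)  # biphenyl
  # aromatic ring removed from a fused pair re-aromatizes the survivor
  expect_equal(scaffold_parent("c1ccc2ccccc2c1"), benzene)       # naphthalene
  # pendant ring attached by a linker goes before the fused system
  # (fewest acyclic linker bonds in the parent)
  expect_equal(scaffold_parent("C1CCC(CC2CCc3ccccc32)CC1"),
               canonicalize_smiles("C1Cc2ccccc2C1"))  # indane survives
  expect_error(scaffold_parent("CCCC"), "acyclic")
})

test_that("a k-ring molecule yields a scaffold chain of length exactly k", {
  cases <- list(list(smi = "Cc1ccccc1", k = 1),                        # toluene
                list(smi = "c1ccc2ccccc2c1", k = 2),                   # naphthalene
                list(smi = "Cn1cnc2c1c(=O)n(C)c(=O)n2C", k = 2),       # caffeine
                list(smi = "c1ccc2c(c1)ccc1ccccc12", k = 3),           # phenanthrene
                list(smi = "C1CCC(CC2CCc3ccccc32)CC1", k = 3))
  for (cs in cases) {
    chain <- scaffold_chain(cs$smi)
    expect_length(chain, cs$k)
    # last element is a single ring, each step removes exactly one ring
    expect_true(is.na(scaffold_parent(chain[length(chain)])))
  }
  expect_error(scaffold_chain("CCO"), "acyclic")
})

test_that("acyclic decomposition prunes to the carbon backbone deterministically", {
  expect_equal(decompose_acyclic("CC"), canonicalize_smiles("CC"))
  oct <- decompose_acyclic("OCCCCCCCC")  # n-octanol
  expect_equal(oct, canonicalize_smiles(c("OCCCCCCCC", "CCCCCCCC")))
  expect_error(decompose_acyclic("Cn1cnc2c1c(=O)n(C)c(=O)n2C"), "cyclic")
  # branched: isopentanol ends in its unbranched backbone
  chain <- decompose_acyclic("CC(C)CCO")
  expect_equal(chain[1], canonicalize_smiles("CC(C)CCO"))
  last <- chain[length(chain)]
  expect_identical(decompose_acyclic(last), last)
})

test_that("forest merges shared scaffolds and partitions ring/acyclic chemistry", {
  lib <- compound_library(c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1"),
                          c("a", "b", "c"))$compounds
  f <- build_forest(lib)
  expect_equal(nrow(f$nodes), 1L)
  expect_equal(forest_roots(f), benzene)
  expect_equal(f$members[[benzene]], c("a", "b", "c"))

  lib2 <- compound_library(c("c1ccccc1", "C1CCNCC1"), c("a", "b"))$compounds
  expect_length(forest_roots(build_forest(lib2)), 2L)

  lib3 <- compound_library(c("c1ccccc1", "CCO"), c("r", "x"))$compounds
  f3 <- build_forest(lib3)
  expect_equal(forest_roots(f3, ring_only = TRUE), benzene)
  expect_length(forest_roots(f3), 2L)
})

test_that("the fixture grammar yields exactly its five single-ring roots", {
  fx <- small_fixture()
  f <- build_forest(fx$lib)
  roots <- forest_roots(f, ring_only = TRUE)
  expect_equal(sort(roots), sort(canonicalize_smiles(fx$cfg$scaffold_grammar)))
  # member propagation: every compound is in its leaf and all ancestors
  for (cid in fx$lib$compound_id[1:25]) {
    node <- f$leaf_of[[cid]]
    while (!is.na(node)) {
      expect_true(cid %in% f$members[[node]])
      node <- f$nodes$parent[f$nodes$scaffold == node]
    }
  }
  # leaves partition the library
  expect_setequal(names(f$leaf_of), fx$lib$compound_id)
})

test_that("permuting the input order leaves the forest invariant", {
  fx <- small_fixture()
  lib <- fx$lib[1:40, ]
  f1 <- build_forest(lib)
  set.seed(8)
  f2 <- build_forest(lib[sample.int(nrow(lib)), ])
  expect_equal(f1$nodes[order(f1$nodes$scaffold), ],
               f2$nodes[order(f2$nodes$scaffold), ], ignore_attr = TRUE)
  expect_equal(f1$members, f2$members[names(f1$members)])
  expect_equal(forest_compound_order(f1), forest_compound_order(f2))
})

test_that("forest serialization round-trips structure", {
  fx <- small_fixture()
  f <- build_forest(fx$lib[1:20, ])
  p <- withr::local_tempfile(fileext = ".json")
  write_forest_json(f, p)
  j <- jsonlite::read_json(p)
  expect_length(j, nrow(f$nodes))
  expect_setequal(vapply(j, `[[`, "", "scaffold_smiles"), f$nodes$scaffold)
  nwk <- forest_newick(f)
  expect_true(startsWith(nwk, "(") && endsWith(nwk, ");"))
})
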