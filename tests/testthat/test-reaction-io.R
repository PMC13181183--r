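test_that("reaction SMILES parse into the expected graphs", {
  rx <- parse_reaction("CC(=O)O.OCC>>CC(=O)OCC")
  expect_equal(rx$reactants$n_atoms, 7L)
  expect_equal(length(unique(rx$reactants$component_ids)), 2L)
  expect_equal(rx$product$n_atoms, 6L)
  expect_null(rx$atom_map)

  rx <- parse_reaction("C>>C")
  expect_equal(rx$reactants$n_atoms, 1L)
  expect_equal(nrow(rx$product$bonds), 0L)

  rx <- parse_reaction(
    "[CH3:1][C:2](=[O:3])[OH:4].[OH:5][CH3:6]>>[CH3:1][C:2](=[O:3])[O:5][CH3:6]")
  expect_length(rx$atom_map, 5L)
  pm <- rx$product$mol$atoms$map
  rm <- rx$reactants$mol$atoms$map
  expect_equal(rm[rx$atom_map], pm)
  expect_false(anyDuplicated(rx$atom_map) > 0)
})

test_that("malformed reaction SMILES raise informative errors", {
  expect_error(parse_reaction("CC>CC"), ">>")
  expect_error(parse_reaction("CC>>CC>>CC"), ">>")
  expect_error(parse_reaction("C(C>>CC"), "reactant")
  expect_error(parse_reaction("CC>>C)C"), "product")
  expect_error(parse_reaction("[CH3:1][CH3:1]>>[CH3:1]C"), "duplicate")
  expect_error(parse_reaction("[CH4:2]>>[CH4:7]"), "7")
})

test_that("atom features are block one-hot with an 'other' fallback", {
  d <- feature_dims()
  g <- mol_graph("CCO")
  expect_equal(ncol(g$X), d$d_x)
  # each atom hits exactly one bit per categorical block; flags add 0/1
  n_blocks <- 6L  # element, charge, chirality, hybridization, degree, H count
  ones <- rowSums(g$X)
  expect_true(all(ones >= n_blocks & ones <= n_blocks + 2L))

  benz <- mol_graph("c1ccccc1")
  expect_true(all(benz$E[, 4] == 1))   # aromatic bond-type bit
  expect_true(all(benz$E[, ncol(benz$E)] == 1))  # ring flag

  se <- mol_graph(parse_smiles("[Te]"))  # element outside the vocabulary
  expect_equal(unname(se$X[1, 17]), 1)   # 'other' element bucket
  expect_equal(ncol(se$X), d$d_x)
})

test_that("adjacency row sums equal the degrees used in featurization", {
  for (smi in fixture_smiles) {
    g <- mol_graph(smi)
    deg <- rowSums(g$A)
    block <- g$X[, 35:41, drop = FALSE]  # degree one-hot block (0..6)
    expect_equal(unname(apply(block, 1L, which.max) - 1L), unname(deg),
                 info = smi)
  }
})

test_that("parse-serialize-parse round trips preserve the graph", {
  for (smi in c(fixture_smiles, "CC(=O)OCC", "O=C(O)c1ccccc1")) {
    g1 <- mol_graph(smi)
    s2 <- as.character(write_smiles(g1$mol))
    g2 <- mol_graph(s2)
    expect_equal(g2$n_atoms, g1$n_atoms, info = smi)
    expect_equal(nrow(g2$bonds), nrow(g1$bonds), info = smi)
    # same multiset of feature rows (atom order may differ)
    key <- function(X) sort(apply(X, 1L, paste, collapse = ""))
    expect_equal(key(g2$X), key(g1$X), info = smi)
  }
})

test_that("openbabel agrees that written SMILES are the same molecules", {
  obabel_canonical <- function(smi) {
    out <- suppressWarnings(system2("obabel", c(paste0("-:", shQuote(smi)),
                                                "-ocan"),
                                    stdout = TRUE, stderr = FALSE))
    trimws(out[length(out)])
  }
  for (smi in c("CC(=O)OCC", "Cc1ccc(C)cc1", "CC(C)CO")) {
    mol <- parse_smiles(smi)
    set.seed(42)
    perm <- sample(nrow(mol$atoms))
    permuted <- as.character(write_smiles(rxngraph:::.mol_permute(mol, perm)))
    expect_equal(obabel_canonical(permuted), obabel_canonical(smi), info = smi)
  }
})

test_that("dual graph matches the brute-force shared-atom relation", {
  ethanol <- build_dual_graph(mol_graph("CCO"))
  expect_equal(ethanol$n_nodes, 2L)
  expect_equal(nrow(ethanol$edges), 1L)

  expect_equal(build_dual_graph(mol_graph("C"))$n_nodes, 0L)

  benz <- build_dual_graph(mol_graph("c1ccccc1"))
  expect_equal(benz$n_nodes, 6L)
  expect_equal(nrow(benz$edges), 6L)  # 6-cycle in the dual
  deg <- tabulate(c(benz$edges$a, benz$edges$b), 6L)
  expect_true(all(deg == 2L))

  # random synthetic products vs double-loop oracle
  ds <- generate_reactions(generator_config(n_reactions = 30, seed = 77))
  for (k in seq_len(nrow(ds))) {
    g <- parse_reaction(ds$rxn_smiles[k])$product
    d <- build_dual_graph(g)
    expect_equal(d$n_nodes, nrow(g$bonds))
    expected <- list()
    nb <- nrow(g$bonds)
    if (nb > 1L) for (a in seq_len(nb - 1L)) for (b in (a + 1L):nb) {
      shared <- length(intersect(c(g$bonds$i[a], g$bonds$j[a]),
                                 c(g$bonds$i[b], g$bonds$j[b])))
      if (shared == 1L) expected[[length(expected) + 1L]] <- c(a, b)
    }
    got <- unname(split(as.matrix(d$edges), seq_len(nrow(d$edges))))
    expect_equal(nrow(d$edges), length(expected))
  }
})

test_that("canonicalization is idempotent and permutation-invariant", {
  smi <- "[CH3:4][CH2:3][CH2:2][CH2:1][C:5](=[O:6])O.[OH:7][CH3:8]>>[O:7]([CH3:8])[C:5](=[O:6])[CH2:1][CH2:2][CH2:3][CH3:4]"
  rx <- parse_reaction(smi)
  c1 <- canonicalize_and_remap(rx)
  c2 <- canonicalize_and_remap(c1)
  expect_equal(attr(c1, "canonical_smiles"), attr(c2, "canonical_smiles"))
  # permuting the product atom order does not change the canonical output
  sides <- strsplit(smi, ">>", fixed = TRUE)[[1L]]
  for (seed in 1:5) {
    set.seed(seed)
    pmol <- parse_smiles(sides[2L])
    permuted <- rxngraph:::.mol_permute(pmol, sample(nrow(pmol$atoms)))
    smi_perm <- paste0(sides[1L], ">>", as.character(write_smiles(permuted)))
    cp <- canonicalize_and_remap(parse_reaction(smi_perm))
    expect_equal(attr(cp, "canonical_smiles"), attr(c1, "canonical_smiles"))
  }
  # map stays injective and total
  expect_length(c1$atom_map, c1$product$n_atoms)
  expect_false(anyDuplicated(c1$atom_map) > 0)
  expect_error(canonicalize_and_remap(parse_reaction("CCO>>CC")), "atom map")
})

test_that("dataset round trips through CSV and splits within one row", {
  ds <- generate_reactions(generator_config(n_reactions = 20, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$rxn_smiles, ds$rxn_smiles)
  expect_equal(back$class, ds$class)

  empty <- ds[0, ]
  write_dataset(empty, path)
  expect_equal(nrow(read_dataset(path)), 0L)

  split <- split_dataset(ds, c(8, 1, 1), seed = 1)
  counts <- table(split$split)
  expect_true(abs(counts[["train"]] - 16) <= 1)
  expect_true(abs(counts[["validation"]] - 2) <= 1)
  expect_true(abs(counts[["test"]] - 2) <= 1)
})
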