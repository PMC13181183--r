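test_that("similarity is the plain embedding dot product", {
  expect_equal(similarity(diag(3), diag(3)), diag(3))
  H <- rbind(c(1, 0), c(0, 1))
  expect_equal(similarity(H, H)[1, 2], 0)
  set.seed(1)
  A <- matrix(rnorm(12), 3); B <- matrix(rnorm(16), 4)
  S <- similarity(A, B)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(S[i, j], sum(A[i, ] * B[j, ]))
  }
  expect_error(similarity(matrix(0, 2, 3), matrix(0, 2, 4)), "dimension")
})

test_that("sinkhorn normalizes, is shift-invariant and equivariant", {
  expect_equal(sinkhorn(matrix(5, 4, 4), 10, 0.1), matrix(0.25, 4, 4))

  set.seed(2)
  A <- diag(6) * 10 + matrix(rnorm(36, sd = 0.1), 6)
  M <- sinkhorn(A, 20, 1)
  expect_true(all(abs(M - diag(6))[upper.tri(M) | lower.tri(M)] < 0.01))

  B <- matrix(rnorm(49), 7)
  M1 <- sinkhorn(B, 50, 1)
  expect_lt(max(abs(rowSums(M1) - 1)), 1e-4)
  expect_lt(max(abs(colSums(M1) - 1)), 1e-4)
  # adding a constant to the raw input leaves the output unchanged
  expect_equal(sinkhorn(B + 3.7, 20, 0.5), sinkhorn(B, 20, 0.5), tolerance = 1e-10)
  # permuting rows of the input permutes rows of the output identically
  perm <- sample(7)
  expect_equal(sinkhorn(B[perm, ], 20, 0.5), sinkhorn(B, 20, 0.5)[perm, ])

  # rectangular: proper row distributions, no overfull columns
  R <- matrix(rnorm(5 * 9), 5, 9)
  MR <- sinkhorn(R, 20, 0.5)
  expect_lt(max(abs(rowSums(MR) - 1)), 1e-10)
  expect_lt(max(colSums(MR)), 1 + 0.05)

  expect_error(sinkhorn(matrix(c(1, Inf, 0, 1), 2)), "finite")
})

test_that("hard assignment takes the row argmax with lowest-index ties", {
  expect_equal(hard_assign(diag(4)), 1:4)
  expect_equal(hard_assign(matrix(0.25, 1, 4)), 1L)
  set.seed(3)
  A <- diag(5) * 8 + matrix(rnorm(25, sd = 0.1), 5)
  expect_equal(hard_assign(sinkhorn(A, 20, 1)), 1:5)
})

test_that("WL classes capture molecular symmetry", {
  expect_equal(length(wl_partition(mol_graph("c1ccccc1"))$classes), 1L)
  expect_equal(length(wl_partition(mol_graph("CCO"))$classes), 3L)
  sizes <- unname(sort(lengths(wl_partition(mol_graph("Cc1ccc(C)cc1"))$classes)))
  expect_equal(sizes, c(2L, 2L, 4L))
})

test_that("every automorphism orbit lies inside one WL class", {
  for (nm in names(fixture_smiles)) {
    mol <- parse_smiles(fixture_smiles[[nm]])
    wl <- wl_partition(mol)
    orbits <- automorphism_orbits(mol)
    for (o in unique(orbits)) {
      members <- which(orbits == o)
      expect_length(unique(wl$class_id[members]), 1L)
    }
  }
})

test_that("symmetry refinement redistributes collisions within WL classes", {
  benz_p <- wl_partition(mol_graph("c1ccccc1"))
  benz_r <- wl_partition(mol_graph("c1ccccc1"))
  # injective assignment untouched
  a <- symmetry_refine(1:6, benz_p, benz_r)
  expect_equal(as.integer(a), 1:6)
  expect_length(attr(a, "unresolved"), 0L)
  # collision: two atoms assigned to reactant atom 1
  a2 <- symmetry_refine(c(1L, 1L, 3L, 4L, 5L, 6L), benz_p, benz_r)
  expect_false(anyDuplicated(as.integer(a2)) > 0)
  expect_length(attr(a2, "unresolved"), 0L)
  # infeasible: singleton reactant class, collision stays and is flagged
  eth_p <- wl_partition(mol_graph("CC(C)C"))
  eth_r <- wl_partition(mol_graph("CCO"))
  a3 <- symmetry_refine(c(3L, 3L, 3L, 3L), eth_p, eth_r)
  expect_gt(length(attr(a3, "unresolved")), 0L)
})

test_that("consistency score matches algebra and the brute-force oracle", {
  g <- mol_graph("CCCCC")  # 5-node path
  expect_equal(consistency_score(diag(5), g$A, g$A), 2 * 4)

  n <- 4
  U <- matrix(1 / n, n, n)
  g2 <- mol_graph("CCCC")
  expect_equal(consistency_score(U, g2$A, g2$A), (2 * 3)^2 / n^2)

  # against the independent quadruple loop, soft and hard
  set.seed(4)
  M <- matrix(runif(20), 4, 5)
  A_P <- random_adjacency(4); A_R <- random_adjacency(5)
  expect_equal(consistency_score(M, A_P, A_R), brute_consistency(M, A_P, A_R))

  # a hard permutation counts preserved ordered bonded pairs
  perm <- c(3L, 1L, 4L, 2L, 5L)
  P <- matrix(0, 5, 5); P[cbind(1:5, perm)] <- 1
  A1 <- random_adjacency(5); A2 <- A1[order(perm), order(perm)]
  expect_equal(consistency_score(P, A1, A1),
               brute_consistency(P, A1, A1))

  # the planted relabeling of a path maximizes the score over all 120 perms
  path5 <- mol_graph("CCCCC")$A
  relab <- c(2L, 4L, 1L, 5L, 3L)  # new index of old atom
  A_rel <- matrix(0L, 5, 5)
  for (i in 1:5) for (j in 1:5) A_rel[relab[i], relab[j]] <- path5[i, j]
  best <- -Inf; argbest <- NULL
  for (p in all_perms(5L)) {
    P <- matrix(0, 5, 5); P[cbind(1:5, p)] <- 1
    sc <- consistency_score(P, path5, A_rel)
    if (sc > best) { best <- sc; argbest <- p }
  }
  Ptrue <- matrix(0, 5, 5); Ptrue[cbind(1:5, relab)] <- 1
  expect_equal(consistency_score(Ptrue, path5, A_rel), best)
})

test_that("symmetry-aware accuracy forgives symmetric permutations", {
  wl <- wl_partition(mol_graph("CCO"))
  expect_equal(symmetry_aware_accuracy(1:3, 1:3, wl), 1)
  benz <- wl_partition(mol_graph("c1ccccc1"))
  rotation <- c(2:6, 1L)
  expect_equal(symmetry_aware_accuracy(rotation, 1:6, benz), 1)
  # one of ten atoms mapped outside its class
  wl10 <- wl_partition(mol_graph("CCCCCCCCCC"))
  truth <- 1:10
  pred <- truth; pred[4] <- 1L
  expect_equal(symmetry_aware_accuracy(pred, truth, wl10), 0.9)
})
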