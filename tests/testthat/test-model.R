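test_that("encoder handles degenerate graphs and is deterministic", {
  cfg <- small_config(seed = 4)
  params <- init_params(cfg)
  g1 <- mol_graph("C")
  H <- encode(g1, params, cfg)
  expect_equal(dim(H), c(1L, cfg$hidden_dim))
  expect_equal(encode(g1, params, cfg), H)  # deterministic
  expect_error(encode(mol_graph("CCO", featurize = FALSE), params, cfg),
               "featurized")
})

test_that("encoder is permutation-equivariant", {
  cfg <- small_config(seed = 7)
  params <- init_params(cfg)
  for (smi in c("CC(=O)OCC", "Cc1ccc(C)cc1")) {
    g <- mol_graph(smi)
    H <- encode(g, params, cfg)
    set.seed(8)
    for (rep in 1:5) {
      perm <- sample(g$n_atoms)
      gp <- permute_graph(g, perm)
      Hp <- encode(gp, params, cfg)
      expect_equal(Hp, H[perm, , drop = FALSE], tolerance = 1e-10)
    }
  }
  # isomorphic graphs share the multiset of embedding rows
  g1 <- mol_graph("CC(C)O")
  g2 <- mol_graph("OC(C)C")
  k <- function(H) sort(apply(round(H, 8), 1L, paste, collapse = ","))
  expect_equal(k(encode(g2, params, cfg)), k(encode(g1, params, cfg)))
})

test_that("cross-attention gathers value projections of assigned atoms", {
  cfg <- small_config(seed = 2)
  params <- init_params(cfg)
  set.seed(3)
  H_R <- matrix(rnorm(5 * cfg$hidden_dim), 5)
  H_P <- matrix(rnorm(3 * cfg$hidden_dim), 3)
  a <- c(2L, 5L, 1L)
  Ht <- cross_attend(H_P, H_R, a, params, cfg)
  # softmax over a single candidate is 1: each row is exactly W_V h_{a_i}
  for (i in 1:3) expect_equal(Ht[i, ], as.vector(H_R[a[i], ] %*% params$Wv))
  # swapping two assignments swaps the corresponding output rows
  a2 <- c(5L, 2L, 1L)
  Ht2 <- cross_attend(H_P, H_R, a2, params, cfg)
  expect_equal(Ht2[1, ], Ht[2, ])
  expect_equal(Ht2[2, ], Ht[1, ])
  # identity assignment with H_R = H_P: value projections of H_P itself
  Ht3 <- cross_attend(H_P, H_P, 1:3, params, cfg)
  expect_equal(Ht3, H_P %*% params$Wv)
})

test_that("enrichment concatenates and preserves the encoder half", {
  H <- matrix(1:6, 3, 2)
  Z <- matrix(0, 3, 2)
  E <- enrich(H, Z)
  expect_equal(dim(E), c(3L, 4L))
  expect_equal(E[, 1:2], H)
  expect_equal(E[, 3:4], Z)
  expect_error(enrich(H, matrix(0, 2, 2)), "row mismatch")
})

test_that("dual encoder returns one embedding per bond", {
  cfg <- small_config(seed = 5)
  params <- init_params(cfg)
  expect_equal(nrow(encode_dual(build_dual_graph(mol_graph("C")), params, cfg)), 0L)
  HD <- encode_dual(build_dual_graph(mol_graph("CCO")), params, cfg)
  expect_equal(dim(HD), c(2L, cfg$hidden_dim))
})

test_that("heads behave per their closed-form degenerate cases", {
  cfg <- small_config(seed = 6)
  params <- init_params(cfg)
  h <- cfg$hidden_dim
  zero <- params
  zero$atom <- lapply(params$atom, function(x) x * 0)
  zero$bond <- lapply(params$bond, function(x) x * 0)
  Hhat <- matrix(rnorm(4 * 2 * h), 4)
  expect_equal(atom_head(Hhat, zero), rep(0.5, 4))
  # monotone in the output bias
  zero$atom$b2 <- 2
  expect_true(all(atom_head(Hhat, zero) > 0.5))

  g <- mol_graph("CCO")
  dual <- build_dual_graph(g)
  HD <- encode_dual(dual, params, cfg)
  Hh <- cbind(encode(g, params, cfg), matrix(0, 3, h))
  ys <- atom_head(Hh, params)
  expect_length(ys, 3L)
  expect_true(all(ys > 0 & ys < 1))
  zs <- bond_head(Hh, g$E, HD, ys, g$bonds, params)
  expect_length(zs, 2L)
  # orientation invariance: reversing every bond's (i, j) leaves scores alone
  rev_bonds <- data.frame(i = g$bonds$j, j = g$bonds$i)
  zs_rev <- bond_head(Hh, g$E, HD, ys, rev_bonds, params)
  expect_equal(zs_rev, zs)
  expect_equal(bond_head(Hh, g$E, HD, ys, g$bonds, zero), rep(0.5, 2))

  probs <- classify(Hh, params, cfg)
  expect_length(probs, cfg$n_classes)
  expect_equal(sum(probs), 1)
  # identical rows pool to that row
  one <- matrix(rnorm(2 * h), 1)
  rep4 <- one[rep(1, 4), , drop = FALSE]
  expect_equal(classify(rep4, params, cfg), classify(one, params, cfg))
})

test_that("model_forward wires modes and teacher forcing correctly", {
  cfg <- small_config(seed = 9)
  params <- init_params(cfg)
  ds <- generate_reactions(generator_config(n_reactions = 2, seed = 13))
  rx <- parse_reaction(ds$rxn_smiles[1], ds$class[1])

  full <- model_forward(rx, params, cfg, mode = "full")
  expect_s3_class(full$correspondence, "correspondence_matrix")
  expect_true(all(full$edit_scores$atom_scores > 0 &
                    full$edit_scores$atom_scores < 1))
  expect_equal(sum(full$class_scores), 1)
  # determinism
  full2 <- model_forward(rx, params, cfg, mode = "full")
  expect_equal(full2$edit_scores$atom_scores, full$edit_scores$atom_scores)

  # teacher path (atom-mapped input) uses the ground-truth assignment
  expect_equal(full$correspondence$assignment, rx$atom_map)
  # explicit assignment overrides and changes the attended embeddings
  alt <- model_forward(rx, params, cfg, mode = "full",
                       assignment = full$correspondence$hard)
  expect_equal(alt$correspondence$assignment, full$correspondence$hard)

  po <- model_forward(rx, params, cfg, mode = "products_only")
  expect_s3_class(po$correspondence, "correspondence_matrix")

  # products_only without reactants: no mapping output, heads still run
  prod_only <- structure(list(reactants = NULL, product = rx$product,
                              atom_map = NULL, class_label = NULL,
                              raw_smiles = ""), class = "rxn_reaction")
  out <- model_forward(prod_only, params, cfg, mode = "products_only")
  expect_null(out$correspondence)
  expect_length(out$edit_scores$atom_scores, rx$product$n_atoms)
  expect_error(model_forward(prod_only, params, cfg, mode = "full"),
               "reactants")
})

test_that("analytic gradients match finite differences end to end", {
  cfg <- encoder_config(num_layers = 2L, hidden_dim = 8L, num_heads = 2L,
                        dual_layers = 1L, n_classes = 10L, seed = 3L)
  params <- init_params(cfg)
  ds <- generate_reactions(generator_config(n_reactions = 1, seed = 5))
  rx <- parse_reaction(ds$rxn_smiles[1], ds$class[1])
  prep <- rxngraph:::.prepare_reaction(rx)
  for (lconf in list(loss_config(), loss_config(weighting = "uncertainty"))) {
    lossfn <- function(p) {
      fwd <- rxngraph:::.forward_reaction(prep, p, cfg, mode = "full",
                                          teacher = TRUE)
      unname(rxngraph:::.backward_reaction(prep, fwd, p, cfg, lconf,
                                           rxngraph:::.zeros_like(p))$losses["total"])
    }
    fwd <- rxngraph:::.forward_reaction(prep, params, cfg, mode = "full",
                                        teacher = TRUE)
    bk <- rxngraph:::.backward_reaction(prep, fwd, params, cfg, lconf,
                                        rxngraph:::.zeros_like(params))
    getp <- function(pp, path) { for (nm in path) pp <- pp[[nm]]; pp }
    setp <- function(pp, path, idx, val) {
      if (length(path) == 1L) { pp[[path[[1]]]][idx] <- val; return(pp) }
      pp[[path[[1]]]] <- setp(pp[[path[[1]]]], path[-1], idx, val)
      pp
    }
    set.seed(11)
    paths <- list(list("W_in"), list("b_in"), list("enc", 1L, "W1"),
                  list("enc", 2L, "We"), list("enc", 1L, "gate"),
                  list("enc", 2L, "eps"), list("Wv"), list("atom", "W1"),
                  list("bond", "W1"), list("cls", "W2"),
                  list("dual", 1L, "W1"), list("Wd_in"))
    if (lconf$weighting == "uncertainty") paths <- c(paths, list(list("log_sigma2")))
    for (path in paths) {
      g_an <- getp(bk$grads, path)
      idx <- sample(length(g_an), 1L)
      h <- 1e-5
      v0 <- getp(params, path)[idx]
      fd <- (lossfn(setp(params, path, idx, v0 + h)) -
               lossfn(setp(params, path, idx, v0 - h))) / (2 * h)
      expect_equal(unname(g_an[idx]), fd, tolerance = 1e-4,
                   info = paste(unlist(path), collapse = "$"))
    }
  }
})
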