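# Shared fixtures and independent brute-force oracles.

# small molecules (all <= 8 heavy atoms) exercising symmetry, rings,
# heteroatoms and branching
fixture_smiles <- c(
  benzene = "c1ccccc1",
  para_xylene = "Cc1ccc(C)cc1",
  ethanol = "CCO",
  isobutane = "CC(C)C",
  cyclopropane = "C1CC1",
  acetic_acid = "CC(=O)O",
  furan = "c1ccoc1",
  butadiene = "C=CC=C"
)

# all permutations of 1..n as a list (n <= 8 at call sites): insert n at
# every position of each permutation of 1..n-1
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# brute-force graph automorphisms (element- and adjacency-preserving
# permutations), found by backtracking
graph_automorphisms <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(0L, n, n)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1L
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1L
  }
  el <- mol$atoms$element
  autos <- list()
  assign_next <- function(perm) {
    k <- length(perm) + 1L
    if (k > n) {
      autos[[length(autos) + 1L]] <<- perm
      return(invisible())
    }
    for (cand in seq_len(n)) {
      if (cand %in% perm) next
      if (el[cand] != el[k]) next
      ok <- TRUE
      for (prev in seq_len(k - 1L)) {
        if (A[k, prev] != A[cand, perm[prev]]) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(perm, cand))
    }
  }
  assign_next(integer(0))
  autos
}

# automorphism orbits as an atom -> orbit-id vector
automorphism_orbits <- function(mol) {
  autos <- graph_automorphisms(mol)
  n <- nrow(mol$atoms)
  orbit <- seq_len(n)
  for (p in autos) {
    for (i in seq_len(n)) {
      a <- min(orbit[i], orbit[p[i]])
      orbit[orbit == orbit[i] | orbit == orbit[p[i]]] <- a
    }
  }
  match(orbit, unique(orbit))
}

# independent quadruple-loop oracle for the structural consistency score
brute_consistency <- function(M, A_P, A_R) {
  total <- 0
  for (i in seq_len(nrow(A_P))) for (j in seq_len(nrow(A_P))) {
    if (A_P[i, j] == 0) next
    for (ip in seq_len(nrow(A_R))) for (jp in seq_len(nrow(A_R))) {
      total <- total + A_R[ip, jp] * M[i, ip] * M[j, jp]
    }
  }
  total
}

# rewrite a reaction SMILES with both sides' atom orders permuted; atom-map
# numbers travel with the atoms, so the reaction is unchanged
permute_reaction_smiles <- function(smiles, seed) {
  set.seed(seed)
  sides <- strsplit(smiles, ">>", fixed = TRUE)[[1L]]
  permute_side <- function(s) {
    mol <- rxngraph:::.mol_permute(parse_smiles(s), sample(nrow(parse_smiles(s)$atoms)))
    as.character(write_smiles(mol))
  }
  paste0(permute_side(sides[1L]), ">>", permute_side(sides[2L]))
}

# permute the atoms of a featurized graph; returns list(graph, perm) where
# new atom k is old atom perm[k]
permute_graph <- function(graph, perm) {
  mol_graph(rxngraph:::.mol_permute(graph$mol, perm))
}

# small random Erdos-Renyi-ish adjacency matrix (symmetric, zero diagonal)
random_adjacency <- function(n, p = 0.5) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p) { A[i, j] <- 1L; A[j, i] <- 1L }
  }
  A
}

small_config <- function(seed = 1L, ...) {
  encoder_config(num_layers = 2L, hidden_dim = 16L, num_heads = 2L,
                 dual_layers = 1L, n_classes = 10L, seed = seed, ...)
}
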