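# Soft graph matching --------------------------------------------------------

#' Raw similarity matrix between product and reactant embeddings
#'
#' @param H_P,H_R Embedding matrices (|V_P| x d and |V_R| x d).
#' @return The |V_P| x |V_R| matrix of pairwise dot products.
#' @export
similarity <- function(H_P, H_R) {
  H_P <- as.matrix(H_P); H_R <- as.matrix(H_R)
  if (ncol(H_P) != ncol(H_R)) {
    stop("embedding dimension mismatch: ", ncol(H_P), " vs ", ncol(H_R))
  }
  H_P %*% t(H_R)
}

#' Sinkhorn normalization of a similarity matrix
#'
#' Exponentiates `raw / temperature` and alternates row normalization with
#' capacity-constrained column scaling (only columns whose mass exceeds one
#' are shrunk) `iterations` times, finishing with a row normalization so
#' every product atom carries a proper distribution over reactant
#' candidates. On square inputs the result converges to a doubly stochastic
#' matrix (the row constraint pins the total mass to the column budget); on
#' rectangular |V_P| < |V_R| inputs rows sum to one while column sums stay
#' at most about one, so reactant atoms without a product counterpart
#' (leaving groups, reagents) are not forced to absorb probability mass.
#' The computation runs in the log domain, is unconditionally stable for
#' any input magnitude, and is smooth, so gradients can be traced back
#' through every scaling step.
#'
#' @param raw Real matrix of similarities (finite entries).
#' @param iterations Number of row+column sweeps (>= 1), default 10.
#' @param temperature Positive softmax temperature, default 0.1.
#' @return The soft correspondence matrix, entries in \[0, 1\].
#' @export
sinkhorn <- function(raw, iterations = 10L, temperature = 0.1) {
  # the max of the input is subtracted before exponentiation for numerical
  # stability; the scaling recursion is invariant to constant shifts
  .sinkhorn_cached(raw, iterations, temperature)$M
}

#' Hard assignment from a soft correspondence matrix
#'
#' Row-wise argmax; ties are broken toward the lowest reactant index.
#'
#' @param soft Soft correspondence matrix (|V_P| x |V_R|).
#' @return Integer vector: reactant index per product atom.
#' @export
hard_assign <- function(soft) {
  soft <- as.matrix(soft)
  apply(soft, 1L, which.max)
}

# Weisfeiler-Lehman symmetry classes -----------------------------------------

#' Weisfeiler-Lehman equivalence classes of a molecular graph
#'
#' Colors start from the atom-type tuple (element, formal charge, aromatic
#' flag) and are refined by rehashing (own color, sorted multiset of
#' neighbour colors) until a fixed point (or `max_iterations`). Atoms with
#' identical final colors and identical elements form one equivalence
#' class; every automorphism orbit is contained in a single class.
#'
#' @param graph A `mol_graph` (or `rxn_mol`).
#' @param max_iterations Cap on refinement rounds; defaults to the atom
#'   count, which always reaches the fixed point.
#' @return A `wl_partition`: list with `class_id` (integer per atom),
#'   `classes` (list of atom index vectors) and `labels_per_iteration`
#'   (color history, one character vector per round).
#' @export
wl_partition <- function(graph, max_iterations = NULL) {
  mol <- if (inherits(graph, "mol_graph")) graph$mol else graph
  stopifnot(inherits(mol, "rxn_mol"))
  n <- mol_n_atoms(mol)
  if (!n) stop("wl_partition() requires a nonempty graph")
  if (is.null(max_iterations)) max_iterations <- n
  adj <- mol_adjlist(mol)
  color <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$aromatic)
  history <- list(color)
  for (it in seq_len(max_iterations)) {
    new_color <- vapply(seq_len(n), function(i) {
      paste(color[i], "|", paste(sort(color[adj[[i]]]), collapse = ","))
    }, character(1))
    # relabel to compact ids so strings do not grow without bound
    new_color <- as.character(match(new_color, sort(unique(new_color))))
    history[[length(history) + 1L]] <- new_color
    if (length(unique(new_color)) == length(unique(color))) {
      color <- new_color
      break
    }
    color <- new_color
  }
  key <- paste(color, mol$atoms$element)
  class_id <- match(key, unique(key))
  structure(list(
    class_id = class_id,
    classes = split(seq_len(n), class_id),
    labels_per_iteration = history
  ), class = "wl_partition")
}

#' @export
print.wl_partition <- function(x, ...) {
  cat(sprintf("<wl_partition> %d atoms in %d class(es)\n",
              length(x$class_id), length(x$classes)))
  invisible(x)
}

#' Symmetry-aware refinement of a hard assignment
#'
#' Within each product WL class (in lowest-index order), colliding
#' assignments are redistributed greedily over unused members of the
#' targeted reactant equivalence class, restoring injectivity where the
#' class has enough members. Already-injective assignments are untouched;
#' infeasible collisions are left as-is and flagged via the `unresolved`
#' attribute.
#'
#' @param assignment Integer vector, reactant index per product atom.
#' @param product_partition,reactant_partition `wl_partition`s of the two
#'   graphs.
#' @return The refined assignment (attribute `unresolved`: product atom
#'   indices whose collision could not be resolved).
#' @export
symmetry_refine <- function(assignment, product_partition, reactant_partition) {
  stopifnot(inherits(product_partition, "wl_partition"),
            inherits(reactant_partition, "wl_partition"))
  a <- as.integer(assignment)
  unresolved <- integer(0)
  for (cls in product_partition$classes) {
    members <- sort(cls)
    taken <- integer(0)
    for (i in members) {
      t <- a[i]
      if (!(t %in% taken)) {
        taken <- c(taken, t)
      } else {
        rcls <- which(reactant_partition$class_id == reactant_partition$class_id[t])
        free <- setdiff(sort(rcls), taken)
        if (length(free)) {
          a[i] <- free[1L]
          taken <- c(taken, free[1L])
        } else {
          unresolved <- c(unresolved, i)
        }
      }
    }
  }
  attr(a, "unresolved") <- unresolved
  a
}

# Structural consistency and mapping metrics ----------------------------------

#' Structural consistency score of a soft correspondence
#'
#' Computes the quadratic-assignment objective
#' sum over ordered pairs of A_P(i,j) A_R(i',j') M(i,i') M(j,j'): the mass of
#' product bonds whose endpoint alignments land on reactant bonds. For a
#' hard permutation this counts the ordered bonded pairs preserved by the
#' permutation (2 x the number of preserved undirected bonds).
#'
#' @param M Soft (or hard 0/1) correspondence matrix.
#' @param A_P,A_R Adjacency matrices of product and reactant graphs.
#' @return A single number.
#' @export
consistency_score <- function(M, A_P, A_R) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == nrow(A_P), ncol(M) == nrow(A_R))
  sum((t(M) %*% A_P %*% M) * A_R)
}

#' Symmetry-aware atom-mapping accuracy
#'
#' Fraction of product atoms whose predicted reactant atom lies in the same
#' reactant WL equivalence class as the ground-truth reactant atom, so any
#' symmetrically valid mapping (e.g. a benzene ring rotation) scores
#' perfectly.
#'
#' @param predicted,truth Integer assignments (reactant index per product
#'   atom), both total.
#' @param reactant_partition `wl_partition` of the reactant graph.
#' @return Accuracy in \[0, 1\].
#' @export
symmetry_aware_accuracy <- function(predicted, truth, reactant_partition) {
  stopifnot(length(predicted) == length(truth),
            inherits(reactant_partition, "wl_partition"))
  cid <- reactant_partition$class_id
  mean(cid[as.integer(predicted)] == cid[as.integer(truth)])
}
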