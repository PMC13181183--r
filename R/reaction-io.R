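# Feature vocabularies ------------------------------------------------------
#
# Closed one-hot vocabularies with a reserved "other" bucket so the feature
# width is constant across runs. Elements cover the species common in organic
# reaction corpora; everything else falls into "other".

FEATURE_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                      "B", "Si", "Sn", "Se", "Cu", "Zn", "Mg")
FEATURE_CHARGES <- -2:2
FEATURE_CHIRAL <- c("none", "@", "@@")
FEATURE_HYBRID <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
FEATURE_DEGREES <- 0:6
FEATURE_HCOUNTS <- 0:4
FEATURE_BOND_TYPES <- c("single", "double", "triple", "aromatic")
FEATURE_BOND_STEREO <- c("none", "Z", "E")

# one-hot over a closed vocabulary plus trailing "other" bucket
.one_hot_other <- function(values, vocab) {
  idx <- match(values, vocab)
  idx[is.na(idx)] <- length(vocab) + 1L
  out <- matrix(0, length(values), length(vocab) + 1L)
  out[cbind(seq_along(values), idx)] <- 1
  out
}

#' Atom and bond feature dimensions
#'
#' The atom feature vector concatenates one-hot blocks for element, formal
#' charge, chirality tag, hybridization, degree and total hydrogen count
#' (each closed by an "other" bucket where categorical), plus binary
#' aromaticity and ring-membership flags. Bond features concatenate bond
#' type, a conjugation flag, a stereo tag and a ring flag.
#'
#' @return Named list with `d_x` (atom feature width) and `d_e` (bond
#'   feature width).
#' @export
feature_dims <- function() {
  list(
    d_x = (length(FEATURE_ELEMENTS) + 1L) + (length(FEATURE_CHARGES) + 1L) +
      (length(FEATURE_CHIRAL) + 1L) + (length(FEATURE_HYBRID) + 1L) + 1L +
      length(FEATURE_DEGREES) + length(FEATURE_HCOUNTS) + 1L,
    d_e = (length(FEATURE_BOND_TYPES) + 1L) + 1L +
      (length(FEATURE_BOND_STEREO) + 1L) + 1L
  )
}

# simple hybridization assignment from bond pattern; aromatic atoms are sp2
.hybridization <- function(mol) {
  n <- mol_n_atoms(mol)
  n_double <- integer(n); n_triple <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$aromatic[k]) next
      if (mol$bonds$order[k] == 2) {
        n_double[mol$bonds$i[k]] <- n_double[mol$bonds$i[k]] + 1L
        n_double[mol$bonds$j[k]] <- n_double[mol$bonds$j[k]] + 1L
      } else if (mol$bonds$order[k] == 3) {
        n_triple[mol$bonds$i[k]] <- n_triple[mol$bonds$i[k]] + 1L
        n_triple[mol$bonds$j[k]] <- n_triple[mol$bonds$j[k]] + 1L
      }
    }
  }
  vapply(seq_len(n), function(i) {
    if (mol$atoms$aromatic[i]) return("sp2")
    if (n_triple[i] >= 1L || n_double[i] >= 2L) return("sp")
    if (n_double[i] == 1L) return("sp2")
    if (mol$atoms$element[i] %in% ORGANIC_SUBSET) return("sp3")
    "other"
  }, character(1))
}

# Molecular graph container --------------------------------------------------

#' Build a molecular graph from an internal molecule
#'
#' Wraps a parsed molecule into the `mol_graph` container used throughout:
#' symmetric binary adjacency matrix, canonical bond list (i < j), both
#' directed bond copies for message passing, per-atom component index and
#' (optionally) feature matrices `X` and `E`.
#'
#' @param mol A `rxn_mol`, or a SMILES string.
#' @param featurize Populate `X`/`E` immediately.
#' @return A `mol_graph`.
#' @export
mol_graph <- function(mol, featurize = TRUE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "rxn_mol"))
  n <- mol_n_atoms(mol)
  A <- matrix(0L, n, n)
  nb <- nrow(mol$bonds)
  if (nb) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1L
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1L
  }
  edges_dir <- if (nb) {
    data.frame(
      src = c(mol$bonds$i, mol$bonds$j),
      dst = c(mol$bonds$j, mol$bonds$i),
      bond = rep(seq_len(nb), 2L)
    )
  } else data.frame(src = integer(0), dst = integer(0), bond = integer(0))
  g <- structure(list(
    mol = mol,
    n_atoms = n,
    A = A,
    bonds = mol$bonds[, c("i", "j"), drop = FALSE],
    edges_dir = edges_dir,
    component_ids = mol_components(mol),
    ring_bonds = mol_ring_bonds(mol),
    X = NULL, E = NULL
  ), class = "mol_graph")
  if (featurize) g <- featurize(g) # nolint
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, %d component(s)%s\n",
              x$n_atoms, nrow(x$bonds), length(unique(x$component_ids)),
              if (is.null(x$X)) "" else sprintf(", featurized (d_x=%d, d_e=%d)",
                                               ncol(x$X), ncol(x$E))))
  invisible(x)
}

#' Compute atom and bond feature matrices
#'
#' Populates `X` (|V| x d_x) and `E` (|E| x d_e) on a [mol_graph()] using the
#' fixed one-hot vocabularies of [feature_dims()]. Out-of-vocabulary
#' categories land in a reserved "other" bucket, so featurization never
#' fails. Conjugation is flagged for aromatic bonds and for bonds whose
#' endpoints both carry some multiple or aromatic bond.
#'
#' @param graph A `mol_graph`.
#' @return The graph with `X` and `E` filled in.
#' @export
featurize <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  mol <- graph$mol
  n <- graph$n_atoms
  deg <- mol_degree(mol)
  ring_atoms <- mol_ring_atoms(mol, graph$ring_bonds)
  hyb <- .hybridization(mol)
  X <- cbind(
    .one_hot_other(mol$atoms$element, FEATURE_ELEMENTS),
    .one_hot_other(mol$atoms$charge, FEATURE_CHARGES),
    .one_hot_other(mol$atoms$chiral, FEATURE_CHIRAL),
    .one_hot_other(hyb, FEATURE_HYBRID),
    matrix(as.numeric(mol$atoms$aromatic), n, 1L),
    .one_hot_other(pmin(deg, max(FEATURE_DEGREES)), FEATURE_DEGREES)[, seq_along(FEATURE_DEGREES), drop = FALSE],
    .one_hot_other(pmin(mol$atoms$nH, max(FEATURE_HCOUNTS)), FEATURE_HCOUNTS)[, seq_along(FEATURE_HCOUNTS), drop = FALSE],
    matrix(as.numeric(ring_atoms), n, 1L)
  )
  nb <- nrow(mol$bonds)
  bond_type <- if (nb) ifelse(mol$bonds$aromatic, "aromatic",
    c("single", "double", "triple")[pmin(mol$bonds$order, 3)]) else character(0)
  has_multiple <- logical(n)
  if (nb) {
    multi <- mol$bonds$aromatic | mol$bonds$order >= 2
    has_multiple[unique(c(mol$bonds$i[multi], mol$bonds$j[multi]))] <- TRUE
  }
  conj <- if (nb) {
    as.numeric(mol$bonds$aromatic |
                 (has_multiple[mol$bonds$i] & has_multiple[mol$bonds$j]))
  } else numeric(0)
  E <- cbind(
    .one_hot_other(bond_type, FEATURE_BOND_TYPES),
    matrix(conj, nb, 1L),
    .one_hot_other(rep("none", nb), FEATURE_BOND_STEREO),
    matrix(as.numeric(graph$ring_bonds), nb, 1L)
  )
  dims <- feature_dims()
  stopifnot(ncol(X) == dims$d_x, nb == 0L || ncol(E) == dims$d_e)
  if (nb == 0L) E <- matrix(0, 0L, dims$d_e)
  graph$X <- X
  graph$E <- E
  graph
}

# Reaction parsing -----------------------------------------------------------

#' Parse a reaction SMILES into a reaction object
#'
#' Splits `reactants>>product` (dot-separated molecules allowed on either
#' side), parses both sides into featurized [mol_graph()]s and, when every
#' product atom carries an atom-map number found on the reactant side,
#' records the index-based atom map (product atom index -> reactant atom
#' index, 1-based). Atom-map numbers must be unique within each side.
#'
#' @param smiles Reaction SMILES string with exactly one `>>`.
#' @param class_label Optional reaction class (integer in 1..K).
#' @return A `rxn_reaction` with fields `reactants`, `product`, `atom_map`
#'   (or `NULL`), `class_label`, `raw_smiles`.
#' @examples
#' rx <- parse_reaction("CC(=O)O.OCC>>CC(=O)OCC")
#' rx$product$n_atoms
#' @export
parse_reaction <- function(smiles, class_label = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (lengths(regmatches(smiles, gregexpr(">>", smiles, fixed = TRUE))) != 1L) {
    stop("reaction SMILES must contain exactly one '>>' separator: ", smiles)
  }
  sides <- strsplit(smiles, ">>", fixed = TRUE)[[1L]]
  if (length(sides) != 2L || !nzchar(sides[1L]) || !nzchar(sides[2L])) {
    stop("reaction SMILES must have non-empty reactant and product sides")
  }
  mol_r <- tryCatch(parse_smiles(sides[1L]), error = function(e) {
    stop("failed to parse reactant side: ", conditionMessage(e), call. = FALSE)
  })
  mol_p <- tryCatch(parse_smiles(sides[2L]), error = function(e) {
    stop("failed to parse product side: ", conditionMessage(e), call. = FALSE)
  })
  for (side in list(reactant = mol_r, product = mol_p)) {
    maps <- side$atoms$map[side$atoms$map > 0L]
    if (anyDuplicated(maps)) {
      stop("duplicate atom-map number(s) on one reaction side: ",
           paste(unique(maps[duplicated(maps)]), collapse = ", "))
    }
  }
  atom_map <- NULL
  pmaps <- mol_p$atoms$map
  if (any(pmaps > 0L)) {
    orphans <- setdiff(pmaps[pmaps > 0L], mol_r$atoms$map)
    if (length(orphans)) {
      stop("product atom-map number(s) absent from reactants: ",
           paste(sort(orphans), collapse = ", "))
    }
    if (all(pmaps > 0L)) {
      atom_map <- match(pmaps, mol_r$atoms$map)
    }
  }
  if (!is.null(class_label)) {
    stopifnot(is.numeric(class_label), length(class_label) == 1L, class_label >= 1)
    class_label <- as.integer(class_label)
  }
  structure(list(
    reactants = mol_graph(mol_r),
    product = mol_graph(mol_p),
    atom_map = atom_map,
    class_label = class_label,
    raw_smiles = smiles
  ), class = "rxn_reaction")
}

#' @export
print.rxn_reaction <- function(x, ...) {
  cat(sprintf("<rxn_reaction> %d reactant atoms >> %d product atoms%s%s\n",
              x$reactants$n_atoms, x$product$n_atoms,
              if (is.null(x$atom_map)) "" else ", atom-mapped",
              if (is.null(x$class_label)) "" else paste0(", class ", x$class_label)))
  invisible(x)
}

#' Serialize a reaction back to reaction SMILES
#'
#' @param reaction A `rxn_reaction`.
#' @return A reaction SMILES string (current atom order, maps included).
#' @export
write_reaction_smiles <- function(reaction) {
  stopifnot(inherits(reaction, "rxn_reaction"))
  paste0(as.character(write_smiles(reaction$reactants$mol)), ">>",
         as.character(write_smiles(reaction$product$mol)))
}

# Dual (line) graph ----------------------------------------------------------

#' Build the dual (line) graph of a product graph
#'
#' Every bond of the input becomes a dual node (ordered by the canonical
#' (i, j) bond list); two dual nodes are adjacent iff their bonds share an
#' atom. Bond feature vectors become the initial dual node features. A
#' bond-free graph yields an empty dual graph.
#'
#' @param product A featurized `mol_graph`.
#' @return A `dual_graph` with `n_nodes`, `edges` (data.frame a < b),
#'   `node_features`, and `incidence` (the bond list, mapping product bond k
#'   to dual node k).
#' @export
build_dual_graph <- function(product) {
  stopifnot(inherits(product, "mol_graph"))
  bonds <- product$bonds
  nb <- nrow(bonds)
  ea <- integer(0); eb <- integer(0)
  if (nb > 1L) {
    for (a in seq_len(nb - 1L)) {
      for (b in (a + 1L):nb) {
        shared <- length(intersect(c(bonds$i[a], bonds$j[a]),
                                   c(bonds$i[b], bonds$j[b])))
        if (shared == 1L) { ea <- c(ea, a); eb <- c(eb, b) }
      }
    }
  }
  structure(list(
    n_nodes = nb,
    edges = data.frame(a = ea, b = eb),
    node_features = if (is.null(product$E)) NULL else product$E,
    incidence = bonds
  ), class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf("<dual_graph> %d bond nodes, %d dual edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

# Canonicalization -----------------------------------------------------------

#' Canonicalize an atom-mapped reaction and regenerate its alignment
#'
#' Rewrites the product in canonical atom order (canonical SMILES emission
#' order), renumbers atom maps 1..|V_P| along that order, transfers the new
#' numbers to the mapped reactant atoms (reactant atom order is left
#' unchanged), and re-parses the canonical reaction SMILES. Idempotent: a
#' second application returns an identical reaction, and any permutation of
#' the input product atom order yields the same canonical output.
#'
#' @param reaction A `rxn_reaction` with a ground-truth atom map.
#' @return The canonicalized `rxn_reaction` (attribute `canonical_smiles`
#'   holds the emitted string).
#' @export
canonicalize_and_remap <- function(reaction) {
  stopifnot(inherits(reaction, "rxn_reaction"))
  if (is.null(reaction$atom_map)) {
    stop("canonicalize_and_remap() requires a reaction with a ground-truth atom map")
  }
  prod_mol <- reaction$product$mol
  react_mol <- reaction$reactants$mol
  s1 <- write_smiles(prod_mol, canonical = TRUE)
  emission <- attr(s1, "emission_order")
  new_map <- integer(mol_n_atoms(prod_mol))
  new_map[emission] <- seq_along(emission)
  prod_mol$atoms$map <- new_map
  react_mol$atoms$map <- 0L
  react_mol$atoms$map[reaction$atom_map] <- new_map
  rxn_smiles <- paste0(
    as.character(write_smiles(react_mol)), ">>",
    as.character(write_smiles(prod_mol, canonical = TRUE))
  )
  out <- parse_reaction(rxn_smiles, class_label = reaction$class_label)
  attr(out, "canonical_smiles") <- rxn_smiles
  out
}

# Dataset I/O ----------------------------------------------------------------

#' Read a reaction dataset from CSV
#'
#' Expects a header `id,rxn_smiles,class` (class may be empty). Also accepts
#' headerless two-column `rxn_smiles<TAB>class` lines via `format = "tsv"`.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return A tibble with columns `id`, `rxn_smiles`, `class`.
#' @export
read_dataset <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "rxn_smiles") %in% names(df)))
    if (!"class" %in% names(df)) df$class <- NA_integer_
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- "rxn_smiles"
    df$class <- if (ncol(df) >= 2L) as.integer(df[[2L]]) else NA_integer_
    df$id <- seq_len(nrow(df))
  }
  tibble::tibble(id = df$id, rxn_smiles = df$rxn_smiles,
                 class = as.integer(df$class))
}

#' Write a reaction dataset to CSV
#'
#' @param reactions A tibble/data.frame with columns `id`, `rxn_smiles`,
#'   `class` (as produced by [generate_reactions()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(reactions, path) {
  stopifnot(all(c("id", "rxn_smiles", "class") %in% names(reactions)))
  utils::write.csv(
    as.data.frame(reactions[, c("id", "rxn_smiles", "class")]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Split a dataset into train/validation/test partitions
#'
#' Deterministic 8:1:1 split by default: partition sizes are the largest
#' counts consistent with the ratios (within one reaction of exact), and
#' rows are assigned after an optional seeded shuffle.
#'
#' @param reactions Dataset tibble.
#' @param ratios Length-3 nonnegative weights for train/validation/test.
#' @param seed Optional integer seed for shuffling before assignment.
#' @return The tibble with an added `split` column
#'   (`"train"`, `"validation"`, `"test"`).
#' @export
split_dataset <- function(reactions, ratios = c(8, 1, 1), seed = NULL) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  n <- nrow(reactions)
  idx <- seq_len(n)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    idx <- sample(idx)
  }
  p <- cumsum(ratios) / sum(ratios)
  cuts <- round(p * n)
  split <- character(n)
  split[idx[seq_len(cuts[1L])]] <- "train"
  if (cuts[2L] > cuts[1L]) split[idx[(cuts[1L] + 1L):cuts[2L]]] <- "validation"
  if (n > cuts[2L]) split[idx[(cuts[2L] + 1L):n]] <- "test"
  reactions$split <- split
  reactions
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
}
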