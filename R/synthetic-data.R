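# Synthetic atom-mapped reaction generator -----------------------------------
#
# Ten hand-coded transformation templates applied to sampled scaffolds.
# Templates are written directly as graph edits (atoms, bonds, hydrogen
# counts, charges are constructed explicitly), so the ground-truth atom map
# and edit set are exact by construction and independent of the labeling
# code they are used to test. Atom-map numbers equal the product atom
# construction order (1..|V_P|); reactant-only atoms (leaving groups,
# reagents) stay unmapped.

# -- small molecule builders -------------------------------------------------

.mol_empty <- function() {
  new_mol(
    data.frame(element = character(0), aromatic = logical(0),
               charge = integer(0), nH = integer(0), map = integer(0),
               chiral = character(0), stringsAsFactors = FALSE),
    data.frame(i = integer(0), j = integer(0), order = numeric(0),
               aromatic = logical(0))
  )
}

.mol_add_atom <- function(mol, element, nH, charge = 0L, aromatic = FALSE, map = 0L) {
  mol$atoms <- rbind(mol$atoms, data.frame(
    element = element, aromatic = aromatic, charge = as.integer(charge),
    nH = as.integer(nH), map = as.integer(map), chiral = "none",
    stringsAsFactors = FALSE
  ))
  list(mol = mol, idx = nrow(mol$atoms))
}

.mol_add_bond <- function(mol, a, b, order = 1, aromatic = FALSE, consume_h = TRUE) {
  if (consume_h) {
    mol$atoms$nH[a] <- mol$atoms$nH[a] - order
    mol$atoms$nH[b] <- mol$atoms$nH[b] - order
    if (mol$atoms$nH[a] < 0L || mol$atoms$nH[b] < 0L) {
      stop("template produced a negative hydrogen count")
    }
  }
  mol$bonds <- rbind(mol$bonds, data.frame(
    i = min(a, b), j = max(a, b), order = order, aromatic = aromatic
  ))
  mol
}

.mol_append <- function(mol, frag) {
  off <- nrow(mol$atoms)
  mol$atoms <- rbind(mol$atoms, frag$atoms)
  if (nrow(frag$bonds)) {
    fb <- frag$bonds
    fb$i <- fb$i + off; fb$j <- fb$j + off
    mol$bonds <- rbind(mol$bonds, fb)
  }
  list(mol = mol, offset = off)
}

.mol_finalize <- function(mol) {
  if (nrow(mol$bonds)) {
    lo <- pmin(mol$bonds$i, mol$bonds$j)
    hi <- pmax(mol$bonds$i, mol$bonds$j)
    mol$bonds$i <- lo; mol$bonds$j <- hi
    mol$bonds <- mol$bonds[order(mol$bonds$i, mol$bonds$j), , drop = FALSE]
    rownames(mol$bonds) <- NULL
  }
  rownames(mol$atoms) <- NULL
  mol
}

.mol_permute <- function(mol, perm) {
  # perm[k] = old index placed at new position k
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mol$atoms <- mol$atoms[perm, , drop = FALSE]
  if (nrow(mol$bonds)) {
    mol$bonds$i <- inv[mol$bonds$i]
    mol$bonds$j <- inv[mol$bonds$j]
  }
  .mol_finalize(mol)
}

# fragment with sequential map tags starting at `start`; attachment atom is
# always the fragment's first atom
.frag_tagged <- function(smiles, start) {
  mol <- parse_smiles(smiles)
  mol$atoms$map <- start + seq_len(mol_n_atoms(mol)) - 1L
  list(mol = mol, next_tag = start + mol_n_atoms(mol))
}

.frag_untagged <- function(smiles) {
  mol <- parse_smiles(smiles)
  mol$atoms$map <- 0L
  mol
}

# -- transformation templates ------------------------------------------------
#
# Each template returns list(product = mol, reactants = list(mol, ...),
# atom_edits = map numbers of reactive atoms,
# bond_edits = list of sorted map-number pairs of reactive product bonds).
# Templates receive already-chosen scaffold SMILES.

.tpl_ester_coupling <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c_tag <- f1$next_tag; o1_tag <- c_tag + 1L; o2_tag <- c_tag + 2L
  f2 <- .frag_tagged(r2, c_tag + 3L)
  build_acyl <- function(extra_oh) {
    m <- f1$mol
    r <- .mol_add_atom(m, "C", 4L, map = c_tag); m <- r$mol; ci <- r$idx
    m <- .mol_add_bond(m, 1L, ci)
    r <- .mol_add_atom(m, "O", 2L, map = o1_tag); m <- r$mol; oi <- r$idx
    m <- .mol_add_bond(m, ci, oi, order = 2)
    list(mol = m, ci = ci)
  }
  # product: R1-C(=O)-O-R2
  p <- build_acyl()
  r <- .mol_add_atom(p$mol, "O", 2L, map = o2_tag); pm <- r$mol; o2 <- r$idx
  pm <- .mol_add_bond(pm, p$ci, o2)
  ap <- .mol_append(pm, f2$mol); pm <- ap$mol
  pm <- .mol_add_bond(pm, o2, ap$offset + 1L)
  # reactant 1: R1-C(=O)-OH (the hydroxyl oxygen is unmapped, it leaves)
  a <- build_acyl()
  r <- .mol_add_atom(a$mol, "O", 2L, map = 0L); am <- r$mol
  am <- .mol_add_bond(am, a$ci, r$idx)
  # reactant 2: HO-R2
  r <- .mol_add_atom(.mol_empty(), "O", 2L, map = o2_tag); bm <- r$mol
  ab <- .mol_append(bm, f2$mol); bm <- ab$mol
  bm <- .mol_add_bond(bm, 1L, ab$offset + 1L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(bm)),
       atom_edits = o2_tag, bond_edits = list(sort(c(c_tag, o2_tag))))
}

.tpl_amide_coupling <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c_tag <- f1$next_tag; o_tag <- c_tag + 1L; n_tag <- c_tag + 2L
  f2 <- .frag_tagged(r2, c_tag + 3L)
  build_acyl <- function() {
    m <- f1$mol
    r <- .mol_add_atom(m, "C", 4L, map = c_tag); m <- r$mol; ci <- r$idx
    m <- .mol_add_bond(m, 1L, ci)
    r <- .mol_add_atom(m, "O", 2L, map = o_tag); m <- r$mol
    m <- .mol_add_bond(m, ci, r$idx, order = 2)
    list(mol = m, ci = ci)
  }
  p <- build_acyl()
  r <- .mol_add_atom(p$mol, "N", 3L, map = n_tag); pm <- r$mol; ni <- r$idx
  pm <- .mol_add_bond(pm, p$ci, ni)
  ap <- .mol_append(pm, f2$mol); pm <- ap$mol
  pm <- .mol_add_bond(pm, ni, ap$offset + 1L)
  a <- build_acyl()
  r <- .mol_add_atom(a$mol, "O", 2L, map = 0L); am <- r$mol
  am <- .mol_add_bond(am, a$ci, r$idx)
  r <- .mol_add_atom(.mol_empty(), "N", 3L, map = n_tag); bm <- r$mol
  ab <- .mol_append(bm, f2$mol); bm <- ab$mol
  bm <- .mol_add_bond(bm, 1L, ab$offset + 1L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(bm)),
       atom_edits = n_tag, bond_edits = list(sort(c(c_tag, n_tag))))
}

.tpl_ether_coupling <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  o_tag <- f1$next_tag
  f2 <- .frag_tagged(r2, o_tag + 1L)
  # product: R1-O-R2
  pm <- f1$mol
  r <- .mol_add_atom(pm, "O", 2L, map = o_tag); pm <- r$mol; oi <- r$idx
  pm <- .mol_add_bond(pm, 1L, oi)
  ap <- .mol_append(pm, f2$mol); pm <- ap$mol
  pm <- .mol_add_bond(pm, oi, ap$offset + 1L)
  # reactants: R1-Br, HO-R2
  am <- f1$mol
  r <- .mol_add_atom(am, "Br", 1L, map = 0L); am <- r$mol
  am <- .mol_add_bond(am, 1L, r$idx)
  r <- .mol_add_atom(.mol_empty(), "O", 2L, map = o_tag); bm <- r$mol
  ab <- .mol_append(bm, f2$mol); bm <- ab$mol
  bm <- .mol_add_bond(bm, 1L, ab$offset + 1L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(bm)),
       atom_edits = o_tag, bond_edits = list(sort(c(1L, o_tag))))
}

.tpl_amine_alkylation <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  n_tag <- f1$next_tag
  f2 <- .frag_tagged(r2, n_tag + 1L)
  pm <- f1$mol
  r <- .mol_add_atom(pm, "N", 3L, map = n_tag); pm <- r$mol; ni <- r$idx
  pm <- .mol_add_bond(pm, 1L, ni)
  ap <- .mol_append(pm, f2$mol); pm <- ap$mol
  pm <- .mol_add_bond(pm, ni, ap$offset + 1L)
  am <- f1$mol
  r <- .mol_add_atom(am, "Br", 1L, map = 0L); am <- r$mol
  am <- .mol_add_bond(am, 1L, r$idx)
  r <- .mol_add_atom(.mol_empty(), "N", 3L, map = n_tag); bm <- r$mol
  ab <- .mol_append(bm, f2$mol); bm <- ab$mol
  bm <- .mol_add_bond(bm, 1L, ab$offset + 1L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(bm)),
       atom_edits = n_tag, bond_edits = list(sort(c(1L, n_tag))))
}

.carbinol <- function(f1, f2, c_tag, o_tag, co_order) {
  m <- f1$mol
  r <- .mol_add_atom(m, "C", 4L, map = c_tag); m <- r$mol; ci <- r$idx
  m <- .mol_add_bond(m, 1L, ci)
  r <- .mol_add_atom(m, "O", 2L, map = o_tag); m <- r$mol
  m <- .mol_add_bond(m, ci, r$idx, order = co_order)
  ap <- .mol_append(m, f2$mol); m <- ap$mol
  m <- .mol_add_bond(m, ci, ap$offset + 1L)
  .mol_finalize(m)
}

.tpl_alcohol_oxidation <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c_tag <- f1$next_tag; o_tag <- c_tag + 1L
  f2 <- .frag_tagged(r2, c_tag + 2L)
  list(product = .carbinol(f1, f2, c_tag, o_tag, 2),
       reactants = list(.carbinol(f1, f2, c_tag, o_tag, 1)),
       atom_edits = c(c_tag, o_tag), bond_edits = list(sort(c(c_tag, o_tag))))
}

.tpl_ketone_reduction <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c_tag <- f1$next_tag; o_tag <- c_tag + 1L
  f2 <- .frag_tagged(r2, c_tag + 2L)
  list(product = .carbinol(f1, f2, c_tag, o_tag, 1),
       reactants = list(.carbinol(f1, f2, c_tag, o_tag, 2)),
       atom_edits = c(c_tag, o_tag), bond_edits = list(sort(c(c_tag, o_tag))))
}

.tpl_elimination <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c1_tag <- f1$next_tag; c2_tag <- c1_tag + 1L
  build <- function(order, with_br) {
    m <- f1$mol
    r <- .mol_add_atom(m, "C", 4L, map = c1_tag); m <- r$mol; c1 <- r$idx
    m <- .mol_add_bond(m, 1L, c1)
    r <- .mol_add_atom(m, "C", 4L, map = c2_tag); m <- r$mol; c2 <- r$idx
    m <- .mol_add_bond(m, c1, c2, order = order)
    if (with_br) {
      r <- .mol_add_atom(m, "Br", 1L, map = 0L); m <- r$mol
      m <- .mol_add_bond(m, c1, r$idx)
    }
    .mol_finalize(m)
  }
  list(product = build(2, FALSE), reactants = list(build(1, TRUE)),
       atom_edits = c2_tag, bond_edits = list(sort(c(c1_tag, c2_tag))))
}

.tpl_ester_hydrolysis <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  c_tag <- f1$next_tag; o1_tag <- c_tag + 1L; oh_tag <- c_tag + 2L
  build_acyl <- function() {
    m <- f1$mol
    r <- .mol_add_atom(m, "C", 4L, map = c_tag); m <- r$mol; ci <- r$idx
    m <- .mol_add_bond(m, 1L, ci)
    r <- .mol_add_atom(m, "O", 2L, map = o1_tag); m <- r$mol
    m <- .mol_add_bond(m, ci, r$idx, order = 2)
    list(mol = m, ci = ci)
  }
  # product: R1-C(=O)-OH with the hydroxyl oxygen mapped to water
  p <- build_acyl()
  r <- .mol_add_atom(p$mol, "O", 2L, map = oh_tag); pm <- r$mol
  pm <- .mol_add_bond(pm, p$ci, r$idx)
  # reactants: R1-C(=O)-O-R2 (ester oxygen and R2 unmapped) + water
  a <- build_acyl()
  r <- .mol_add_atom(a$mol, "O", 2L, map = 0L); am <- r$mol; oe <- r$idx
  am <- .mol_add_bond(am, a$ci, oe)
  ab <- .mol_append(am, .frag_untagged(r2)); am <- ab$mol
  am <- .mol_add_bond(am, oe, ab$offset + 1L)
  wr <- .mol_add_atom(.mol_empty(), "O", 2L, map = oh_tag)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(wr$mol)),
       atom_edits = oh_tag, bond_edits = list(sort(c(c_tag, oh_tag))))
}

.tpl_deprotonation <- function(r1, r2) {
  f1 <- .frag_tagged(r1, 1L)
  o_tag <- f1$next_tag
  # product: R1-[O-]
  pm <- f1$mol
  r <- .mol_add_atom(pm, "O", 1L, charge = -1L, map = o_tag); pm <- r$mol
  pm <- .mol_add_bond(pm, 1L, r$idx)
  # reactants: R1-OH + sodium counterion reagent (unmapped component)
  am <- f1$mol
  r <- .mol_add_atom(am, "O", 2L, map = o_tag); am <- r$mol
  am <- .mol_add_bond(am, 1L, r$idx)
  na <- .mol_add_atom(.mol_empty(), "Na", 0L, charge = 1L, map = 0L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(am), .mol_finalize(na$mol)),
       atom_edits = o_tag, bond_edits = list())
}

.tpl_aromatic_bromination <- function(r1, r2) {
  arene <- parse_smiles(r1)
  ch <- which(arene$atoms$aromatic & arene$atoms$nH >= 1L)
  if (!length(ch)) stop("infeasible: scaffold has no aromatic C-H for bromination")
  sub <- ch[1L]
  n_ar <- mol_n_atoms(arene)
  arene$atoms$map <- seq_len(n_ar)
  br_tag <- n_ar + 1L
  pm <- arene
  r <- .mol_add_atom(pm, "Br", 1L, map = br_tag); pm <- r$mol
  pm <- .mol_add_bond(pm, sub, r$idx)
  r <- .mol_add_atom(.mol_empty(), "Br", 1L, map = br_tag); bm <- r$mol
  r <- .mol_add_atom(bm, "Br", 1L, map = 0L); bm <- r$mol
  bm <- .mol_add_bond(bm, 1L, 2L)
  list(product = .mol_finalize(pm),
       reactants = list(.mol_finalize(arene), .mol_finalize(bm)),
       atom_edits = arene$atoms$map[sub],
       bond_edits = list(sort(c(arene$atoms$map[sub], br_tag))))
}

.templates <- function() {
  list(
    .tpl_ester_coupling, .tpl_amide_coupling, .tpl_ether_coupling,
    .tpl_amine_alkylation, .tpl_alcohol_oxidation, .tpl_ketone_reduction,
    .tpl_elimination, .tpl_ester_hydrolysis, .tpl_deprotonation,
    .tpl_aromatic_bromination
  )
}

.default_scaffolds <- c("C", "CC", "CCC", "CCCC", "CC(C)C")
.symmetric_scaffolds <- c("c1ccccc1", "Cc1ccc(C)cc1")
.arene_scaffolds <- c("c1ccccc1", "Cc1ccccc1")

#' Generator configuration
#'
#' @param n_reactions Number of reactions to generate.
#' @param seed Integer seed; generation is fully reproducible.
#' @param class_weights Nonnegative sampling weights over the 10 template
#'   classes (default uniform).
#' @param scaffold_pool SMILES of base fragments substituted into templates
#'   (attachment at the first atom).
#' @param symmetric_fraction Fraction of reactions whose scaffolds carry
#'   WL-nontrivial symmetry (aromatic rings), stressing mapping ambiguity.
#' @param permute_atoms Randomly permute atom order in every written
#'   molecule to defeat positional shortcuts.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_reactions = 100L, seed = 1L,
                             class_weights = rep(1, 10),
                             scaffold_pool = .default_scaffolds,
                             symmetric_fraction = 0.3,
                             permute_atoms = TRUE) {
  stopifnot(n_reactions >= 0, length(class_weights) == 10L,
            all(class_weights >= 0), sum(class_weights) > 0,
            symmetric_fraction >= 0, symmetric_fraction <= 1)
  structure(list(
    n_reactions = as.integer(n_reactions), seed = as.integer(seed),
    class_weights = class_weights, scaffold_pool = scaffold_pool,
    symmetric_fraction = symmetric_fraction,
    permute_atoms = isTRUE(permute_atoms)
  ), class = "generator_config")
}

#' Generate synthetic atom-mapped reactions with known edit sets
#'
#' Applies the ten built-in transformation templates (ester/amide/ether
#' couplings, amine alkylation, alcohol oxidation, ketone reduction,
#' elimination, ester hydrolysis, deprotonation, aromatic bromination) to
#' sampled scaffolds. Every emitted reaction carries a total, injective
#' ground-truth atom map (map numbers 1..|V_P|), the exact reactive atom and
#' bond sets, and its template class index in 1..10.
#'
#' @param config A [generator_config()] (or arguments passed through `...`).
#' @param ... Convenience: fields forwarded to [generator_config()] when
#'   `config` is missing.
#' @return A tibble with columns `id`, `rxn_smiles`, `class`, and
#'   list-columns `atom_edits` (reactive product atom-map numbers) and
#'   `bond_edits` (list of sorted map-number pairs).
#' @examples
#' reactions <- generate_reactions(generator_config(n_reactions = 5, seed = 7))
#' reactions$rxn_smiles[1]
#' @export
generate_reactions <- function(config = generator_config(...), ...) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  tpls <- .templates()
  rows <- vector("list", config$n_reactions)
  for (k in seq_len(config$n_reactions)) {
    cls <- sample.int(10L, 1L, prob = config$class_weights)
    symmetric <- stats::runif(1) < config$symmetric_fraction
    pool <- if (symmetric) .symmetric_scaffolds else config$scaffold_pool
    r1 <- sample(pool, 1L)
    r2 <- sample(config$scaffold_pool, 1L)
    if (cls %in% c(3L, 4L)) {
      # symmetric-linker templates (R1-O-R2, R1-NH-R2): distinct fragments
      # keep the ground-truth map identifiable up to graph symmetry
      tries <- 0L
      while (identical(r2, r1) && tries < 10L &&
             length(unique(c(config$scaffold_pool, pool))) > 1L) {
        r2 <- sample(config$scaffold_pool, 1L)
        tries <- tries + 1L
      }
      if (identical(r2, r1)) r1 <- pool[match(TRUE, pool != r2)] %||% r1
    }
    if (cls == 10L) {
      r1 <- if (symmetric) .arene_scaffolds[1L] else sample(.arene_scaffolds, 1L)
    }
    spec <- tryCatch(tpls[[cls]](r1, r2), error = function(e) {
      warning("skipping infeasible template/scaffold pair (class ", cls,
              ", scaffold ", r1, "): ", conditionMessage(e))
      NULL
    })
    if (is.null(spec)) next
    prod_mol <- spec$product
    react_mols <- spec$reactants
    if (config$permute_atoms) {
      prod_mol <- .mol_permute(prod_mol, sample(mol_n_atoms(prod_mol)))
      react_mols <- lapply(react_mols, function(m) {
        .mol_permute(m, sample(mol_n_atoms(m)))
      })
    }
    smi <- paste0(
      paste(vapply(react_mols, function(m) as.character(write_smiles(m)),
                   character(1)), collapse = "."),
      ">>", as.character(write_smiles(prod_mol))
    )
    rows[[k]] <- tibble::tibble(
      id = k, rxn_smiles = smi, class = cls,
      atom_edits = list(sort(spec$atom_edits)),
      bond_edits = list(spec$bond_edits)
    )
  }
  dplyr::bind_rows(rows)
}

#' Translate generator edit sets into product-indexed labels
#'
#' Converts map-number keyed edit sets (as emitted by
#' [generate_reactions()]) into 0/1 label vectors aligned to a parsed
#' reaction's product atoms and canonical bond list, for comparison against
#' [derive_edit_labels()].
#'
#' @param reaction A parsed `rxn_reaction`.
#' @param atom_edits Integer vector of reactive atom-map numbers.
#' @param bond_edits List of sorted map-number pairs of reactive bonds.
#' @return An `edit_labels` list.
#' @export
truth_edit_labels <- function(reaction, atom_edits, bond_edits) {
  pm <- reaction$product$mol$atoms$map
  atom_labels <- as.integer(pm %in% atom_edits)
  pb <- reaction$product$bonds
  keys <- vapply(bond_edits, function(p) paste(sort(p), collapse = "-"), character(1))
  bond_labels <- integer(nrow(pb))
  if (nrow(pb)) {
    bkey <- vapply(seq_len(nrow(pb)), function(k) {
      paste(sort(c(pm[pb$i[k]], pm[pb$j[k]])), collapse = "-")
    }, character(1))
    bond_labels <- as.integer(bkey %in% keys)
  }
  structure(list(atom_labels = atom_labels, bond_labels = bond_labels),
            class = "edit_labels")
}
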