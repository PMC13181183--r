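#' @keywords internal
"_PACKAGE"

# Internal molecule representation ------------------------------------------
#
# A `rxn_mol` is a light container for one (possibly multi-component) set of
# molecules:
#   atoms: data.frame(element, aromatic, charge, nH, map, chiral)
#   bonds: data.frame(i, j, order, aromatic)   with i < j after finalization
# All indices are 1-based. Hydrogens are implicit: `nH` is the total hydrogen
# count of the heavy atom. `map` is the SMILES atom-map number (0 = unmapped).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# default valence lists used for implicit hydrogen assignment
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

new_mol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "rxn_mol")
}

#' @export
print.rxn_mol <- function(x, ...) {
  cat(sprintf(
    "<rxn_mol> %d atoms, %d bonds, %d component(s)\n",
    nrow(x$atoms), nrow(x$bonds), length(unique(mol_components(x)))
  ))
  invisible(x)
}

mol_n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list: integer vector of neighbours per atom
mol_adjlist <- function(mol) {
  n <- mol_n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else v)
}

mol_degree <- function(mol) {
  n <- mol_n_atoms(mol)
  d <- integer(n)
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$i, n)
    t2 <- tabulate(mol$bonds$j, n)
    d <- t1 + t2
  }
  d
}

# per-atom connected-component index (1-based, in order of first atom)
mol_components <- function(mol) {
  n <- mol_n_atoms(mol)
  adj <- mol_adjlist(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# effective bond order used in valence bookkeeping (aromatic counts 1.5)
bond_order_values <- function(mol) {
  ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
}

# sum of bond orders incident to each atom
mol_bond_order_sums <- function(mol) {
  n <- mol_n_atoms(mol)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    v <- bond_order_values(mol)
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + v[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + v[k]
    }
  }
  s
}

# implicit H count for a neutral organic-subset atom; NA when the SMILES
# implicit-valence rule does not apply (bracket-only atoms)
implicit_h_count <- function(element, charge, bond_order_sum) {
  if (charge != 0L || !(element %in% names(.default_valences))) return(NA_integer_)
  need <- ceiling(bond_order_sum - 1e-9)
  vs <- .default_valences[[element]]
  ok <- vs[vs >= need]
  if (!length(ok)) return(0L)
  as.integer(min(ok) - need)
}

# ring membership: a bond is in a ring iff its endpoints stay connected after
# removing it; atoms are in a ring iff incident to a ring bond
mol_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    # BFS from i to j avoiding bond k
    n <- mol_n_atoms(mol)
    seen <- logical(n); seen[i] <- TRUE
    queue <- i
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (b in seq_len(nb)) {
        if (b == k) next
        bi <- mol$bonds$i[b]; bj <- mol$bonds$j[b]
        w <- if (bi == v) bj else if (bj == v) bi else next
        if (!seen[w]) {
          if (w == j) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[k] <- found
  }
  out
}

mol_ring_atoms <- function(mol, ring_bonds = mol_ring_bonds(mol)) {
  n <- mol_n_atoms(mol)
  out <- logical(n)
  if (any(ring_bonds)) {
    out[mol$bonds$i[ring_bonds]] <- TRUE
    out[mol$bonds$j[ring_bonds]] <- TRUE
  }
  out
}

# SMILES parser --------------------------------------------------------------

#' Parse a SMILES string into a molecule
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, bracket atoms with isotope digits (ignored), charge, explicit
#' hydrogen counts, tetrahedral chirality tags and atom-map numbers, ring
#' closures (including `%nn`), branches and dot-separated components.
#' Hydrogens are implicit: the graph contains heavy atoms only, with hydrogen
#' counts stored per atom. Kekule-form six-membered C/N rings with alternating
#' single/double bonds are perceived as aromatic so that aromatic systems
#' compare consistently regardless of input dialect.
#'
#' @param smiles A single SMILES string (no `>>`; see [parse_reaction()] for
#'   reaction SMILES).
#' @return An internal molecule object of class `rxn_mol`.
#' @examples
#' m <- parse_smiles("CC(=O)O")
#' m$atoms$element
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  nch <- length(chars)
  if (!nch) stop("empty SMILES string")

  el <- character(0); arom <- logical(0); chg <- integer(0)
  nH <- integer(0); mapno <- integer(0); chiral <- character(0)
  bi <- integer(0); bj <- integer(0); bord <- numeric(0); barom <- logical(0)

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL
  rings <- list()  # ring id -> list(atom, sym)

  resolve_bond <- function(a, b, sym) {
    if (is.null(sym)) {
      if (arom[a] && arom[b]) list(order = 1, aromatic = TRUE)
      else list(order = 1, aromatic = FALSE)
    } else if (sym == "-") list(order = 1, aromatic = FALSE)
    else if (sym == "=") list(order = 2, aromatic = FALSE)
    else if (sym == "#") list(order = 3, aromatic = FALSE)
    else if (sym == ":") list(order = 1, aromatic = TRUE)
    else if (sym %in% c("/", "\\")) list(order = 1, aromatic = FALSE)
    else stop("unknown bond symbol: ", sym)
  }

  add_bond <- function(a, b, sym) {
    if (a == b) stop("self-bond in SMILES")
    spec <- resolve_bond(a, b, sym)
    bi <<- c(bi, a); bj <<- c(bj, b)
    bord <<- c(bord, spec$order); barom <<- c(barom, spec$aromatic)
  }

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_,
                       map = 0L, chir = "none") {
    el <<- c(el, element); arom <<- c(arom, aromatic); chg <<- c(chg, charge)
    nH <<- c(nH, h); mapno <<- c(mapno, map); chiral <<- c(chiral, chir)
    idx <- length(el)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    prev <<- idx
    pending <<- NULL
    idx
  }

  handle_ring <- function(id) {
    if (is.na(prev)) stop("ring closure digit before any atom")
    if (!is.null(rings[[id]])) {
      opened <- rings[[id]]
      sym <- if (!is.null(opened$sym)) opened$sym else pending
      add_bond(opened$atom, prev, sym)
      rings[[id]] <<- NULL
    } else {
      rings[[id]] <- list(atom = prev, sym = pending)
      rings <<- rings
    }
    pending <<- NULL
  }

  parse_bracket <- function(cont) {
    m <- regexec(
      "^([0-9]*)([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
      cont
    )
    g <- regmatches(cont, m)[[1L]]
    if (!length(g)) stop("unparsable bracket atom: [", cont, "]")
    elem_tok <- g[3L]
    aromatic <- grepl("^[a-z]", elem_tok)
    element <- paste0(toupper(substr(elem_tok, 1L, 1L)), substring(elem_tok, 2L))
    chir <- if (g[4L] == "") "none" else g[4L]
    h <- if (g[5L] == "") 0L else if (g[5L] == "H") 1L else as.integer(substring(g[5L], 2L))
    chs <- g[6L]
    charge <- if (chs == "") 0L
      else if (chs == "+") 1L
      else if (chs == "-") -1L
      else if (grepl("^\\+[0-9]+$", chs)) as.integer(substring(chs, 2L))
      else if (grepl("^-[0-9]+$", chs)) -as.integer(substring(chs, 2L))
      else if (grepl("^\\++$", chs)) nchar(chs)
      else -nchar(chs)
    map <- if (g[7L] == "") 0L else as.integer(substring(g[7L], 2L))
    add_atom(element, aromatic, as.integer(charge), h, map, chir)
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch open before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch) stop("truncated %nn ring closure")
      handle_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      handle_ring(ch); i <- i + 1L
    } else if (ch == "[") {
      close <- i
      while (close <= nch && chars[close] != "]") close <- close + 1L
      if (close > nch) stop("unclosed '[' in SMILES")
      parse_bracket(paste(chars[(i + 1L):(close - 1L)], collapse = ""))
      i <- close + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE); i <- i + 1L
      } else stop("atom '", ch, "' must be written in brackets")
    } else if (ch %in% AROMATIC_ORGANIC) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES at position ", i)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings)) stop("unclosed ring bond(s): ", paste(open_rings, collapse = ", "))
  if (!length(el)) stop("SMILES contains no atoms")

  atoms <- data.frame(
    element = el, aromatic = arom, charge = chg, nH = nH,
    map = mapno, chiral = chiral, stringsAsFactors = FALSE
  )
  # canonical bond list with i < j; reject duplicates
  if (length(bi)) {
    lo <- pmin(bi, bj); hi <- pmax(bi, bj)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) stop("duplicate bond in SMILES")
    bonds <- data.frame(i = lo, j = hi, order = bord, aromatic = barom)
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = numeric(0), aromatic = logical(0))
  }
  mol <- new_mol(atoms, bonds)
  mol <- .assign_implicit_h(mol)
  mol <- .perceive_aromatic(mol)
  mol
}

.assign_implicit_h <- function(mol) {
  miss <- which(is.na(mol$atoms$nH))
  if (length(miss)) {
    sums <- mol_bond_order_sums(mol)
    for (a in miss) {
      h <- implicit_h_count(mol$atoms$element[a], mol$atoms$charge[a], sums[a])
      mol$atoms$nH[a] <- if (is.na(h)) 0L else h
    }
  }
  mol
}

# perceive aromaticity for Kekule-form six-membered C/N rings with an
# alternating single/double bond pattern; aromatic-form input is left as-is
.perceive_aromatic <- function(mol) {
  if (nrow(mol$bonds) < 6L) return(mol)
  adj <- mol_adjlist(mol)
  n <- mol_n_atoms(mol)
  bond_idx <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    which(mol$bonds$i == lo & mol$bonds$j == hi)
  }
  seen_keys <- character(0)
  cycles <- list()
  walk <- function(path) {
    u <- path[length(path)]
    for (v in adj[[u]]) {
      if (length(path) == 6L) {
        if (v == path[1L]) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen_keys)) {
            seen_keys <<- c(seen_keys, key)
            cycles[[length(cycles) + 1L]] <<- path
          }
        }
      } else if (!(v %in% path) && v > path[1L]) {
        walk(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  for (cyc in cycles) {
    if (!all(mol$atoms$element[cyc] %in% c("C", "N"))) next
    bidx <- vapply(seq_along(cyc), function(k) {
      bond_idx(cyc[k], cyc[if (k == length(cyc)) 1L else k + 1L])
    }, integer(1))
    if (any(mol$bonds$aromatic[bidx])) next
    ords <- mol$bonds$order[bidx]
    alternating <- all(ords[c(1, 3, 5)] == ords[1]) &&
      all(ords[c(2, 4, 6)] == ords[2]) && sort(unique(ords)) %==% c(1, 2)
    if (alternating) {
      mol$bonds$aromatic[bidx] <- TRUE
      mol$bonds$order[bidx] <- 1
      mol$atoms$aromatic[cyc] <- TRUE
    }
  }
  mol
}

`%==%` <- function(a, b) length(a) == length(b) && all(a == b)

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

# SMILES writer --------------------------------------------------------------

.atom_token <- function(mol, idx, bond_sums) {
  a <- mol$atoms[idx, ]
  imp <- implicit_h_count(a$element, a$charge, bond_sums[idx])
  plain_sym <- if (a$aromatic) tolower(a$element) else a$element
  plain_ok <- a$map == 0L && a$charge == 0L && a$chiral == "none" &&
    a$element %in% ORGANIC_SUBSET && !is.na(imp) && imp == a$nH &&
    (!a$aromatic || tolower(a$element) %in% AROMATIC_ORGANIC)
  if (plain_ok) return(plain_sym)
  hstr <- if (a$nH == 0L) "" else if (a$nH == 1L) "H" else paste0("H", a$nH)
  cstr <- if (a$charge == 0L) ""
    else if (a$charge == 1L) "+"
    else if (a$charge == -1L) "-"
    else if (a$charge > 0L) paste0("+", a$charge)
    else paste0("-", abs(a$charge))
  chs <- if (a$chiral == "none") "" else a$chiral
  mstr <- if (a$map > 0L) paste0(":", a$map) else ""
  paste0("[", plain_sym, chs, hstr, cstr, mstr, "]")
}

.bond_symbol <- function(mol, k) {
  b <- mol$bonds[k, ]
  both_arom <- mol$atoms$aromatic[b$i] && mol$atoms$aromatic[b$j]
  if (b$aromatic) { if (both_arom) "" else ":" }
  else if (b$order == 2) "="
  else if (b$order == 3) "#"
  else if (both_arom) "-"
  else ""
}

#' Write a molecule as a SMILES string
#'
#' Emits dot-separated components, bracket atoms whenever a plain atom symbol
#' would lose information (map number, charge, chirality, non-standard
#' hydrogen count), and ring-closure digits for cycle bonds. With
#' `canonical = TRUE` atoms are visited in canonical priority order (see
#' [canonical_ranks()]) so that isomorphic inputs yield identical strings.
#'
#' @param mol A `rxn_mol`.
#' @param canonical Use canonical atom priorities for the traversal.
#' @return A SMILES string; the attribute `emission_order` records the atom
#'   indices in the order they appear in the string.
#' @export
write_smiles <- function(mol, canonical = FALSE) {
  n <- mol_n_atoms(mol)
  prio <- if (canonical) canonical_ranks(mol) else seq_len(n)
  adj <- mol_adjlist(mol)
  bond_lookup <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(mol$bonds))) {
    assign(paste(mol$bonds$i[k], mol$bonds$j[k]), k, envir = bond_lookup)
  }
  get_bond <- function(a, b) get(paste(min(a, b), max(a, b)), envir = bond_lookup)
  bond_sums <- mol_bond_order_sums(mol)

  visited <- logical(n)
  edge_used <- logical(nrow(mol$bonds))
  disc <- integer(n); disc_ctr <- 0L
  children <- vector("list", n)
  back_edges <- integer(0)  # bond indices

  dfs <- function(u) {
    visited[u] <<- TRUE
    disc_ctr <<- disc_ctr + 1L
    disc[u] <<- disc_ctr
    for (v in adj[[u]][order(prio[adj[[u]]])]) {
      k <- get_bond(u, v)
      if (edge_used[k]) next
      edge_used[k] <<- TRUE
      if (!visited[v]) {
        children[[u]] <<- c(children[[u]], v)
        dfs(v)
      } else {
        back_edges <<- c(back_edges, k)
      }
    }
  }

  comp <- mol_components(mol)
  roots <- integer(0)
  for (cid in unique(comp[order(prio)])) {
    members <- which(comp == cid)
    roots <- c(roots, members[which.min(prio[members])])
  }
  # de-duplicate while keeping order of first appearance
  roots <- roots[!duplicated(comp[roots])]
  for (r in roots) if (!visited[r]) dfs(r)

  # ring digits: unique per back edge, attached to both endpoints
  ring_tok <- vector("list", n)
  for (m in seq_along(back_edges)) {
    k <- back_edges[m]
    dig <- if (m <= 9L) as.character(m) else sprintf("%%%02d", m)
    a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
    first <- if (disc[a] <= disc[b]) a else b
    second <- if (first == a) b else a
    sym <- .bond_symbol(mol, k)
    ring_tok[[first]] <- c(ring_tok[[first]], paste0(sym, dig))
    ring_tok[[second]] <- c(ring_tok[[second]], dig)
  }

  emission <- integer(0)
  emit <- function(u) {
    emission <<- c(emission, u)
    s <- paste0(.atom_token(mol, u, bond_sums), paste(ring_tok[[u]], collapse = ""))
    kids <- children[[u]]
    if (length(kids)) {
      parts <- vapply(kids, function(v) {
        paste0(.bond_symbol(mol, get_bond(u, v)), emit(v))
      }, character(1))
      if (length(parts) > 1L) {
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""))
      }
      s <- paste0(s, parts[length(parts)])
    }
    s
  }
  pieces <- vapply(roots, emit, character(1))
  out <- paste(pieces, collapse = ".")
  attr(out, "emission_order") <- emission
  out
}

# Canonical atom ranking -----------------------------------------------------

#' Canonical atom priorities via iterative neighbourhood refinement
#'
#' Morgan-style canonical ranking: atoms start from an invariant tuple
#' (element, degree, charge, hydrogen count, aromaticity, ring membership)
#' and ranks are refined by repeatedly appending the sorted multiset of
#' neighbour ranks. Remaining ties are broken by individualizing the
#' lowest-index member of the smallest tied class and re-refining. For
#' molecular graphs whose refinement classes coincide with automorphism
#' orbits (all fixture-scale molecules here) the resulting canonical SMILES
#' is invariant to input atom order.
#'
#' @param mol A `rxn_mol`.
#' @return An integer vector of distinct priorities, 1 = highest.
#' @export
canonical_ranks <- function(mol) {
  n <- mol_n_atoms(mol)
  if (n == 1L) return(1L)
  adj <- mol_adjlist(mol)
  ring_atoms <- mol_ring_atoms(mol)
  deg <- mol_degree(mol)
  inv0 <- paste(mol$atoms$element, deg, mol$atoms$charge, mol$atoms$nH,
                mol$atoms$aromatic, ring_atoms)
  rank <- match(inv0, sort(unique(inv0)))

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        paste(formatC(rank[i], width = 6, flag = "0"),
              paste(sort(rank[adj[[i]]]), collapse = ","))
      }, character(1))
      new_rank <- match(key, sort(unique(key)))
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1L])
    cls <- min(tied)
    a <- min(which(rank == cls))
    r2 <- rank * 2L
    r2[a] <- r2[a] - 1L
    rank <- match(r2, sort(unique(r2)))
    rank <- refine(rank)
  }
  rank
}
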