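# Model surface ---------------------------------------------------------------
#
# Exported operations wrap the cached numeric core in R/nn.R. The encoder is
# shared between reactant and product passes; cross-attention gathers each
# product atom's assigned reactant embedding (the printed attention softmax
# runs over a single candidate, so each head's output is exactly its value
# projection; the query/key projections are kept for fidelity but are inert).

#' Encode a molecular graph into node embeddings
#'
#' Edge-aware message passing: each layer aggregates
#' `relu(neighbour + edge-feature projection)`, combines it with
#' `(1 + eps) * self`, applies a two-layer MLP and a learnable gated
#' residual (`gate * update + (1 - gate) * input`).
#'
#' @param graph A featurized `mol_graph`.
#' @param params Model parameters from [init_params()].
#' @param config The matching [encoder_config()].
#' @return Matrix |V| x hidden_dim of node embeddings.
#' @export
encode <- function(graph, params, config) {
  .encode_cached(graph, params, config)$H
}

#' Mapping-guided cross-attention
#'
#' Each product atom attends to its single assigned reactant counterpart;
#' the softmax over one candidate is identically 1, so every head returns
#' its value projection of the counterpart embedding and the concatenated
#' head outputs equal `H_R[assignment, ] %*% W_V`.
#'
#' @param H_P,H_R Node embedding matrices.
#' @param assignment Integer reactant index per product atom (ground truth
#'   during training, predicted at inference).
#' @param params,config Model parameters and configuration.
#' @return Matrix |V_P| x hidden_dim.
#' @export
cross_attend <- function(H_P, H_R, assignment, params, config) {
  stopifnot(length(assignment) == nrow(H_P), all(assignment >= 1),
            all(assignment <= nrow(H_R)))
  H_R[as.integer(assignment), , drop = FALSE] %*% params$Wv
}

#' Concatenate product embeddings with their attended counterparts
#'
#' @param H_P,H_tilde Matrices with equal row counts.
#' @return The enriched matrix `[H_P || H_tilde]` of width 2d.
#' @export
enrich <- function(H_P, H_tilde) {
  if (nrow(H_P) != nrow(H_tilde)) {
    stop("row mismatch between product embeddings and attended embeddings")
  }
  cbind(H_P, H_tilde)
}

#' Encode the dual (bond-node) graph
#'
#' Message passing of the same gated GIN-style family (separate parameters,
#' no edge features) over the line graph; returns one embedding per product
#' bond. An empty dual graph yields a 0-row matrix.
#'
#' @param dual A `dual_graph` from [build_dual_graph()].
#' @param params,config Model parameters and configuration.
#' @return Matrix |E_P| x hidden_dim.
#' @export
encode_dual <- function(dual, params, config) {
  .encode_dual_cached(dual, params, config)$H
}

#' Atom reactivity head
#'
#' @param H_hat Enriched product embeddings (|V_P| x 2d).
#' @param params Model parameters.
#' @return Probability per product atom, in (0, 1).
#' @export
atom_head <- function(H_hat, params) {
  as.vector(.sigmoid(.mlp2_cached(H_hat, params$atom$W1, params$atom$b1,
                                  params$atom$W2, params$atom$b2)$Out))
}

# orientation-invariant bond head input: features of (i, j) and (j, i) are
# averaged before the MLP, so scores are symmetric by construction
.bond_input <- function(H_hat, E, HD, atom_scores, bonds) {
  bi <- bonds$i; bj <- bonds$j
  Hm <- (H_hat[bi, , drop = FALSE] + H_hat[bj, , drop = FALSE]) / 2
  ym <- (atom_scores[bi] + atom_scores[bj]) / 2
  cbind(Hm, Hm, E, HD, ym, ym)
}

#' Bond reactivity head
#'
#' Per product bond (i, j), an MLP over the concatenation of both enriched
#' endpoint embeddings, the bond feature vector, the dual-graph bond
#' embedding and both endpoint atom scores. Inputs for (i, j) and (j, i)
#' are averaged before the MLP, so the score is orientation-invariant.
#'
#' @param H_hat Enriched product embeddings.
#' @param E Product bond feature matrix (canonical bond list order).
#' @param HD Dual-graph bond embeddings.
#' @param atom_scores Output of [atom_head()].
#' @param bonds Canonical product bond list (data.frame i, j).
#' @param params Model parameters.
#' @return Probability per product bond, in (0, 1).
#' @export
bond_head <- function(H_hat, E, HD, atom_scores, bonds, params) {
  if (!nrow(bonds)) return(numeric(0))
  In <- .bond_input(H_hat, E, HD, atom_scores, bonds)
  as.vector(.sigmoid(.mlp2_cached(In, params$bond$W1, params$bond$b1,
                                  params$bond$W2, params$bond$b2)$Out))
}

#' Reaction classifier
#'
#' Mean-pools the enriched product embeddings and applies an MLP with a
#' softmax over the K reaction classes.
#'
#' @param H_hat Enriched product embeddings (>= 1 row).
#' @param params,config Model parameters and configuration.
#' @return Probability vector over `config$n_classes` classes (sums to 1).
#' @export
classify <- function(H_hat, params, config) {
  stopifnot(nrow(H_hat) >= 1L)
  pooled <- matrix(colMeans(H_hat), 1L)
  .softmax(as.vector(.mlp2_cached(pooled, params$cls$W1, params$cls$b1,
                                  params$cls$W2, params$cls$b2)$Out))
}

# Prepared reactions ----------------------------------------------------------

# precompute everything the forward/backward passes need for one reaction
.prepare_reaction <- function(reaction, with_labels = TRUE) {
  prep <- list(
    reaction = reaction,
    dual = build_dual_graph(reaction$product),
    truth_map = reaction$atom_map,
    class_label = reaction$class_label
  )
  if (with_labels && !is.null(reaction$atom_map)) {
    lab <- derive_edit_labels(reaction)
    prep$atom_labels <- lab$atom_labels
    prep$bond_labels <- lab$bond_labels
    prep$wl_reactants <- wl_partition(reaction$reactants)
    prep$wl_product <- wl_partition(reaction$product)
  }
  prep
}

# Full cached forward for one prepared reaction ------------------------------

.forward_reaction <- function(prep, params, config,
                              mode = c("full", "products_only"),
                              teacher = TRUE) {
  mode <- match.arg(mode)
  rx <- prep$reaction
  h <- config$hidden_dim
  out <- list(mode = mode)
  encP <- .encode_cached(rx$product, params, config)
  out$encP <- encP
  has_reactants <- !is.null(rx$reactants) && rx$reactants$n_atoms > 0L
  if (mode == "full" && !has_reactants) {
    stop("full mode requires reactants")
  }
  if (has_reactants) {
    encR <- .encode_cached(rx$reactants, params, config)
    out$encR <- encR
    out$raw <- encP$H %*% t(encR$H)
    out$sink <- .sinkhorn_cached(out$raw, config$sinkhorn_iterations,
                                 config$sinkhorn_temperature)
    out$soft <- out$sink$M
    hard <- hard_assign(out$soft)
    out$hard <- hard
    if (teacher && !is.null(prep$truth_map)) {
      out$assignment <- prep$truth_map
    } else {
      wlr <- if (!is.null(prep$wl_reactants)) prep$wl_reactants
        else wl_partition(rx$reactants)
      wlp <- if (!is.null(prep$wl_product)) prep$wl_product
        else wl_partition(rx$product)
      out$assignment <- as.integer(symmetry_refine(hard, wlp, wlr))
    }
  }
  if (mode == "full") {
    out$H_tilde <- out$encR$H[out$assignment, , drop = FALSE] %*% params$Wv
    out$H_hat <- cbind(encP$H, out$H_tilde)
    out$H_hat_cls <- out$H_hat
  } else {
    # products-only: reactivity heads never see reactant information;
    # classification uses the enriched path when reactants are available
    out$H_hat <- cbind(encP$H, matrix(0, encP$n, h))
    if (has_reactants) {
      out$H_tilde <- out$encR$H[out$assignment, , drop = FALSE] %*% params$Wv
      out$H_hat_cls <- cbind(encP$H, out$H_tilde)
    } else {
      out$H_hat_cls <- out$H_hat
    }
  }
  out$dualc <- .encode_dual_cached(prep$dual, params, config)
  out$atom_mlp <- .mlp2_cached(out$H_hat, params$atom$W1, params$atom$b1,
                               params$atom$W2, params$atom$b2)
  out$atom_scores <- as.vector(.sigmoid(out$atom_mlp$Out))
  bonds <- rx$product$bonds
  out$bonds <- bonds
  if (nrow(bonds)) {
    out$bond_in <- .bond_input(out$H_hat, rx$product$E, out$dualc$H,
                               out$atom_scores, bonds)
    out$bond_mlp <- .mlp2_cached(out$bond_in, params$bond$W1, params$bond$b1,
                                 params$bond$W2, params$bond$b2)
    out$bond_scores <- as.vector(.sigmoid(out$bond_mlp$Out))
  } else {
    out$bond_scores <- numeric(0)
  }
  out$pooled <- matrix(colMeans(out$H_hat_cls), 1L)
  out$cls_mlp <- .mlp2_cached(out$pooled, params$cls$W1, params$cls$b1,
                              params$cls$W2, params$cls$b2)
  out$class_probs <- .softmax(as.vector(out$cls_mlp$Out))
  out
}

# Backward pass: losses + gradient tree for one reaction ----------------------

.backward_reaction <- function(prep, fwd, params, config, lconf, grads) {
  rx <- prep$reaction
  n_p <- rx$product$n_atoms
  h <- config$hidden_dim
  eps <- lconf$epsilon

  # component losses; the mapping NLL is evaluated on the log-domain
  # Sinkhorn output so its gradient stays informative even when the truth
  # entry's probability underflows
  L_map <- if (!is.null(fwd$soft) && !is.null(prep$truth_map)) {
    idx_map <- cbind(seq_len(nrow(fwd$soft)), prep$truth_map)
    -mean(fwd$sink$logM[idx_map])
  } else 0
  L_atom <- lconf$lambda_dice * dice_loss(fwd$atom_scores, prep$atom_labels,
                                          lconf$dice_smooth) +
    (1 - lconf$lambda_dice) * focal_loss(fwd$atom_scores, prep$atom_labels,
                                         lconf$focal_gamma, lconf$focal_alpha, eps)
  L_bond <- if (length(fwd$bond_scores)) {
    lconf$lambda_dice * dice_loss(fwd$bond_scores, prep$bond_labels,
                                  lconf$dice_smooth) +
      (1 - lconf$lambda_dice) * focal_loss(fwd$bond_scores, prep$bond_labels,
                                           lconf$focal_gamma, lconf$focal_alpha, eps)
  } else 0
  L_cls <- if (!is.null(prep$class_label)) {
    classification_loss(fwd$class_probs, prep$class_label, eps)
  } else 0
  tw <- .total_loss_weights(lconf, params$log_sigma2,
                            c(L_map, L_atom + L_bond, L_cls))
  total <- total_loss(L_map, L_atom, L_bond, L_cls, lconf, params$log_sigma2)
  if (lconf$weighting == "uncertainty") {
    grads$log_sigma2 <- grads$log_sigma2 + tw$ds
  }
  w_map <- tw$w[1]; w_react <- tw$w[2]; w_cls <- tw$w[3]

  dH_hat <- matrix(0, n_p, 2 * h)
  dHD <- if (fwd$dualc$empty) NULL else matrix(0, fwd$dualc$n, h)
  datom_p <- numeric(n_p)

  # classification head
  if (!is.null(prep$class_label) && w_cls != 0) {
    K <- config$n_classes
    dlogits <- fwd$class_probs
    dlogits[prep$class_label] <- dlogits[prep$class_label] - 1
    dlogits <- matrix(w_cls * dlogits, 1L)
    bk <- .mlp2_backward(fwd$cls_mlp, params$cls$W1, params$cls$W2, dlogits)
    grads$cls$W1 <- grads$cls$W1 + bk$dW1; grads$cls$b1 <- grads$cls$b1 + bk$db1
    grads$cls$W2 <- grads$cls$W2 + bk$dW2; grads$cls$b2 <- grads$cls$b2 + bk$db2
    dH_hat_cls <- matrix(rep(as.vector(bk$dIn) / n_p, each = n_p), n_p)
  } else dH_hat_cls <- NULL

  # bond head
  if (length(fwd$bond_scores) && w_react != 0) {
    dp_bond <- w_react * .reactivity_grad(fwd$bond_scores, prep$bond_labels, lconf)
    dlogit_b <- matrix(dp_bond * fwd$bond_scores * (1 - fwd$bond_scores), ncol = 1L)
    bk <- .mlp2_backward(fwd$bond_mlp, params$bond$W1, params$bond$W2, dlogit_b)
    grads$bond$W1 <- grads$bond$W1 + bk$dW1; grads$bond$b1 <- grads$bond$b1 + bk$db1
    grads$bond$W2 <- grads$bond$W2 + bk$dW2; grads$bond$b2 <- grads$bond$b2 + bk$db2
    dIn <- bk$dIn
    bi <- fwd$bonds$i; bj <- fwd$bonds$j
    dHm <- (dIn[, 1:(2 * h), drop = FALSE] +
              dIn[, (2 * h + 1):(4 * h), drop = FALSE]) / 2
    dH_hat <- dH_hat + .agg_rows(dHm, bi, n_p) + .agg_rows(dHm, bj, n_p)
    d_e <- ncol(rx$product$E)
    if (!is.null(dHD)) {
      dHD <- dHD + dIn[, (4 * h + d_e + 1):(5 * h + d_e), drop = FALSE]
    }
    dym <- (dIn[, 5 * h + d_e + 1] + dIn[, 5 * h + d_e + 2]) / 2
    datom_p <- datom_p + .agg_rows(matrix(dym, ncol = 1L), bi, n_p)[, 1L] +
      .agg_rows(matrix(dym, ncol = 1L), bj, n_p)[, 1L]
  }

  # atom head (direct loss + contribution through bond-head inputs)
  if (w_react != 0) {
    datom_p <- datom_p + w_react * .reactivity_grad(fwd$atom_scores,
                                                    prep$atom_labels, lconf)
  }
  if (any(datom_p != 0)) {
    dlogit_a <- matrix(datom_p * fwd$atom_scores * (1 - fwd$atom_scores), ncol = 1L)
    bk <- .mlp2_backward(fwd$atom_mlp, params$atom$W1, params$atom$W2, dlogit_a)
    grads$atom$W1 <- grads$atom$W1 + bk$dW1; grads$atom$b1 <- grads$atom$b1 + bk$db1
    grads$atom$W2 <- grads$atom$W2 + bk$dW2; grads$atom$b2 <- grads$atom$b2 + bk$db2
    dH_hat <- dH_hat + bk$dIn
  }

  # dual encoder
  if (!is.null(dHD) && any(dHD != 0)) {
    grads <- .encode_dual_backward(fwd$dualc, params, config, dHD, grads)
  }

  # split enriched embeddings back into encoder and attention paths; in
  # products-only mode the reactivity-path second half is a zero pad, so its
  # gradient never reaches the attention module
  dH_P <- dH_hat[, 1:h, drop = FALSE]
  dH_tilde <- if (fwd$mode == "full") dH_hat[, (h + 1):(2 * h), drop = FALSE]
    else matrix(0, n_p, h)
  dH_R <- NULL
  if (!is.null(fwd$encR)) dH_R <- matrix(0, fwd$encR$n, h)

  if (!is.null(dH_hat_cls)) {
    dH_P <- dH_P + dH_hat_cls[, 1:h, drop = FALSE]
    if (!is.null(fwd$H_tilde)) {
      dH_tilde <- dH_tilde + dH_hat_cls[, (h + 1):(2 * h), drop = FALSE]
    }
  }

  # cross-attention (gather + value projection)
  if (!is.null(fwd$H_tilde) && any(dH_tilde != 0)) {
    a <- fwd$assignment
    HRsel <- fwd$encR$H[a, , drop = FALSE]
    grads$Wv <- grads$Wv + t(HRsel) %*% dH_tilde
    dHRsel <- dH_tilde %*% t(params$Wv)
    dH_R <- dH_R + .agg_rows(dHRsel, a, fwd$encR$n)
  }

  # mapping loss through Sinkhorn and the similarity product
  if (w_map != 0 && !is.null(fwd$soft) && !is.null(prep$truth_map)) {
    M <- fwd$soft
    dlogM <- matrix(0, nrow(M), ncol(M))
    dlogM[cbind(seq_len(nrow(M)), prep$truth_map)] <- -w_map / nrow(M)
    draw <- .sinkhorn_backward(fwd$sink, dlogM = dlogM)
    dH_P <- dH_P + draw %*% fwd$encR$H
    dH_R <- dH_R + t(draw) %*% fwd$encP$H
  }

  grads <- .encode_backward(fwd$encP, params, config, dH_P, grads)
  if (!is.null(dH_R) && any(dH_R != 0)) {
    grads <- .encode_backward(fwd$encR, params, config, dH_R, grads)
  }

  list(grads = grads, losses = c(map = L_map, atom = L_atom, bond = L_bond,
                                 cls = L_cls, total = total))
}

# Public forward --------------------------------------------------------------

#' Run the full model on one reaction
#'
#' Full mode encodes both graphs with the shared encoder, soft-matches them
#' (Sinkhorn), cross-attends using the supplied assignment (ground-truth
#' map during training, symmetry-refined prediction at inference), enriches
#' the product embeddings and runs the atom, bond and class heads.
#' Products-only mode feeds the reactivity heads zero-padded embeddings
#' `[H_P || 0]`; classification still uses the enriched path when reactants
#' are present.
#'
#' @param reaction A parsed `rxn_reaction`.
#' @param params,config Model parameters and configuration.
#' @param mode `"full"` or `"products_only"`.
#' @param assignment Optional explicit assignment for cross-attention;
#'   defaults to the ground-truth map when present, otherwise the
#'   symmetry-refined hard Sinkhorn assignment.
#' @return List with `correspondence` (raw/soft/hard, `NULL` without
#'   reactants), `edit_scores` (atom/bond probabilities and dual
#'   embeddings) and `class_scores`.
#' @export
model_forward <- function(reaction, params, config,
                          mode = c("full", "products_only"),
                          assignment = NULL) {
  mode <- match.arg(mode)
  prep <- .prepare_reaction(reaction, with_labels = FALSE)
  if (!is.null(reaction$atom_map)) prep$truth_map <- reaction$atom_map
  teacher <- !is.null(reaction$atom_map) && is.null(assignment)
  fwd <- .forward_reaction(prep, params, config, mode = mode, teacher = teacher)
  if (!is.null(assignment)) {
    # re-run attention path with the explicit assignment
    fwd$assignment <- as.integer(assignment)
    if (mode == "full") {
      fwd$H_tilde <- fwd$encR$H[fwd$assignment, , drop = FALSE] %*% params$Wv
      fwd$H_hat <- cbind(fwd$encP$H, fwd$H_tilde)
      fwd$H_hat_cls <- fwd$H_hat
      fwd$atom_mlp <- .mlp2_cached(fwd$H_hat, params$atom$W1, params$atom$b1,
                                   params$atom$W2, params$atom$b2)
      fwd$atom_scores <- as.vector(.sigmoid(fwd$atom_mlp$Out))
      if (nrow(fwd$bonds)) {
        fwd$bond_in <- .bond_input(fwd$H_hat, reaction$product$E, fwd$dualc$H,
                                   fwd$atom_scores, fwd$bonds)
        fwd$bond_mlp <- .mlp2_cached(fwd$bond_in, params$bond$W1, params$bond$b1,
                                     params$bond$W2, params$bond$b2)
        fwd$bond_scores <- as.vector(.sigmoid(fwd$bond_mlp$Out))
      }
      fwd$pooled <- matrix(colMeans(fwd$H_hat_cls), 1L)
      fwd$cls_mlp <- .mlp2_cached(fwd$pooled, params$cls$W1, params$cls$b1,
                                  params$cls$W2, params$cls$b2)
      fwd$class_probs <- .softmax(as.vector(fwd$cls_mlp$Out))
    }
  }
  corr <- if (!is.null(fwd$soft)) {
    structure(list(raw = fwd$raw, soft = fwd$soft, hard = fwd$hard,
                   assignment = fwd$assignment),
              class = "correspondence_matrix")
  } else NULL
  structure(list(
    correspondence = corr,
    edit_scores = structure(list(atom_scores = fwd$atom_scores,
                                 bond_scores = fwd$bond_scores,
                                 bonds = fwd$bonds,
                                 dual_embeddings = fwd$dualc$H),
                            class = "edit_scores"),
    class_scores = fwd$class_probs,
    mode = mode
  ), class = "rxn_prediction")
}

#' @export
print.correspondence_matrix <- function(x, ...) {
  cat(sprintf("<correspondence_matrix> %d x %d (product x reactant atoms)\n",
              nrow(x$soft), ncol(x$soft)))
  invisible(x)
}
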