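# Training loop, prediction and evaluation ------------------------------------

.tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .tree_scale, s = s) else a * s
}

# parse + prepare every reaction of a dataset tibble
.prepare_dataset <- function(dataset, with_labels = TRUE) {
  stopifnot("rxn_smiles" %in% names(dataset))
  cls <- if ("class" %in% names(dataset)) dataset$class else
    rep(NA_integer_, nrow(dataset))
  lapply(seq_len(nrow(dataset)), function(k) {
    rx <- parse_reaction(dataset$rxn_smiles[k],
                         class_label = if (is.na(cls[k])) NULL else cls[k])
    .prepare_reaction(rx, with_labels = with_labels)
  })
}

# macro F1 over classes
.macro_f1 <- function(predicted, true, K) {
  f1s <- vapply(seq_len(K), function(k) {
    tp <- sum(predicted == k & true == k)
    fp <- sum(predicted == k & true != k)
    fn <- sum(predicted != k & true == k)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

# run inference over prepared reactions and compute all evaluation metrics
.evaluate_prepared <- function(preps, params, config, mode = "full",
                               grid = seq(0.05, 0.95, by = 0.05)) {
  n <- length(preps)
  scores <- vector("list", n); labels <- vector("list", n)
  pred_class <- integer(n); true_class <- integer(n)
  map_hits <- numeric(0)
  for (k in seq_len(n)) {
    prep <- preps[[k]]
    fwd <- .forward_reaction(prep, params, config, mode = mode, teacher = FALSE)
    scores[[k]] <- list(atom_scores = fwd$atom_scores,
                        bond_scores = fwd$bond_scores)
    labels[[k]] <- list(atom_labels = prep$atom_labels,
                        bond_labels = prep$bond_labels)
    pred_class[k] <- which.max(fwd$class_probs)
    true_class[k] <- if (is.null(prep$class_label)) NA_integer_ else prep$class_label
    if (!is.null(prep$truth_map) && !is.null(fwd$assignment)) {
      map_hits <- c(map_hits, symmetry_aware_accuracy(
        fwd$assignment, prep$truth_map, prep$wl_reactants))
    }
  }
  atom_pool <- unlist(lapply(scores, `[[`, "atom_scores"))
  atom_lab <- unlist(lapply(labels, `[[`, "atom_labels"))
  bond_pool <- unlist(lapply(scores, `[[`, "bond_scores"))
  bond_lab <- unlist(lapply(labels, `[[`, "bond_labels"))
  thr <- select_thresholds(atom_pool, atom_lab, bond_pool, bond_lab, grid)
  top <- vapply(c(1L, 3L, 5L), function(nn) {
    as.numeric(top_n_edit_accuracy(scores, labels, nn))
  }, numeric(1))
  names(top) <- c("top1", "top3", "top5")
  has_cls <- !is.na(true_class)
  cls_acc <- if (any(has_cls)) {
    classification_accuracy(pred_class[has_cls], true_class[has_cls])
  } else NA_real_
  K <- config$n_classes
  edit_correct <- vapply(seq_len(n), function(k) {
    isTRUE(as.logical(top_n_edit_accuracy(scores[k], labels[k], 1L) == 1))
  }, logical(1))
  class_correct <- has_cls & (pred_class == true_class)
  per_class <- if (any(has_cls)) {
    dplyr::bind_rows(lapply(sort(unique(true_class[has_cls])), function(k) {
      sel <- which(true_class == k)
      tibble::tibble(
        class = k, support = length(sel),
        class_accuracy = mean(pred_class[sel] == k),
        top1_edit = as.numeric(top_n_edit_accuracy(scores[sel], labels[sel], 1L)),
        consistency = mean(class_correct[sel] & edit_correct[sel])
      )
    }))
  } else tibble::tibble()
  structure(list(
    top_n_edit = top,
    class_accuracy = cls_acc,
    map_accuracy = if (length(map_hits)) mean(map_hits) else NA_real_,
    atom_f1 = thr$atom_f1, bond_f1 = thr$bond_f1,
    class_f1 = if (any(has_cls)) .macro_f1(pred_class[has_cls],
                                           true_class[has_cls], K) else NA_real_,
    thresholds = c(atom = thr$atom_threshold, bond = thr$bond_threshold),
    consistency = if (any(has_cls)) consistency(class_correct, edit_correct)
      else NA_real_,
    per_class = per_class,
    n_reactions = n
  ), class = "rxn_eval_report")
}

#' @export
print.rxn_eval_report <- function(x, ...) {
  cat("<rxn_eval_report>\n")
  cat(sprintf("  reactions: %d\n", x$n_reactions))
  cat(sprintf("  top-1/3/5 edit accuracy: %.3f / %.3f / %.3f\n",
              x$top_n_edit[1], x$top_n_edit[2], x$top_n_edit[3]))
  cat(sprintf("  class accuracy: %.3f   mapping accuracy: %.3f\n",
              x$class_accuracy, x$map_accuracy))
  cat(sprintf("  atom F1: %.3f (thr %.2f)   bond F1: %.3f (thr %.2f)\n",
              x$atom_f1, x$thresholds["atom"], x$bond_f1, x$thresholds["bond"]))
  cat(sprintf("  consistency (class AND top-1 edits): %.3f\n", x$consistency))
  invisible(x)
}

#' Train the multi-task reaction model
#'
#' Teacher-forced training: the ground-truth atom map drives
#' cross-attention while the Sinkhorn correspondence is supervised with the
#' mapping loss; reactivity heads use the hybrid Dice-Focal loss and the
#' classifier standard cross-entropy, combined per [total_loss()].
#' Optimization is AdamW. Early stopping monitors an equal-weight
#' scalarization of validation atom F1, bond F1 and class macro-F1 with the
#' given patience (in evaluations); the best parameters are restored.
#'
#' @param dataset Tibble with `rxn_smiles` (atom-mapped in full mode) and
#'   `class` columns, e.g. from [generate_reactions()].
#' @param model_config An [encoder_config()].
#' @param loss A [loss_config()].
#' @param mode `"full"` or `"products_only"`.
#' @param max_epochs,batch_size,learning_rate,weight_decay,patience
#'   Optimization settings (defaults mirror the reference configuration:
#'   batch 32, AdamW lr 1e-4, weight decay 5e-5, patience 10).
#' @param eval_every Validation cadence in epochs (0 disables early
#'   stopping and validation tracking).
#' @param validation Optional validation tibble (defaults to `dataset`).
#' @param seed Integer seed for shuffling (parameter initialization is
#'   seeded by `model_config$seed`).
#' @param resume An earlier `rxn_fit` to continue training from.
#' @param verbose Print a line per evaluation.
#' @return A `rxn_fit` with parameters, optimizer state, configs, selected
#'   thresholds and a per-epoch `history` tibble.
#' @export
train_model <- function(dataset, model_config = encoder_config(),
                        loss = loss_config(), mode = c("full", "products_only"),
                        max_epochs = 100L, batch_size = 32L,
                        learning_rate = 1e-4, weight_decay = 5e-5,
                        patience = 10L, eval_every = 1L, validation = NULL,
                        seed = 1L, resume = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  preps <- .prepare_dataset(dataset, with_labels = TRUE)
  if (mode == "full") {
    missing_map <- vapply(preps, function(p) is.null(p$truth_map), logical(1))
    if (any(missing_map)) {
      stop("full mode requires atom-mapped reactions; missing map for rows: ",
           paste(utils::head(which(missing_map), 5L), collapse = ", "))
    }
  }
  val_preps <- if (is.null(validation)) preps else
    .prepare_dataset(validation, with_labels = TRUE)

  if (!is.null(resume)) {
    stopifnot(inherits(resume, "rxn_fit"))
    params <- resume$params
    opt <- resume$opt_state
    epoch_offset <- resume$n_epochs
    history <- resume$history
  } else {
    params <- init_params(model_config)
    opt <- .adam_init(params)
    epoch_offset <- 0L
    history <- tibble::tibble()
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- length(preps)
  best_scalar <- -Inf
  best_params <- params
  stale <- 0L
  stopped <- FALSE
  for (epoch in seq_len(max_epochs)) {
    total_epoch <- epoch_offset + epoch
    set.seed(seed + total_epoch)
    ord <- sample.int(n)
    ep_losses <- c(map = 0, atom = 0, bond = 0, cls = 0, total = 0)
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      grads <- .zeros_like(params)
      for (k in batch) {
        fwd <- .forward_reaction(preps[[k]], params, model_config,
                                 mode = mode, teacher = TRUE)
        bk <- .backward_reaction(preps[[k]], fwd, params, model_config,
                                 loss, grads)
        grads <- bk$grads
        ep_losses <- ep_losses + bk$losses / n
      }
      step <- .adam_step(params, .tree_scale(grads, 1 / length(batch)), opt,
                         lr = learning_rate, weight_decay = weight_decay)
      params <- step$params
      opt <- step$state
    }
    row <- tibble::tibble(
      epoch = total_epoch, loss_map = ep_losses["map"],
      loss_atom = ep_losses["atom"], loss_bond = ep_losses["bond"],
      loss_cls = ep_losses["cls"], loss_total = ep_losses["total"],
      sigma_map = sqrt(exp(params$log_sigma2[1])),
      sigma_react = sqrt(exp(params$log_sigma2[2])),
      sigma_cls = sqrt(exp(params$log_sigma2[3])),
      val_scalar = NA_real_
    )
    if (eval_every > 0L && (epoch %% eval_every == 0L || epoch == max_epochs)) {
      rep <- .evaluate_prepared(val_preps, params, model_config, mode = mode)
      scalar <- mean(c(rep$atom_f1, rep$bond_f1, rep$class_f1), na.rm = TRUE)
      row$val_scalar <- scalar
      if (verbose) {
        message(sprintf("epoch %d: total loss %.4f, val scalar %.4f",
                        total_epoch, ep_losses["total"], scalar))
      }
      if (scalar > best_scalar + 1e-12) {
        best_scalar <- scalar
        best_params <- params
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale > patience) { history <- dplyr::bind_rows(history, row); stopped <- TRUE }
      }
    }
    if (!stopped) history <- dplyr::bind_rows(history, row)
    if (stopped) break
  }
  final_params <- if (is.finite(best_scalar)) best_params else params
  final_report <- .evaluate_prepared(val_preps, final_params, model_config,
                                     mode = mode)
  structure(list(
    params = final_params, opt_state = opt, config = model_config,
    loss_config = loss, mode = mode, history = history,
    n_epochs = epoch_offset + if (exists("epoch")) epoch else 0L,
    thresholds = final_report$thresholds,
    validation_report = final_report
  ), class = "rxn_fit")
}

#' @export
print.rxn_fit <- function(x, ...) {
  cat(sprintf("<rxn_fit> %s mode, %d epoch(s), hidden %d x %d layer(s)\n",
              x$mode, x$n_epochs, x$config$hidden_dim, x$config$num_layers))
  print(x$validation_report)
  invisible(x)
}

#' Predict mappings, reaction centers and classes for new reactions
#'
#' Runs the trained model at inference (predicted, symmetry-refined
#' assignments drive cross-attention). In products-only mode, or when an
#' input has no reactant side (plain product SMILES), mapping output is
#' omitted.
#'
#' @param fit A `rxn_fit`.
#' @param smiles Character vector of reaction SMILES (`reactants>>product`)
#'   or plain product SMILES.
#' @param mode Override the fit's mode.
#' @return A tibble with one row per input: predicted class, class
#'   probabilities, atom/bond reactivity scores, the (refined) atom map and
#'   the soft correspondence matrix (`NULL` where reactants are absent).
#' @export
predict_reactions <- function(fit, smiles, mode = NULL) {
  stopifnot(inherits(fit, "rxn_fit"))
  mode <- if (is.null(mode)) fit$mode else
    match.arg(mode, c("full", "products_only"))
  rows <- lapply(seq_along(smiles), function(k) {
    s <- smiles[k]
    rx <- if (grepl(">>", s, fixed = TRUE)) parse_reaction(s) else {
      structure(list(reactants = NULL, product = mol_graph(s),
                     atom_map = NULL, class_label = NULL, raw_smiles = s),
                class = "rxn_reaction")
    }
    use_mode <- if (is.null(rx$reactants)) "products_only" else mode
    prep <- .prepare_reaction(rx, with_labels = FALSE)
    fwd <- .forward_reaction(prep, params = fit$params, config = fit$config,
                             mode = use_mode, teacher = FALSE)
    tibble::tibble(
      id = k, rxn_smiles = s,
      predicted_class = which.max(fwd$class_probs),
      class_probs = list(fwd$class_probs),
      atom_scores = list(fwd$atom_scores),
      bond_scores = list(fwd$bond_scores),
      mapping = list(if (is.null(fwd$assignment)) NULL else fwd$assignment),
      correspondence = list(if (is.null(fwd$soft)) NULL else fwd$soft)
    )
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a trained model on a labeled dataset
#'
#' Computes Top-1/3/5 edit accuracy, classification accuracy,
#' symmetry-aware mapping accuracy, atom/bond F1 with selected thresholds,
#' prediction consistency, and a per-class breakdown.
#'
#' @param fit A `rxn_fit`.
#' @param dataset Tibble with atom-mapped `rxn_smiles` and `class`.
#' @return A `rxn_eval_report`.
#' @export
evaluate_model <- function(fit, dataset) {
  stopifnot(inherits(fit, "rxn_fit"))
  preps <- .prepare_dataset(dataset, with_labels = TRUE)
  .evaluate_prepared(preps, fit$params, fit$config, mode = fit$mode)
}
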