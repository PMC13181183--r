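# Multi-task objective --------------------------------------------------------

#' Loss configuration
#'
#' @param lambda_map,lambda_react,lambda_cls Nonnegative task weights used
#'   in `fixed` weighting mode.
#' @param lambda_dice Mixing weight in \[0, 1\] of the Dice term inside the
#'   hybrid Dice-Focal reactivity loss (default 0.4).
#' @param focal_gamma Focusing exponent of the focal loss (default 2).
#' @param focal_alpha Positive-class weight; positives are upweighted to
#'   counter the sparsity of reactive atoms/bonds (default 5).
#' @param weighting `"fixed"` (weighted sum with the lambdas) or
#'   `"uncertainty"` (homoscedastic-uncertainty weighting with learnable
#'   per-task log-variances; mapping, reactivity and classification are the
#'   three tasks, reactivity counting atom+bond as one).
#' @param dice_smooth Smoothing constant of the Dice loss (default 1).
#' @param epsilon Clamp for all log/division operations (default 1e-8).
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_map = 1, lambda_react = 1, lambda_cls = 1,
                        lambda_dice = 0.4, focal_gamma = 2, focal_alpha = 5,
                        weighting = c("fixed", "uncertainty"),
                        dice_smooth = 1, epsilon = 1e-8) {
  weighting <- match.arg(weighting)
  stopifnot(lambda_map >= 0, lambda_react >= 0, lambda_cls >= 0,
            lambda_dice >= 0, lambda_dice <= 1, focal_gamma >= 0,
            focal_alpha > 0, dice_smooth >= 0, epsilon > 0)
  structure(list(
    lambda_map = lambda_map, lambda_react = lambda_react,
    lambda_cls = lambda_cls, lambda_dice = lambda_dice,
    focal_gamma = focal_gamma, focal_alpha = focal_alpha,
    weighting = weighting, dice_smooth = dice_smooth, epsilon = epsilon
  ), class = "loss_config")
}

.clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Focal loss
#'
#' Mean of `-alpha_t (1 - p_t)^gamma log p_t` with `p_t = p` for positives
#' and `1 - p` for negatives; `alpha_t = alpha` on positives and 1 on
#' negatives. With `gamma = 0, alpha = 1` this is exactly binary
#' cross-entropy. Scores at 0/1 are clamped by `eps`.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels Binary labels.
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Positive-class weight.
#' @param eps Numerical clamp.
#' @return A single nonnegative number.
#' @export
focal_loss <- function(scores, labels, gamma = 2, alpha = 1, eps = 1e-8) {
  stopifnot(length(scores) == length(labels))
  if (!length(scores)) return(0)
  p <- .clamp01(scores, eps)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, alpha, 1)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# dL/dscores for the focal loss (mean reduction)
.focal_grad <- function(scores, labels, gamma, alpha, eps) {
  p <- .clamp01(scores, eps)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, alpha, 1)
  term <- (1 - pt)^gamma / pt
  if (gamma > 0) term <- term - gamma * (1 - pt)^(gamma - 1) * log(pt)
  dpt <- -at * term / length(scores)
  ifelse(labels == 1, dpt, -dpt)
}

#' Dice loss
#'
#' `1 - (2 sum(p y) + s) / (sum(p) + sum(y) + s)` with smoothing `s`, which
#' keeps the degenerate all-negative / all-zero case at loss 0.
#'
#' @inheritParams focal_loss
#' @param smooth Smoothing constant (default 1).
#' @return A single number in \[0, 1\].
#' @export
dice_loss <- function(scores, labels, smooth = 1) {
  stopifnot(length(scores) == length(labels))
  if (!length(scores)) return(0)
  num <- 2 * sum(scores * labels) + smooth
  den <- sum(scores) + sum(labels) + smooth
  1 - num / den
}

.dice_grad <- function(scores, labels, smooth) {
  num <- 2 * sum(scores * labels) + smooth
  den <- sum(scores) + sum(labels) + smooth
  -(2 * labels * den - num) / den^2
}

#' Hybrid Dice-Focal reactivity loss
#'
#' Convex combination `lambda_dice * Dice + (1 - lambda_dice) * Focal`,
#' computed independently for atoms and bonds.
#'
#' @param atom_scores,atom_labels,bond_scores,bond_labels Scores and binary
#'   labels on product atoms / bonds.
#' @param config A [loss_config()].
#' @return Named list with `atom` and `bond` losses.
#' @export
reactivity_loss <- function(atom_scores, atom_labels, bond_scores, bond_labels,
                            config = loss_config()) {
  lam <- config$lambda_dice
  one <- function(p, y) {
    lam * dice_loss(p, y, config$dice_smooth) +
      (1 - lam) * focal_loss(p, y, config$focal_gamma, config$focal_alpha,
                             config$epsilon)
  }
  list(atom = one(atom_scores, atom_labels), bond = one(bond_scores, bond_labels))
}

.reactivity_grad <- function(scores, labels, config) {
  lam <- config$lambda_dice
  lam * .dice_grad(scores, labels, config$dice_smooth) +
    (1 - lam) * .focal_grad(scores, labels, config$focal_gamma,
                            config$focal_alpha, config$epsilon)
}

#' Atom-mapping loss
#'
#' Row-wise negative log-likelihood of the ground-truth reactant atom under
#' the Sinkhorn-normalized correspondence matrix: mean over product atoms of
#' `-log M[i, truth(i)]`.
#'
#' @param soft Soft correspondence matrix (|V_P| x |V_R|).
#' @param truth_map Integer ground-truth assignment (reactant index per
#'   product atom).
#' @param eps Probability clamp.
#' @return A single nonnegative number.
#' @export
mapping_loss <- function(soft, truth_map, eps = 1e-8) {
  soft <- as.matrix(soft)
  stopifnot(length(truth_map) == nrow(soft))
  p <- soft[cbind(seq_len(nrow(soft)), as.integer(truth_map))]
  mean(-log(pmax(p, eps)))
}

#' Classification cross-entropy
#'
#' @param class_probs Probability vector over K classes (or matrix, one row
#'   per reaction).
#' @param true_class Integer class in 1..K (vector when `class_probs` is a
#'   matrix).
#' @param eps Probability clamp.
#' @return Mean negative log-likelihood.
#' @export
classification_loss <- function(class_probs, true_class, eps = 1e-8) {
  if (is.matrix(class_probs)) {
    p <- class_probs[cbind(seq_len(nrow(class_probs)), as.integer(true_class))]
  } else {
    p <- class_probs[as.integer(true_class)]
  }
  mean(-log(pmax(p, eps)))
}

#' Combine task losses into the total training objective
#'
#' Fixed mode: `lambda_map L_map + lambda_react (L_atom + L_bond) +
#' lambda_cls L_cls`. Uncertainty mode: `sum_i (1 / (2 sigma_i^2)) L_i +
#' log sigma_i` over the three tasks (mapping, reactivity = atom + bond,
#' classification), with `log_variances = log sigma_i^2` learned jointly
#' during training and held fixed at inference.
#'
#' @param L_map,L_atom,L_bond,L_cls Component losses (finite).
#' @param config A [loss_config()].
#' @param log_variances Numeric length-3 vector `log sigma_i^2` for tasks
#'   (map, react, cls); used only in uncertainty mode.
#' @return The scalar total loss.
#' @export
total_loss <- function(L_map, L_atom, L_bond, L_cls, config = loss_config(),
                       log_variances = c(0, 0, 0)) {
  stopifnot(is.finite(L_map), is.finite(L_atom), is.finite(L_bond),
            is.finite(L_cls))
  if (config$weighting == "fixed") {
    config$lambda_map * L_map + config$lambda_react * (L_atom + L_bond) +
      config$lambda_cls * L_cls
  } else {
    L <- c(L_map, L_atom + L_bond, L_cls)
    s <- log_variances
    sum(exp(-s) / 2 * L + s / 2)
  }
}

# per-task multipliers dTotal/dL_i and dTotal/ds_i
.total_loss_weights <- function(config, log_variances = c(0, 0, 0),
                                L = c(0, 0, 0)) {
  if (config$weighting == "fixed") {
    list(w = c(config$lambda_map, config$lambda_react, config$lambda_cls),
         ds = c(0, 0, 0))
  } else {
    s <- log_variances
    list(w = exp(-s) / 2, ds = -exp(-s) / 2 * L + 0.5)
  }
}
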