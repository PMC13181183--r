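# Evaluation metrics -----------------------------------------------------------

#' Top-n edit accuracy
#'
#' Atoms and bonds compete in one ranked candidate list per reaction
#' (descending predicted probability; ties broken by list position, atoms
#' before bonds). A reaction with e true edits counts as correct at level n
#' when its entire edit set appears within the top `n - 1 + e` candidates,
#' i.e. the full edit set is recovered allowing at most `n - 1` spurious
#' intrusions. For single-edit reactions this reduces to the usual
#' "true edit in the top n" convention (`single_edit_mode = TRUE` forces
#' that convention regardless of e). Reactions with zero true edits are
#' excluded from the rate and counted separately.
#'
#' @param scores List of per-reaction score lists, each with `atom_scores`
#'   and `bond_scores` (an `edit_scores` object works).
#' @param labels List of per-reaction label lists, each with `atom_labels`
#'   and `bond_labels` (an `edit_labels` object works).
#' @param n Ranking depth (e.g. 1, 3, 5).
#' @param single_edit_mode Score only the top-n membership of each true
#'   edit set's single best candidate window of size n.
#' @return Accuracy in \[0, 1\]; attribute `n_excluded` counts zero-edit
#'   reactions.
#' @export
top_n_edit_accuracy <- function(scores, labels, n, single_edit_mode = FALSE) {
  stopifnot(length(scores) == length(labels), n >= 1L)
  correct <- logical(0)
  excluded <- 0L
  for (k in seq_along(scores)) {
    s <- c(scores[[k]]$atom_scores, scores[[k]]$bond_scores)
    y <- c(labels[[k]]$atom_labels, labels[[k]]$bond_labels)
    stopifnot(length(s) == length(y))
    e <- sum(y)
    if (e == 0L) { excluded <- excluded + 1L; next }
    ord <- order(-s)  # stable: ties keep list position, atoms first
    depth <- if (single_edit_mode) n else n - 1L + e
    top <- ord[seq_len(min(depth, length(ord)))]
    correct <- c(correct, all(which(y == 1L) %in% top))
  }
  out <- if (length(correct)) mean(correct) else NA_real_
  attr(out, "n_excluded") <- excluded
  out
}

#' Reaction classification accuracy
#'
#' @param predicted,true Integer class vectors.
#' @return Fraction of exact matches.
#' @export
classification_accuracy <- function(predicted, true) {
  stopifnot(length(predicted) == length(true))
  mean(as.integer(predicted) == as.integer(true))
}

.f1_score <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Select atom and bond reactivity thresholds by F1 grid search
#'
#' Scans the grid independently for atoms and bonds and returns the
#' threshold maximizing F1; ties are broken toward the lower threshold.
#'
#' @param atom_scores,atom_labels,bond_scores,bond_labels Pooled validation
#'   scores and binary labels.
#' @param grid Candidate thresholds in (0, 1).
#' @return Named list `atom_threshold`, `bond_threshold` (with their F1
#'   values as `atom_f1`, `bond_f1`).
#' @export
select_thresholds <- function(atom_scores, atom_labels, bond_scores,
                              bond_labels, grid = seq(0.05, 0.95, by = 0.05)) {
  if (!length(grid)) stop("threshold grid must be nonempty")
  pick <- function(s, y) {
    if (!length(s)) return(list(threshold = 0.5, f1 = NA_real_))
    f1 <- vapply(grid, function(t) .f1_score(s, y, t), numeric(1))
    best <- which.max(f1)  # first maximum = lowest threshold on ties
    list(threshold = grid[best], f1 = f1[best])
  }
  a <- pick(atom_scores, atom_labels)
  b <- pick(bond_scores, bond_labels)
  list(atom_threshold = a$threshold, bond_threshold = b$threshold,
       atom_f1 = a$f1, bond_f1 = b$f1)
}

#' Prediction consistency
#'
#' Fraction of reactions where both the class prediction and the Top-1 edit
#' set are correct.
#'
#' @param class_correct,edit_correct Logical vectors of equal length.
#' @return Mean of the logical AND.
#' @export
consistency <- function(class_correct, edit_correct) {
  if (length(class_correct) != length(edit_correct)) {
    stop("flag vectors must have equal length")
  }
  mean(class_correct & edit_correct)
}
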