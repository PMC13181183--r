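# broom-style tidiers and ggplot2 autoplot methods ---------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted reaction model
#'
#' @param x A `rxn_fit`.
#' @param ... Unused.
#' @return The per-epoch training history as a tibble (losses, task
#'   uncertainties, validation scalarization).
#' @method tidy rxn_fit
#' @export
tidy.rxn_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted reaction model
#'
#' @param x A `rxn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with epochs trained and the final validation
#'   metrics.
#' @method glance rxn_fit
#' @export
glance.rxn_fit <- function(x, ...) {
  r <- x$validation_report
  tibble::tibble(
    n_epochs = x$n_epochs,
    top1_edit = unname(r$top_n_edit["top1"]),
    top3_edit = unname(r$top_n_edit["top3"]),
    top5_edit = unname(r$top_n_edit["top5"]),
    class_accuracy = r$class_accuracy,
    map_accuracy = r$map_accuracy,
    atom_f1 = r$atom_f1,
    bond_f1 = r$bond_f1,
    consistency = r$consistency
  )
}

#' Tidy an evaluation report
#'
#' @param x A `rxn_eval_report`.
#' @param ... Unused.
#' @return The per-class breakdown tibble.
#' @method tidy rxn_eval_report
#' @export
tidy.rxn_eval_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x A `rxn_eval_report`.
#' @param ... Unused.
#' @return A one-row tibble of all aggregate metrics.
#' @method glance rxn_eval_report
#' @export
glance.rxn_eval_report <- function(x, ...) {
  tibble::tibble(
    n_reactions = x$n_reactions,
    top1_edit = unname(x$top_n_edit["top1"]),
    top3_edit = unname(x$top_n_edit["top3"]),
    top5_edit = unname(x$top_n_edit["top5"]),
    class_accuracy = x$class_accuracy,
    map_accuracy = x$map_accuracy,
    atom_f1 = x$atom_f1,
    bond_f1 = x$bond_f1,
    atom_threshold = unname(x$thresholds["atom"]),
    bond_threshold = unname(x$thresholds["bond"]),
    consistency = x$consistency
  )
}

#' Heatmap of a soft correspondence matrix
#'
#' Product atoms on the y axis, reactant atoms on the x axis, fill by
#' alignment probability — the attention-heatmap view of a predicted atom
#' mapping.
#'
#' @param object A `correspondence_matrix` (from [model_forward()] or the
#'   `correspondence` column of [predict_reactions()] output).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correspondence_matrix
#' @export
autoplot.correspondence_matrix <- function(object, ...) {
  M <- object$soft
  df <- tidyr::expand_grid(product_atom = seq_len(nrow(M)),
                           reactant_atom = seq_len(ncol(M)))
  df$probability <- as.vector(t(M))[
    (df$product_atom - 1L) * ncol(M) + df$reactant_atom]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reactant_atom,
                                   y = .data$product_atom,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "reactant atom", y = "product atom",
                  fill = "P(align)") +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted reaction model
#'
#' @param object A `rxn_fit`.
#' @param ... Unused.
#' @return A ggplot object with per-task loss curves over epochs.
#' @method autoplot rxn_fit
#' @export
autoplot.rxn_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[, c("epoch", "loss_map", "loss_atom", "loss_bond", "loss_cls")],
    -"epoch", names_to = "task", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss") +
    ggplot2::theme_minimal()
}

#' Per-class accuracy chart of an evaluation report
#'
#' @param object A `rxn_eval_report`.
#' @param ... Unused.
#' @return A ggplot object (per-class Top-1 edit and classification
#'   accuracy).
#' @method autoplot rxn_eval_report
#' @export
autoplot.rxn_eval_report <- function(object, ...) {
  pc <- object$per_class
  long <- tidyr::pivot_longer(
    pc[, c("class", "class_accuracy", "top1_edit", "consistency")],
    -"class", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reaction class", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
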