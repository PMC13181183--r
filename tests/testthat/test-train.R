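# Training loop, prediction interface and checkpoints (desk-scale smoke
# configuration: tiny encoder, few epochs).

train_fixture <- function() {
  list(
    ds = generate_reactions(generator_config(n_reactions = 10, seed = 2)),
    cfg = small_config(seed = 2)
  )
}

test_that("training is reproducible and records history", {
  fx <- train_fixture()
  f1 <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                    max_epochs = 3, batch_size = 5, learning_rate = 1e-3,
                    eval_every = 0, seed = 4)
  f2 <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                    max_epochs = 3, batch_size = 5, learning_rate = 1e-3,
                    eval_every = 0, seed = 4)
  expect_equal(f1$history$loss_total, f2$history$loss_total)
  expect_equal(nrow(f1$history), 3L)
  expect_true(all(is.finite(f1$history$loss_total)))
  # losses should be moving: epoch 3 differs from epoch 1
  expect_false(isTRUE(all.equal(f1$history$loss_total[1],
                                f1$history$loss_total[3])))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(glance(f1)), 1L)
})

test_that("early stopping with patience 0 halts at the first plateau", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                     max_epochs = 30, batch_size = 5, learning_rate = 0,
                     patience = 0, eval_every = 1, seed = 4)
  # zero learning rate: the validation scalar never improves after the
  # first evaluation, so training stops at the second
  expect_lte(fit$n_epochs, 3L)
})

test_that("resuming training continues from the stored state", {
  fx <- train_fixture()
  a <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                   max_epochs = 2, batch_size = 5, learning_rate = 1e-3,
                   eval_every = 0, seed = 4)
  b <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                   max_epochs = 2, batch_size = 5, learning_rate = 1e-3,
                   eval_every = 0, seed = 4, resume = a)
  expect_equal(b$n_epochs, 4L)
  expect_equal(nrow(b$history), 4L)
})

test_that("uncertainty weighting learns per-task log-variances", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(weighting = "uncertainty"),
                     mode = "full", max_epochs = 3, batch_size = 5,
                     learning_rate = 1e-3, eval_every = 0, seed = 4)
  expect_false(all(fit$params$log_sigma2 == 0))
  expect_true(all(is.finite(fit$params$log_sigma2)))
})

test_that("prediction output is deterministic and mode-aware", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                     max_epochs = 2, batch_size = 5, learning_rate = 1e-3,
                     eval_every = 0, seed = 4)
  p1 <- predict_reactions(fit, fx$ds$rxn_smiles[1:3])
  p2 <- predict_reactions(fit, fx$ds$rxn_smiles[1:3])
  expect_identical(p1, p2)
  expect_true(all(vapply(p1$mapping, Negate(is.null), logical(1))))
  expect_true(all(vapply(p1$correspondence, is.matrix, logical(1))))
  # mappings are total over product atoms with valid reactant indices
  for (k in 1:3) {
    rx <- parse_reaction(fx$ds$rxn_smiles[k])
    expect_length(p1$mapping[[k]], rx$product$n_atoms)
    expect_true(all(p1$mapping[[k]] >= 1 &
                      p1$mapping[[k]] <= rx$reactants$n_atoms))
  }

  # plain product SMILES: no mapping, scores still produced
  po <- predict_reactions(fit, "CCO")
  expect_null(po$mapping[[1]])
  expect_null(po$correspondence[[1]])
  expect_length(po$atom_scores[[1]], 3L)
  expect_equal(sum(po$class_probs[[1]]), 1)
})

test_that("products-only training runs without reactant leakage", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(), mode = "products_only",
                     max_epochs = 2, batch_size = 5, learning_rate = 1e-3,
                     eval_every = 0, seed = 4)
  rep <- evaluate_model(fit, fx$ds)
  expect_true(is.finite(rep$class_accuracy))
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("checkpoints round trip and reject incompatible files", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                     max_epochs = 1, batch_size = 5, learning_rate = 1e-3,
                     eval_every = 0, seed = 4)
  path <- tempfile(fileext = ".ckpt")
  on.exit(unlink(path), add = TRUE)
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, fit$params)
  p1 <- predict_reactions(fit, fx$ds$rxn_smiles[1])
  p2 <- predict_reactions(back, fx$ds$rxn_smiles[1])
  expect_equal(p1$class_probs[[1]], p2$class_probs[[1]])
  saveRDS(list(version = 99L), path)
  expect_error(load_checkpoint(path), "version")
})

test_that("evaluation report is complete and plottable", {
  fx <- train_fixture()
  fit <- train_model(fx$ds, fx$cfg, loss_config(), mode = "full",
                     max_epochs = 2, batch_size = 5, learning_rate = 1e-3,
                     eval_every = 0, seed = 4)
  rep <- evaluate_model(fit, fx$ds)
  expect_named(rep$top_n_edit, c("top1", "top3", "top5"))
  expect_true(all(unlist(rep$top_n_edit) >= 0 & unlist(rep$top_n_edit) <= 1))
  expect_true(rep$thresholds["atom"] > 0 && rep$thresholds["atom"] < 1)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_gt(nrow(tidy(rep)), 0L)
  pr <- predict_reactions(fit, fx$ds$rxn_smiles[1])
  corr <- structure(list(soft = pr$correspondence[[1]]),
                    class = "correspondence_matrix")
  expect_s3_class(ggplot2::autoplot(corr), "ggplot")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
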