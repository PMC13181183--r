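test_that("focal loss reduces to BCE at gamma = 0 and matches closed forms", {
  set.seed(5)
  for (rep in 1:5) {
    p <- runif(40, 0.01, 0.99)
    y <- rbinom(40, 1, 0.3)
    bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    expect_equal(focal_loss(p, y, gamma = 0, alpha = 1), bce, tolerance = 1e-10)
  }
  # direct evaluation of the focal formula at p = 0.9, y = 1, gamma = 2
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 1),
               -(0.1)^2 * log(0.9), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 1), 1.0536e-3,
               tolerance = 1e-4)
  # perfect confident predictions drive the loss to ~0 (epsilon clamp)
  expect_lt(focal_loss(c(1, 0, 1), c(1, 0, 1), gamma = 2, alpha = 1), 1e-12)
  # positive-class weight scales positive terms linearly
  expect_equal(focal_loss(0.7, 1, gamma = 1, alpha = 5),
               5 * focal_loss(0.7, 1, gamma = 1, alpha = 1))
})

test_that("dice loss honors overlap and the smoothing contract", {
  y <- c(1, 0, 0, 1, 0)
  expect_lt(dice_loss(y, y, smooth = 1), 0.2)
  expect_equal(dice_loss(y, y, smooth = 0), 0)
  # disjoint prediction: loss tends to 1 as smoothing vanishes
  expect_gt(dice_loss(c(0, 1, 1, 0, 1), y, smooth = 1e-8), 1 - 1e-6)
  # degenerate all-negative labels with all-zero scores stay at 0
  expect_equal(dice_loss(rep(0, 4), rep(0, 4), smooth = 1), 0)
})

test_that("reactivity loss interpolates between dice and focal", {
  set.seed(6)
  p <- runif(20); y <- rbinom(20, 1, 0.2)
  cfg0 <- loss_config(lambda_dice = 0)
  cfg1 <- loss_config(lambda_dice = 1)
  r0 <- reactivity_loss(p, y, p, y, cfg0)
  expect_equal(r0$atom, focal_loss(p, y, cfg0$focal_gamma, cfg0$focal_alpha))
  r1 <- reactivity_loss(p, y, p, y, cfg1)
  expect_equal(r1$atom, dice_loss(p, y, 1))
  expect_equal(loss_config()$lambda_dice, 0.4)
  rmix <- reactivity_loss(p, y, p, y, loss_config())
  expect_equal(rmix$atom, 0.4 * r1$atom + 0.6 * r0$atom)
})

test_that("mapping loss is a row-wise NLL on the soft matrix", {
  P <- diag(4)
  expect_equal(mapping_loss(P, 1:4), 0, tolerance = 1e-7)
  U <- matrix(1 / 5, 3, 5)
  expect_equal(mapping_loss(U, c(1L, 3L, 5L)), log(5))
  # loss decreases monotonically as diagonal mass grows on a 3x3 toy
  losses <- vapply(seq(0, 4, by = 0.5), function(s) {
    mapping_loss(sinkhorn(diag(3) * s, 20, 1), 1:3)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("total loss combines tasks per the fixed and uncertainty schemes", {
  cfg <- loss_config(lambda_map = 1, lambda_react = 1, lambda_cls = 1)
  expect_equal(total_loss(1, 2, 3, 4, cfg), 1 + (2 + 3) + 4)
  cfg2 <- loss_config(lambda_map = 0.5, lambda_react = 2, lambda_cls = 0)
  expect_equal(total_loss(1, 2, 3, 4, cfg2), 0.5 + 2 * 5)

  ucfg <- loss_config(weighting = "uncertainty")
  # all sigma_i = 1 (log-variances 0): total equals sum of task losses / 2
  expect_equal(total_loss(1, 2, 3, 4, ucfg, log_variances = c(0, 0, 0)),
               (1 + (2 + 3) + 4) / 2)
  # gradient wrt each task loss is 1 / (2 sigma_i^2) — finite differences
  s <- c(log(2), log(0.5), log(3))
  eps <- 1e-6
  for (i in 1:3) {
    L <- c(1, 5, 4)
    bump <- function(d) {
      Li <- L; Li[i] <- Li[i] + d
      total_loss(Li[1], Li[2], 0, Li[3], ucfg, s)
    }
    fd <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_equal(fd, 1 / (2 * exp(s[i])), tolerance = 1e-5)
  }
})

test_that("the optimal uncertainty equals the task loss at the stationary point", {
  ucfg <- loss_config(weighting = "uncertainty")
  for (L in c(0.3, 1, 2.5)) {
    opt <- stats::optimize(function(s) exp(-s) / 2 * L + s / 2,
                           interval = c(-10, 10))
    expect_equal(exp(opt$minimum), L, tolerance = 1e-4)
    # and the package's total-loss weights are stationary there
    w <- rxngraph:::.total_loss_weights(ucfg, rep(log(L), 3), rep(L, 3))
    expect_equal(w$ds, rep(0, 3), tolerance = 1e-12)
  }
})

test_that("classification loss is the usual cross-entropy", {
  p <- c(0.1, 0.7, 0.2)
  expect_equal(classification_loss(p, 2L), -log(0.7))
  P <- rbind(p, c(0.5, 0.25, 0.25))
  expect_equal(classification_loss(P, c(2L, 1L)), mean(-log(c(0.7, 0.5))))
})
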