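# Numeric core: parameter containers, cached forward passes, hand-derived
# reverse-mode gradients, and AdamW. Everything is plain base-R matrix
# algebra; graphs at desk scale are small enough that this is fast.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# rowsum aligned to 1..n (rows absent from idx stay zero)
.agg_rows <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M)) {
    rs <- rowsum(M, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# Sinkhorn in the log domain (single source of truth for the forward
# recursion; the exported sinkhorn() delegates here). Working with
# log-probabilities makes the scaling unconditionally stable for any input
# magnitude / temperature, and is exactly equivalent to alternating
# row/column normalization of exp(raw / temperature).
.lse_rows <- function(L) {
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

.sinkhorn_cached <- function(raw, iterations = 10L, temperature = 0.1) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("sinkhorn() requires finite input entries")
  stopifnot(iterations >= 1L, temperature > 0)
  L <- raw / temperature
  steps <- vector("list", 2L * iterations + 1L)
  k <- 0L
  push <- function(type, Lpost, active = NULL) {
    k <<- k + 1L
    steps[[k]] <<- list(type = type, Lpost = Lpost, active = active)
  }
  # on wide inputs (|V_P| < |V_R|) columns are capacity-constrained rather
  # than fully normalized: only columns whose mass exceeds 1 are shrunk, so
  # reactant atoms with no product counterpart (leaving groups, reagents)
  # keep their low mass instead of extorting probability from product rows;
  # square (and tall) inputs use plain normalization, whose fixed point is
  # doubly stochastic
  clamp_cols <- ncol(L) > nrow(L)
  for (it in seq_len(iterations)) {
    L <- L - .lse_rows(L); push("row", L)
    s <- .lse_rows(t(L))
    active <- if (clamp_cols) s > 0 else rep(TRUE, ncol(L))
    L <- t(t(L) - if (clamp_cols) pmax(s, 0) else s); push("col", L, active)
  }
  L <- L - .lse_rows(L); push("row", L)
  list(M = exp(L), logM = L, steps = steps, temperature = temperature)
}

# gradient of a scalar loss wrt `raw` given either dL/dM or (preferably, for
# likelihood losses) dL/dlogM on the Sinkhorn output
.sinkhorn_backward <- function(cache, dM = NULL, dlogM = NULL) {
  dL <- if (!is.null(dlogM)) dlogM else dM * cache$M
  for (k in rev(seq_along(cache$steps))) {
    st <- cache$steps[[k]]
    P <- exp(st$Lpost)
    if (st$type == "row") {
      dL <- dL - P * rowSums(dL)
    } else {
      adj <- t(t(P) * colSums(dL))
      adj[, !st$active] <- 0
      dL <- dL - adj
    }
  }
  dL / cache$temperature
}

# Configuration and initialization -------------------------------------------

#' Encoder / model configuration
#'
#' Defaults mirror the reference training configuration (5 edge-aware
#' message-passing layers with 512-dimensional embeddings and 8 attention
#' heads); desk-scale runs typically shrink `hidden_dim`/`num_layers`.
#'
#' @param num_layers Number of encoder layers (>= 1).
#' @param hidden_dim Embedding width; must be divisible by `num_heads`.
#' @param num_heads Attention heads (per-head key width `hidden_dim /
#'   num_heads`).
#' @param dual_layers Layers of the dual (bond-node) graph encoder.
#' @param n_classes Number of reaction classes K (default 10).
#' @param sinkhorn_iterations,sinkhorn_temperature Soft-matching defaults.
#' @param seed Seed for parameter initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(num_layers = 5L, hidden_dim = 512L, num_heads = 8L,
                           dual_layers = 2L, n_classes = 10L,
                           sinkhorn_iterations = 10L,
                           sinkhorn_temperature = 0.1, seed = 1L) {
  stopifnot(num_layers >= 1L, hidden_dim >= 1L, num_heads >= 1L,
            hidden_dim %% num_heads == 0L, dual_layers >= 1L, n_classes >= 2L)
  structure(list(
    num_layers = as.integer(num_layers), hidden_dim = as.integer(hidden_dim),
    num_heads = as.integer(num_heads), dual_layers = as.integer(dual_layers),
    n_classes = as.integer(n_classes),
    sinkhorn_iterations = as.integer(sinkhorn_iterations),
    sinkhorn_temperature = sinkhorn_temperature, seed = as.integer(seed)
  ), class = "encoder_config")
}

.rmat <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Initialize model parameters
#'
#' Fan-in scaled Gaussian initialization for all projection matrices; skip
#' gates start at 0.5 (raw 0) and the GIN self-weights at 0. The encoder
#' parameter block is shared between reactant and product passes.
#'
#' @param config An [encoder_config()].
#' @return A nested list of parameter matrices (`rxn_params`).
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  d <- feature_dims()
  h <- config$hidden_dim
  K <- config$n_classes
  layer <- function(edge = TRUE) {
    l <- list(
      W1 = .rmat(h, h), b1 = numeric(h),
      W2 = .rmat(h, h), b2 = numeric(h),
      eps = 0, gate = 0
    )
    if (edge) { l$We <- .rmat(d$d_e, h, d$d_e); l$be <- numeric(h) }
    l
  }
  p <- list(
    W_in = .rmat(d$d_x, h, d$d_x), b_in = numeric(h),
    enc = lapply(seq_len(config$num_layers), function(i) layer(edge = TRUE)),
    Wq = .rmat(h, h), Wk = .rmat(h, h), Wv = .rmat(h, h),
    Wd_in = .rmat(d$d_e, h, d$d_e), bd_in = numeric(h),
    dual = lapply(seq_len(config$dual_layers), function(i) layer(edge = FALSE)),
    atom = list(W1 = .rmat(2 * h, h, 2 * h), b1 = numeric(h),
                W2 = .rmat(h, 1), b2 = 0),
    bond = list(W1 = .rmat(5 * h + d$d_e + 2, h, 5 * h + d$d_e + 2),
                b1 = numeric(h), W2 = .rmat(h, 1), b2 = 0),
    cls = list(W1 = .rmat(2 * h, h, 2 * h), b1 = numeric(h),
               W2 = .rmat(h, K), b2 = numeric(K)),
    log_sigma2 = c(map = 0, react = 0, cls = 0)
  )
  structure(p, class = "rxn_params")
}

# zero-filled gradient tree with the same shape as params
.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

.tree_add <- function(a, b, scale = 1) {
  if (is.list(a)) {
    out <- Map(.tree_add, a, b, MoreArgs = list(scale = scale))
    attributes(out) <- attributes(a)
    out
  } else a + scale * b
}

# Encoder --------------------------------------------------------------------

# cached GINE-style forward over one graph; returns H plus per-layer caches
.encode_cached <- function(graph, params, config) {
  if (graph$n_atoms == 0L) stop("cannot encode an empty graph")
  if (is.null(graph$X)) stop("graph must be featurized before encoding")
  n <- graph$n_atoms
  src <- graph$edges_dir$src; dst <- graph$edges_dir$dst
  bid <- graph$edges_dir$bond
  Edir <- if (length(bid)) graph$E[bid, , drop = FALSE] else
    matrix(0, 0L, ncol(graph$E))
  H <- .addb(graph$X %*% params$W_in, params$b_in)
  H0 <- H
  layers <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    pl <- params$enc[[l]]
    Pre <- if (length(src)) H[src, , drop = FALSE] + .addb(Edir %*% pl$We, pl$be)
      else matrix(0, 0L, config$hidden_dim)
    Msg <- pmax(Pre, 0)
    agg <- .agg_rows(Msg, dst, n)
    S <- (1 + pl$eps) * H + agg
    Z1 <- .addb(S %*% pl$W1, pl$b1)
    R1 <- pmax(Z1, 0)
    U <- .addb(R1 %*% pl$W2, pl$b2)
    g <- .sigmoid(pl$gate)
    Hout <- g * U + (1 - g) * H
    layers[[l]] <- list(H_in = H, Pre = Pre, S = S, Z1 = Z1, R1 = R1, U = U, g = g)
    H <- Hout
  }
  list(H = H, H0 = H0, layers = layers, src = src, dst = dst, Edir = Edir,
       X = graph$X, n = n)
}

# accumulate encoder gradients into `grads` given dL/dH at the output
.encode_backward <- function(cache, params, config, dH, grads) {
  n <- cache$n
  for (l in rev(seq_len(config$num_layers))) {
    pl <- params$enc[[l]]
    cl <- cache$layers[[l]]
    dU <- cl$g * dH
    dgate <- sum(dH * (cl$U - cl$H_in)) * cl$g * (1 - cl$g)
    dH_in <- (1 - cl$g) * dH
    grads$enc[[l]]$W2 <- grads$enc[[l]]$W2 + t(cl$R1) %*% dU
    grads$enc[[l]]$b2 <- grads$enc[[l]]$b2 + colSums(dU)
    dR1 <- dU %*% t(pl$W2)
    dZ1 <- dR1 * (cl$Z1 > 0)
    grads$enc[[l]]$W1 <- grads$enc[[l]]$W1 + t(cl$S) %*% dZ1
    grads$enc[[l]]$b1 <- grads$enc[[l]]$b1 + colSums(dZ1)
    dS <- dZ1 %*% t(pl$W1)
    grads$enc[[l]]$eps <- grads$enc[[l]]$eps + sum(dS * cl$H_in)
    grads$enc[[l]]$gate <- grads$enc[[l]]$gate + dgate
    dH_in <- dH_in + (1 + pl$eps) * dS
    if (length(cache$src)) {
      dMsg <- dS[cache$dst, , drop = FALSE] * (cl$Pre > 0)
      dH_in <- dH_in + .agg_rows(dMsg, cache$src, n)
      grads$enc[[l]]$We <- grads$enc[[l]]$We + t(cache$Edir) %*% dMsg
      grads$enc[[l]]$be <- grads$enc[[l]]$be + colSums(dMsg)
    }
    dH <- dH_in
  }
  grads$W_in <- grads$W_in + t(cache$X) %*% dH
  grads$b_in <- grads$b_in + colSums(dH)
  grads
}

# Dual-graph encoder (GIN-style, no edge features, separate parameters) ------

.encode_dual_cached <- function(dual, params, config) {
  nb <- dual$n_nodes
  h <- config$hidden_dim
  if (nb == 0L) {
    return(list(H = matrix(0, 0L, h), empty = TRUE))
  }
  src <- c(dual$edges$a, dual$edges$b)
  dst <- c(dual$edges$b, dual$edges$a)
  H <- .addb(dual$node_features %*% params$Wd_in, params$bd_in)
  layers <- vector("list", config$dual_layers)
  for (l in seq_len(config$dual_layers)) {
    pl <- params$dual[[l]]
    agg <- if (length(src)) .agg_rows(H[src, , drop = FALSE], dst, nb)
      else matrix(0, nb, h)
    S <- (1 + pl$eps) * H + agg
    Z1 <- .addb(S %*% pl$W1, pl$b1)
    R1 <- pmax(Z1, 0)
    U <- .addb(R1 %*% pl$W2, pl$b2)
    g <- .sigmoid(pl$gate)
    Hout <- g * U + (1 - g) * H
    layers[[l]] <- list(H_in = H, S = S, Z1 = Z1, R1 = R1, U = U, g = g)
    H <- Hout
  }
  list(H = H, layers = layers, src = src, dst = dst,
       X = dual$node_features, n = nb, empty = FALSE)
}

.encode_dual_backward <- function(cache, params, config, dH, grads) {
  if (isTRUE(cache$empty)) return(grads)
  n <- cache$n
  for (l in rev(seq_len(config$dual_layers))) {
    pl <- params$dual[[l]]
    cl <- cache$layers[[l]]
    dU <- cl$g * dH
    dgate <- sum(dH * (cl$U - cl$H_in)) * cl$g * (1 - cl$g)
    dH_in <- (1 - cl$g) * dH
    grads$dual[[l]]$W2 <- grads$dual[[l]]$W2 + t(cl$R1) %*% dU
    grads$dual[[l]]$b2 <- grads$dual[[l]]$b2 + colSums(dU)
    dR1 <- dU %*% t(pl$W2)
    dZ1 <- dR1 * (cl$Z1 > 0)
    grads$dual[[l]]$W1 <- grads$dual[[l]]$W1 + t(cl$S) %*% dZ1
    grads$dual[[l]]$b1 <- grads$dual[[l]]$b1 + colSums(dZ1)
    dS <- dZ1 %*% t(pl$W1)
    grads$dual[[l]]$eps <- grads$dual[[l]]$eps + sum(dS * cl$H_in)
    grads$dual[[l]]$gate <- grads$dual[[l]]$gate + dgate
    dH_in <- dH_in + (1 + pl$eps) * dS
    if (length(cache$src)) {
      dH_in <- dH_in + .agg_rows(dS[cache$dst, , drop = FALSE], cache$src, n)
    }
    dH <- dH_in
  }
  grads$Wd_in <- grads$Wd_in + t(cache$X) %*% dH
  grads$bd_in <- grads$bd_in + colSums(dH)
  grads
}

# Heads ----------------------------------------------------------------------

.mlp2_cached <- function(In, W1, b1, W2, b2) {
  Z1 <- .addb(In %*% W1, b1)
  R1 <- pmax(Z1, 0)
  Out <- .addb(R1 %*% W2, b2)
  list(In = In, Z1 = Z1, R1 = R1, Out = Out)
}

# returns list(dIn, dW1, db1, dW2, db2) for dL/dOut
.mlp2_backward <- function(cache, W1, W2, dOut) {
  dW2 <- t(cache$R1) %*% dOut
  db2 <- colSums(dOut)
  dR1 <- dOut %*% t(W2)
  dZ1 <- dR1 * (cache$Z1 > 0)
  dW1 <- t(cache$In) %*% dZ1
  db1 <- colSums(dZ1)
  list(dIn = dZ1 %*% t(W1), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# AdamW ----------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 5e-5) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      nms <- names(p)
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]],
                  if (is.null(nms)) name else nms[k])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      wd <- if (identical(name, "log_sigma2")) 0 else weight_decay
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v, "")
  r$p <- structure(r$p, class = class(params))
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
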