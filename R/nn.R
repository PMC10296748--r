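# Self-contained recurrent-network numerics: stacked bidirectional LSTM with
# backpropagation through time, SELU activations, inverted dropout, batch
# normalization, a dense head, binary/categorical cross-entropy, and
# RMSProp/Adam updates. Everything operates on batches as plain matrices and
# 3-D arrays (batch x time x features); all loops over time are vectorized
# over the batch.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA  <- 1.6732632423543772

selu <- function(x) {
  p <- x > 0
  x[p] <- SELU_LAMBDA * x[p]
  x[!p] <- SELU_LAMBDA * SELU_ALPHA * expm1(x[!p])
  x
}

# derivative from the pre-activation
selu_grad <- function(x) {
  g <- x
  p <- x > 0
  g[p] <- SELU_LAMBDA
  g[!p] <- SELU_LAMBDA * SELU_ALPHA * exp(x[!p])
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot_uniform <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

# ---- LSTM (one direction) ---------------------------------------------------

# Gate order in the fused weight matrices: input, forget, candidate, output.
# The recurrence uses the standard bounded LSTM nonlinearities (logistic
# gates, tanh candidate and cell output), which keeps the 10^2-step
# recursion contractive; the stack's SELU activation is applied to the
# bidirectional layer's per-position outputs (see layer_bilstm), not inside
# the cell, where an unbounded >1-slope activation makes the cell state
# diverge in deep stacks.
lstm_params <- function(input_dim, units) {
  list(
    Wx = glorot_uniform(input_dim, 4 * units),
    Wh = glorot_uniform(units, 4 * units),
    b  = c(rep(0, units), rep(1, units), rep(0, 2 * units))  # forget bias 1
  )
}

# X: B x L x D array. Returns per-position outputs H (B x L x u) plus the
# caches needed for BPTT.
lstm_forward <- function(X, prm) {
  dims <- dim(X); B <- dims[1]; L <- dims[2]; D <- dims[3]
  u <- ncol(prm$Wh) / 4
  Xm <- matrix(X, B * L, D)                      # rows ordered (batch, time)
  proj <- Xm %*% prm$Wx
  proj <- sweep(proj, 2, prm$b, "+")
  # per-timestep caches kept as lists of B x u matrices (cheap to index)
  I <- Fg <- Gpre <- O <- C <- Hc <- Hs <- vector("list", L)
  h <- matrix(0, B, u); cstate <- matrix(0, B, u)
  i_ix <- seq_len(u); f_ix <- u + i_ix; g_ix <- 2 * u + i_ix; o_ix <- 3 * u + i_ix
  for (t in seq_len(L)) {
    rows <- ((t - 1) * B + 1):(t * B)
    z <- proj[rows, , drop = FALSE] + h %*% prm$Wh
    ig <- sigmoid(z[, i_ix, drop = FALSE])
    fg <- sigmoid(z[, f_ix, drop = FALSE])
    gp <- z[, g_ix, drop = FALSE]
    og <- sigmoid(z[, o_ix, drop = FALSE])
    cstate <- fg * cstate + ig * tanh(gp)
    hc <- tanh(cstate)
    h <- og * hc
    I[[t]] <- ig; Fg[[t]] <- fg; Gpre[[t]] <- gp; O[[t]] <- og
    C[[t]] <- cstate; Hc[[t]] <- hc; Hs[[t]] <- h
  }
  H <- array(0, c(B, L, u))
  for (t in seq_len(L)) H[, t, ] <- Hs[[t]]
  list(H = H, cache = list(I = I, Fg = Fg, Gpre = Gpre, O = O, C = C,
                           Hc = Hc, Hs = Hs, Xm = Xm, dims = dims, u = u))
}

# dH: B x L x u gradient w.r.t. every per-position output.
lstm_backward <- function(dH, cache, prm) {
  dims <- cache$dims; B <- dims[1]; L <- dims[2]; D <- dims[3]; u <- cache$u
  dWx <- matrix(0, D, 4 * u); dWh <- matrix(0, u, 4 * u); db <- numeric(4 * u)
  dXm <- matrix(0, B * L, D)
  zero <- matrix(0, B, u)
  dh_rec <- zero; dc <- zero
  for (t in rev(seq_len(L))) {
    dh <- matrix(dH[, t, ], B, u) + dh_rec
    ig <- cache$I[[t]]; fg <- cache$Fg[[t]]; gp <- cache$Gpre[[t]]
    og <- cache$O[[t]]; cs <- cache$C[[t]]; hc <- cache$Hc[[t]]
    cprev <- if (t > 1) cache$C[[t - 1]] else zero
    hprev <- if (t > 1) cache$Hs[[t - 1]] else zero
    do_ <- dh * hc
    dc <- dc + dh * og * (1 - hc * hc)
    gt <- tanh(gp)
    dz <- cbind((dc * gt) * ig * (1 - ig),
                (dc * cprev) * fg * (1 - fg),
                (dc * ig) * (1 - gt * gt),
                do_ * og * (1 - og))
    rows <- ((t - 1) * B + 1):(t * B)
    xt <- cache$Xm[rows, , drop = FALSE]
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dh_rec <- tcrossprod(dz, prm$Wh)
    dXm[rows, ] <- tcrossprod(dz, prm$Wx)
    dc <- dc * fg
  }
  list(dX = array(dXm, dims), grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- layers -----------------------------------------------------------------

layer_bilstm <- function(input_dim, units) {
  list(type = "bilstm", units = units, input_dim = input_dim,
       params = list(fwd = lstm_params(input_dim, units),
                     bwd = lstm_params(input_dim, units)))
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate,
                                     params = list())

# Running-statistic momentum 0.9: suited to short training runs, where a
# slower schedule would leave inference statistics dominated by their
# initialization.
layer_batchnorm <- function(n_features, momentum = 0.9, eps = 1e-3) {
  list(type = "batchnorm", eps = eps, momentum = momentum,
       params = list(gamma = rep(1, n_features), beta = rep(0, n_features)),
       state = list(mean = rep(0, n_features), var = rep(1, n_features)))
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(input_dim, units, activation = "selu") {
  list(type = "dense", units = units, activation = activation,
       params = list(W = glorot_uniform(input_dim, units),
                     b = rep(0, units)))
}

reverse_time <- function(X) {
  L <- dim(X)[2]
  X[, L:1, , drop = FALSE]
}

forward_layer <- function(layer, x, training) {
  switch(layer$type,
    bilstm = {
      f <- lstm_forward(x, layer$params$fwd)
      b <- lstm_forward(reverse_time(x), layer$params$bwd)
      Hb <- reverse_time(b$H)
      u <- layer$units
      pre <- array(0, c(dim(x)[1], dim(x)[2], 2 * u))
      pre[, , seq_len(u)] <- f$H
      pre[, , u + seq_len(u)] <- Hb
      list(out = selu(pre),
           cache = list(f = f$cache, b = b$cache, pre = pre), layer = layer)
    },
    dropout = {
      if (!training || layer$rate == 0)
        return(list(out = x, cache = NULL, layer = layer))
      mask <- array(stats::runif(length(x)) >= layer$rate, dim(x)) /
        (1 - layer$rate)
      list(out = x * mask, cache = mask, layer = layer)
    },
    batchnorm = {
      d <- dim(x)
      xm <- if (length(d) == 3) matrix(x, d[1] * d[2], d[3]) else x
      if (training) {
        mu <- colMeans(xm)
        xc <- sweep(xm, 2, mu)
        v <- colMeans(xc * xc)
        istd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2, istd, "*")
        m <- layer$momentum
        layer$state$mean <- m * layer$state$mean + (1 - m) * mu
        layer$state$var <- m * layer$state$var + (1 - m) * v
        cache <- list(xhat = xhat, istd = istd, xc = xc, d = d)
      } else {
        istd <- 1 / sqrt(layer$state$var + layer$eps)
        xhat <- sweep(sweep(xm, 2, layer$state$mean), 2, istd, "*")
        cache <- NULL
      }
      y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                 layer$params$beta, "+")
      if (length(d) == 3) dim(y) <- d
      list(out = y, cache = cache, layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- matrix(x, d[1], prod(d[-1]))
      list(out = y, cache = d, layer = layer)
    },
    dense = {
      z <- sweep(x %*% layer$params$W, 2, layer$params$b, "+")
      a <- switch(layer$activation,
                  selu = selu(z), linear = z,
                  stop("unknown dense activation", call. = FALSE))
      list(out = a, cache = list(x = x, z = z), layer = layer)
    },
    stop("unknown layer type", call. = FALSE)
  )
}

backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    bilstm = {
      u <- layer$units
      dout <- dout * selu_grad(cache$pre)
      df <- dout[, , seq_len(u), drop = FALSE]
      db_ <- dout[, , u + seq_len(u), drop = FALSE]
      bf <- lstm_backward(df, cache$f, layer$params$fwd)
      bb <- lstm_backward(reverse_time(db_), cache$b, layer$params$bwd)
      list(dx = bf$dX + reverse_time(bb$dX),
           grads = list(fwd = bf$grads, bwd = bb$grads))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = list())
      else list(dx = dout * cache, grads = list())
    },
    batchnorm = {
      d <- cache$d
      dy <- if (length(d) == 3) matrix(dout, d[1] * d[2], d[3]) else dout
      N <- nrow(dy)
      dgamma <- colSums(dy * cache$xhat)
      dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, layer$params$gamma, "*")
      # standard batch-norm backward (batch statistics)
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dx <- sweep(t1 - t2, 2, cache$istd, "*")
      if (length(d) == 3) dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache
      list(dx = dx, grads = list())
    },
    dense = {
      dz <- switch(layer$activation,
                   selu = dout * selu_grad(cache$z),
                   linear = dout)
      list(dx = tcrossprod(dz, layer$params$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    }
  )
}

# ---- network ----------------------------------------------------------------

network_forward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  out <- X
  for (i in seq_along(net$layers)) {
    r <- forward_layer(net$layers[[i]], out, training)
    out <- r$out
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer   # batch-norm running stats
  }
  list(out = out, caches = caches, net = net)
}

network_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- backward_layer(net$layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  grads
}

# Loss on raw (linear) network output; returns loss value and dZ.
loss_and_grad <- function(z, y, loss) {
  B <- nrow(z)
  if (loss == "binary_crossentropy") {
    p <- sigmoid(z[, 1])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    value <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dz <- matrix((p - y) / B, B, 1)
    list(value = value, dz = dz, prob = p)
  } else if (loss == "categorical_crossentropy") {
    P <- softmax_rows(z)
    value <- -mean(log(pmax(rowSums(P * y), 1e-12)))
    list(value = value, dz = (P - y) / B, prob = P)
  } else stop("unknown loss", call. = FALSE)
}

# ---- optimizers -------------------------------------------------------------

# Apply f(param, grad, path) over the nested parameter lists of every layer.
map_params <- function(layers, grads, f) {
  walk <- function(p, g, path) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- walk(p[[nm]], g[[nm]], c(path, nm))
      p
    } else f(p, g, paste(path, collapse = "."))
  }
  for (i in seq_along(layers)) {
    if (length(layers[[i]]$params) == 0) next
    layers[[i]]$params <- walk(layers[[i]]$params, grads[[i]],
                               as.character(i))
  }
  layers
}

make_optimizer <- function(name, learning_rate = 1e-3) {
  name <- match.arg(name, c("rmsprop", "adam"))
  env <- new.env(parent = emptyenv())
  env$slots <- list()
  env$t <- 0
  list(name = name, lr = learning_rate, env = env)
}

optimizer_step <- function(opt, layers, grads) {
  env <- opt$env
  env$t <- env$t + 1
  lr <- opt$lr
  if (opt$name == "rmsprop") {
    rho <- 0.9; eps <- 1e-7
    map_params(layers, grads, function(p, g, key) {
      v <- env$slots[[key]]
      if (is.null(v)) v <- p * 0
      v <- rho * v + (1 - rho) * g * g
      env$slots[[key]] <- v
      p - lr * g / (sqrt(v) + eps)
    })
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; t <- env$t
    map_params(layers, grads, function(p, g, key) {
      m <- env$slots[[paste0(key, ".m")]]
      v <- env$slots[[paste0(key, ".v")]]
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      env$slots[[paste0(key, ".m")]] <- m
      env$slots[[paste0(key, ".v")]] <- v
      mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
      p - lr * mhat / (sqrt(vhat) + eps)
    })
  }
}
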