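# Native neural-network primitives: a reverse-mode tape plus the layer set
# needed by the counting network (conv, transposed conv, batch norm, ReLU,
# sigmoid, nearest-neighbour upsampling, element-wise add). Feature maps are
# 4-d arrays [C, H, W, N] (channel fastest); conv weights are
# [Cin, k, k, Cout] and transposed-conv weights [Cout, k, k, Cin], matching
# the GEMM layout of the compiled kernels.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$ops <- vector("list", 64L); t$n_ops <- 0L
  t$grads <- new.env(parent = emptyenv())
  t$next_id <- 0L
  t
}

tape_id <- function(tape) {
  tape$next_id <- tape$next_id + 1L
  tape$next_id
}

tape_record <- function(tape, out_id, fn) {
  n <- tape$n_ops + 1L
  if (n > length(tape$ops)) length(tape$ops) <- 2L * length(tape$ops)
  tape$ops[[n]] <- list(out = out_id, fn = fn)
  tape$n_ops <- n
}

acc_grad <- function(tape, id, g) {
  key <- as.character(id)
  cur <- tape$grads[[key]]
  tape$grads[[key]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

get_grad <- function(tape, id) tape$grads[[as.character(id)]]

# seed the output gradient and sweep the tape in reverse
tape_backward <- function(tape, out_id, g0) {
  rm(list = ls(tape$grads), envir = tape$grads)
  acc_grad(tape, out_id, g0)
  for (i in rev(seq_len(tape$n_ops))) {
    op <- tape$ops[[i]]
    g <- get_grad(tape, op$out)
    if (!is.null(g)) op$fn(g)
  }
  invisible(NULL)
}

# value node: the array plus its tape id (NULL id when not tracked)
vnode <- function(v, id = NULL) list(v = v, id = id)

# --- parameters ------------------------------------------------------------

make_param <- function(dim, sd = NULL, value = NULL) {
  p <- new.env(parent = emptyenv())
  p$w <- if (!is.null(value)) array(value, dim) else array(rnorm(prod(dim), sd = sd), dim)
  p$g <- array(0, dim)
  p$m <- NULL; p$v <- NULL   # Adam state, allocated lazily
  p
}

param_add_grad <- function(p, g) { p$g <- p$g + g; invisible(NULL) }

# fan-in scaled (He) initialisation for a conv weight [Cin, k, k, Cout]
he_conv_param <- function(cin, k, cout) {
  make_param(c(cin, k, k, cout), sd = sqrt(2 / (cin * k * k)))
}

# --- layers ----------------------------------------------------------------

mk_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = FALSE, w_sd = NULL) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$k <- k; l$s <- stride; l$p <- pad
  l$w <- if (is.null(w_sd)) he_conv_param(cin, k, cout) else
    make_param(c(cin, k, k, cout), sd = w_sd)
  l$b <- if (bias) make_param(cout, value = 0) else NULL
  l
}

# transposed conv; weight is the kernel of the adjoint conv cout -> cin
mk_deconv <- function(cin, cout, k, stride, pad) {
  l <- new.env(parent = emptyenv())
  l$type <- "deconv"; l$k <- k; l$s <- stride; l$p <- pad
  l$cin <- cin; l$cout <- cout
  l$w <- he_conv_param(cout, k, cin)
  l
}

mk_bn <- function(c) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$gamma <- make_param(c, value = 1)
  l$beta <- make_param(c, value = 0)
  l$rm <- rep(0, c); l$rv <- rep(1, c)   # running stats (not trainable)
  l$momentum <- 0.1; l$eps <- 1e-5
  l
}

layer_params <- function(l) {
  switch(l$type,
         conv = if (is.null(l$b)) list(l$w) else list(l$w, l$b),
         deconv = list(l$w),
         bn = list(l$gamma, l$beta))
}

op_conv <- function(tape, x, l) {
  y <- conv2d_forward(x$v, l$w$w, l$s, l$p)
  if (!is.null(l$b)) {
    co <- dim(y)[1]
    y <- y + as.vector(l$b$w)  # recycles over channel-fastest layout
  }
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x; H <- dim(x$v)[2]; W <- dim(x$v)[3]
  tape_record(tape, out$id, function(g) {
    param_add_grad(l$w, conv2d_backward_weight(xin$v, g, l$k, l$s, l$p))
    if (!is.null(l$b))
      param_add_grad(l$b, rowSums(matrix(g, nrow = dim(g)[1])))
    if (!is.null(xin$id))
      acc_grad(tape, xin$id, conv2d_backward_data(g, l$w$w, l$s, l$p, H, W))
  })
  out
}

op_deconv <- function(tape, x, l) {
  di <- dim(x$v)
  Ho <- (di[2] - 1L) * l$s + l$k - 2L * l$p
  Wo <- (di[3] - 1L) * l$s + l$k - 2L * l$p
  y <- conv2d_backward_data(x$v, l$w$w, l$s, l$p, Ho, Wo)
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x
  tape_record(tape, out$id, function(g) {
    # the underlying conv runs output -> input, so roles swap here
    param_add_grad(l$w, conv2d_backward_weight(g, xin$v, l$k, l$s, l$p))
    if (!is.null(xin$id))
      acc_grad(tape, xin$id, conv2d_forward(g, l$w$w, l$s, l$p))
  })
  out
}

op_bn <- function(tape, x, l, train = TRUE) {
  d <- dim(x$v); C <- d[1]; m <- prod(d[-1])
  if (train) {
    mo <- channel_moments(x$v, C)
    mu <- mo$mean; va <- mo$var
    if (m > 1) {
      l$rm <- (1 - l$momentum) * l$rm + l$momentum * mu
      l$rv <- (1 - l$momentum) * l$rv + l$momentum * va * m / (m - 1)
    }
  } else {
    mu <- l$rm; va <- l$rv
  }
  inv <- 1 / sqrt(va + l$eps)
  gam <- as.vector(l$gamma$w)
  # y = gamma * (x - mu) * inv + beta, fused as one channel-affine pass
  y <- channel_affine(x$v, gam * inv, as.vector(l$beta$w) - gam * inv * mu)
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x
  tape_record(tape, out$id, function(g) {
    xhat <- channel_affine(xin$v, inv, -mu * inv)
    cd <- channel_dots(g, xhat, C)
    param_add_grad(l$gamma, cd$dgamma)
    param_add_grad(l$beta, cd$dbeta)
    if (!is.null(xin$id)) {
      if (train) {
        # gx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) with
        # dxhat = gamma * g; the channel means follow from dgamma / dbeta
        gx <- channel_affine2(g, xhat,
                              inv * gam,
                              -inv * gam * cd$dgamma / m,
                              -inv * gam * cd$dbeta / m)
      } else {
        gx <- channel_affine(g, inv * gam, numeric(C))
      }
      acc_grad(tape, xin$id, gx)
    }
  })
  out
}

op_relu <- function(tape, x) {
  y <- relu_forward(x$v)
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x; yv <- y
  tape_record(tape, out$id, function(g) {
    if (!is.null(xin$id)) acc_grad(tape, xin$id, relu_backward(g, yv))
  })
  out
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x; yv <- y
  tape_record(tape, out$id, function(g) {
    if (!is.null(xin$id)) acc_grad(tape, xin$id, g * yv * (1 - yv))
  })
  out
}

op_add <- function(tape, a, b) {
  y <- a$v + b$v
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  ain <- a; bin <- b
  tape_record(tape, out$id, function(g) {
    if (!is.null(ain$id)) acc_grad(tape, ain$id, g)
    if (!is.null(bin$id)) acc_grad(tape, bin$id, g)
  })
  out
}

op_upsample2 <- function(tape, x) {
  d <- dim(x$v); H <- d[2]; W <- d[3]
  y <- x$v[, rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
  if (is.null(tape)) return(vnode(y))
  out <- vnode(y, tape_id(tape))
  xin <- x
  tape_record(tape, out$id, function(g) {
    if (!is.null(xin$id)) {
      o1 <- seq(1L, 2L * H, by = 2L); o2 <- o1 + 1L
      e1 <- seq(1L, 2L * W, by = 2L); e2 <- e1 + 1L
      gx <- g[, o1, e1, , drop = FALSE] + g[, o2, e1, , drop = FALSE] +
            g[, o1, e2, , drop = FALSE] + g[, o2, e2, , drop = FALSE]
      acc_grad(tape, xin$id, gx)
    }
  })
  out
}

# --- optimiser -------------------------------------------------------------

adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1L) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (p in params) {
    if (is.null(p$m)) { p$m <- array(0, dim(p$w)); p$v <- array(0, dim(p$w)) }
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$v <- beta2 * p$v + (1 - beta2) * p$g * p$g
    p$w <- p$w - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}
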