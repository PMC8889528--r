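# Internal minimal neural-network engine. Activations are arrays with dim
# (H, W, C, N) until flattened to a (features x N) matrix; convolution and
# max-pooling kernels are compiled (src/nn_ops.cpp), everything else is R.

L_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       params = NULL, frozen = FALSE)
}
L_relu <- function() list(type = "relu")
L_pool <- function(size, stride = size, pad = 0L) {
  list(type = "pool", size = as.integer(size), stride = as.integer(stride),
       pad = as.integer(pad))
}
L_bn <- function(c) list(type = "bn", c = c, params = NULL, frozen = FALSE)
L_flatten <- function() list(type = "flatten")
L_gap <- function() list(type = "gap")
L_dense <- function(din, dout) {
  list(type = "dense", din = din, dout = dout, params = NULL, frozen = FALSE)
}
# residual unit: out = relu(F(x) + S(x)); S is identity when shortcut = NULL
L_res <- function(f_layers, shortcut = NULL) {
  list(type = "res", f = f_layers, s = shortcut)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      sd <- sqrt(2 / (l$kh * l$kw * l$cin))
      l$params <- list(
        W = array(stats::rnorm(l$kh * l$kw * l$cin * l$cout, 0, sd),
                  dim = c(l$kh, l$kw, l$cin, l$cout)),
        b = numeric(l$cout))
    } else if (l$type == "dense") {
      sd <- sqrt(2 / l$din)
      l$params <- list(W = matrix(stats::rnorm(l$dout * l$din, 0, sd), l$dout, l$din),
                       b = numeric(l$dout))
    } else if (l$type == "bn") {
      l$params <- list(gamma = rep(1, l$c), beta = numeric(l$c))
      l$running_mean <- numeric(l$c)
      l$running_var <- rep(1, l$c)
    } else if (l$type == "res") {
      l$f <- nn_init(l$f)
      if (!is.null(l$s)) l$s <- nn_init(l$s)
    }
    layers[[i]] <- l
  }
  layers
}

# per-channel moments of a (H,W,C,N) array
channel_stats <- function(x) {
  d <- dim(x)
  x3 <- array(x, dim = c(d[1] * d[2], d[3], d[4]))
  mu <- vapply(seq_len(d[3]), function(c) mean(x3[, c, ]), 0)
  va <- vapply(seq_len(d[3]), function(c) mean((x3[, c, ] - mu[c])^2), 0)
  list(mu = mu, va = va)
}

bn_apply <- function(x, mu, va, gamma, beta) {
  d <- dim(x)
  sc <- gamma / sqrt(va + BN_EPS)
  sh <- beta - mu * sc
  x * array(rep(sc, each = d[1] * d[2]), dim = d) +
    array(rep(sh, each = d[1] * d[2]), dim = d)
}

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      caches[[i]] <- list(x = x)
      x <- nn_conv_forward(x, l$params$W, l$params$b, l$stride, l$pad)
    } else if (l$type == "relu") {
      x <- pmax(x, 0)
      caches[[i]] <- list(mask = x > 0)
    } else if (l$type == "pool") {
      xd <- dim(x)
      out <- nn_maxpool_forward(x, l$size, l$stride, l$pad)
      x <- out$y
      caches[[i]] <- list(idx = out$idx, xdim = xd)
    } else if (l$type == "bn") {
      st <- if (train) channel_stats(x) else
        list(mu = l$running_mean, va = l$running_var)
      caches[[i]] <- list(x = x, mu = st$mu, va = st$va)
      x <- bn_apply(x, st$mu, st$va, l$params$gamma, l$params$beta)
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      x <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
    } else if (l$type == "gap") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      x3 <- array(x, dim = c(d[1] * d[2], d[3], d[4]))
      x <- apply(x3, c(2, 3), mean)
      if (is.null(dim(x))) x <- matrix(x, nrow = d[3])
    } else if (l$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- l$params$W %*% x + l$params$b
    } else if (l$type == "res") {
      fw <- nn_forward(l$f, x, train)
      sv <- if (is.null(l$s)) list(out = x, caches = NULL) else
        nn_forward(l$s, x, train)
      pre <- fw$out + sv$out
      y <- pmax(pre, 0)
      caches[[i]] <- list(f = fw$caches, s = sv$caches, mask = pre > 0)
      x <- y
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# returns list(dx = ..., grads = list per layer); train-mode backward
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cc <- caches[[i]]
    if (l$type == "conv") {
      g <- nn_conv_backward(cc$x, l$params$W, dout, l$stride, l$pad)
      grads[[i]] <- list(W = g$dw, b = g$db)
      dout <- g$dx
    } else if (l$type == "relu") {
      dout <- dout * cc$mask
    } else if (l$type == "pool") {
      dout <- nn_maxpool_backward(cc$idx, dout, cc$xdim)
    } else if (l$type == "bn") {
      d <- dim(cc$x)
      m <- d[1] * d[2] * d[4]
      x3 <- array(cc$x, dim = c(d[1] * d[2], d[3], d[4]))
      dy3 <- array(dout, dim = c(d[1] * d[2], d[3], d[4]))
      dgamma <- numeric(d[3]); dbeta <- numeric(d[3])
      dx3 <- array(0, dim = dim(x3))
      for (c in seq_len(d[3])) {
        xh <- (x3[, c, ] - cc$mu[c]) / sqrt(cc$va[c] + BN_EPS)
        dy <- dy3[, c, ]
        dgamma[c] <- sum(dy * xh)
        dbeta[c] <- sum(dy)
        dxh <- dy * l$params$gamma[c]
        dx3[, c, ] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) /
          sqrt(cc$va[c] + BN_EPS)
      }
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dout <- array(dx3, dim = d)
    } else if (l$type == "flatten") {
      dout <- array(dout, dim = cc$xdim)
    } else if (l$type == "gap") {
      d <- cc$xdim
      dout <- array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    } else if (l$type == "dense") {
      grads[[i]] <- list(W = dout %*% t(cc$x), b = rowSums(dout))
      dout <- t(l$params$W) %*% dout
    } else if (l$type == "res") {
      dsum <- dout * cc$mask
      bf <- nn_backward(l$f, cc$f, dsum)
      if (is.null(l$s)) {
        ds <- dsum
        grads[[i]] <- list(f = bf$grads, s = NULL)
      } else {
        bs <- nn_backward(l$s, cc$s, dsum)
        ds <- bs$dx
        grads[[i]] <- list(f = bf$grads, s = bs$grads)
      }
      dout <- bf$dx + ds
    }
  }
  list(dx = dout, grads = grads)
}

# Adam step over (possibly nested) layers; frozen layers are skipped.
# Batch-norm running stats are refreshed here from the forward caches.
nn_adam_step <- function(layers, grads, caches, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "res") {
      sub <- nn_adam_step(l$f, grads[[i]]$f, caches[[i]]$f,
                          state[[i]]$f %||% list(), lr, t, beta1, beta2, eps)
      l$f <- sub$layers
      st <- list(f = sub$state)
      if (!is.null(l$s)) {
        sub2 <- nn_adam_step(l$s, grads[[i]]$s, caches[[i]]$s,
                             state[[i]]$s %||% list(), lr, t, beta1, beta2, eps)
        l$s <- sub2$layers
        st$s <- sub2$state
      }
      state[[i]] <- st
      layers[[i]] <- l
      next
    }
    if (is.null(l$params)) next
    if (l$type == "bn") {
      cc <- caches[[i]]
      l$running_mean <- (1 - BN_MOMENTUM) * l$running_mean + BN_MOMENTUM * cc$mu
      l$running_var <- (1 - BN_MOMENTUM) * l$running_var + BN_MOMENTUM * cc$va
    }
    if (!isTRUE(l$frozen) && !is.null(grads[[i]])) {
      st <- state[[i]] %||% list()
      for (nm in names(l$params)) {
        g <- grads[[i]][[nm]]
        m <- st[[nm]]$m %||% (g * 0)
        v <- st[[nm]]$v %||% (g * 0)
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        st[[nm]] <- list(m = m, v = v)
      }
      state[[i]] <- st
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_param_count <- function(layers) {
  n <- 0
  for (l in layers) {
    if (l$type == "res") {
      n <- n + nn_param_count(l$f)
      if (!is.null(l$s)) n <- n + nn_param_count(l$s)
    } else if (!is.null(l$params)) {
      n <- n + sum(vapply(l$params, length, 0L))
    }
  }
  n
}

nn_collect_params <- function(layers, path = "") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    id <- paste0(path, i)
    if (l$type == "res") {
      out <- c(out, nn_collect_params(l$f, paste0(id, "f.")))
      if (!is.null(l$s)) out <- c(out, nn_collect_params(l$s, paste0(id, "s.")))
    } else if (!is.null(l$params)) {
      for (nm in names(l$params)) out[[paste0(id, ".", nm)]] <- l$params[[nm]]
    }
  }
  out
}
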