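# Minimal CPU engine for the two architectures: stride-1 convolutions
# (same/valid padding) computed as nine shifted matrix products, 2x2
# max-pooling with floor semantics, inverted dropout, dense layers, ReLU,
# sigmoid output with binary cross-entropy, RMSprop updates. Activations are
# arrays (height, width, channels, batch).

init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gw_model_spec"))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  shape <- spec$input_shape
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    st <- ly
    if (ly$kind == "convolution") {
      cin <- shape[3]
      fan_in <- ly$kernel[1] * ly$kernel[2] * cin
      # He-scaled init for ReLU layers
      st$W <- array(stats::rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                    dim = c(ly$kernel[1], ly$kernel[2], cin, ly$filters))
      st$b <- numeric(ly$filters)
      shape <- if (ly$padding == "same") {
        c(shape[1], shape[2], ly$filters)
      } else {
        c(shape[1] - ly$kernel[1] + 1L, shape[2] - ly$kernel[2] + 1L,
          ly$filters)
      }
    } else if (ly$kind == "dense") {
      fan_in <- shape[1]
      sd <- if (identical(ly$activation, "relu")) sqrt(2 / fan_in)
            else sqrt(1 / fan_in)
      st$W <- matrix(stats::rnorm(fan_in * ly$units, sd = sd),
                     fan_in, ly$units)
      st$b <- numeric(ly$units)
      shape <- ly$units
    } else if (ly$kind == "maxpool") {
      shape <- c(shape[1] %/% ly$pool[1], shape[2] %/% ly$pool[2], shape[3])
    } else if (ly$kind == "flatten") {
      shape <- prod(shape)
    }
    layers[[i]] <- st
  }
  structure(list(spec = spec, layers = layers), class = "gw_network")
}

count_trainable <- function(net) {
  sum(vapply(net$layers, function(ly) {
    length(ly$W) + length(ly$b)
  }, numeric(1)))
}

pad_same <- function(x, kh, kw) {
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  out
}

# x: (H, W, C, N) -> list(out, cache) ; out: (H', W', F, N)
conv_forward <- function(x, ly) {
  kh <- ly$kernel[1]
  kw <- ly$kernel[2]
  xp <- if (ly$padding == "same") pad_same(x, kh, kw) else x
  d <- dim(xp)
  ho <- d[1] - kh + 1L
  wo <- d[2] - kw + 1L
  cin <- d[3]
  n <- d[4]
  f <- ly$filters
  acc <- matrix(0, ho * wo * n, f)
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      sl <- xp[di:(di + ho - 1L), dj:(dj + wo - 1L), , , drop = FALSE]
      m <- matrix(aperm(sl, c(1L, 2L, 4L, 3L)), ho * wo * n, cin)
      acc <- acc + m %*% matrix(ly$W[di, dj, , ], cin, f)
    }
  }
  acc <- sweep(acc, 2L, ly$b, `+`)
  pre <- aperm(array(acc, dim = c(ho, wo, n, f)), c(1L, 2L, 4L, 3L))
  out <- if (identical(ly$activation, "relu")) pmax(pre, 0) else pre
  list(out = out, cache = list(xp = xp, mask = out > 0, dims = d))
}

# dout: gradient wrt layer output. Returns list(dx, dW, db); dx is NULL when
# need_dx is FALSE (first layer).
conv_backward <- function(dout, ly, cache, need_dx = TRUE) {
  if (identical(ly$activation, "relu")) dout <- dout * cache$mask
  kh <- ly$kernel[1]
  kw <- ly$kernel[2]
  xp <- cache$xp
  d <- dim(xp)
  ho <- dim(dout)[1]
  wo <- dim(dout)[2]
  f <- ly$filters
  cin <- d[3]
  n <- d[4]
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ho * wo * n, f)
  dW <- array(0, dim = dim(ly$W))
  dxp <- if (need_dx) array(0, dim = d) else NULL
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      sl <- xp[di:(di + ho - 1L), dj:(dj + wo - 1L), , , drop = FALSE]
      m <- matrix(aperm(sl, c(1L, 2L, 4L, 3L)), ho * wo * n, cin)
      dW[di, dj, , ] <- crossprod(m, dmat)
      if (need_dx) {
        dsl <- dmat %*% t(matrix(ly$W[di, dj, , ], cin, f))
        dsl <- aperm(array(dsl, dim = c(ho, wo, n, cin)), c(1L, 2L, 4L, 3L))
        dxp[di:(di + ho - 1L), dj:(dj + wo - 1L), , ] <-
          dxp[di:(di + ho - 1L), dj:(dj + wo - 1L), , , drop = FALSE] + dsl
      }
    }
  }
  db <- colSums(dmat)
  dx <- NULL
  if (need_dx) {
    if (ly$padding == "same") {
      ph <- (kh - 1L) %/% 2L
      pw <- (kw - 1L) %/% 2L
      dx <- dxp[ph + seq_len(d[1] - 2L * ph), pw + seq_len(d[2] - 2L * pw), , ,
                drop = FALSE]
    } else {
      dx <- dxp
    }
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x, ly) {
  d <- dim(x)
  ho <- d[1] %/% ly$pool[1]
  wo <- d[2] %/% ly$pool[2]
  r1 <- seq.int(1L, 2L * ho, by = 2L)
  c1 <- seq.int(1L, 2L * wo, by = 2L)
  a <- x[r1, c1, , , drop = FALSE]
  b <- x[r1 + 1L, c1, , , drop = FALSE]
  cc <- x[r1, c1 + 1L, , , drop = FALSE]
  dd <- x[r1 + 1L, c1 + 1L, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  m1 <- a == out
  m2 <- (b == out) & !m1
  m3 <- (cc == out) & !m1 & !m2
  m4 <- (dd == out) & !m1 & !m2 & !m3
  list(out = out,
       cache = list(m = list(m1, m2, m3, m4), in_dim = d, r1 = r1, c1 = c1))
}

maxpool_backward <- function(dout, cache) {
  dx <- array(0, dim = cache$in_dim)
  r1 <- cache$r1
  c1 <- cache$c1
  m <- cache$m
  dx[r1, c1, , ] <- dout * m[[1]]
  dx[r1 + 1L, c1, , ] <- dout * m[[2]]
  dx[r1, c1 + 1L, , ] <- dout * m[[3]]
  dx[r1 + 1L, c1 + 1L, , ] <- dout * m[[4]]
  dx
}

# Full forward pass. training = TRUE applies inverted dropout (draws from
# the current RNG stream); caches are kept for backprop.
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  cur <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$kind == "convolution") {
      r <- conv_forward(cur, ly)
      cur <- r$out
      caches[[i]] <- r$cache
    } else if (ly$kind == "maxpool") {
      r <- maxpool_forward(cur, ly)
      cur <- r$out
      caches[[i]] <- r$cache
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- array(stats::runif(length(cur)) < keep, dim = dims_of(cur))
        cur <- cur * mask / keep
        caches[[i]] <- list(mask = mask, keep = keep)
      }
    } else if (ly$kind == "flatten") {
      d <- dim(cur)
      caches[[i]] <- list(in_dim = d)
      cur <- t(matrix(cur, prod(d[1:3]), d[4]))  # (N, features)
    } else if (ly$kind == "dense") {
      pre <- sweep(cur %*% ly$W, 2L, ly$b, `+`)
      out <- switch(ly$activation,
                    relu = pmax(pre, 0),
                    sigmoid = 1 / (1 + exp(-pre)),
                    pre)
      caches[[i]] <- list(x = cur, out = out)
      cur <- out
    }
  }
  list(out = cur, caches = caches)
}

dims_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Backward pass from the output-layer delta (dpre of the final sigmoid
# dense layer). Returns gradient list parallel to net$layers.
nn_backward <- function(net, caches, dpre_out) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  dcur <- dpre_out  # gradient wrt final dense pre-activation
  for (i in rev(seq_len(n_layers))) {
    ly <- net$layers[[i]]
    if (ly$kind == "dense") {
      cache <- caches[[i]]
      dpre <- if (i == n_layers) {
        dcur
      } else if (identical(ly$activation, "relu")) {
        dcur * (cache$out > 0)
      } else if (identical(ly$activation, "sigmoid")) {
        dcur * cache$out * (1 - cache$out)
      } else {
        dcur
      }
      grads[[i]] <- list(dW = crossprod(cache$x, dpre), db = colSums(dpre))
      dcur <- tcrossprod(dpre, ly$W)
    } else if (ly$kind == "flatten") {
      d <- caches[[i]]$in_dim
      dcur <- array(t(dcur), dim = d)
    } else if (ly$kind == "dropout") {
      cache <- caches[[i]]
      if (!is.null(cache)) dcur <- dcur * cache$mask / cache$keep
    } else if (ly$kind == "maxpool") {
      dcur <- maxpool_backward(dcur, caches[[i]])
    } else if (ly$kind == "convolution") {
      r <- conv_backward(dcur, ly, caches[[i]], need_dx = i > 1L)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dcur <- r$dx
    }
  }
  grads
}

rmsprop_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (is.null(ly$W)) NULL
    else list(W = array(0, dim = dims_of(ly$W)), b = numeric(length(ly$b)))
  })
}

rmsprop_update <- function(net, grads, state, lr, rho = 0.9, eps = 1e-7) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$W <- rho * st$W + (1 - rho) * g$dW^2
    st$b <- rho * st$b + (1 - rho) * g$db^2
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * g$dW / (sqrt(st$W) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * g$db / (sqrt(st$b) + eps)
    state[[i]] <- st
  }
  list(net = net, state = state)
}
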