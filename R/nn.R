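# Compact CNN engine backing the encoder and recognition units.
#
# A batch of feature maps is a "state": list(x, B, H, W, C) where x is a
# (B*H*W) x C matrix, rows ordered sample-major then row-major in space
# (row = (b*H + y)*W + x, 0-based).  After global average pooling the
# state collapses to H = W = 1 and x is B x C.  Layers are plain lists;
# nets are lists of layers.  Forward returns per-layer caches so the
# backward pass is exact; parameters are updated with Adam.

nn_conv <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(type = "conv", cin = cin, cout = cout,
       params = list(W = matrix(stats::rnorm(9 * cin * cout, sd = sd), 9 * cin, cout),
                     b = numeric(cout)))
}

nn_bn <- function(c, momentum = 0.25, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       buffers = list(rm = numeric(c), rv = rep(1, c)))
}

nn_lrelu <- function(slope = 0.01) list(type = "lrelu", slope = slope)
nn_pool <- function() list(type = "pool")
nn_sigmoid <- function() list(type = "sigmoid")
nn_gap <- function() list(type = "gap")

nn_linear <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(type = "linear", cin = cin, cout = cout,
       params = list(W = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
                     b = numeric(cout)))
}

# residual block: conv-BN-act-conv-BN + identity skip, activation after the add
nn_res <- function(c, slope = 0.01) {
  list(type = "res", slope = slope,
       layers = list(nn_conv(c, c), nn_bn(c), nn_lrelu(slope),
                     nn_conv(c, c), nn_bn(c)))
}

new_state <- function(x, B, H, W) list(x = x, B = B, H = H, W = W, C = ncol(x))

layer_forward <- function(layer, st, training) {
  switch(layer$type,
    conv = {
      cols <- cpp_im2col(st$x, st$B, st$H, st$W)
      y <- cols %*% layer$params$W
      y <- sweep(y, 2, layer$params$b, "+")
      list(layer = layer, st = new_state(y, st$B, st$H, st$W),
           cache = if (training) list(cols = cols, H = st$H, W = st$W, cin = layer$cin))
    },
    bn = {
      x <- st$x
      if (training) {
        m <- colMeans(x)
        xc <- sweep(x, 2, m, "-")
        v <- colMeans(xc * xc)
        invstd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2, invstd, "*")
        mom <- layer$momentum
        layer$buffers$rm <- (1 - mom) * layer$buffers$rm + mom * m
        layer$buffers$rv <- (1 - mom) * layer$buffers$rv + mom * v
        cache <- list(xhat = xhat, invstd = invstd)
      } else {
        invstd <- 1 / sqrt(layer$buffers$rv + layer$eps)
        xhat <- sweep(sweep(x, 2, layer$buffers$rm, "-"), 2, invstd, "*")
        cache <- NULL
      }
      y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
      list(layer = layer, st = new_state(y, st$B, st$H, st$W), cache = cache)
    },
    lrelu = {
      neg <- st$x < 0
      y <- st$x
      y[neg] <- y[neg] * layer$slope
      list(layer = layer, st = new_state(y, st$B, st$H, st$W),
           cache = if (training) list(neg = neg))
    },
    pool = {
      r <- cpp_maxpool(st$x, st$B, st$H, st$W)
      list(layer = layer, st = new_state(r$y, st$B, st$H %/% 2L, st$W %/% 2L),
           cache = if (training) list(idx = r$idx, nrow_in = nrow(st$x)))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-st$x))
      list(layer = layer, st = new_state(y, st$B, st$H, st$W),
           cache = if (training) list(y = y))
    },
    gap = {
      hw <- st$H * st$W
      grp <- rep(seq_len(st$B), each = hw)
      y <- rowsum(st$x, grp, reorder = TRUE) / hw
      list(layer = layer, st = new_state(y, st$B, 1L, 1L),
           cache = if (training) list(H = st$H, W = st$W))
    },
    linear = {
      y <- sweep(st$x %*% layer$params$W, 2, layer$params$b, "+")
      list(layer = layer, st = new_state(y, st$B, 1L, 1L),
           cache = if (training) list(x = st$x))
    },
    res = {
      x_in <- st$x
      sub_caches <- vector("list", length(layer$layers))
      cur <- st
      for (i in seq_along(layer$layers)) {
        r <- layer_forward(layer$layers[[i]], cur, training)
        layer$layers[[i]] <- r$layer
        sub_caches[i] <- list(r$cache)
        cur <- r$st
      }
      s <- cur$x + x_in
      neg <- s < 0
      y <- s
      y[neg] <- y[neg] * layer$slope
      list(layer = layer, st = new_state(y, st$B, st$H, st$W),
           cache = if (training) list(sub = sub_caches, neg = neg))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy, st_dims) {
  # st_dims: list(B, H, W) of the layer INPUT
  switch(layer$type,
    conv = {
      dW <- crossprod(cache$cols, dy)
      db <- colSums(dy)
      dcols <- dy %*% t(layer$params$W)
      dx <- cpp_col2im(dcols, st_dims$B, cache$H, cache$W, cache$cin)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      n <- nrow(dy)
      xhat <- cache$xhat
      dgamma <- colSums(dy * xhat)
      dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, layer$params$gamma, "*")
      t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
      t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
      dx <- sweep(t1 - t2, 2, cache$invstd, "*")
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      dx <- dy
      dx[cache$neg] <- dx[cache$neg] * layer$slope
      list(dx = dx, grads = NULL)
    },
    pool = {
      list(dx = cpp_maxpool_bw(dy, cache$idx, cache$nrow_in), grads = NULL)
    },
    sigmoid = {
      list(dx = dy * cache$y * (1 - cache$y), grads = NULL)
    },
    gap = {
      hw <- cache$H * cache$W
      dx <- dy[rep(seq_len(nrow(dy)), each = hw), , drop = FALSE] / hw
      list(dx = dx, grads = NULL)
    },
    linear = {
      list(dx = dy %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    res = {
      ds <- dy
      ds[cache$neg] <- ds[cache$neg] * layer$slope
      cur <- ds
      grads <- vector("list", length(layer$layers))
      dims <- st_dims
      for (i in rev(seq_along(layer$layers))) {
        r <- layer_backward(layer$layers[[i]], cache$sub[[i]], cur, dims)
        grads[i] <- list(r$grads)
        cur <- r$dx
      }
      list(dx = cur + ds, grads = list(sub = grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(net, st, training = FALSE) {
  caches <- vector("list", length(net))
  dims <- vector("list", length(net))
  for (i in seq_along(net)) {
    dims[[i]] <- list(B = st$B, H = st$H, W = st$W)
    r <- layer_forward(net[[i]], st, training)
    net[[i]] <- r$layer
    caches[i] <- list(r$cache)
    st <- r$st
  }
  list(net = net, st = st, caches = caches, dims = dims)
}

net_backward <- function(net, fwd, dy) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], fwd$caches[[i]], dy, fwd$dims[[i]])
    grads[i] <- list(r$grads)
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# ---- parameter bookkeeping / Adam ------------------------------------

zero_like_params <- function(layer) {
  if (layer$type == "res") return(list(sub = lapply(layer$layers, zero_like_params)))
  if (is.null(layer$params)) return(NULL)
  lapply(layer$params, function(p) p * 0)
}

adam_init <- function(net) {
  list(m = lapply(net, zero_like_params), v = lapply(net, zero_like_params), t = 0L)
}

.adam_layer <- function(layer, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.null(g)) return(list(layer = layer, m = m, v = v))
  if (layer$type == "res") {
    for (i in seq_along(layer$layers)) {
      r <- .adam_layer(layer$layers[[i]], g$sub[[i]], m$sub[[i]], v$sub[[i]],
                       lr_t, beta1, beta2, eps)
      layer$layers[[i]] <- r$layer
      m$sub[i] <- list(r$m)
      v$sub[i] <- list(r$v)
    }
    return(list(layer = layer, m = m, v = v))
  }
  for (nm in names(layer$params)) {
    gi <- g[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gi
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gi * gi
    layer$params[[nm]] <- layer$params[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + eps)
  }
  list(layer = layer, m = m, v = v)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (i in seq_along(net)) {
    r <- .adam_layer(net[[i]], grads[[i]], state$m[[i]], state$v[[i]],
                     lr_t, beta1, beta2, eps)
    net[[i]] <- r$layer
    state$m[i] <- list(r$m)
    state$v[i] <- list(r$v)
  }
  list(net = net, state = state)
}

# flat numeric vector of all parameters (for determinism / freeze checks)
net_param_vector <- function(net) {
  unlist(lapply(net, function(layer) {
    if (layer$type == "res") return(net_param_vector(layer$layers))
    if (is.null(layer$params)) return(numeric(0))
    unlist(layer$params, use.names = FALSE)
  }), use.names = FALSE)
}

net_n_params <- function(net) length(net_param_vector(net))

# accumulate two grad structures (a + b), used for loss-term mixing
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

scale_grads <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  g * s
}

grad_norm <- function(g) {
  if (is.null(g)) return(0)
  if (is.list(g)) return(sqrt(sum(vapply(g, function(x) grad_norm(x)^2,
                                         numeric(1)))))
  sqrt(sum(g * g))
}

# clip the global norm of a grad structure to `max_norm`
clip_grads <- function(g, max_norm) {
  n <- grad_norm(g)
  if (is.finite(max_norm) && n > max_norm) scale_grads(g, max_norm / n) else g
}

# ---- tensor <-> array helpers ----------------------------------------

# H x W x C array (or H x W matrix) -> single-sample state matrix
img_to_tensor <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  matrix(aperm(img, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

tensor_to_img <- function(x, H, W) {
  C <- ncol(x)
  arr <- aperm(array(x, c(W, H, C)), c(2, 1, 3))
  if (C == 1L) arr[, , 1] else arr
}

# stack a list of H x W x C arrays into one batch state
stack_tensors <- function(imgs) {
  d <- dim(imgs[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  x <- do.call(rbind, lapply(imgs, img_to_tensor))
  new_state(x, length(imgs), d[1], d[2])
}

# resize an H x W x C array (bilinear, per channel)
resize_img <- function(img, outH, outW) {
  if (is.matrix(img)) return(cpp_resize_bilinear(img, outH, outW))
  out <- array(0, c(outH, outW, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- cpp_resize_bilinear(img[, , c], outH, outW)
  }
  out
}

# evaluate code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
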