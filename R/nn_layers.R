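# Layer engine for the SE-SPP convolutional classifiers.
#
# Layers are mutable environments holding hyperparameters, parameters
# (`par`, named list of numeric arrays), gradients (`grad`, written by the
# backward pass), optimizer state (`vel`) and, for batch norm, running
# buffers (`buf`). Activations flow as (H, W, C, N) arrays until the SPP
# layer, which flattens to a features x batch matrix. Forward passes
# return `list(out, cache)`; backward passes consume the cache, store
# parameter gradients on the layer and return the input gradient.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- "nn_layer"
  l
}

he_init <- function(fan_in, n_out, k = 1L) {
  matrix(rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
}

ly_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  new_layer("conv", cin = cin, cout = cout, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            par = list(w = he_init(k * k * cin, cout)))
}

ly_bn <- function(c) {
  new_layer("bn", c = c, eps = 1e-5, momentum = 0.1,
            par = list(gamma = rep(1, c), beta = rep(0, c)),
            buf = list(rmean = rep(0, c), rvar = rep(1, c)))
}

ly_relu <- function() new_layer("relu")
ly_maxpool <- function(k, stride, pad = 0L)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
ly_avgpool <- function(k, stride = k)
  new_layer("avgpool", k = as.integer(k), stride = as.integer(stride))
ly_spp <- function(levels) new_layer("spp", levels = as.integer(levels))

ly_fc <- function(din, dout) {
  new_layer("fc", din = din, dout = dout,
            par = list(w = he_init(din, dout), b = rep(0, dout)))
}

ly_se <- function(c, reduction) {
  if (reduction > c) stop("SE reduction exceeds channel count")
  h <- max(1L, c %/% reduction)
  new_layer("se", c = c, hidden = h,
            par = list(w1 = he_init(c, h), b1 = rep(0, h),
                       w2 = he_init(h, c), b2 = rep(0, c)))
}

ly_seq <- function(...) new_layer("seq", layers = list(...))

# one composite layer of a dense block: BN-ReLU-(1x1 conv)-BN-ReLU-3x3 conv
dense_unit <- function(cin, growth, bottleneck) {
  if (bottleneck) {
    mid <- 4L * growth
    ly_seq(ly_bn(cin), ly_relu(), ly_conv(cin, mid, 1L),
           ly_bn(mid), ly_relu(), ly_conv(mid, growth, 3L))
  } else {
    ly_seq(ly_bn(cin), ly_relu(), ly_conv(cin, growth, 3L))
  }
}

ly_dense_block <- function(cin, n_layers, growth, bottleneck = TRUE) {
  units <- vector("list", n_layers)
  c <- cin
  for (k in seq_len(n_layers)) {
    units[[k]] <- dense_unit(c, growth, bottleneck)
    c <- c + growth
  }
  new_layer("dense_block", layers = units, cin = cin, growth = growth,
            cout = c)
}

ly_transition <- function(cin) {
  cout <- cin %/% 2L
  new_layer("transition", cout = cout,
            layers = list(ly_seq(ly_bn(cin), ly_relu(), ly_conv(cin, cout, 1L),
                                 ly_avgpool(2L))))
}

ly_resblock <- function(cin, cout, stride = 1L) {
  down <- if (stride != 1L || cin != cout)
    ly_seq(ly_conv(cin, cout, 1L, stride, 0L), ly_bn(cout)) else NULL
  new_layer("resblock", cin = cin, cout = cout,
            layers = list(main = ly_seq(ly_conv(cin, cout, 3L, stride),
                                        ly_bn(cout), ly_relu(),
                                        ly_conv(cout, cout, 3L), ly_bn(cout)),
                          down = down))
}

ly_fw <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      out <- conv2d_fw_cpp(x, l$par$w, l$k, l$k, l$stride, l$pad)
      list(out = out, cache = x)
    },
    bn = {
      d <- dim(x)
      if (training) {
        xm <- as_channel_mat(x)
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        l$buf$rmean <- (1 - l$momentum) * l$buf$rmean + l$momentum * mu
        l$buf$rvar <- (1 - l$momentum) * l$buf$rvar + l$momentum * va
      } else {
        mu <- l$buf$rmean; va <- l$buf$rvar
      }
      inv <- 1 / sqrt(va + l$eps)
      xhat <- (x - bc_channel(mu, d)) * bc_channel(inv, d)
      out <- xhat * bc_channel(l$par$gamma, d) + bc_channel(l$par$beta, d)
      dim(out) <- d
      list(out = out, cache = list(x = x, xhat = xhat, mu = mu, inv = inv,
                                   training = training))
    },
    relu = list(out = pmax(x, 0), cache = x > 0),
    maxpool = {
      r <- maxpool_fw_cpp(x, l$k, l$stride, l$pad)
      list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)))
    },
    avgpool = list(out = avgpool_fw_cpp(x, l$k, l$stride),
                   cache = dim(x)),
    spp = {
      r <- spp_fw_cpp(x, l$levels)
      list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)))
    },
    fc = list(out = crossprod(l$par$w, x) + l$par$b, cache = x),
    se = {
      d <- dim(x)
      s <- colMeans(matrix(x, nrow = d[1] * d[2]))      # (C*N) means
      s <- matrix(s, d[3], d[4])                        # C x N squeeze
      z1 <- crossprod(l$par$w1, s) + l$par$b1
      a1 <- pmax(z1, 0)
      g <- sigmoid(crossprod(l$par$w2, a1) + l$par$b2)  # C x N gates
      out <- x * bc_cn(g, d)
      dim(out) <- d
      list(out = out, cache = list(x = x, s = s, a1 = a1, g = g))
    },
    seq = {
      caches <- vector("list", length(l$layers))
      for (k in seq_along(l$layers)) {
        r <- ly_fw(l$layers[[k]], x, training)
        x <- r$out; caches[[k]] <- r$cache
      }
      list(out = x, cache = caches)
    },
    transition = ly_fw_seq1(l, x, training),
    dense_block = {
      caches <- vector("list", length(l$layers))
      for (k in seq_along(l$layers)) {
        r <- ly_fw(l$layers[[k]], x, training)
        caches[[k]] <- r$cache
        x <- cat_channels(x, r$out)
      }
      list(out = x, cache = caches)
    },
    resblock = {
      rm_ <- ly_fw(l$layers$main, x, training)
      if (!is.null(l$layers$down)) {
        rd <- ly_fw(l$layers$down, x, training)
        s <- rd$out; dcache <- rd$cache
      } else {
        s <- x; dcache <- NULL
      }
      pre <- rm_$out + s
      list(out = pmax(pre, 0),
           cache = list(main = rm_$cache, down = dcache, relu = pre > 0))
    },
    stop("unknown layer type: ", l$type)
  )
}

ly_fw_seq1 <- function(l, x, training) {
  r <- ly_fw(l$layers[[1]], x, training)
  list(out = r$out, cache = r$cache)
}

ly_bw <- function(l, cache, gout) {
  switch(l$type,
    conv = {
      r <- conv2d_bw_cpp(cache, l$par$w, gout, l$k, l$k, l$stride, l$pad)
      l$grad <- list(w = r$gw)
      r$gx
    },
    bn = {
      d <- dim(cache$x)
      m <- d[1] * d[2] * d[4]
      xc <- cache$x - bc_channel(cache$mu, d)
      gm <- as_channel_mat(gout)
      xhm <- as_channel_mat(cache$xhat)
      l$grad <- list(gamma = colSums(gm * xhm), beta = colSums(gm))
      if (!cache$training) {
        gx <- gout * bc_channel(l$par$gamma * cache$inv, d)
        dim(gx) <- d
        return(gx)
      }
      gxhat <- gout * bc_channel(l$par$gamma, d)
      gxhm <- as_channel_mat(gxhat)
      xcm <- as_channel_mat(xc)
      gvar <- colSums(gxhm * xcm) * (-0.5) * cache$inv^3
      gmu <- -colSums(gxhm) * cache$inv
      gx <- gxhat * bc_channel(cache$inv, d) +
        xc * bc_channel(2 * gvar / m, d) + bc_channel(gmu / m, d)
      dim(gx) <- d
      gx
    },
    relu = gout * cache,
    maxpool = maxpool_bw_cpp(cache$idx, cache$xdim, gout),
    avgpool = avgpool_bw_cpp(cache, gout, l$k, l$stride),
    spp = spp_bw_cpp(cache$idx, cache$xdim, gout),
    fc = {
      l$grad <- list(w = cache %*% t(gout), b = rowSums(gout))
      l$par$w %*% gout
    },
    se = {
      d <- dim(cache$x)
      hw <- d[1] * d[2]
      gx_direct <- gout * bc_cn(cache$g, d)
      gg <- matrix(colSums(matrix(gout * cache$x, nrow = hw)), d[3], d[4])
      gz2 <- gg * cache$g * (1 - cache$g)
      ga1 <- l$par$w2 %*% gz2
      gz1 <- ga1 * (cache$a1 > 0)
      gs <- l$par$w1 %*% gz1
      l$grad <- list(w1 = cache$s %*% t(gz1), b1 = rowSums(gz1),
                     w2 = cache$a1 %*% t(gz2), b2 = rowSums(gz2))
      gx <- gx_direct + bc_cn(gs / hw, d)
      dim(gx) <- d
      gx
    },
    seq = {
      for (k in rev(seq_along(l$layers)))
        gout <- ly_bw(l$layers[[k]], cache[[k]], gout)
      gout
    },
    transition = ly_bw(l$layers[[1]], cache, gout),
    dense_block = {
      g <- gout
      growth <- l$growth
      for (k in rev(seq_along(l$layers))) {
        ctot <- dim(g)[3]
        gk <- g[, , (ctot - growth + 1L):ctot, , drop = FALSE]
        grest <- g[, , seq_len(ctot - growth), , drop = FALSE]
        g <- grest + ly_bw(l$layers[[k]], cache[[k]], gk)
      }
      g
    },
    resblock = {
      gpre <- gout * cache$relu
      gx <- ly_bw(l$layers$main, cache$main, gpre)
      if (!is.null(l$layers$down)) {
        gx <- gx + ly_bw(l$layers$down, cache$down, gpre)
      } else {
        gx <- gx + gpre
      }
      gx
    },
    stop("unknown layer type: ", l$type)
  )
}

# depth-first walk over every parameterized layer
walk_layers <- function(l, f) {
  if (is.list(l)) {
    for (el in l) if (!is.null(el)) walk_layers(el, f)
    return(invisible())
  }
  if (!inherits(l, "nn_layer")) return(invisible())
  if (!is.null(l$par)) f(l)
  if (!is.null(l$layers)) walk_layers(l$layers, f)
  invisible()
}

# snapshot / restore parameters and batch-norm buffers
snapshot_params <- function(layers) {
  snap <- list()
  i <- 0L
  walk_layers(layers, function(l) {
    i <<- i + 1L
    snap[[i]] <<- list(par = l$par, buf = l$buf)
  })
  snap
}

restore_params <- function(layers, snap) {
  i <- 0L
  walk_layers(layers, function(l) {
    i <<- i + 1L
    l$par <- snap[[i]]$par
    if (!is.null(snap[[i]]$buf)) l$buf <- snap[[i]]$buf
  })
  invisible()
}

# SGD with momentum and decoupled-by-name weight decay (decay applied to
# weight matrices, not to biases or batch-norm affine parameters)
sgd_step <- function(layers, lr, momentum, weight_decay) {
  decayed <- c("w", "w1", "w2")
  walk_layers(layers, function(l) {
    if (is.null(l$grad)) return()
    if (is.null(l$vel)) l$vel <- lapply(l$par, function(p) p * 0)
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      if (is.null(g)) next
      if (nm %in% decayed) g <- g + weight_decay * l$par[[nm]]
      l$vel[[nm]] <- momentum * l$vel[[nm]] - lr * g
      l$par[[nm]] <- l$par[[nm]] + l$vel[[nm]]
    }
  })
  invisible()
}
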