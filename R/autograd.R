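# A small reverse-mode automatic differentiation tape for the volumetric
# network. Tensors are plain R arrays of dim (channels, nx, ny, nz); a node
# wraps a value with links to its parents and a backward closure that maps
# the output gradient to parent gradients. Convolutions run through the
# GEMM kernels in src/; everything elementwise is vectorised R.

ag_counter <- local({ i <- 0L; function() { i <<- i + 1L; as.character(i) } })

ag_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$id <- ag_counter()
  class(e) <- "ag_node"
  e
}

#' Wrap an array as an autograd leaf
#'
#' @param value numeric array (or scalar).
#' @return An `ag_node` leaf; gradients accumulate into `$grad` after
#'   [ag_backward()].
#' @keywords internal
ag_leaf <- function(value) ag_node(value)

# a leaf that never needs a gradient (e.g. the input chunk); ops may skip
# computing its input gradient
ag_const <- function(value) {
  n <- ag_node(value)
  n$is_const <- TRUE
  n
}

#' Run backpropagation from a scalar loss node
#'
#' Topologically sorts the tape below `root` and accumulates gradients into
#' every node's `$grad` (sum over all paths).
#'
#' @param root the scalar output node.
#' @return `root`, invisibly.
#' @keywords internal
ag_backward <- function(root) {
  order <- vector("list", 256L); n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    if (top$stage == 1L) {
      if (!is.null(seen[[nd$id]])) next
      seen[[nd$id]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (is.null(seen[[p$id]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  root$grad <- if (is.null(dim(root$value))) rep(1, length(root$value))
               else array(1, dim(root$value))
  for (i in seq(n_ord, 1L)) {
    nd <- order[[i]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- tensor ops -----------------------------------------------------------

# 3D convolution: x (ic, s, s, s), w matrix (oc x ic*k^3), b vector (oc)
ag_conv3d <- function(x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  dims <- dim(x$value)
  out <- cpp_conv3d_forward(x$value, dims, w$value, b$value,
                            k, stride, pad)
  need_dx <- !isTRUE(x$is_const)
  ag_node(out, list(x, w, b), function(g) {
    bw <- cpp_conv3d_backward(x$value, dims, w$value,
                              g, k, stride, pad,
                              as.integer(need_dx))
    list(if (need_dx) bw$dx else NULL, bw$dw, as.numeric(bw$db))
  })
}

# transposed convolution, kernel = stride = k: x (ic, s,s,s) -> (oc, ks,ks,ks)
ag_tconv3d <- function(x, w, b, k = 2L) {
  dims <- dim(x$value)
  out <- cpp_tconv3d_forward(x$value, dims, w$value, b$value, k)
  ag_node(out, list(x, w, b), function(g) {
    bw <- cpp_tconv3d_backward(x$value, dims, w$value, g, k)
    list(bw$dx, bw$dw, as.numeric(bw$db))
  })
}

# Instance normalisation with learnable per-channel scale/shift. For a batch
# of one chunk (the training regime here) batch norm computes the same
# statistics, so both config options share this implementation.
ag_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[1]; V <- prod(d[-1])
  xm <- matrix(x$value, C, V)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu * mu
  sd_ <- sqrt(va + eps)
  xhat <- (xm - mu) / sd_
  y <- xhat * gamma$value + beta$value
  dim(y) <- d
  ag_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, C, V)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gamma$value
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

ACTIVATIONS <- c("leaky_relu", "relu", "prelu", "gelu", "silu", "mish")

# fixed (non-learnable) elementwise activations
ag_activation <- function(x, kind, slope = 0.025) {
  v <- x$value
  res <- switch(kind,
    relu = list(y = pmax(v, 0), d = (v > 0) * 1),
    leaky_relu = {
      pos <- v > 0
      list(y = v * (pos + slope * !pos), d = pos + slope * !pos)
    },
    gelu = {
      ph <- stats::pnorm(v)
      list(y = v * ph, d = ph + v * stats::dnorm(v))
    },
    silu = {
      s <- 1 / (1 + exp(-v))
      list(y = v * s, d = s * (1 + v * (1 - s)))
    },
    mish = {
      sp <- log1p(exp(pmin(v, 20))) + pmax(v - 20, 0)  # stable softplus
      th <- tanh(sp)
      s <- 1 / (1 + exp(-v))
      list(y = v * th, d = th + v * (1 - th^2) * s)
    },
    stop("unknown activation '", kind, "'")
  )
  y <- res$y; dim(y) <- dim(v)
  ag_node(y, list(x), function(g) list(g * res$d))
}

# PReLU with learnable per-channel negative slope
ag_prelu <- function(x, a) {
  d <- dim(x$value)
  C <- d[1]; V <- prod(d[-1])
  xm <- matrix(x$value, C, V)
  pos <- xm > 0
  y <- ifelse(pos, xm, a$value * xm)
  ag_node(array(y, d), list(x, a), function(g) {
    gm <- matrix(g, C, V)
    dx <- ifelse(pos, gm, a$value * gm)
    da <- rowSums(gm * ifelse(pos, 0, xm))
    list(array(dx, d), da)
  })
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  dim(s) <- dim(x$value)
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(x, y) {
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

# concatenate along the channel axis
ag_concat <- function(x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  out <- array(0, c(dx[1] + dy[1], dx[2:4]))
  out[seq_len(dx[1]), , , ] <- x$value
  out[dx[1] + seq_len(dy[1]), , , ] <- y$value
  ag_node(out, list(x, y), function(g) {
    list(array(g[seq_len(dx[1]), , , ], dx),
         array(g[dx[1] + seq_len(dy[1]), , , ], dy))
  })
}

# multiply a (C, s, s, s) tensor by a single-channel gate, broadcast over C
ag_gate_mul <- function(x, gate) {
  d <- dim(x$value)
  C <- d[1]; V <- prod(d[-1])
  xm <- matrix(x$value, C, V)
  gv <- rep(as.numeric(gate$value), each = C)
  y <- x$value * gv
  ag_node(y, list(x, gate), function(g) {
    dx <- g * gv
    dgate <- colSums(matrix(g * x$value, C, V))
    dim(dgate) <- dim(gate$value)
    list(dx, dgate)
  })
}

# nearest-neighbour upsampling by integer factor f on the spatial axes
ag_upsample_nn <- function(x, f = 2L) {
  d <- dim(x$value)
  ix <- rep(seq_len(d[2]), each = f)
  iy <- rep(seq_len(d[3]), each = f)
  iz <- rep(seq_len(d[4]), each = f)
  y <- x$value[, ix, iy, iz, drop = FALSE]
  ag_node(y, list(x), function(g) {
    # adjoint: sum gradient over each f^3 block
    gg <- array(g, c(d[1], f, d[2], f, d[3], f, d[4]))
    gg <- aperm(gg, c(1, 3, 5, 7, 2, 4, 6))
    list(array(rowSums(gg, dims = 4), d))
  })
}

# ---- scalar loss terminals ------------------------------------------------

# binary cross-entropy between probabilities and a binary target, voxel mean
ag_bce <- function(pred, target, clamp = 1e-7) {
  p <- pmin(pmax(pred$value, clamp), 1 - clamp)
  t <- as.numeric(target)
  n <- length(p)
  loss <- -mean(t * log(p) + (1 - t) * log(1 - p))
  inside <- (pred$value > clamp) & (pred$value < 1 - clamp)
  ag_node(loss, list(pred), function(g) {
    dp <- (-t / p + (1 - t) / (1 - p)) / n
    dp[!inside] <- 0
    list(array(g * dp, dim(pred$value)))
  })
}

# soft Dice family. variant: "dice" (linear denominator), "squared"
# (squared-sum denominator), "log_cosh" (log cosh of the linear Dice loss)
ag_dice <- function(pred, target, eps = 1e-5, variant = "dice") {
  p <- as.numeric(pred$value)
  t <- as.numeric(target)
  num <- 2 * sum(p * t) + eps
  if (variant == "squared") {
    den <- sum(p * p) + sum(t * t) + eps
    loss <- 1 - num / den
    ag_node(loss, list(pred), function(g) {
      dp <- (2 * num * p - 2 * t * den) / den^2
      list(array(g * dp, dim(pred$value)))
    })
  } else {
    den <- sum(p) + sum(t) + eps
    ld <- 1 - num / den
    dp_lin <- function() (num - 2 * t * den) / den^2
    if (variant == "log_cosh") {
      loss <- log(cosh(ld))
      ag_node(loss, list(pred), function(g) {
        list(array(g * tanh(ld) * dp_lin(), dim(pred$value)))
      })
    } else {
      ag_node(ld, list(pred), function(g) {
        list(array(g * dp_lin(), dim(pred$value)))
      })
    }
  }
}

# mean squared error over all channels and voxels
ag_mse <- function(pred, target) {
  d <- pred$value - target
  n <- length(d)
  ag_node(mean(d * d), list(pred), function(g) {
    list(array(g * 2 * d / n, dim(pred$value)))
  })
}

# weighted sum of scalar nodes
ag_wsum <- function(nodes, weights = rep(1, length(nodes))) {
  val <- sum(vapply(nodes, function(n) n$value, numeric(1)) * weights)
  ag_node(val, nodes, function(g) as.list(g * weights))
}
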