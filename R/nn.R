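# 1D convolutional network primitives.
#
# The generator and discriminator are represented as plain lists of layers,
# each carrying its weights in a matricized layout so that forward and
# backward passes reduce to BLAS matrix products:
#   dense:  W (n_out x n_in)
#   conv:   W (C_out x (C_in * k)), column index c + (j - 1) * C_in for
#           input channel c and kernel tap j (im2col pairing)
#   tconv:  W ((C_out * k) x C_in), row index c_out + (j - 1) * C_out
#   flatten_dense: W (1 x (C * L))
# Activations store their elementwise derivative ("mask") for backprop.
# All activations are evaluated one sample at a time; batches are small.

# gather sliding windows of a padded C x Lp matrix into a (C*k) x Lout matrix
im2col <- function(Xp, k, stride, Lout) {
  starts <- (seq_len(Lout) - 1L) * stride
  idx <- outer(seq_len(k), starts, `+`)
  Xc <- Xp[, as.vector(idx), drop = FALSE]
  dim(Xc) <- c(nrow(Xp) * k, Lout)
  Xc
}

# adjoint of im2col: scatter-add windows back onto the padded input
col2im <- function(dXc, cin, k, stride, Lout, Lp) {
  dXp <- matrix(0, cin, Lp)
  dim(dXc) <- c(cin, k, Lout)
  starts <- (seq_len(Lout) - 1L) * stride
  for (j in seq_len(k)) {
    cols <- starts + j
    dXp[, cols] <- dXp[, cols] + dXc[, j, ]
  }
  dXp
}

conv_pads <- function(Lin, k, stride) {
  Lout <- as.integer(ceiling(Lin / stride))
  total <- max(0L, (Lout - 1L) * stride + k - Lin)
  c(left = total %/% 2L, right = total - total %/% 2L, Lout = Lout)
}

act_apply <- function(S, act, slope = 0.2) {
  switch(act,
    identity = list(h = S, mask = 1),
    relu = {
      m <- (S > 0) * 1
      list(h = S * m, mask = m)
    },
    lrelu = {
      m <- ifelse(S > 0, 1, slope)
      list(h = S * m, mask = m)
    },
    tanh = {
      h <- tanh(S)
      list(h = h, mask = 1 - h^2)
    },
    stop("unknown activation: ", act)
  )
}

reflect_idx <- function(pos, L) {
  pos[pos < 1L] <- 2L - pos[pos < 1L]
  pos[pos > L] <- 2L * L - pos[pos > L]
  pos
}

#' Phase shuffle of a feature-map stack
#'
#' Shifts each feature map independently in time by an integer drawn uniformly
#' from `[-n, n]`, with reflection padding at the edges and unchanged length.
#' Used as a training regularizer in the discriminator to suppress the
#' periodic artifacts of transpose convolutions; it is disabled at probe time.
#'
#' @param maps A numeric matrix (maps in rows) or a `feature_map_stack`.
#' @param n Maximum absolute shift in samples (`n = 0` is the identity).
#' @return Object of the same type with shifted maps; the drawn shifts are
#'   attached as attribute `"shifts"`.
#' @export
phase_shuffle <- function(maps, n) {
  if (n < 0) stop("phase_shuffle: n must be >= 0")
  stack <- inherits(maps, "feature_map_stack")
  M <- if (stack) maps$maps else maps
  if (!is.matrix(M)) M <- matrix(M, nrow = 1)
  n <- as.integer(n)
  shifts <- if (n == 0) rep(0L, nrow(M)) else
    sample(seq(-n, n), nrow(M), replace = TRUE)
  out <- ps_forward(M, shifts)
  if (stack) {
    maps$maps <- out
    attr(maps, "shifts") <- shifts
    maps
  } else {
    attr(out, "shifts") <- shifts
    out
  }
}

ps_forward <- function(M, shifts) {
  L <- ncol(M)
  out <- M
  for (i in which(shifts != 0L)) {
    out[i, ] <- M[i, reflect_idx(seq_len(L) - shifts[i], L)]
  }
  out
}

# adjoint of ps_forward: scatter gradients back through the (possibly
# duplicating) reflection gather
ps_backward <- function(G, shifts) {
  L <- ncol(G)
  out <- G
  for (i in which(shifts != 0L)) {
    idx <- reflect_idx(seq_len(L) - shifts[i], L)
    acc <- numeric(L)
    sums <- rowsum(G[i, ], idx)
    acc[as.integer(rownames(sums))] <- sums
    out[i, ] <- acc
  }
  out
}

# ---- single-layer forward passes (returning caches for backprop) ----

layer_forward <- function(layer, x, train = FALSE) {
  type <- layer$type
  if (type == "dense") {
    S <- as.vector(layer$W %*% x + layer$b)
    a <- act_apply(S, layer$act, layer$slope %||% 0.2)
    h <- a$h
    if (!is.null(layer$out_shape)) h <- matrix(h, layer$out_shape[1], layer$out_shape[2])
    return(list(out = h, cache = list(x = x, mask = a$mask)))
  }
  if (type == "conv") {
    k <- layer$k; s <- layer$stride
    Lin <- ncol(x)
    p <- conv_pads(Lin, k, s)
    Xp <- cbind(matrix(0, nrow(x), p[["left"]]), x,
                matrix(0, nrow(x), p[["right"]]))
    Xc <- im2col(Xp, k, s, p[["Lout"]])
    S <- layer$W %*% Xc + layer$b
    a <- act_apply(S, layer$act, layer$slope %||% 0.2)
    h <- a$h
    shifts <- NULL
    if (train && (layer$ps_n %||% 0L) > 0L) {
      shifts <- sample(seq(-layer$ps_n, layer$ps_n), nrow(h), replace = TRUE)
      h <- ps_forward(h, shifts)
    }
    return(list(out = h,
                cache = list(Xc = Xc, mask = a$mask, shifts = shifts,
                             Lin = Lin, pads = p, post = a$h)))
  }
  if (type == "tconv") {
    k <- layer$k; s <- layer$stride
    Lin <- ncol(x); cout <- layer$cout
    Yc <- layer$W %*% x                      # (cout*k) x Lin
    Lf <- (Lin - 1L) * s + k
    out_len <- Lin * s
    crop <- if (identical(layer$pad, "causal")) 0L else (k - s) %/% 2L
    Yfull <- matrix(0, cout, max(Lf, crop + out_len))
    dim(Yc) <- c(cout, k, Lin)
    starts <- (seq_len(Lin) - 1L) * s
    for (j in seq_len(k)) {
      cols <- starts + j
      Yfull[, cols] <- Yfull[, cols] + Yc[, j, ]
    }
    S <- Yfull[, crop + seq_len(out_len), drop = FALSE] + layer$b
    a <- act_apply(S, layer$act, layer$slope %||% 0.2)
    return(list(out = a$h,
                cache = list(x = x, mask = a$mask, Lin = Lin, Lf = Lf,
                             crop = crop, out_len = out_len)))
  }
  if (type == "flatten_dense") {
    v <- as.vector(x)
    S <- as.vector(layer$W %*% v + layer$b)
    return(list(out = S, cache = list(v = v, shape = dim(x), mask = 1)))
  }
  stop("unknown layer type: ", type)
}

# Backward through one layer. `g` is the gradient w.r.t. the layer output
# (post-activation, post-phase-shuffle). Returns the pre-activation adjoint
# `a`, parameter gradients, and the gradient w.r.t. the layer input.
layer_backward <- function(layer, cache, g, need_input = TRUE) {
  type <- layer$type
  if (type == "dense") {
    a <- as.vector(g) * cache$mask
    dW <- a %o% as.vector(cache$x)
    db <- a
    dx <- if (need_input) as.vector(crossprod(layer$W, a)) else NULL
    return(list(a = a, dW = dW, db = db, dx = dx))
  }
  if (type == "conv") {
    if (!is.null(cache$shifts)) g <- ps_backward(g, cache$shifts)
    a <- g * cache$mask
    dW <- a %*% t(cache$Xc)
    db <- rowSums(a)
    dx <- NULL
    if (need_input) {
      dXc <- crossprod(layer$W, a)
      p <- cache$pads
      Lp <- cache$Lin + p[["left"]] + p[["right"]]
      dXp <- col2im(dXc, layer$cin, layer$k, layer$stride, p[["Lout"]], Lp)
      dx <- dXp[, p[["left"]] + seq_len(cache$Lin), drop = FALSE]
    }
    return(list(a = a, dW = dW, db = db, dx = dx))
  }
  if (type == "tconv") {
    a <- g * cache$mask
    k <- layer$k; s <- layer$stride; cout <- layer$cout
    db <- rowSums(a)
    width <- max(cache$Lf, cache$crop + cache$out_len)
    dYfull <- matrix(0, cout, width)
    dYfull[, cache$crop + seq_len(cache$out_len)] <- a
    starts <- (seq_len(cache$Lin) - 1L) * s
    dYc <- matrix(0, cout * k, cache$Lin)
    for (j in seq_len(k)) {
      dYc[(j - 1L) * cout + seq_len(cout), ] <- dYfull[, starts + j]
    }
    dW <- dYc %*% t(cache$x)
    dx <- if (need_input) crossprod(layer$W, dYc) else NULL
    return(list(a = a, a_scatter = dYc, dW = dW, db = db, dx = dx))
  }
  if (type == "flatten_dense") {
    a <- as.vector(g)
    dW <- matrix(a * cache$v, 1)
    db <- a
    dx <- if (need_input) matrix(a * as.vector(layer$W),
                                 cache$shape[1], cache$shape[2]) else NULL
    return(list(a = a, dW = dW, db = db, dx = dx))
  }
  stop("unknown layer type: ", type)
}

# Linearized (tangent) forward through one layer: same linear maps, masks and
# shuffle shifts taken from the cache, biases omitted. Used for the
# double-backward pass of the gradient penalty. Returns the tangent output and
# the input-side factor that pairs with the pre-activation adjoint to give the
# penalty's weight gradient.
layer_tangent <- function(layer, cache, t_in) {
  type <- layer$type
  if (type == "dense") {
    tS <- as.vector(layer$W %*% t_in) * cache$mask
    if (!is.null(layer$out_shape)) {
      tS <- matrix(tS, layer$out_shape[1], layer$out_shape[2])
    }
    return(list(out = tS, pair = as.vector(t_in)))
  }
  if (type == "conv") {
    p <- cache$pads
    Tp <- cbind(matrix(0, nrow(t_in), p[["left"]]), t_in,
                matrix(0, nrow(t_in), p[["right"]]))
    Tc <- im2col(Tp, layer$k, layer$stride, p[["Lout"]])
    tS <- (layer$W %*% Tc) * cache$mask
    if (!is.null(cache$shifts)) tS <- ps_forward(tS, cache$shifts)
    return(list(out = tS, pair = Tc))
  }
  if (type == "flatten_dense") {
    return(list(out = as.vector(layer$W %*% as.vector(t_in)),
                pair = as.vector(t_in)))
  }
  stop("tangent pass not needed for layer type: ", type)
}
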