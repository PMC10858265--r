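# Internal numerical core of the shape-layer network.
#
# A model is a width-1 convolutional "self" layer (channels -> filter_size)
# followed by L stacked shape layers over the double-linked node chain.
# One shape layer, for every node i with neighbours i-1 and i+1 (caps
# self-link at the boundaries):
#
#   lam = W1 X_{i-1} + W2 X_{i+1} + b1          (gate coefficients)
#   alp = W3 X_{i-1} + W4 X_{i+1} + b2          (additive term)
#   u   = batchnorm(relu(lam * X_i + alp))      (elementwise gating)
#   X~_i = GRUCell(input = u, state = X_i)
#
# with GRU convention z = sigmoid(Wz u + Uz h + bz), r = sigmoid(Wr u +
# Ur h + br), n = tanh(Wn u + Un (r*h) + bn), h' = (1-z)*h + z*n.
# Each layer has a scalar output head per node: y = tanh(rowMeans(X~)),
# applied after dropout during training.
#
# For speed the per-layer trainables are stored as three stacked matrices
# (the algebra is unchanged, just fused into fewer matrix products):
#   W_la ((2F+1) x 2F): rows = [from-prev; from-next; bias],
#                       cols = [lambda block (W1,W2,b1); alpha block (W3,W4,b2)]
#   W_zr ((2F+1) x 2F): rows = [from-u; from-state; bias], cols = [z; r]
#   W_n  ((2F+1) x  F): rows = [from-u; from-r*state; bias]
# plus batchnorm gamma/beta. The self layer is W_s ((C+1) x F) with a bias
# row. sn_unpack_params() recovers the named algebraic views.

cmul <- function(m, v) m * rep(v, each = nrow(m))   # column-wise scale
cadd <- function(m, v) m + rep(v, each = nrow(m))   # column-wise shift
sigm <- function(x) 1 / (1 + exp(-x))

sn_init_params <- function(n_channels, config) {
  f <- config$filter_size
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc,
                                                 sd = sqrt(2 / (nr + nc))),
                                    nr, nc)
  # blocks drawn at the granularity of the algebraic weights, then fused
  stack2 <- function() rbind(cbind(glorot(f, f), glorot(f, f)),
                             cbind(glorot(f, f), glorot(f, f)),
                             matrix(0, 1L, 2L * f))
  layer <- function() list(
    W_la = stack2(),
    gamma = rep(1, f), beta = numeric(f),
    W_zr = stack2(),
    W_n = rbind(glorot(f, f), glorot(f, f), matrix(0, 1L, f)))
  list(W_s = rbind(glorot(n_channels, f), matrix(0, 1L, f)),
       layers = lapply(seq_len(config$n_shape_layers), function(i) layer()))
}

# Named algebraic views of the fused parameter matrices.
sn_unpack_params <- function(params, f) {
  upl <- function(pl) {
    i1 <- seq_len(f); i2 <- f + i1
    list(omega1 = pl$W_la[i1, i1], omega2 = pl$W_la[i2, i1],
         B1 = pl$W_la[2L * f + 1L, i1],
         theta1 = pl$W_la[i1, i2], theta2 = pl$W_la[i2, i2],
         B2 = pl$W_la[2L * f + 1L, i2],
         bn_gamma = pl$gamma, bn_beta = pl$beta,
         Wz = pl$W_zr[i1, i1], Uz = pl$W_zr[i2, i1],
         bz = pl$W_zr[2L * f + 1L, i1],
         Wr = pl$W_zr[i1, i2], Ur = pl$W_zr[i2, i2],
         br = pl$W_zr[2L * f + 1L, i2],
         Wn = pl$W_n[i1, ], Un = pl$W_n[i2, ],
         bn = pl$W_n[2L * f + 1L, ])
  }
  list(self_W = params$W_s[-nrow(params$W_s), , drop = FALSE],
       self_b = params$W_s[nrow(params$W_s), ],
       layers = lapply(params$layers, upl))
}

sn_init_bn <- function(config) {
  f <- config$filter_size
  lapply(seq_len(config$n_shape_layers), function(i)
    list(mean = numeric(f), var = rep(1, f)))
}

# Forward pass over one batch of concatenated chains.
#   E1      : nodes x (channels+1) encoding matrix with a trailing 1 column
#   iprev/inext : neighbour index vectors (caps self-link)
#   training: batch-statistic batchnorm + dropout on the head branch
# Returns list(Y = nodes x L head outputs, cache, bn_run).
sn_forward <- function(params, E1, iprev, inext, bn_run, config,
                       training = FALSE, keep_cache = FALSE) {
  L <- length(params$layers)
  f <- config$filter_size
  i1 <- seq_len(f); i2 <- f + i1
  eps <- config$bn_eps
  p_drop <- if (training) config$dropout_ratio else 0
  H <- E1 %*% params$W_s
  N <- nrow(H)
  ones <- rep(1, N)
  Y <- matrix(0, N, L)
  Mall <- if (p_drop > 0)
    matrix((stats::runif(N * f * L) >= p_drop) / (1 - p_drop), N)
  cache <- if (keep_cache) vector("list", L)

  for (l in seq_len(L)) {
    pl <- params$layers[[l]]
    PN1 <- cbind(H[iprev, , drop = FALSE], H[inext, , drop = FALSE], ones)
    LA <- PN1 %*% pl$W_la
    lam <- LA[, i1, drop = FALSE]
    s <- lam * H + LA[, i2, drop = FALSE]
    r0 <- pmax(s, 0)

    if (training) {
      mu <- colMeans(r0)
      ctr <- cadd(r0, -mu)
      va <- colMeans(ctr * ctr)
      mom <- config$bn_momentum
      bn_run[[l]]$mean <- (1 - mom) * bn_run[[l]]$mean + mom * mu
      bn_run[[l]]$var  <- (1 - mom) * bn_run[[l]]$var  + mom * va
    } else {
      mu <- bn_run[[l]]$mean
      va <- bn_run[[l]]$var
      ctr <- cadd(r0, -mu)
    }
    isd <- 1 / sqrt(va + eps)
    xhat <- cmul(ctr, isd)
    u <- cadd(cmul(xhat, pl$gamma), pl$beta)

    UH1 <- cbind(u, H, ones)
    ZR <- sigm(UH1 %*% pl$W_zr)
    z <- ZR[, i1, drop = FALSE]
    r <- ZR[, i2, drop = FALSE]
    rH <- r * H
    UR1 <- cbind(u, rH, ones)
    hh <- tanh(UR1 %*% pl$W_n)
    Hout <- H + z * (hh - H)

    if (p_drop > 0) {
      M <- Mall[, (l - 1L) * f + i1, drop = FALSE]
      Y[, l] <- tanh(rowMeans(Hout * M))
    } else {
      M <- NULL
      Y[, l] <- tanh(rowMeans(Hout))
    }

    if (keep_cache)
      cache[[l]] <- list(Hin = H, PN1 = PN1, lam = lam, s = s,
                         xhat = xhat, isd = isd, UH1 = UH1, z = z, r = r,
                         UR1 = UR1, hh = hh, M = M, y = Y[, l],
                         training = training)
    H <- Hout
  }
  list(Y = Y, cache = cache, bn_run = bn_run)
}

sn_zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# Backprop. dY is the nodes x L gradient of the loss w.r.t. the head
# outputs. Returns gradients with the same structure as `params`.
sn_backward <- function(params, E1, iprev, inext, cache, dY, config) {
  L <- length(params$layers)
  f <- config$filter_size
  i1 <- seq_len(f); i2 <- f + i1
  N <- nrow(E1)
  grads <- list(W_s = NULL, layers = vector("list", L))
  dH <- matrix(0, N, f)   # gradient flowing into the layer-(l+1) input

  scatter_add <- function(target, rows, values) {
    sm <- rowsum(values, rows)
    idx <- as.integer(rownames(sm))
    target[idx, ] <- target[idx, , drop = FALSE] + sm
    target
  }

  for (l in rev(seq_len(L))) {
    pl <- params$layers[[l]]
    ca <- cache[[l]]

    # head branch: y = tanh(rowMeans(Hout * M))
    dy <- dY[, l] * (1 - ca$y^2) / f
    dHout <- if (is.null(ca$M)) matrix(dy, N, f) else dy * ca$M
    dHout <- dHout + dH

    # GRU cell: Hout = Hin + z*(hh - Hin)
    dz <- dHout * (ca$hh - ca$Hin)
    dhh <- dHout * ca$z
    dHin <- dHout * (1 - ca$z)

    an <- dhh * (1 - ca$hh^2)
    gWn <- crossprod(ca$UR1, an)
    dUR1 <- an %*% t(pl$W_n)
    du <- dUR1[, i1, drop = FALSE]
    drH <- dUR1[, i2, drop = FALSE]
    dr <- drH * ca$Hin
    dHin <- dHin + drH * ca$r

    azr <- cbind(dz * ca$z * (1 - ca$z), dr * ca$r * (1 - ca$r))
    gWzr <- crossprod(ca$UH1, azr)
    dUH1 <- azr %*% t(pl$W_zr)
    du <- du + dUH1[, i1, drop = FALSE]
    dHin <- dHin + dUH1[, i2, drop = FALSE]

    # batchnorm (+ scale/shift)
    ggamma <- colSums(du * ca$xhat)
    gbeta <- colSums(du)
    dxhat <- cmul(du, pl$gamma)
    if (isTRUE(ca$training)) {
      # batch statistics participate in the graph
      sum_dx <- colSums(dxhat)
      sum_dx_xhat <- colSums(dxhat * ca$xhat)
      dr0 <- cmul(dxhat - cadd(cmul(ca$xhat, sum_dx_xhat / N), sum_dx / N),
                  ca$isd)
    } else {
      dr0 <- cmul(dxhat, ca$isd)
    }

    # relu and elementwise gate
    ds <- dr0 * (ca$s > 0)
    dla <- cbind(ds * ca$Hin, ds)
    dHin <- dHin + ds * ca$lam
    gWla <- crossprod(ca$PN1, dla)
    dPN1 <- dla %*% t(pl$W_la)
    dHin <- scatter_add(dHin, iprev, dPN1[, i1, drop = FALSE])
    dHin <- scatter_add(dHin, inext, dPN1[, i2, drop = FALSE])

    grads$layers[[l]] <- list(W_la = gWla, gamma = ggamma, beta = gbeta,
                              W_zr = gWzr, W_n = gWn)
    dH <- dHin
  }
  grads$W_s <- crossprod(E1, dH)
  grads
}

# SGD with classical momentum: v <- momentum*v + g ; p <- p - lr*v
sn_sgd_step <- function(params, grads, vel, lr, momentum) {
  vel$W_s <- momentum * vel$W_s + grads$W_s
  params$W_s <- params$W_s - lr * vel$W_s
  for (l in seq_along(params$layers)) {
    pl <- params$layers[[l]]; gl <- grads$layers[[l]]; vl <- vel$layers[[l]]
    for (nm in names(pl)) {
      vl[[nm]] <- momentum * vl[[nm]] + gl[[nm]]
      pl[[nm]] <- pl[[nm]] - lr * vl[[nm]]
    }
    params$layers[[l]] <- pl
    vel$layers[[l]] <- vl
  }
  list(params = params, vel = vel)
}
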