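# Minimal 1D convolutional network used by the model inverter.
#
# Architecture: three valid-mode conv layers (kernel `kernel`, `n_filters`
# filters, ReLU, dropout after each), pairwise max-pooling of the last
# feature map inside each window, and a dense sigmoid read-out of the
# window centre. Trained with binary cross entropy and Adadelta on
# full-batch gradients. All windows of a chromosome share the convolution
# work: features are computed once per chromosome and gathered per window.

cnn_new <- function(window_bins = 401L, n_filters = 15L, kernel = 10L,
                    n_channels = 2L, seed = 1L) {
  stopifnot(window_bins > 3L * (kernel - 1L) + 2L, window_bins %% 2L == 1L)
  conv_out <- window_bins - 3L * (kernel - 1L)
  m <- conv_out %/% 2L
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  w <- list(
    W1 = glorot(kernel * n_channels, n_filters), b1 = numeric(n_filters),
    W2 = glorot(kernel * n_filters, n_filters), b2 = numeric(n_filters),
    W3 = glorot(kernel * n_filters, n_filters), b3 = numeric(n_filters),
    wd = matrix(stats::runif(m * n_filters, -0.05, 0.05), ncol = 1L),
    bd = 0
  )
  list(w = w, window_bins = as.integer(window_bins),
       kernel = as.integer(kernel), n_filters = as.integer(n_filters),
       n_channels = as.integer(n_channels), m = as.integer(m))
}

# valid 1D convolution through an im2col gather; returns output and the
# gathered input needed for the backward pass
conv_fwd <- function(X, W, b, kernel) {
  L <- nrow(X); C <- ncol(X)
  Lout <- L - kernel + 1L
  Xc <- matrix(0, Lout, kernel * C)
  for (o in seq_len(kernel) - 1L)
    Xc[, (o * C + 1L):(o * C + C)] <- X[(1L + o):(Lout + o), , drop = FALSE]
  Y <- Xc %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, Xc = Xc, L = L, C = C)
}

conv_bwd <- function(dY, fwd, W, kernel) {
  dW <- crossprod(fwd$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(W)
  dX <- matrix(0, fwd$L, fwd$C)
  Lout <- nrow(dY); C <- fwd$C
  for (o in seq_len(kernel) - 1L)
    dX[(1L + o):(Lout + o), ] <- dX[(1L + o):(Lout + o), ] +
      dXc[, (o * C + 1L):(o * C + C), drop = FALSE]
  list(dW = dW, db = db, dX = dX)
}

# full forward pass over one chromosome; starts = window start rows,
# training = apply dropout masks
cnn_forward <- function(net, X, starts, dropout = 0, training = FALSE) {
  k <- net$kernel; f <- net$n_filters; m <- net$m
  cache <- list()
  A <- X
  for (l in 1:3) {
    W <- net$w[[paste0("W", l)]]; b <- net$w[[paste0("b", l)]]
    fw <- conv_fwd(A, W, b, k)
    pre <- fw$Y
    act <- pmax(pre, 0)
    drop_mask <- NULL
    if (training && dropout > 0) {
      drop_mask <- matrix(stats::runif(length(act)) >= dropout,
                          nrow(act), ncol(act))
      act <- act * drop_mask / (1 - dropout)
    }
    cache[[l]] <- list(fw = fw, pre = pre, drop = drop_mask)
    A <- act
  }
  F3 <- A
  N <- length(starts)
  offs <- seq.int(0L, by = 2L, length.out = m)
  I1 <- as.vector(outer(starts, offs, "+"))
  I2 <- I1 + 1L
  A1 <- F3[I1, , drop = FALSE]
  A2 <- F3[I2, , drop = FALSE]
  takeA <- A1 >= A2
  P <- pmax(A1, A2)
  Xd <- matrix(as.vector(P), nrow = N)
  z <- as.vector(Xd %*% net$w$wd) + net$w$bd
  p <- stats::plogis(z)
  list(p = p, z = z, Xd = Xd, takeA = takeA, I1 = I1, I2 = I2,
       F3_nrow = nrow(F3), cache = cache, N = N, dropout = dropout)
}

# backward pass given dz (dLoss/dz per window); returns gradient list
cnn_backward <- function(net, fwdpass, dz) {
  k <- net$kernel; f <- net$n_filters
  g <- list()
  g$wd <- crossprod(fwdpass$Xd, dz)
  g$bd <- sum(dz)
  dXd <- dz %*% t(net$w$wd)                       # N x (m*f)
  dP <- matrix(as.vector(dXd), nrow = fwdpass$N * net$m, ncol = f)
  C1 <- dP * fwdpass$takeA
  C2 <- dP * (!fwdpass$takeA)
  idx <- c(fwdpass$I1, fwdpass$I2)
  agg <- rowsum(rbind(C1, C2), idx)
  dF3 <- matrix(0, fwdpass$F3_nrow, f)
  dF3[as.integer(rownames(agg)), ] <- agg
  dA <- dF3
  for (l in 3:1) {
    cc <- fwdpass$cache[[l]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop / (1 - fwdpass$dropout)
    dA <- dA * (cc$pre > 0)
    bw <- conv_bwd(dA, cc$fw, net$w[[paste0("W", l)]], k)
    g[[paste0("W", l)]] <- bw$dW
    g[[paste0("b", l)]] <- bw$db
    dA <- bw$dX
  }
  g
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

adadelta_init <- function(w) {
  list(Eg = lapply(w, function(x) x * 0), Ed = lapply(w, function(x) x * 0))
}

adadelta_step <- function(w, g, st, rho = 0.95, eps = 1e-6) {
  for (nm in names(w)) {
    gn <- g[[nm]]
    if (is.null(gn)) next
    st$Eg[[nm]] <- rho * st$Eg[[nm]] + (1 - rho) * gn^2
    upd <- -sqrt(st$Ed[[nm]] + eps) / sqrt(st$Eg[[nm]] + eps) * gn
    st$Ed[[nm]] <- rho * st$Ed[[nm]] + (1 - rho) * upd^2
    w[[nm]] <- w[[nm]] + upd
  }
  list(w = w, st = st)
}

# reflective padding of a feature matrix by `pad` rows on each side
reflect_pad <- function(X, pad) {
  L <- nrow(X)
  stopifnot(pad < L)
  rbind(X[(pad + 1L):2L, , drop = FALSE], X,
        X[(L - 1L):(L - pad), , drop = FALSE])
}
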