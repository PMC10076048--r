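# Minimal LSTM machinery: seeded initialization, batched forward pass with
# cached activations, and exact backpropagation through time. Everything is
# dense base-R matrix algebra (BLAS-backed).
#
# Internal layout: a batch of sequences is a single (B*T) x D matrix whose
# row blocks are time steps (rows (t-1)*B+1 .. t*B hold step t for all batch
# members). This lets the input projections, weight-gradient accumulations
# and per-frame linear layers run as one large GEMM each instead of T small
# ones; only the recurrent h %*% U products stay sequential.
#
# Gate layout: the 4H columns of W/U/b are [input | forget | cell | output].

sigmoid <- function(x) 1 / (1 + exp(-x))

# slice frame t of a B x T x D array as a B x D matrix (dims never dropped)
slice_t <- function(A, t) matrix(A[, t, ], nrow = dim(A)[1])

# B x T x D array <-> (B*T) x D stacked matrix (pure re-dimming, no copy of
# element order: both are column-major with b fastest, then t)
stack_bt <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3])
  X
}
unstack_bt <- function(M, B, TT) {
  dim(M) <- c(B, TT, ncol(M))
  M
}

t_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

lstm_init <- function(input_dim, hidden_dim) {
  k <- 1 / sqrt(hidden_dim)
  W <- matrix(stats::runif(input_dim * 4 * hidden_dim, -k, k),
              nrow = input_dim)
  U <- matrix(stats::runif(hidden_dim * 4 * hidden_dim, -k, k),
              nrow = hidden_dim)
  b <- rep(0, 4 * hidden_dim)
  # forget-gate bias of 1: standard trick to keep early memory open
  b[(hidden_dim + 1):(2 * hidden_dim)] <- 1
  list(W = W, U = U, b = b)
}

linear_init <- function(input_dim, output_dim) {
  k <- 1 / sqrt(input_dim)
  list(W = matrix(stats::runif(input_dim * output_dim, -k, k),
                  nrow = input_dim),
       b = rep(0, output_dim))
}

# Forward pass over a whole stacked batch Xm ((B*T) x D). Returns the hidden
# outputs H ((B*T) x H) plus per-gate activation caches for the backward
# pass.
lstm_forward <- function(par, Xm, B, TT) {
  H <- nrow(par$U)
  ih <- 1:H; fh <- (H + 1):(2 * H); gh <- (2 * H + 1):(3 * H)
  oh <- (3 * H + 1):(4 * H)
  Ax <- Xm %*% par$W
  BT <- B * TT
  Hs <- matrix(0, BT, H)
  I <- matrix(0, BT, H); Fg <- matrix(0, BT, H); G <- matrix(0, BT, H)
  O <- matrix(0, BT, H); C <- matrix(0, BT, H); TC <- matrix(0, BT, H)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  bmat <- matrix(par$b, nrow = B, ncol = 4 * H, byrow = TRUE)
  for (t in seq_len(TT)) {
    rows <- t_rows(t, B)
    A <- Ax[rows, , drop = FALSE] + h %*% par$U + bmat
    i <- sigmoid(A[, ih, drop = FALSE])
    f <- sigmoid(A[, fh, drop = FALSE])
    g <- tanh(A[, gh, drop = FALSE])
    o <- sigmoid(A[, oh, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    Hs[rows, ] <- h
    I[rows, ] <- i; Fg[rows, ] <- f; G[rows, ] <- g
    O[rows, ] <- o; C[rows, ] <- cc; TC[rows, ] <- tc
  }
  list(H = Hs, I = I, Fg = Fg, G = G, O = O, C = C, TC = TC, B = B, TT = TT)
}

# Exact BPTT. dH is the gradient w.r.t. every hidden output ((B*T) x H; zero
# rows where the output is unused). Returns parameter gradients and the
# gradient w.r.t. the stacked input.
lstm_backward <- function(par, Xm, fwd, dH) {
  B <- fwd$B; TT <- fwd$TT
  H <- nrow(par$U)
  BT <- B * TT
  DA <- matrix(0, BT, 4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tU <- t(par$U)
  zeroB <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    rows <- t_rows(t, B)
    i <- fwd$I[rows, , drop = FALSE]; f <- fwd$Fg[rows, , drop = FALSE]
    g <- fwd$G[rows, , drop = FALSE]; o <- fwd$O[rows, , drop = FALSE]
    tc <- fwd$TC[rows, , drop = FALSE]
    c_prev <- if (t > 1L) fwd$C[rows - B, , drop = FALSE] else zeroB
    dh <- dH[rows, , drop = FALSE] + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g
    df <- dc * c_prev
    dg <- dc * i
    dA <- cbind(di * i * (1 - i),
                df * f * (1 - f),
                dg * (1 - g^2),
                do_ * o * (1 - o))
    DA[rows, ] <- dA
    dh_next <- dA %*% tU
    dc_next <- dc * f
  }
  # previous-step hidden states, aligned row-block-wise (zero at t = 1)
  Hprev <- matrix(0, BT, H)
  if (TT > 1L) Hprev[(B + 1L):BT, ] <- fwd$H[1:(BT - B), ]
  list(dW = crossprod(Xm, DA),
       dU = crossprod(Hprev, DA),
       db = colSums(DA),
       dX = DA %*% t(par$W))
}

# Adam optimizer state and update over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
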