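# Forward and backward passes over a packed batch.
#
# Layout: "big" matrices are time-major, (B*n) x d, with the row of
# sentence b at time t being (t-1)*B + b. Padded positions carry the <PAD>
# id and mask 0; they are zeroed inside the LSTM and excluded entirely from
# attention and the CRF, so a sentence scores identically alone or batched.

t_block <- function(t, B) ((t - 1L) * B + 1L):(t * B)
sent_rows <- function(b, nb, B) (seq_len(nb) - 1L) * B + b

# One LSTM direction over the packed batch. reverse = TRUE runs right to
# left (the backward encoder). Returns hidden states h (big matrix, B*n x H)
# and the caches needed for backpropagation.
lstm_forward <- function(Xbig, W, U, b_vec, mask, B, n, reverse = FALSE) {
  H <- ncol(W) / 4L
  preW <- Xbig %*% W
  bias <- matrix(b_vec, B, 4L * H, byrow = TRUE)
  hbig <- matrix(0, B * n, H)
  cache <- vector("list", n)
  hprev <- matrix(0, B, H)
  cprev <- matrix(0, B, H)
  ord <- if (reverse) n:1 else seq_len(n)
  for (t in ord) {
    G <- preW[t_block(t, B), , drop = FALSE] + hprev %*% U + bias
    i_g <- sigmoid(G[, seq_len(H), drop = FALSE])
    f_g <- sigmoid(G[, H + seq_len(H), drop = FALSE])
    o_g <- sigmoid(G[, 2L * H + seq_len(H), drop = FALSE])
    g_g <- tanh(G[, 3L * H + seq_len(H), drop = FALSE])
    m <- mask[, t]
    c_t <- (f_g * cprev + i_g * g_g) * m
    tc <- tanh(c_t)
    h_t <- (o_g * tc) * m
    cache[[t]] <- list(i = i_g, f = f_g, o = o_g, g = g_g, tc = tc,
                       hprev = hprev, cprev = cprev)
    hbig[t_block(t, B), ] <- h_t
    hprev <- h_t
    cprev <- c_t
  }
  list(h = hbig, cache = cache, ord = ord)
}

lstm_backward <- function(dh_big, lst, Xbig, W, U, mask, B, n) {
  H <- ncol(W) / 4L
  dGbig <- matrix(0, B * n, 4L * H)
  dU <- matrix(0, nrow(U), ncol(U))
  dh_rec <- matrix(0, B, H)
  dc_rec <- matrix(0, B, H)
  for (t in rev(lst$ord)) {
    ca <- lst$cache[[t]]
    m <- mask[, t]
    dh <- (dh_big[t_block(t, B), , drop = FALSE] + dh_rec) * m
    do_ <- dh * ca$tc
    dc <- (dc_rec + dh * ca$o * (1 - ca$tc^2)) * m
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$cprev
    dG <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o), dg * (1 - ca$g^2))
    dGbig[t_block(t, B), ] <- dG
    dU <- dU + crossprod(ca$hprev, dG)
    dh_rec <- tcrossprod(dG, U)
    dc_rec <- dc * ca$f
  }
  list(dW = crossprod(Xbig, dGbig), dU = dU, db = colSums(dGbig),
       dX = tcrossprod(dGbig, W))
}

# Full forward pass. Returns emissions per sentence plus caches.
forward_batch <- function(par, cfg, batch, training = FALSE) {
  B <- batch$B; n <- batch$n; lens <- batch$lens
  H <- cfg$lstm_hidden
  d_in <- cfg_d_in(cfg)
  # time-major flatten: as.vector of a B x n matrix is column-major, i.e.
  # b fastest within t — exactly the big-matrix row layout.
  ids_char <- as.vector(batch$ids$char)
  Xbig <- par$E_char[ids_char, , drop = FALSE]
  if (cfg$use_dict) Xbig <- cbind(Xbig, par$E_dict[as.vector(batch$ids$dict), , drop = FALSE])
  if (cfg$use_pos) Xbig <- cbind(Xbig, par$E_pos[as.vector(batch$ids$pos), , drop = FALSE])

  drop_x <- NULL
  if (training && cfg$dropout > 0) {
    drop_x <- matrix(
      (runif(length(Xbig)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(Xbig), ncol(Xbig))
    Xbig <- Xbig * drop_x
  }

  fwd <- lstm_forward(Xbig, par$Wf, par$Uf, par$bf, batch$mask, B, n, reverse = FALSE)
  bwd <- lstm_forward(Xbig, par$Wb, par$Ub, par$bb, batch$mask, B, n, reverse = TRUE)
  Hbig <- cbind(fwd$h, bwd$h)

  drop_h <- NULL
  if (training && cfg$dropout > 0) {
    drop_h <- matrix(
      (runif(length(Hbig)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(Hbig), ncol(Hbig))
    Hbig <- Hbig * drop_h
  }

  sent <- vector("list", B)
  for (b in seq_len(B)) {
    nb <- lens[b]
    rows <- sent_rows(b, nb, B)
    Hs <- Hbig[rows, , drop = FALSE]
    if (cfg$attention) {
      Rs <- if (cfg$alignment_source == "inputs")
        Xbig[rows, , drop = FALSE] else Hs
      e <- attention_scores(Rs, par$w_a, r = cfg$attention_width)
      A <- attention_weights(e)
      C <- A %*% Hs
      ZH <- cbind(C, Hs)
      Z <- tanh(ZH %*% par$W_z)
    } else {
      Rs <- NULL; e <- NULL; A <- NULL; ZH <- NULL
      Z <- Hs
    }
    Spre <- Z %*% par$W_p
    S <- if (cfg$emission_activation == "tanh") tanh(Spre) else Spre
    sent[[b]] <- list(rows = rows, Rs = Rs, e = e, A = A, Hs = Hs,
                      ZH = ZH, Z = Z, S = S)
  }
  list(Xbig = Xbig, Hbig = Hbig, fwd = fwd, bwd = bwd,
       drop_x = drop_x, drop_h = drop_h, sent = sent, batch = batch)
}

# Backward pass: dS_list is a list of per-sentence emission gradients.
# Returns gradients for every parameter except Trans (handled by crf_grad).
backward_batch <- function(par, cfg, fw, dS_list) {
  batch <- fw$batch
  B <- batch$B; n <- batch$n
  H <- cfg$lstm_hidden
  d_in <- cfg_d_in(cfg)
  dHbig <- matrix(0, B * n, 2L * H)
  dXbig <- matrix(0, B * n, d_in)
  dW_p <- matrix(0, nrow(par$W_p), ncol(par$W_p))
  if (cfg$attention) {
    dW_z <- matrix(0, nrow(par$W_z), ncol(par$W_z))
    dw_a <- numeric(length(par$w_a))
    da <- length(par$w_a) / 2L
    u <- par$w_a[seq_len(da)]
    v <- par$w_a[da + seq_len(da)]
  }

  for (b in seq_len(B)) {
    sc <- fw$sent[[b]]
    dS <- dS_list[[b]]
    dpreS <- if (cfg$emission_activation == "tanh") dS * (1 - sc$S^2) else dS
    dW_p <- dW_p + crossprod(sc$Z, dpreS)
    dZ <- tcrossprod(dpreS, par$W_p)
    if (cfg$attention) {
      dpreZ <- dZ * (1 - sc$Z^2)
      dW_z <- dW_z + crossprod(sc$ZH, dpreZ)
      dZH <- tcrossprod(dpreZ, par$W_z)
      dC <- dZH[, seq_len(2L * H), drop = FALSE]
      dHs <- dZH[, 2L * H + seq_len(2L * H), drop = FALSE]
      dA <- tcrossprod(dC, sc$Hs)
      dHs <- dHs + crossprod(sc$A, dC)
      # softmax rows
      dE <- sc$A * (dA - rowSums(dA * sc$A))
      # through tanh; masked entries (e = -Inf) carry no gradient
      fin <- is.finite(sc$e)
      dP <- matrix(0, nrow(dE), ncol(dE))
      dP[fin] <- dE[fin] * (1 - sc$e[fin]^2)
      rs <- rowSums(dP); csum <- colSums(dP)
      dw_a <- dw_a + c(crossprod(sc$Rs, rs), crossprod(sc$Rs, csum))
      dRs <- outer(rs, u) + outer(csum, v)
      if (cfg$alignment_source == "inputs") {
        dXbig[sc$rows, ] <- dXbig[sc$rows, , drop = FALSE] + dRs
      } else {
        dHs <- dHs + dRs
      }
      dHbig[sc$rows, ] <- dHbig[sc$rows, , drop = FALSE] + dHs
    } else {
      dHbig[sc$rows, ] <- dHbig[sc$rows, , drop = FALSE] + dZ
    }
  }

  if (!is.null(fw$drop_h)) dHbig <- dHbig * fw$drop_h

  bf <- lstm_backward(dHbig[, seq_len(H), drop = FALSE], fw$fwd, fw$Xbig,
                      par$Wf, par$Uf, batch$mask, B, n)
  bb <- lstm_backward(dHbig[, H + seq_len(H), drop = FALSE], fw$bwd, fw$Xbig,
                      par$Wb, par$Ub, batch$mask, B, n)
  dXbig <- dXbig + bf$dX + bb$dX
  if (!is.null(fw$drop_x)) dXbig <- dXbig * fw$drop_x

  grads <- list(Wf = bf$dW, Uf = bf$dU, bf = bf$db,
                Wb = bb$dW, Ub = bb$dU, bb = bb$db, W_p = dW_p)
  if (cfg$attention) { grads$W_z <- dW_z; grads$w_a <- dw_a }

  # scatter embedding gradients
  scatter <- function(ids_vec, dcols, vocab_n) {
    rs <- rowsum(dcols, group = ids_vec)
    out <- matrix(0, vocab_n, ncol(dcols))
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  off <- 0L
  grads$E_char <- scatter(as.vector(batch$ids$char),
                          dXbig[, off + seq_len(cfg$d_char), drop = FALSE],
                          nrow(par$E_char))
  off <- cfg$d_char
  if (cfg$use_dict) {
    grads$E_dict <- scatter(as.vector(batch$ids$dict),
                            dXbig[, off + seq_len(cfg$d_feature), drop = FALSE],
                            nrow(par$E_dict))
    off <- off + cfg$d_feature
  }
  if (cfg$use_pos) {
    grads$E_pos <- scatter(as.vector(batch$ids$pos),
                           dXbig[, off + seq_len(cfg$d_feature), drop = FALSE],
                           nrow(par$E_pos))
  }
  # <PAD> embedding stays frozen at zero
  grads$E_char[1, ] <- 0
  if (cfg$use_dict) grads$E_dict[1, ] <- 0
  if (cfg$use_pos) grads$E_pos[1, ] <- 0
  grads
}
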