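#' Windowed additive attention primitives
#'
#' The sentence-level attention layer compares the representation of
#' position `t` with every position `j` of the same sentence through a
#' scalar alignment score
#' \deqn{e_{tj} = \tanh(w_a \cdot [R_t ; R_j])}
#' normalizes each row by a softmax into weights \eqn{\alpha_{tj}}, forms a
#' context vector \eqn{c_t = \sum_j \alpha_{tj} h_j} from the encoder
#' outputs, and fuses it with the encoder state,
#' \eqn{z_t = \tanh(W_z [c_t ; h_t])}. An attention width `r` confines each
#' position to the `2r+1`-wide window `|t-j| <= r` (the center position is
#' included); positions outside the window — and padded positions — get
#' score `-Inf` and therefore weight exactly 0.
#'
#' These functions are the layer's algebra on plain matrices; the fitted
#' model calls them internally but they are exported so the properties
#' (row-stochasticity, window zeroing, tanh range) can be exercised
#' directly.
#'
#' @param R `n x d` matrix of alignment-source representations (the
#'   embedded inputs by default, or the encoder states).
#' @param w_a Numeric vector of length `2d`: the alignment map, applied to
#'   the concatenation `[R_t; R_j]`.
#' @param r Attention width (non-negative integer or `Inf`).
#' @param mask Optional logical vector of length `n`; `FALSE` positions are
#'   padding and receive zero weight from every row.
#' @param e `n x n` score matrix from `attention_scores()`.
#' @param A `n x n` row-stochastic weight matrix.
#' @param H `n x d_h` encoder output matrix.
#' @param W_z `(2 d_h) x d_z` fusion weight matrix.
#' @param Z `n x d_z` fused representation.
#' @param W_p `d_z x K` scoring matrix (one column per tag).
#' @param activation `"linear"` (default) or `"tanh"` (bounding emissions
#'   to (-1, 1)).
#' @return `attention_scores()`: `n x n` matrix with `-Inf` outside the
#'   window; `attention_weights()`: row-stochastic `n x n` matrix;
#'   `attention_fuse()`: list with `C` (contexts) and `Z`;
#'   `emissions()`: `n x K` emission matrix.
#' @examples
#' R <- matrix(rnorm(6), 3, 2)
#' e <- attention_scores(R, rep(0.1, 4), r = 1)
#' rowSums(attention_weights(e))
#' @name attention
NULL

#' @rdname attention
#' @export
attention_scores <- function(R, w_a, r = Inf, mask = NULL) {
  n <- nrow(R); d <- ncol(R)
  stopifnot(length(w_a) == 2 * d, r >= 0)
  u <- w_a[seq_len(d)]; v <- w_a[d + seq_len(d)]
  e <- tanh(outer(drop(R %*% u), rep(1, n)) + outer(rep(1, n), drop(R %*% v)))
  if (is.finite(r)) {
    idx <- seq_len(n)
    e[abs(outer(idx, idx, "-")) > r] <- -Inf
  }
  if (!is.null(mask)) e[, !mask] <- -Inf
  e
}

#' @rdname attention
#' @export
attention_weights <- function(e) {
  n <- nrow(e)
  A <- matrix(0, n, ncol(e))
  for (t in seq_len(n)) {
    row <- e[t, ]
    m <- max(row)
    if (!is.finite(m)) abort(sprintf("Attention row %d is fully masked.", t))
    w <- exp(row - m)
    w[!is.finite(row)] <- 0
    A[t, ] <- w / sum(w)
  }
  A
}

#' @rdname attention
#' @export
attention_fuse <- function(A, H, W_z) {
  C <- A %*% H
  Z <- tanh(cbind(C, H) %*% W_z)
  list(C = C, Z = Z)
}

#' @rdname attention
#' @export
emissions <- function(Z, W_p, activation = c("linear", "tanh")) {
  activation <- match.arg(activation)
  S <- Z %*% W_p
  if (activation == "tanh") S <- tanh(S)
  S
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}
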