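#' Linear-chain CRF over emission and transition scores
#'
#' The decoder on top of the network is a linear-chain conditional random
#' field. Given a sentence of `n` characters and `K` tags, the network
#' yields an emission matrix `S` (`n x K`, score of tag `j` at position
#' `i`), and the CRF holds a transition matrix `T` of size
#' `(K+2) x (K+2)` whose last two indices are the `START` (`K+1`) and
#' `STOP` (`K+2`) boundary states. A tag path `y` scores
#'
#' \deqn{S(X, y) = T[\mathrm{START}, y_1] + \sum_i S[i, y_i] +
#'   \sum_i T[y_i, y_{i+1}] + T[y_n, \mathrm{STOP}]}
#'
#' Training minimizes the negative log-likelihood
#' \eqn{\log\sum_{y'} e^{S(X,y')} - S(X,y)}; the normalizer is computed by
#' the forward recursion entirely in log space, and decoding uses Viterbi.
#' Transitions into `START` and out of `STOP` are structurally impossible
#' (`-Inf`); the functions enforce this whatever values the passed matrix
#' carries there.
#'
#' @param S Emission matrix, `n x K`.
#' @param Trans Transition matrix, `(K+2) x (K+2)`; rows index the source
#'   tag, columns the target.
#' @param y Integer tag path (values in `1..K`), length `n`.
#' @return `crf_score_path()` and `crf_log_partition()` a scalar;
#'   `crf_neg_log_likelihood()` a non-negative scalar;
#'   `crf_viterbi()` a list with `path` (integer vector) and `score`.
#' @examples
#' S <- matrix(0, 2, 2); Tr <- matrix(0, 4, 4)
#' crf_log_partition(S, Tr)  # log(4): four equally scored paths
#' crf_viterbi(S, Tr)$path   # all ties break to tag 1
#' @name crf
NULL

crf_boundary <- function(Trans, K) {
  Trans[, K + 1L] <- -Inf  # into START
  Trans[K + 2L, ] <- -Inf  # out of STOP
  Trans
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  fin <- is.finite(m)
  out <- m
  if (any(fin))
    out[fin] <- m[fin] + log(colSums(exp(sweep(M[, fin, drop = FALSE], 2, m[fin]))))
  out
}

#' @rdname crf
#' @export
crf_score_path <- function(S, Trans, y) {
  n <- nrow(S); K <- ncol(S)
  y <- as.integer(y)
  if (length(y) != n) abort("Path length must equal the number of emission rows.")
  Trans <- crf_boundary(Trans, K)
  sc <- Trans[K + 1L, y[1]] + sum(S[cbind(seq_len(n), y)]) + Trans[y[n], K + 2L]
  if (n > 1) sc <- sc + sum(Trans[cbind(y[-n], y[-1])])
  sc
}

#' @rdname crf
#' @export
crf_log_partition <- function(S, Trans) {
  n <- nrow(S); K <- ncol(S)
  Trans <- crf_boundary(Trans, K)
  a <- Trans[K + 1L, seq_len(K)] + S[1, ]
  if (n > 1) {
    TT <- Trans[seq_len(K), seq_len(K), drop = FALSE]
    for (i in 2:n) a <- col_logsumexp(a + TT) + S[i, ]
  }
  logsumexp(a + Trans[seq_len(K), K + 2L])
}

#' @rdname crf
#' @export
crf_neg_log_likelihood <- function(S, Trans, y) {
  crf_log_partition(S, Trans) - crf_score_path(S, Trans, y)
}

#' @rdname crf
#' @export
crf_viterbi <- function(S, Trans) {
  n <- nrow(S); K <- ncol(S)
  Trans <- crf_boundary(Trans, K)
  TT <- Trans[seq_len(K), seq_len(K), drop = FALSE]
  a <- Trans[K + 1L, seq_len(K)] + S[1, ]
  back <- matrix(0L, n, K)
  if (n > 1) for (i in 2:n) {
    M <- a + TT  # M[prev, cur]
    back[i, ] <- apply(M, 2, which.max)  # first max = lowest tag index
    a <- M[cbind(back[i, ], seq_len(K))] + S[i, ]
  }
  fin <- a + Trans[seq_len(K), K + 2L]
  path <- integer(n)
  path[n] <- which.max(fin)
  if (n > 1) for (i in n:2) path[i - 1L] <- back[i, path[i]]
  list(path = path, score = max(fin))
}

# Forward/backward marginals and gradient of the NLL w.r.t. S and Trans.
# Returns list(nll, dS, dT) with dT over the full (K+2)^2 matrix
# (structurally impossible entries get zero gradient).
crf_grad <- function(S, Trans, y) {
  n <- nrow(S); K <- ncol(S)
  Tm <- crf_boundary(Trans, K)
  TT <- Tm[seq_len(K), seq_len(K), drop = FALSE]
  alpha <- matrix(-Inf, n, K)
  alpha[1, ] <- Tm[K + 1L, seq_len(K)] + S[1, ]
  if (n > 1) for (i in 2:n)
    alpha[i, ] <- col_logsumexp(alpha[i - 1L, ] + TT) + S[i, ]
  logZ <- logsumexp(alpha[n, ] + Tm[seq_len(K), K + 2L])
  beta <- matrix(-Inf, n, K)
  beta[n, ] <- Tm[seq_len(K), K + 2L]
  if (n > 1) for (i in (n - 1L):1)
    beta[i, ] <- col_logsumexp(sweep(t(TT), 1, S[i + 1L, ] + beta[i + 1L, ], "+"))
  # unary marginals
  marg <- exp(alpha + beta - logZ)
  dS <- marg
  dS[cbind(seq_len(n), y)] <- dS[cbind(seq_len(n), y)] - 1
  dT <- matrix(0, K + 2L, K + 2L)
  # boundary transitions
  p1 <- marg[1, ]
  dT[K + 1L, seq_len(K)] <- p1
  dT[K + 1L, y[1]] <- dT[K + 1L, y[1]] - 1
  pn <- marg[n, ]
  dT[seq_len(K), K + 2L] <- pn
  dT[y[n], K + 2L] <- dT[y[n], K + 2L] - 1
  if (n > 1) for (i in seq_len(n - 1L)) {
    Q <- exp(outer(alpha[i, ], S[i + 1L, ] + beta[i + 1L, ], "+") + TT - logZ)
    Q[!is.finite(Q)] <- 0
    dT[seq_len(K), seq_len(K)] <- dT[seq_len(K), seq_len(K)] + Q
    dT[y[i], y[i + 1L]] <- dT[y[i], y[i + 1L]] - 1
  }
  list(nll = logZ - crf_score_path(S, Trans, y), dS = dS, dT = dT)
}

#' Structural transition mask for the BIESO scheme
#'
#' Builds an additive `(K+2) x (K+2)` mask (0 for allowed, `-Inf` for
#' forbidden) that rules out tag bigrams impossible under BIESO: spans must
#' run `B-t (I-t)* E-t` with one type, `S-t` and `O` are complete units,
#' `START` can only open a span or emit `O`, and only `O`, `E-t` or `S-t`
#' may precede `STOP`. Adding the mask to a learned transition matrix makes
#' every Viterbi path decodable without repair. Off by default in training:
#' the transitions are ordinarily learned unconstrained.
#'
#' @param types Character vector of entity types.
#' @return Numeric matrix in the tag order of [tag_alphabet()] followed by
#'   `START`, `STOP`.
#' @examples
#' M <- constrained_transitions(c("AP"))
#' M["O", "I-AP"]  # -Inf: an interior tag cannot follow O
#' @export
constrained_transitions <- function(types) {
  alpha <- tag_alphabet(types)
  K <- length(alpha)
  lab <- c(alpha, "START", "STOP")
  M <- matrix(-Inf, K + 2L, K + 2L, dimnames = list(lab, lab))
  opens <- c("O", paste0("B-", types), paste0("S-", types))   # span-initial tags
  closes <- c("O", paste0("E-", types), paste0("S-", types))  # span-final tags
  M["START", opens] <- 0
  M[closes, "STOP"] <- 0
  for (from in closes) M[from, opens] <- 0
  for (t in types) {
    M[paste0("B-", t), c(paste0("I-", t), paste0("E-", t))] <- 0
    M[paste0("I-", t), c(paste0("I-", t), paste0("E-", t))] <- 0
  }
  M
}
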