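## per-component log marginal likelihoods of count columns:
## L[j, k] = log Dirichlet-multinomial marginal of column k under component j
## (exchangeable counts form, without the multinomial coefficient, i.e. the
## probability of one particular ordering of the residues)
componentLogMarginals <- function(counts, mix) {
  counts <- as.matrix(counts)
  M <- colSums(counts)
  J <- length(mix@weights)
  L <- matrix(0, nrow = J, ncol = ncol(counts))
  astar <- rowSums(mix@alpha)
  for (j in seq_len(J)) {
    aj <- mix@alpha[j, ]
    L[j, ] <- (lgamma(astar[j]) - lgamma(astar[j] + M) +
               colSums(lgamma(aj + counts)) - sum(lgamma(aj)))
  }
  L
}

#' Log-probability of an alignment column under the relatedness model
#'
#' Computes \eqn{\log Q(\vec x)}, the marginal likelihood of the residues of
#' one alignment column under the Dirichlet-mixture prior: the residues are
#' assumed drawn i.i.d. from a single unknown composition \eqn{\theta} with
#' \eqn{\theta} drawn from the mixture. In closed form
#' \deqn{Q(\vec x) = \sum_j q_j \frac{\Gamma(\alpha^*_j)}{\Gamma(\alpha^*_j+M)}
#'   \prod_a \frac{\Gamma(\alpha_{ja}+c_a)}{\Gamma(\alpha_{ja})}}
#' evaluated in log space. An empty column (\eqn{M=0}) has \eqn{\log Q = 0}.
#' Equivalently, \eqn{\log Q} is the sum of log posterior-predictive
#' probabilities of the residues added one at a time, in any order.
#'
#' @param counts 20-vector of residue counts (order = mixture alphabet), or a
#'   20 x K matrix of count columns.
#' @param mix a \linkS4class{DirichletMixture}.
#' @return numeric: \eqn{\log Q} per column (nats).
#' @export
columnLogQ <- function(counts, mix) {
  counts <- as.matrix(counts)
  L <- componentLogMarginals(counts, mix)
  lw <- log(mix@weights)
  out <- apply(L + lw, 2L, logSumExp)
  out[colSums(counts) == 0] <- 0       # empty column: log 1, exactly
  out
}

#' BILD score of an alignment column
#'
#' The Bayesian Integral Log-odds score
#' \eqn{S(\vec x) = \log Q(\vec x) - \sum_a c_a \log p_a}: the log-ratio of
#' the column's probability under relatedness (Dirichlet-mixture marginal)
#' versus independence (product of background frequencies). The score is also
#' mapped to a normalized probability in (0, 1) via the logistic transform
#' \eqn{\sigma(S) = e^S / (1 + e^S)} — the posterior probability that the
#' column was generated by the relatedness model under equal prior odds —
#' which is what the core-block threshold is applied to; see the methods
#' vignette for the rationale of this normalization.
#'
#' @inheritParams columnLogQ
#' @param perObsDivisor if \code{TRUE}, divide \eqn{S} by the number of
#'   observations before the logistic map (a per-observation odds scale).
#'   Default \code{FALSE}: on the per-observation scale even weakly negative
#'   per-residue odds stay far above the block threshold, which defeats
#'   block/background separation.
#' @return a list with numeric elements \code{S} (nats) and \code{prob}.
#' @examples
#' mix <- syntheticMixture20()
#' cnt <- numeric(20); cnt[1] <- 10            # ten alanines
#' bildScore(cnt, mix)$S > 0
#' @export
bildScore <- function(counts, mix, perObsDivisor = FALSE) {
  counts <- as.matrix(counts)
  M <- colSums(counts)
  S <- columnLogQ(counts, mix) -
    colSums(counts * log(pmax(mix@background, PROB_FLOOR)))
  div <- if (perObsDivisor) pmax(M, 1) else 1
  list(S = S, prob = stats::plogis(S / div))
}

#' Posterior-predictive residue probabilities given an observed column
#'
#' The probability of observing each residue next, after updating the
#' Dirichlet-mixture prior with the residues of a column:
#' \deqn{P(a \mid \Theta_M) = \sum_j w_j \frac{\alpha_{ja}+c_a}{\alpha^*_j+M}}
#' with component responsibilities \eqn{w_j \propto q_j Q_j(\vec x)} summing
#' to 1. The 20 probabilities sum to 1, and
#' \eqn{Q(\vec x + e_a) / Q(\vec x) = P(a \mid \Theta_M)} (chain rule).
#'
#' @inheritParams columnLogQ
#' @param residue optional residue character (or vector of characters, one
#'   per count column); when supplied, only its probability is returned.
#' @return a 20 x K matrix of probabilities (rows in mixture alphabet order),
#'   or a length-K vector if \code{residue} is given.
#' @export
posteriorPredictive <- function(counts, mix, residue = NULL) {
  counts <- as.matrix(counts)
  M <- colSums(counts)
  L <- componentLogMarginals(counts, mix)      # J x K
  lw <- log(mix@weights) + L
  lw <- sweep(lw, 2L, apply(lw, 2L, logSumExp))
  W <- exp(lw)                                 # responsibilities, J x K
  astar <- rowSums(mix@alpha)
  ## pred[a, k] = sum_j W[j, k] * (alpha[j, a] + counts[a, k]) / (astar_j + M_k)
  Wn <- W / outer(astar, M, "+")               # J x K
  pred <- t(mix@alpha) %*% Wn + counts * rep(colSums(Wn), each = 20L)
  dimnames(pred) <- list(mix@alphabet, NULL)
  if (is.null(residue)) return(pred)
  idx <- match(toupper(residue), mix@alphabet)
  if (anyNA(idx)) stop("unknown residue: ", residue[is.na(idx)][1L])
  if (length(idx) == 1L) return(unname(pred[idx, ]))
  if (length(idx) != ncol(pred))
    stop("residue vector length must match the number of count columns")
  unname(pred[cbind(idx, seq_along(idx))])
}

#' Bayesian relatedness score between two alignment columns
#'
#' The column-pair substitution score
#' \eqn{R(\vec x, \vec y) = S(\vec{xy}) - S(\vec x) - S(\vec y)
#'   = \log [Q(\vec{xy}) / (Q(\vec x) Q(\vec y))]}
#' where \eqn{\vec{xy}} pools the two columns' counts; the background terms
#' cancel. R is symmetric, and zero against an empty column.
#'
#' @param countsX,countsY 20-vectors (or 20 x K matrices) of residue counts.
#' @inheritParams columnLogQ
#' @return numeric relatedness score(s) in nats; positive means the two
#'   columns look drawn from a shared composition.
#' @export
columnPairScore <- function(countsX, countsY, mix) {
  countsX <- as.matrix(countsX); countsY <- as.matrix(countsY)
  columnLogQ(countsX + countsY, mix) -
    columnLogQ(countsX, mix) - columnLogQ(countsY, mix)
}

#' Relative entropy of a Dirichlet mixture's implied substitution scores
#'
#' Forms the joint distribution of an aligned residue pair under the mixture,
#' \eqn{Q_2(x, y) \propto Q(\{x, y\})} over all 400 ordered pairs, and
#' returns its relative entropy against the independent background,
#' \eqn{H = \sum_{x,y} Q_2(x,y) \log_2 [Q_2(x,y) / (p_x p_y)]} in bits —
#' the conventional scale on which substitution matrices (PAM/BLOSUM) are
#' compared.
#'
#' @inheritParams columnLogQ
#' @return relative entropy in bits (non-negative).
#' @export
mixtureRelativeEntropy <- function(mix) {
  ij <- expand.grid(x = 1:20, y = 1:20)
  counts <- matrix(0, nrow = 20L, ncol = nrow(ij))
  counts[cbind(ij$x, seq_len(nrow(ij)))] <- counts[cbind(ij$x, seq_len(nrow(ij)))] + 1
  counts[cbind(ij$y, seq_len(nrow(ij)))] <- counts[cbind(ij$y, seq_len(nrow(ij)))] + 1
  q2 <- exp(columnLogQ(counts, mix))
  q2 <- q2 / sum(q2)
  pxy <- mix@background[ij$x] * mix@background[ij$y]
  sum(q2 * log2(q2 / pxy))
}

#' Residue counts per alignment column for a set of sequences
#'
#' Tabulates, for every alignment column, the residues contributed by the
#' given member sequences; gaps and \code{'X'} contribute nothing (missing
#' data).
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param members integer vector of member sequence indices.
#' @param alphabet residue row order of the result (use the mixture's
#'   alphabet when the counts feed the scoring functions).
#' @return a 20 x \code{nCols(msa)} integer matrix of counts.
#' @export
columnCounts <- function(msa, members, alphabet = AA20) {
  sub <- msa@mat[members, , drop = FALSE]
  idx <- match(sub, alphabet)                  # NA for '-' and 'X'
  K <- ncol(sub)
  counts <- matrix(0L, nrow = 20L, ncol = K, dimnames = list(alphabet, NULL))
  col <- rep(seq_len(K), each = nrow(sub))
  keep <- !is.na(idx)
  if (any(keep)) {
    tab <- table(factor(idx[keep], levels = 1:20), factor(col[keep], levels = seq_len(K)))
    counts[] <- as.integer(tab)
  }
  counts
}
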