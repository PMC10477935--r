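#' @include autoencoder.R
NULL

## Numerically stable binary cross-entropy in logits form, per entry:
## max(x, 0) - x*y + log(1 + exp(-|x|)).
.bceLogits <- function(x, y) pmax(x, 0) - x * y + log1p(exp(-abs(x)))

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Loss weights for the embedding and alignment objectives
#'
#' The embedding objective is
#' \code{alpha * L_high + gamma * L_1st + lambda * L2 + omega * L_norm};
#' the alignment stage adds the cross-reconstruction loss scaled by
#' \code{phi}. The defaults are the recommended starting point for a new
#' species pair: the higher-order reconstruction term dominates.
#'
#' @param alpha Weight of the higher-order reconstruction loss.
#' @param gamma Weight of the first-order (direct-edge) loss.
#' @param lambda Weight of the L2 penalty on weights (biases excluded).
#' @param omega Weight of the embedding-norm penalty (sum of squared row
#'   norms), guarding against exploding norms.
#' @param phi Weight of the cross-training alignment loss.
#' @return Named list of nonnegative weights.
#' @export
lossWeights <- function(alpha = 100, gamma = 5, lambda = 1, omega = 1,
                        phi = 50) {
    w <- list(alpha = alpha, gamma = gamma, lambda = lambda, omega = omega,
              phi = phi)
    if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
    w
}

#' First-order proximity loss
#'
#' For every edge (i, j), penalizes dissimilar embeddings:
#' \deqn{L = -\frac{1}{2|E|}\sum_{i,j} A_{ij}\log(\mathrm{clamp}(\cos(z_i, z_j), \epsilon, 1))}
#' where the ordered-pair sum counts each undirected edge twice. Only
#' reported edges contribute: absent edges are not treated as negatives
#' because interaction data are incomplete. Cosines at or below 0 are
#' clamped to \code{eps} so the logarithm stays finite.
#'
#' @param Z Numeric matrix of embeddings, one row per vertex (same order
#'   as the network).
#' @param net A \linkS4class{PPINetwork} with at least one edge.
#' @param eps Clamp floor for the cosine.
#' @return Nonnegative scalar loss.
#' @export
lossFirstOrder <- function(Z, net, eps = 1e-8) {
    A <- adjacency(net)
    e <- .edgeIndices(A)
    if (nrow(e) == 0L) stop("network has no edges")
    nrm <- sqrt(rowSums(Z^2))
    deg <- Matrix::rowSums(A)
    bad <- which(nrm == 0 & deg > 0)
    if (length(bad))
        stop("zero-norm embedding row for vertex with edges: row ", bad[1L])
    dots <- rowSums(Z[e[, 1L], , drop = FALSE] * Z[e[, 2L], , drop = FALSE])
    cosv <- dots / (nrm[e[, 1L]] * nrm[e[, 2L]])
    cosv <- pmin(pmax(cosv, eps), 1)
    -sum(log(cosv)) / nrow(e)
}

## Upper-triangle edge indices (i < j) of a sparse symmetric adjacency.
.edgeIndices <- function(A) {
    A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
    keep <- A@i < A@j
    cbind(A@i[keep] + 1L, A@j[keep] + 1L)
}

#' Higher-order reconstruction loss
#'
#' Binary cross-entropy, in stable logits form, between the sigmoid of the
#' reconstruction logits and the random-walk matrix min-max scaled to
#' [0, 1]: the per-entry cross-entropies are summed and divided by the
#' number of rows n, i.e. the average over vertices of their summed
#' row-wise cross-entropy. (Dividing by rows rather than by all n^2
#' entries keeps the reconstruction term the dominant component of the
#' combined objective at the shipped weight alpha = 100, which the
#' objective's design calls for.)
#'
#' @param recon Numeric matrix of pre-sigmoid reconstruction logits.
#' @param M Target: a \linkS4class{NetMFMatrix} (min-max scaled
#'   internally) or a numeric matrix already in [0, 1].
#' @return Nonnegative scalar loss.
#' @export
lossHigh <- function(recon, M) {
    Y <- if (methods::is(M, "NetMFMatrix")) .scaleTargets(M) else M
    if (!all(dim(recon) == dim(Y))) stop("shape mismatch between recon and M")
    if (any(!is.finite(recon))) stop("non-finite reconstruction logits")
    if (min(Y) < 0 || max(Y) > 1) stop("targets must lie in [0, 1]")
    sum(.bceLogits(recon, Y)) / nrow(Y)
}

## Sum of squared weight entries, biases excluded.
.l2Weights <- function(w) sum(vapply(w[c("W1", "W2", "W3", "W4")],
                                     function(m) sum(m^2), 0))

#' Combined embedding loss
#'
#' \code{alpha * lossHigh + gamma * lossFirstOrder + lambda * L2(weights) +
#' omega * sum_i ||z_i||^2}. The L2 term sums squared weight-matrix entries
#' only (biases excluded).
#'
#' @param Z Embedding matrix (n x latent).
#' @param recon Reconstruction logits (n x n).
#' @param net \linkS4class{PPINetwork}.
#' @param M Target \linkS4class{NetMFMatrix} or scaled matrix.
#' @param params \linkS4class{Autoencoder} whose weights feed the L2 term.
#' @param weights A \code{\link{lossWeights}} list.
#' @return Scalar loss.
#' @export
lossEmbed <- function(Z, recon, net, M, params, weights = lossWeights()) {
    weights$alpha * lossHigh(recon, M) +
        weights$gamma * lossFirstOrder(Z, net) +
        weights$lambda * .l2Weights(params@weights) +
        weights$omega * sum(Z^2)
}

#' Cross-training alignment loss
#'
#' For each anchor pair, species A's encoder places the anchor in the
#' joint space and species B's decoder must reconstruct the partner's
#' random-walk neighborhood, and vice versa:
#' \deqn{L = \phi \sum_{(i,i')} \mathrm{BCE}(\sigma(De_B(En_A(m_i))), m'_{i'}) +
#'   \mathrm{BCE}(\sigma(De_A(En_B(m'_{i'}))), m_i)}
#' Each BCE is the mean over the target row's entries, using the same
#' scaled targets and stable logits form as \code{\link{lossHigh}}; the sum
#' over anchors is not normalized (the weight \code{phi} absorbs scale).
#' The value is symmetric under swapping the two species together with
#' transposing the anchors.
#'
#' @param aeA,aeB \linkS4class{Autoencoder} objects for the two species.
#' @param MA,MB \linkS4class{NetMFMatrix} objects (or numeric input
#'   matrices paired with pre-scaled targets).
#' @param anchors \linkS4class{OrthologAnchors} (nonempty).
#' @param phi Nonnegative scalar weight.
#' @return Scalar loss (0 when \code{phi} is 0).
#' @export
lossCross <- function(aeA, aeB, MA, MB, anchors, phi = 50) {
    if (numAnchors(anchors) == 0L) stop("empty anchor set")
    if (phi == 0) return(0)
    XA <- if (methods::is(MA, "NetMFMatrix")) MA@values else MA
    XB <- if (methods::is(MB, "NetMFMatrix")) MB@values else MB
    YA <- .scaleTargets(XA)
    YB <- .scaleTargets(XB)
    p <- anchorPairs(anchors)
    oAB <- .decodeW(aeB@weights, .encodeW(aeA@weights, XA[p[, 1L], , drop = FALSE],
                                          aeA@slope), aeB@slope)
    oBA <- .decodeW(aeA@weights, .encodeW(aeB@weights, XB[p[, 2L], , drop = FALSE],
                                          aeB@slope), aeA@slope)
    phi * (sum(rowMeans(.bceLogits(oAB, YB[p[, 2L], , drop = FALSE]))) +
           sum(rowMeans(.bceLogits(oBA, YA[p[, 1L], , drop = FALSE]))))
}
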