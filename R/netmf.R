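#' @include AllClasses.R
NULL

#' Closed-form random-walk similarity matrix
#'
#' Computes the dense matrix the autoencoder embeds: with adjacency A,
#' degree matrix D and graph volume vol(G),
#' \deqn{R = \frac{vol(G)}{T}\Big(\sum_{i=1}^{T}(D^{-1}A)^i\Big)D^{-1}}
#' and the returned matrix is the truncated elementwise logarithm
#' \eqn{M_{ij} = \max(\log(R_{ij}/b), 0)} wherever \eqn{R_{ij} > 0}, and
#' exactly 0 where \eqn{R_{ij} = 0} (structural zero: no path of length at
#' most T joins i and j, so no logarithm is taken). Entry (i, j) is a
#' weighted count of paths between the two vertices of length at most T,
#' which is what lets the embedding see beyond direct and two-hop
#' neighbors.
#'
#' @param net A preprocessed \linkS4class{PPINetwork} (every degree >= 1).
#' @param window Integer context window T >= 1.
#' @param negative Positive negative-sampling parameter b; larger b shrinks
#'   every entry.
#' @return A \linkS4class{NetMFMatrix}.
#' @examples
#' f <- tempfile(); writeLines(c("a\tb", "b\tc", "c\td", "d\ta"), f)
#' M <- netmfMatrix(readEdgeList(f), window = 1, negative = 1)
#' values(M)[1, 2]  # log(2) on cycle edges
#' @export
netmfMatrix <- function(net, window = 10L, negative = 1) {
    if (window < 1L) stop("window T must be >= 1")
    if (negative <= 0) stop("negative-sampling parameter b must be > 0")
    A <- as.matrix(adjacency(net))
    deg <- rowSums(A)
    if (any(deg == 0))
        stop("network has degree-0 vertices; preprocess it first")
    vol <- sum(deg)
    P <- A / deg                      # D^{-1} A, row-stochastic
    S <- P
    if (window > 1L) {
        Pk <- P
        for (i in 2:window) {
            Pk <- Pk %*% P
            S <- S + Pk
        }
    }
    R <- (vol / window) * sweep(S, 2L, deg, "/")
    M <- matrix(0, nrow(R), ncol(R))
    pos <- R > 0
    M[pos] <- pmax(log(R[pos] / negative), 0)
    ## exact symmetrization: D^{-1} P^k D^{-1} is symmetric analytically but
    ## floating-point products of the two orientations can differ in the
    ## last ulp; average to restore M = M^T.
    M <- (M + t(M)) / 2
    dimnames(M) <- list(vertexIds(net), vertexIds(net))
    methods::new("NetMFMatrix", values = M, window = as.integer(window),
                 negative = as.numeric(negative), vertexIds = vertexIds(net))
}
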