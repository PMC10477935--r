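#' @include AllClasses.R
NULL

.lrelu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))
.lreluGrad <- function(x, slope) slope + (1 - slope) * (x > 0)

## Add a bias row-vector to every row without sweep()'s aperm overhead.
.addBias <- function(X, b) X + rep(b, each = nrow(X))

## Fan-in scaled uniform init, matching the common dense-layer default:
## W, b ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
.initLayer <- function(fanIn, fanOut) {
    s <- 1 / sqrt(fanIn)
    list(W = matrix(stats::runif(fanIn * fanOut, -s, s), fanIn, fanOut),
         b = stats::runif(fanOut, -s, s))
}

#' Initialize an autoencoder
#'
#' Encoder n -> hidden -> latent, decoder latent -> hidden -> n with an
#' independent hidden layer. All weights and biases are drawn from a
#' fan-in-scaled uniform distribution under the given seed, so two calls
#' with the same arguments produce identical parameters.
#'
#' @param n Input/output width (number of network vertices).
#' @param hidden Hidden layer width (default 1024).
#' @param latent Latent embedding width (default 128).
#' @param seed Integer seed.
#' @param slope Negative slope of the leaky rectifier (default 0.1).
#' @return An \linkS4class{Autoencoder}.
#' @export
initAutoencoder <- function(n, hidden = 1024L, latent = 128L, seed = 1L,
                            slope = 0.1) {
    if (n < 1L || hidden < 1L || latent < 1L)
        stop("layer sizes must be positive")
    if (latent > n)
        warning("latent width exceeds input width; embedding will not compress")
    wts <- withSeed(seed, {
        l1 <- .initLayer(n, hidden)
        l2 <- .initLayer(hidden, latent)
        l3 <- .initLayer(latent, hidden)
        l4 <- .initLayer(hidden, n)
        list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
             W3 = l3$W, b3 = l3$b, W4 = l4$W, b4 = l4$b)
    })
    methods::new("Autoencoder",
                 dims = c(n = as.integer(n), hidden = as.integer(hidden),
                          latent = as.integer(latent)),
                 weights = wts, slope = slope, seed = as.integer(seed))
}

## Forward pass helpers on plain weight lists (also used by the gradient
## engine, which works on lists rather than S4 objects in the hot loop).
.encodeW <- function(w, X, slope) {
    H <- .lrelu(.addBias(X %*% w$W1, w$b1), slope)
    .addBias(H %*% w$W2, w$b2)
}

.decodeW <- function(w, Z, slope) {
    H <- .lrelu(.addBias(Z %*% w$W3, w$b3), slope)
    .addBias(H %*% w$W4, w$b4)
}

#' @rdname encode
#' @export
setMethod("encode", "Autoencoder", function(object, x) {
    if (methods::is(x, "NetMFMatrix")) x <- x@values
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    if (ncol(x) != object@dims[["n"]])
        stop("input width ", ncol(x), " does not match encoder input ",
             object@dims[["n"]])
    Z <- .encodeW(object@weights, x, object@slope)
    rownames(Z) <- rownames(x)
    Z
})

#' @rdname decode
#' @export
setMethod("decode", "Autoencoder", function(object, z) {
    if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
    if (ncol(z) != object@dims[["latent"]])
        stop("latent width ", ncol(z), " does not match decoder input ",
             object@dims[["latent"]])
    O <- .decodeW(object@weights, z, object@slope)
    rownames(O) <- rownames(z)
    O
})

## Min-max scale a nonnegative target matrix to [0, 1]; all-constant input
## maps to all zeros. The binary cross-entropy target for reconstruction.
.scaleTargets <- function(M) {
    if (methods::is(M, "NetMFMatrix")) M <- M@values
    lo <- min(M); hi <- max(M)
    if (hi == lo) return(matrix(0, nrow(M), ncol(M)))
    (M - lo) / (hi - lo)
}
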