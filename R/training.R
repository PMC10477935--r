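#' @include losses.R
NULL

## ---- Gradient engine -------------------------------------------------
## Works on plain weight lists. The batch loss is the restriction of the
## full objective to the batch's rows, so summing batch losses over one
## epoch telescopes to the full embedding loss (up to parameter updates
## between batches):
##   alpha * sum_{i in B} BCE_row_i / n
##   - gamma/(2|E|) * sum_{i in B, j} A_ij log clamp cos(z_i, z_j)
##   + omega * sum_{i in B} ||z_i||^2
##   + lambda * (|B|/n) * sum W^2
## Encoding runs over all rows because the first-order term couples batch
## rows to their neighbors' embeddings; decoding only runs on batch rows.
.embedGrad <- function(w, X, Y, edges, lw, batch, slope, eps = 1e-8) {
    n <- nrow(X)
    nB <- length(batch)
    nE <- nrow(edges)
    ## forward (fused in-place kernels; H1/H2 are post-activation, whose
    ## sign also encodes the rectifier gradient mask)
    H1 <- X %*% w$W1
    .addBiasLreluCpp(H1, w$b1, slope)
    Z <- H1 %*% w$W2
    .addBiasCpp(Z, w$b2)
    ZB <- Z[batch, , drop = FALSE]
    H2 <- ZB %*% w$W3
    .addBiasLreluCpp(H2, w$b3, slope)
    O <- H2 %*% w$W4
    .addBiasCpp(O, w$b4)
    YB <- Y[batch, , drop = FALSE]
    ## losses
    lossHighB <- lw$alpha * .bceSumCpp(O, YB) / n
    inB <- logical(n); inB[batch] <- TRUE
    u <- edges[, 1L]; v <- edges[, 2L]
    iIdx <- c(u[inB[u]], v[inB[v]])
    jIdx <- c(v[inB[u]], u[inB[v]])
    k1 <- -lw$gamma / (2 * nE)
    loss1B <- 0
    dZ <- matrix(0, n, ncol(Z))
    if (length(iIdx) && lw$gamma > 0) {
        nrm2 <- rowSums(Z^2)
        dots <- rowSums(Z[iIdx, , drop = FALSE] * Z[jIdx, , drop = FALSE])
        cosv <- dots / sqrt(nrm2[iIdx] * nrm2[jIdx])
        ccl <- pmin(pmax(cosv, eps), 1)
        loss1B <- k1 * sum(log(ccl))
        act <- cosv > eps & cosv < 1
        if (any(act)) {
            ia <- iIdx[act]; ja <- jIdx[act]; da <- dots[act]
            gi <- k1 * (Z[ja, , drop = FALSE] / da -
                        Z[ia, , drop = FALSE] / nrm2[ia])
            gj <- k1 * (Z[ia, , drop = FALSE] / da -
                        Z[ja, , drop = FALSE] / nrm2[ja])
            gAll <- rowsum(rbind(gi, gj), c(ia, ja))
            rows <- as.integer(rownames(gAll))
            dZ[rows, ] <- dZ[rows, ] + gAll
        }
    }
    lossNormB <- lw$omega * sum(ZB^2)
    lossL2B <- lw$lambda * (nB / n) * .l2Weights(w)
    loss <- lossHighB + loss1B + lossNormB + lossL2B
    ## backward (O is overwritten by its own gradient)
    .dLogitsCpp(O, YB, lw$alpha / n)
    dO <- O
    gW4 <- crossprod(H2, dO)
    gb4 <- colSums(dO)
    dH2 <- tcrossprod(dO, w$W4)
    .mulLreluGradCpp(dH2, H2, slope)
    gW3 <- crossprod(ZB, dH2)
    gb3 <- colSums(dH2)
    dZ[batch, ] <- dZ[batch, ] + tcrossprod(dH2, w$W3) + 2 * lw$omega * ZB
    dH1 <- tcrossprod(dZ, w$W2)
    .mulLreluGradCpp(dH1, H1, slope)
    gW2 <- crossprod(H1, dZ)
    gb2 <- colSums(dZ)
    gW1 <- crossprod(X, dH1)
    gb1 <- colSums(dH1)
    sc <- 2 * lw$lambda * (nB / n)
    grads <- list(W1 = gW1 + sc * w$W1, b1 = gb1,
                  W2 = gW2 + sc * w$W2, b2 = gb2,
                  W3 = gW3 + sc * w$W3, b3 = gb3,
                  W4 = gW4 + sc * w$W4, b4 = gb4)
    list(loss = loss, grads = grads)
}

## Cross-training gradient over a batch of anchor pairs. Only encoder
## gradients are produced; gradients flow through (but not into) the
## partner decoders.
.crossGrad <- function(wA, wB, XA, XB, YA, YB, pairs, phi, slopeA, slopeB) {
    oneDir <- function(wEnc, wDec, Xrows, Ytgt, slopeEnc, slopeDec) {
        H1 <- Xrows %*% wEnc$W1
        .addBiasLreluCpp(H1, wEnc$b1, slopeEnc)
        Z <- H1 %*% wEnc$W2
        .addBiasCpp(Z, wEnc$b2)
        H2 <- Z %*% wDec$W3
        .addBiasLreluCpp(H2, wDec$b3, slopeDec)
        O <- H2 %*% wDec$W4
        .addBiasCpp(O, wDec$b4)
        loss <- phi * .bceSumCpp(O, Ytgt) / ncol(O)
        .dLogitsCpp(O, Ytgt, phi / ncol(O))
        dH2 <- tcrossprod(O, wDec$W4)
        .mulLreluGradCpp(dH2, H2, slopeDec)
        dZ <- tcrossprod(dH2, wDec$W3)
        dH1 <- tcrossprod(dZ, wEnc$W2)
        .mulLreluGradCpp(dH1, H1, slopeEnc)
        list(loss = loss,
             grads = list(W1 = crossprod(Xrows, dH1), b1 = colSums(dH1),
                          W2 = crossprod(H1, dZ), b2 = colSums(dZ)))
    }
    d1 <- oneDir(wA, wB, XA[pairs[, 1L], , drop = FALSE],
                 YB[pairs[, 2L], , drop = FALSE], slopeA, slopeB)
    d2 <- oneDir(wB, wA, XB[pairs[, 2L], , drop = FALSE],
                 YA[pairs[, 1L], , drop = FALSE], slopeB, slopeA)
    list(loss = d1$loss + d2$loss, gradsA = d1$grads, gradsB = d2$grads)
}

## ---- Adam optimizer --------------------------------------------------
.adamInit <- function() list(m = list(), v = list(), t = 0L)

## Duplicate a weight list so in-place kernels cannot touch caller memory.
.copyWeights <- function(w) lapply(w, function(x) x + 0)

## Adam with global gradient-norm clipping. The moment buffers and the
## weight tensors are updated in place by the compiled kernel; the caller
## must own them exclusively (fresh from .copyWeights / initAutoencoder).
.adamStep <- function(w, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
    gscale <- 1
    if (!is.null(clip) && is.finite(clip)) {
        nrm <- sqrt(sum(vapply(grads, .sumSquaresCpp, 0)))
        if (nrm > clip) gscale <- clip / nrm
    }
    state$t <- state$t + 1L
    step <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
    for (nm in names(grads)) {
        g <- grads[[nm]]
        if (is.null(state$m[[nm]])) {
            state$m[[nm]] <- numeric(length(g))
            state$v[[nm]] <- numeric(length(g))
        }
        .adamUpdateCpp(w[[nm]], state$m[[nm]], state$v[[nm]], g, gscale,
                       beta1, beta2, step, eps)
    }
    list(w = w, state = state)
}

## ---- Epoch drivers ---------------------------------------------------

## Precomputed per-species training inputs.
.prepSpecies <- function(M, net = NULL) {
    X <- if (methods::is(M, "NetMFMatrix")) M@values else M
    list(X = X, Y = .scaleTargets(X),
         edges = if (is.null(net)) NULL else .edgeIndices(adjacency(net)),
         n = nrow(X))
}

.embedEpoch <- function(w, prep, lw, state, seed, lr, batchSize, clip,
                        slope) {
    perm <- withSeed(seed, sample.int(prep$n))
    starts <- seq(1L, prep$n, by = batchSize)
    total <- 0
    for (s in starts) {
        batch <- perm[s:min(s + batchSize - 1L, prep$n)]
        eg <- .embedGrad(w, prep$X, prep$Y, prep$edges, lw, batch, slope)
        if (!is.finite(eg$loss))
            stop("non-finite embedding loss; training aborted")
        total <- total + eg$loss
        if (lr > 0) {
            up <- .adamStep(w, eg$grads, state, lr = lr, clip = clip)
            w <- up$w
            state <- up$state
        }
    }
    list(w = w, state = state, loss = total)
}

.alignEpoch <- function(wA, wB, prepA, prepB, pairs, phi, stateA, stateB,
                        seed, lr, batchSize, clip, slopeA, slopeB) {
    perm <- withSeed(seed, sample.int(nrow(pairs)))
    starts <- seq(1L, nrow(pairs), by = batchSize)
    total <- 0
    for (s in starts) {
        rows <- perm[s:min(s + batchSize - 1L, nrow(pairs))]
        cg <- .crossGrad(wA, wB, prepA$X, prepB$X, prepA$Y, prepB$Y,
                         pairs[rows, , drop = FALSE], phi, slopeA, slopeB)
        if (!is.finite(cg$loss))
            stop("non-finite alignment loss; training aborted")
        total <- total + cg$loss
        if (lr > 0 && phi > 0) {
            upA <- .adamStep(wA, cg$gradsA, stateA, lr = lr, clip = clip)
            wA <- upA$w; stateA <- upA$state
            upB <- .adamStep(wB, cg$gradsB, stateB, lr = lr, clip = clip)
            wB <- upB$w; stateB <- upB$state
        }
    }
    list(wA = wA, wB = wB, stateA = stateA, stateB = stateB, loss = total)
}

#' One epoch of embedding training
#'
#' Performs one pass over all vertex rows in seeded shuffled mini-batches,
#' taking an adaptive-moment gradient step on the embedding objective per
#' batch. Each batch optimizes the full objective restricted to its rows,
#' so the reported epoch loss is the sum of batch losses.
#'
#' @param ae An \linkS4class{Autoencoder}.
#' @param M Input \linkS4class{NetMFMatrix} (or numeric matrix, e.g. the
#'   adjacency for the ablation mode).
#' @param net The source \linkS4class{PPINetwork}.
#' @param weights \code{\link{lossWeights}}.
#' @param state Optimizer state from a previous call, or \code{NULL}.
#' @param seed Integer seed for the batch shuffle.
#' @param lr Learning rate (0 leaves parameters unchanged).
#' @param batchSize Rows per mini-batch.
#' @param clip Global gradient-norm clip.
#' @return List with \code{ae}, \code{state}, and the epoch \code{loss}.
#' @export
trainEmbedEpoch <- function(ae, M, net, weights = lossWeights(),
                            state = NULL, seed = 1L, lr = 1e-3,
                            batchSize = 128L, clip = 5) {
    prep <- .prepSpecies(M, net)
    if (is.null(state)) state <- .adamInit()
    res <- .embedEpoch(.copyWeights(ae@weights), prep, weights, state, seed,
                       lr, batchSize, clip, ae@slope)
    ae@weights <- res$w
    list(ae = ae, state = res$state, loss = res$loss)
}

#' One epoch of cross-training alignment
#'
#' Iterates over the anchor pairs in seeded mini-batches, stepping the
#' cross-reconstruction loss. Only encoder weights are updated; the
#' decoder weights of both species are bitwise unchanged on return, since
#' the alignment must happen in the latent space rather than the
#' reconstruction space.
#'
#' @param aeA,aeB \linkS4class{Autoencoder} objects.
#' @param MA,MB Input matrices (\linkS4class{NetMFMatrix} or numeric).
#' @param anchors \linkS4class{OrthologAnchors}.
#' @param phi Cross-loss weight.
#' @param stateA,stateB Optimizer states (or \code{NULL}).
#' @param seed Shuffle seed.
#' @param lr Learning rate.
#' @param batchSize Anchor pairs per mini-batch.
#' @param clip Global gradient-norm clip (applied per species).
#' @return List with updated \code{aeA}, \code{aeB}, \code{stateA},
#'   \code{stateB}, and the epoch \code{loss}.
#' @export
trainAlignEpoch <- function(aeA, aeB, MA, MB, anchors, phi = 50,
                            stateA = NULL, stateB = NULL, seed = 1L,
                            lr = 1e-3, batchSize = 128L, clip = 5) {
    if (numAnchors(anchors) == 0L) stop("empty anchor set")
    prepA <- .prepSpecies(MA)
    prepB <- .prepSpecies(MB)
    if (is.null(stateA)) stateA <- .adamInit()
    if (is.null(stateB)) stateB <- .adamInit()
    res <- .alignEpoch(.copyWeights(aeA@weights), .copyWeights(aeB@weights),
                       prepA, prepB, anchorPairs(anchors), phi, stateA,
                       stateB, seed, lr, batchSize, clip, aeA@slope,
                       aeB@slope)
    aeA@weights <- res$wA
    aeB@weights <- res$wB
    list(aeA = aeA, aeB = aeB, stateA = res$stateA, stateB = res$stateB,
         loss = res$loss)
}
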