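#' @include genesets.R
NULL

## Balanced pair standard: keep the given positives, subsample an equal
## number of negative pairs among genes that participate in at least one
## positive pair (mirroring how interaction screens define their
## universe). Returns a data.frame(geneA, geneB, label).
.balancedPairs <- function(positives, seed) {
    pos <- unique(t(apply(positives, 1L, sort)))
    genes <- sort(unique(as.vector(pos)))
    posKey <- paste(pos[, 1L], pos[, 2L])
    nPos <- nrow(pos)
    nGene <- length(genes)
    maxNeg <- nGene * (nGene - 1) / 2 - nPos
    if (maxNeg < nPos)
        stop("not enough non-positive pairs to balance the standard")
    neg <- withSeed(.mixSeed(seed, "sl-negatives"), {
        out <- matrix(character(), 0L, 2L)
        seen <- character()
        while (nrow(out) < nPos) {
            i <- sample(genes, 2L * (nPos - nrow(out)), replace = TRUE)
            j <- sample(genes, 2L * (nPos - nrow(out)), replace = TRUE)
            a <- pmin(i, j); b <- pmax(i, j)
            key <- paste(a, b)
            ok <- a != b & !(key %in% posKey) & !(key %in% seen) &
                !duplicated(key)
            seen <- c(seen, key[ok])
            out <- rbind(out, cbind(a[ok], b[ok]))
        }
        out[seq_len(nPos), , drop = FALSE]
    })
    data.frame(geneA = c(pos[, 1L], neg[, 1L]),
               geneB = c(pos[, 2L], neg[, 2L]),
               label = rep(c(TRUE, FALSE), each = nPos),
               stringsAsFactors = FALSE)
}

## Pair features: elementwise sum of the two genes' embedding rows
## (order-invariant by commutativity).
.pairFeatures <- function(Z, pairs) {
    Z[pairs[, 1L], , drop = FALSE] + Z[pairs[, 2L], , drop = FALSE]
}

## Median-heuristic kernel width for the radial-basis kernel.
.medianGamma <- function(X, seed = 1L, maxRows = 400L) {
    if (nrow(X) > maxRows)
        X <- X[withSeed(.mixSeed(seed, "gamma-sub"),
                        sample.int(nrow(X), maxRows)), , drop = FALSE]
    s <- stats::median(stats::dist(X))
    if (!is.finite(s) || s == 0) return(1 / ncol(X))
    1 / (2 * s^2)
}

## Fit rbf-kernel SVM and return decision scores oriented so larger =
## more likely positive.
.svmScores <- function(Xtr, ytr, Xte, gamma, cost = 1) {
    fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = c("FALSE", "TRUE")),
                      kernel = "radial", gamma = gamma, cost = cost,
                      scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    sgn <- if (startsWith(colnames(dv)[1L], "TRUE")) 1 else -1
    sgn * as.vector(dv)
}

#' Predict genetic interactions from embeddings
#'
#' Evaluates how well latent embeddings predict synthetic-lethality-style
#' gene pairs. The feature of a pair is the elementwise sum of its two
#' embedding rows; a maximum-margin classifier with a radial-basis kernel
#' (width from the median heuristic, regularization \code{cost}) is
#' trained on a balanced standard obtained by subsampling an equal number
#' of non-positive pairs among the genes that participate in at least one
#' positive pair.
#'
#' In \code{within} mode the standard is split into \code{k} folds by
#' gene, never by pair: all of a gene's pairs stay on one side, and pairs
#' spanning folds are excluded entirely. A construction audit verifies
#' that no test-fold gene occurs in any training pair and raises a hard
#' error otherwise. In \code{cross} mode the classifier is trained on one
#' species' standard and evaluated on the other species' standard, both
#' featurized in the joint latent space.
#'
#' @param Z Embedding matrix with gene rownames (within mode), or a list
#'   \code{list(train = , test = )} of two such matrices (cross mode).
#' @param positives Two-column character matrix of positive pairs (within
#'   mode: the single species; cross mode: the training species).
#' @param mode \code{"within"} or \code{"cross"}.
#' @param positivesTest Positive pairs of the evaluation species (cross
#'   mode only).
#' @param k Number of gene-stratified folds (within mode).
#' @param seed Integer seed (negative subsampling, folds, kernel width).
#' @param cost SVM regularization parameter.
#' @return List with \code{auprc}, \code{auroc} (averaged over valid
#'   folds in within mode), \code{perFold} (within mode), and \code{n}
#'   (pairs evaluated).
#' @export
slPredictEval <- function(Z, positives, mode = c("within", "cross"),
                          positivesTest = NULL, k = 5L, seed = 1L,
                          cost = 1) {
    mode <- match.arg(mode)
    if (mode == "cross") {
        if (is.null(positivesTest))
            stop("cross mode needs positivesTest")
        Ztr <- Z$train
        Zte <- Z$test
        std1 <- .balancedPairs(positives, seed = .mixSeed(seed, "train"))
        std2 <- .balancedPairs(positivesTest, seed = .mixSeed(seed, "test"))
        missing1 <- setdiff(unique(c(std1$geneA, std1$geneB)), rownames(Ztr))
        missing2 <- setdiff(unique(c(std2$geneA, std2$geneB)), rownames(Zte))
        if (length(missing1) || length(missing2))
            stop("genes absent from the embedding: ",
                 paste(utils::head(c(missing1, missing2), 3L), collapse = ", "))
        Xtr <- .pairFeatures(Ztr, as.matrix(std1[, 1:2]))
        Xte <- .pairFeatures(Zte, as.matrix(std2[, 1:2]))
        gamma <- .medianGamma(Xtr, seed)
        sc <- .svmScores(Xtr, std1$label, Xte, gamma, cost)
        return(list(auprc = auprcOverRandom(sc, std2$label)$auprc,
                    auroc = aurocScore(sc, std2$label), n = nrow(std2)))
    }
    std <- .balancedPairs(positives, seed = seed)
    genes <- sort(unique(c(std$geneA, std$geneB)))
    missing <- setdiff(genes, rownames(Z))
    if (length(missing))
        stop("genes absent from the embedding: ",
             paste(utils::head(missing, 3L), collapse = ", "))
    folds <- geneStratifiedFolds(genes, k = k, seed = seed)
    fA <- folds$foldA[std$geneA]
    fB <- folds$foldA[std$geneB]
    X <- .pairFeatures(Z, as.matrix(std[, 1:2]))
    perFold <- list()
    for (f in seq_len(k)) {
        te <- fA == f & fB == f
        tr <- fA != f & fB != f & fA == fB
        if (!any(te) || length(unique(std$label[tr])) < 2L) next
        trainGenes <- unique(c(std$geneA[tr], std$geneB[tr]))
        testGenes <- unique(c(std$geneA[te], std$geneB[te]))
        if (length(intersect(trainGenes, testGenes)))
            stop("data leakage: test gene found in training fold")
        gamma <- .medianGamma(X[tr, , drop = FALSE], .mixSeed(seed, paste0("f", f)))
        sc <- .svmScores(X[tr, , drop = FALSE], std$label[tr],
                         X[te, , drop = FALSE], gamma, cost)
        perFold[[length(perFold) + 1L]] <- data.frame(
            fold = f,
            auprc = if (length(unique(std$label[te])) == 2L)
                auprcOverRandom(sc, std$label[te])$auprc else NA_real_,
            auroc = if (length(unique(std$label[te])) == 2L)
                aurocScore(sc, std$label[te]) else NA_real_,
            n = sum(te))
    }
    if (!length(perFold)) stop("no usable folds")
    pf <- do.call(rbind, perFold)
    list(auprc = mean(pf$auprc, na.rm = TRUE),
         auroc = mean(pf$auroc, na.rm = TRUE), perFold = pf,
         n = sum(pf$n))
}
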