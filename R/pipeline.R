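#' @include synthetic.R
NULL

#' Write / read a score matrix as tab-delimited text
#'
#' Rows are species-A genes, columns species-B genes, with a header row
#' and a leading id column.
#'
#' @param S A \linkS4class{ScoreMatrix}.
#' @param path File path.
#' @return \code{writeScoreMatrix} returns \code{path} invisibly;
#'   \code{readScoreMatrix} a \linkS4class{ScoreMatrix}.
#' @export
writeScoreMatrix <- function(S, path) {
    v <- values(S)
    tab <- data.frame(gene = rownames(v), v, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE)
    v <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(v) <- tab[[1L]]
    methods::new("ScoreMatrix", values = v)
}

#' Read a pipeline run configuration from YAML
#'
#' Keys mirror \code{\link{fitJoint}}'s configuration plus input paths:
#' \code{netA}, \code{netB}, \code{anchors}, optional \code{weights} (or
#' \code{weightsA}/\code{weightsB}), \code{blocks}, \code{seed},
#' \code{out}, and any fit-config override (\code{window},
#' \code{negative}, \code{hidden}, \code{latent}, \code{lr},
#' \code{batchSize}, \code{epochsPerBlock}, \code{alignEpochs},
#' \code{adjacencyInput}, \code{crossTraining}).
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

## Hash of the resolved configuration plus the content of the input files;
## stamps outputs and enables idempotent re-run detection.
.configHash <- function(config) {
    paths <- config[c("netA", "netB", "anchors")]
    fileHashes <- vapply(paths, function(p)
        if (!is.null(p) && is.character(p) && file.exists(p))
            .stringHash(paste(readLines(p), collapse = "\n")) else NA_integer_,
        1L)
    flat <- paste(deparse(config[order(names(config))]), collapse = "")
    sprintf("%08x", .stringHash(paste(flat, paste(fileHashes, collapse = ","))))
}

#' Run the full alignment pipeline
#'
#' Read edge lists, preprocess both networks, load anchors, fit the joint
#' embedding, and write the score matrix plus logs into a run directory.
#' Outputs carry the configuration hash; re-running with an unchanged
#' configuration and inputs detects the existing hash and skips the fit.
#'
#' @param config Named list (see \code{\link{readRunConfig}}) or a path to
#'   a YAML file. Required keys: \code{netA}, \code{netB}, \code{anchors}
#'   (file paths), \code{out} (run directory).
#' @return Invisibly, a list with the run directory, the
#'   \linkS4class{JointEmbedding}, the \linkS4class{ScoreMatrix} and the
#'   config hash.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    need <- c("netA", "netB", "anchors", "out")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("pipeline config missing keys: ", paste(miss, collapse = ", "))
    hash <- .configHash(config)
    out <- config$out
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    hashFile <- file.path(out, "config-hash.txt")
    scoreFile <- file.path(out, "scores.tsv")
    if (file.exists(hashFile) && file.exists(scoreFile) &&
        readLines(hashFile)[1L] == hash) {
        message("run directory up to date (hash ", hash, "); skipping")
        return(invisible(list(out = out, hash = hash,
                              scores = readScoreMatrix(scoreFile))))
    }
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    stage <- function(name, expr) tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    rawA <- stage("read", readEdgeList(config$netA))
    rawB <- stage("read", readEdgeList(config$netB))
    ppA <- stage("preprocess", preprocessNetwork(rawA, seed = seed))
    ppB <- stage("preprocess", preprocessNetwork(rawB, seed = seed))
    anchors <- stage("anchors",
                     readAnchorPairs(config$anchors, ppA$network, ppB$network))
    weights <- if (!is.null(config$weightsA))
        list(A = do.call(lossWeights, config$weightsA),
             B = do.call(lossWeights, config$weightsB))
    else if (!is.null(config$weights)) do.call(lossWeights, config$weights)
    else lossWeights()
    fitCfg <- config[intersect(names(config), names(.defaultFitConfig()))]
    blocks <- if (is.null(config$blocks)) 10L else as.integer(config$blocks)
    joint <- stage("fit", fitJoint(ppA$network, ppB$network, anchors,
                                   weights = weights, blocks = blocks,
                                   config = fitCfg, seed = seed))
    S <- stage("score", scoreMatrix(joint))
    writeScoreMatrix(S, scoreFile)
    writeEmb <- function(Z, path) {
        tab <- data.frame(gene = rownames(Z), Z, check.names = FALSE)
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeEmb(latentEmbedding(joint, "A"), file.path(out, "embedding-A.tsv"))
    writeEmb(latentEmbedding(joint, "B"), file.path(out, "embedding-B.tsv"))
    writePreprocessReport(ppA$report, file.path(out, "preprocess-A.tsv"))
    writePreprocessReport(ppB$report, file.path(out, "preprocess-B.tsv"))
    writeEdgeList(ppA$network, file.path(out, "network-A.tsv"))
    writeEdgeList(ppB$network, file.path(out, "network-B.tsv"))
    writeAnchorPairs(anchors, file.path(out, "anchors-used.tsv"))
    jsonlite::write_json(
        list(hash = hash, seed = seed, blocks = blocks,
             droppedAnchors = nrow(anchors@dropped),
             config = joint@config[setdiff(names(joint@config),
                                           c("weightsA", "weightsB"))],
             weightsA = joint@config$weightsA,
             weightsB = joint@config$weightsB,
             trainLog = trainingLog(joint)),
        file.path(out, "run-log.json"), auto_unbox = TRUE, digits = NA)
    writeLines(hash, hashFile)
    invisible(list(out = out, joint = joint, scores = S, hash = hash))
}

#' Write a simulated study to disk
#'
#' Generates a twin network pair with annotations and labeled pairs and
#' writes every artifact as plain text: edge lists, anchors, GAF
#' annotations, ontology table, labeled pairs, and the truth map.
#'
#' @param out Output directory.
#' @param preset Preset name (see \code{\link{twinPreset}}).
#' @param seed Integer seed.
#' @param nTerms,nPos Annotation term and positive-pair counts.
#' @return Invisibly, the list of generated objects.
#' @export
simulateStudy <- function(out, preset = "twin-small", seed = 1L,
                          nTerms = 30L, nPos = 200L) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    pair <- do.call(generateNetworkPair, c(twinPreset(preset),
                                           list(seed = seed)))
    ann <- generateModuleAnnotations(pair$truth, nTerms = nTerms, seed = seed)
    sl <- generateSLPairs(pair$truth, nPos = nPos, seed = seed)
    writeEdgeList(pair$netA, file.path(out, "netA.tsv"))
    writeEdgeList(pair$netB, file.path(out, "netB.tsv"))
    writeAnchorPairs(pair$truth$anchors, file.path(out, "anchors.tsv"))
    writeGAF(ann$annA, file.path(out, "annA.gaf"))
    writeGAF(ann$annB, file.path(out, "annB.gaf"))
    writeOntologyTable(ann$ontology, file.path(out, "ontology.tsv"))
    utils::write.table(pair$truth$trueMap, file.path(out, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sl$A, file.path(out, "slA.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sl$B, file.path(out, "slB.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(list(pair = pair, ann = ann, sl = sl))
}
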