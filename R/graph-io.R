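#' @include AllClasses.R
NULL

## Internal constructor: build a PPINetwork from a 2-column character matrix
## of edges. Dedupes undirected edges, drops self-loops, vertex order is
## first appearance (left column before right column, line by line).
.networkFromEdges <- function(edges, metadata = list()) {
    stopifnot(is.matrix(edges), ncol(edges) == 2L)
    loops <- edges[, 1L] == edges[, 2L]
    metadata$selfLoopsRemoved <- sum(loops)
    edges <- edges[!loops, , drop = FALSE]
    if (nrow(edges) == 0L) stop("empty edge set after removing self-loops")
    ids <- unique(as.vector(t(edges)))
    i <- match(edges[, 1L], ids)
    j <- match(edges[, 2L], ids)
    key <- paste(pmin(i, j), pmax(i, j))
    keep <- !duplicated(key)
    metadata$duplicateEdgesRemoved <- sum(!keep)
    i <- i[keep]; j <- j[keep]
    n <- length(ids)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
    methods::new("PPINetwork", vertexIds = ids, adjacency = A,
                 metadata = metadata)
}

#' Read an undirected network from a delimited edge list
#'
#' Each non-comment line names one edge as two gene identifiers. Self-loops
#' are dropped (counted in the network's metadata), duplicate edges in
#' either orientation are collapsed, and vertices are ordered by first
#' appearance in the file.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter; the default \code{NULL} splits on any
#'   run of whitespace (covers tab-delimited files).
#' @param comment Lines starting with this character are ignored.
#' @return A \linkS4class{PPINetwork}.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc"), f)
#' net <- readEdgeList(f)
#' degrees(net)
#' @export
readEdgeList <- function(path, delimiter = NULL, comment = "#") {
    if (!file.exists(path)) stop("edge-list file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty edge set in ", path)
    split <- if (is.null(delimiter)) "[[:space:]]+" else delimiter
    fields <- strsplit(trimws(lines), split, fixed = FALSE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
        stop(sprintf("malformed edge-list line %d in %s: fewer than 2 fields",
                     lineNo[bad[1L]], path))
    edges <- cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
    if (all(edges[, 1L] == edges[, 2L]))
        stop("empty edge set: all lines are self-loops in ", path)
    .networkFromEdges(edges, metadata = list(source = path))
}

#' Write a network as a tab-delimited edge list
#'
#' @param net A \linkS4class{PPINetwork}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path) {
    e <- edgeList(net)
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## Neighbor sets of every vertex from a sparse symmetric adjacency, as a
## list of increasing integer vectors.
.neighborList <- function(A) {
    A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
    n <- ncol(A)
    lapply(seq_len(n), function(j) {
        if (A@p[j + 1L] > A@p[j]) A@i[(A@p[j] + 1L):A@p[j + 1L]] + 1L
        else integer()
    })
}

#' Preprocess a network for embedding
#'
#' Iterates to a fixpoint: removes degree-0 vertices, then collapses every
#' group of vertices with an identical neighbor set (most commonly
#' degree-1 vertices hanging off the same hub) down to one uniformly
#' random representative. With only topology as input such vertices are
#' indistinguishable to the model, so keeping more than one adds no
#' information. Adjacent vertices never share a neighbor set (self-loops
#' are removed first), so connected pairs are always retained.
#'
#' @param net A valid \linkS4class{PPINetwork}.
#' @param seed Integer seed controlling which group representative is kept.
#' @return A list with components \code{network} (the reduced
#'   \linkS4class{PPINetwork}) and \code{report} (a replayable
#'   \linkS4class{PreprocessReport}).
#' @seealso \code{\link{replayPreprocess}}
#' @export
preprocessNetwork <- function(net, seed = 1L) {
    A <- adjacency(net)
    ids <- vertexIds(net)
    rounds <- list()
    withSeed(.mixSeed(seed, "preprocess"), {
        repeat {
            removedAny <- FALSE
            roundLog <- list(isolated = character(), groups = list())
            deg <- Matrix::rowSums(A)
            iso <- which(deg == 0)
            if (length(iso)) {
                roundLog$isolated <- ids[iso]
                A <- A[-iso, -iso, drop = FALSE]
                ids <- ids[-iso]
                removedAny <- TRUE
            }
            if (length(ids) == 0L) stop("network fully collapsed")
            nb <- .neighborList(A)
            n <- length(ids)
            openKey <- vapply(nb, paste, "", collapse = ",")
            dropIdx <- integer()
            for (grp in split(seq_len(n), openKey)) {
                if (length(grp) < 2L) next
                kept <- grp[sample.int(length(grp), 1L)]
                removed <- setdiff(grp, kept)
                roundLog$groups[[length(roundLog$groups) + 1L]] <-
                    list(kept = ids[kept], removed = ids[removed])
                dropIdx <- c(dropIdx, removed)
                removedAny <- TRUE
            }
            if (length(dropIdx)) {
                A <- A[-dropIdx, -dropIdx, drop = FALSE]
                ids <- ids[-dropIdx]
            }
            if (!removedAny) break
            rounds[[length(rounds) + 1L]] <- roundLog
            if (length(ids) == 0L) stop("network fully collapsed")
        }
    })
    meta <- net@metadata
    loops <- if (is.null(meta$selfLoopsRemoved)) 0L else as.integer(meta$selfLoopsRemoved)
    out <- methods::new("PPINetwork", vertexIds = ids, adjacency = A,
                        metadata = c(meta, list(preprocessed = TRUE)))
    rep <- methods::new("PreprocessReport", selfLoops = loops,
                        rounds = rounds, seed = as.integer(seed))
    list(network = out, report = rep)
}

#' Replay a preprocessing report on a raw network
#'
#' Applies the recorded removals round by round, reproducing the output of
#' \code{\link{preprocessNetwork}} exactly without re-randomizing.
#'
#' @param net The raw \linkS4class{PPINetwork} the report was derived from.
#' @param report A \linkS4class{PreprocessReport}.
#' @return The preprocessed \linkS4class{PPINetwork}.
#' @export
replayPreprocess <- function(net, report) {
    A <- adjacency(net)
    ids <- vertexIds(net)
    for (r in report@rounds) {
        removed <- c(r$isolated,
                     unlist(lapply(r$groups, `[[`, "removed"), use.names = FALSE))
        idx <- match(removed, ids)
        if (anyNA(idx)) stop("report does not match network: unknown vertex")
        if (length(idx)) {
            A <- A[-idx, -idx, drop = FALSE]
            ids <- ids[-idx]
        }
    }
    methods::new("PPINetwork", vertexIds = ids, adjacency = A,
                 metadata = c(net@metadata, list(preprocessed = TRUE)))
}

#' Serialize / read a preprocessing report
#'
#' Tab-delimited log: columns \code{round}, \code{action}
#' (\code{isolated}/\code{duplicate}), \code{kept} and comma-separated
#' \code{removed} ids.
#'
#' @param report A \linkS4class{PreprocessReport}.
#' @param path Output (or input) file path.
#' @return \code{writePreprocessReport} returns \code{path} invisibly;
#'   \code{readPreprocessReport} returns a \linkS4class{PreprocessReport}.
#' @export
writePreprocessReport <- function(report, path) {
    rows <- list(data.frame(round = 0L, action = "self_loops", kept = "",
                            removed = as.character(report@selfLoops)))
    for (i in seq_along(report@rounds)) {
        r <- report@rounds[[i]]
        if (length(r$isolated))
            rows[[length(rows) + 1L]] <- data.frame(
                round = i, action = "isolated", kept = "",
                removed = paste(r$isolated, collapse = ","))
        for (g in r$groups)
            rows[[length(rows) + 1L]] <- data.frame(
                round = i, action = "duplicate", kept = g$kept,
                removed = paste(g$removed, collapse = ","))
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePreprocessReport
#' @export
readPreprocessReport <- function(path) {
    tab <- utils::read.delim(path, colClasses = "character")
    loops <- as.integer(tab$removed[tab$action == "self_loops"][1L])
    if (is.na(loops)) loops <- 0L
    tab <- tab[tab$action != "self_loops", , drop = FALSE]
    rounds <- list()
    for (rn in sort(unique(as.integer(tab$round)))) {
        sub <- tab[as.integer(tab$round) == rn, , drop = FALSE]
        iso <- sub$removed[sub$action == "isolated"]
        iso <- if (length(iso)) strsplit(iso, ",")[[1L]] else character()
        groups <- lapply(which(sub$action == "duplicate"), function(k)
            list(kept = sub$kept[k], removed = strsplit(sub$removed[k], ",")[[1L]]))
        rounds[[length(rounds) + 1L]] <- list(isolated = iso, groups = groups)
    }
    methods::new("PreprocessReport", selfLoops = loops, rounds = rounds,
                 seed = NA_integer_)
}

#' Read ortholog anchor pairs and map them to network indices
#'
#' Reads a two-column tab-delimited file of gene-id pairs (species A id,
#' species B id), drops pairs with either gene absent from the (typically
#' preprocessed) networks, and deduplicates.
#'
#' @param path Path to the anchor file, or a two-column character matrix of
#'   id pairs.
#' @param netA,netB \linkS4class{PPINetwork} objects for the two species.
#' @return An \linkS4class{OrthologAnchors}; dropped pairs are retained in
#'   the \code{dropped} slot.
#' @export
readAnchorPairs <- function(path, netA, netB) {
    if (is.matrix(path)) {
        raw <- path
    } else {
        if (!file.exists(path)) stop("anchor file not found: ", path)
        tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                                 colClasses = "character")
        if (ncol(tab) < 2L) stop("anchor file must have two columns")
        raw <- as.matrix(tab[, 1:2])
    }
    raw <- raw[!duplicated(paste(raw[, 1L], raw[, 2L])), , drop = FALSE]
    i <- match(raw[, 1L], vertexIds(netA))
    j <- match(raw[, 2L], vertexIds(netB))
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) stop("no anchors available for alignment")
    pairs <- cbind(i[ok], j[ok])
    storage.mode(pairs) <- "integer"
    methods::new("OrthologAnchors", pairs = pairs,
                 sourceIds = raw[ok, , drop = FALSE],
                 dropped = raw[!ok, , drop = FALSE])
}

#' Write anchor pairs as a tab-delimited file
#' @param anchors An \linkS4class{OrthologAnchors} or two-column character
#'   matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnchorPairs <- function(anchors, path) {
    m <- if (methods::is(anchors, "OrthologAnchors")) anchors@sourceIds else anchors
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## Content hash of a network: invariant to how it was loaded, sensitive to
## vertex order and edge set. Keys the symmetric randomness scheduler.
.networkHash <- function(net) {
    e <- edgeList(net)
    .stringHash(paste(c(vertexIds(net), paste(e[, 1L], e[, 2L])),
                      collapse = ";"))
}
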