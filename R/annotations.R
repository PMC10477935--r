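#' @include AllClasses.R
NULL

## Build an AnnotationTable from a gene->terms named list.
.annotationFromList <- function(geneToTerms, propagated = FALSE) {
    geneToTerms <- lapply(geneToTerms, function(x) sort(unique(as.character(x))))
    geneToTerms <- geneToTerms[lengths(geneToTerms) > 0L]
    pairsGene <- rep(names(geneToTerms), lengths(geneToTerms))
    pairsTerm <- unlist(geneToTerms, use.names = FALSE)
    termToGenes <- lapply(split(pairsGene, pairsTerm), function(x) sort(unique(x)))
    methods::new("AnnotationTable", geneToTerms = geneToTerms,
                 termToGenes = termToGenes, propagated = propagated)
}

#' Construct an annotation table from gene/term pairs
#'
#' @param genes Character vector of gene ids.
#' @param terms Character vector of term ids (same length as \code{genes}).
#' @param propagated Logical; mark the table as already closed under the
#'   ontology.
#' @return An \linkS4class{AnnotationTable}.
#' @export
annotationTable <- function(genes, terms, propagated = FALSE) {
    stopifnot(length(genes) == length(terms))
    .annotationFromList(split(as.character(terms), as.character(genes)),
                        propagated = propagated)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Standard 17-column Gene Association File. Rows are filtered at read time
#' by ontology aspect and evidence code; qualifiers containing \code{NOT}
#' are always dropped. The defaults keep Biological Process annotations
#' with low-throughput experimental evidence and exclude
#' inferred-from-physical-interaction evidence, which would be circular
#' when the networks themselves are physical interactions.
#'
#' @param path Path to the GAF file (lines starting with \code{!} are
#'   headers).
#' @param aspect Single character; \code{"P"} keeps Biological Process.
#'   \code{NULL} keeps every aspect.
#' @param evidenceAllow Character vector of evidence codes to keep.
#' @param evidenceDeny Codes to drop (applied after the allow list).
#' @param idColumn GAF column holding the gene identifier (2 = DB Object
#'   ID).
#' @return An \linkS4class{AnnotationTable} (not propagated).
#' @export
readGAF <- function(path, aspect = "P",
                    evidenceAllow = c("EXP", "IDA", "IMP", "IGI", "IEP"),
                    evidenceDeny = "IPI", idColumn = 2L) {
    if (!file.exists(path)) stop("GAF file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    if (!length(lines)) stop("no annotation rows in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9L)
    if (length(bad)) stop("malformed GAF row ", bad[1L], " in ", path)
    getCol <- function(k) vapply(fields, `[[`, "", k)
    gene <- getCol(idColumn)
    qualifier <- getCol(4L)
    term <- getCol(5L)
    evidence <- getCol(7L)
    asp <- getCol(9L)
    keep <- !grepl("NOT", qualifier, fixed = TRUE)
    if (!is.null(aspect)) keep <- keep & asp == aspect
    if (!is.null(evidenceAllow)) keep <- keep & evidence %in% evidenceAllow
    if (!is.null(evidenceDeny)) keep <- keep & !(evidence %in% evidenceDeny)
    if (!any(keep)) stop("no annotations pass the aspect/evidence filters")
    annotationTable(gene[keep], term[keep])
}

#' Write an annotation table as a minimal GAF 2.2 file
#'
#' Emits one row per gene/term pair with the given aspect and evidence
#' code; used mainly to round-trip synthetic annotations.
#'
#' @param ann An \linkS4class{AnnotationTable}.
#' @param path Output path.
#' @param aspect,evidence Values for the aspect and evidence columns.
#' @param db Value for the DB column.
#' @return Invisibly, \code{path}.
#' @export
writeGAF <- function(ann, path, aspect = "P", evidence = "IDA",
                     db = "synthetic") {
    g2t <- ann@geneToTerms
    gene <- rep(names(g2t), lengths(g2t))
    term <- unlist(g2t, use.names = FALSE)
    rows <- cbind(db, gene, gene, "", term, "REF:0", evidence, "", aspect,
                  "", "", "protein", "taxon:0000", "20200716", db, "", "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("!gaf-version: 2.2", con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an ontology relation table
#'
#' Three tab-delimited columns: \code{term}, \code{parent},
#' \code{relation}. An OBO file can be reduced to this form with
#' \code{\link{readOBO}}.
#'
#' @param path Path to the table (with header).
#' @return \code{data.frame} with columns term/parent/relation.
#' @export
readOntologyTable <- function(path) {
    tab <- utils::read.delim(path, colClasses = "character")
    need <- c("term", "parent", "relation")
    if (!all(need %in% names(tab)))
        stop("ontology table needs columns: ", paste(need, collapse = ", "))
    tab[need]
}

#' Write an ontology relation table
#' @param ontology \code{data.frame} with columns term/parent/relation.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeOntologyTable <- function(ontology, path) {
    utils::write.table(ontology, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Parse an OBO ontology file to a relation table
#'
#' Minimal parser for \code{[Term]} stanzas: extracts \code{is_a} lines and
#' \code{relationship: part_of} lines. Obsolete terms are skipped.
#'
#' @param path Path to the OBO file.
#' @return \code{data.frame} with columns term/parent/relation.
#' @export
readOBO <- function(path) {
    lines <- readLines(path)
    term <- NA_character_
    inTerm <- FALSE
    obsolete <- FALSE
    rows <- list()
    flush <- function() NULL
    for (ln in lines) {
        ln <- trimws(sub("!.*$", "", ln))
        if (ln == "[Term]") { inTerm <- TRUE; term <- NA; obsolete <- FALSE; next }
        if (grepl("^\\[", ln)) { inTerm <- FALSE; next }
        if (!inTerm || !nzchar(ln)) next
        if (startsWith(ln, "id:")) term <- trimws(sub("^id:", "", ln))
        else if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
        else if (startsWith(ln, "is_a:") && !obsolete)
            rows[[length(rows) + 1L]] <- c(term, trimws(sub("^is_a:", "", ln)), "is_a")
        else if (grepl("^relationship: *part_of ", ln) && !obsolete)
            rows[[length(rows) + 1L]] <-
                c(term, trimws(sub("^relationship: *part_of", "", ln)), "part_of")
    }
    if (!length(rows))
        return(data.frame(term = character(), parent = character(),
                          relation = character()))
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- c("term", "parent", "relation")
    out
}

## Topological order of terms under parent edges; errors naming one cycle.
.topoOrder <- function(terms, parentOf) {
    indeg <- vapply(terms, function(t) sum(vapply(parentOf[[t]], function(p) p %in% terms, TRUE)), 1L)
    ## indeg here counts parents; process terms whose parents are all done.
    done <- character()
    pending <- terms
    order <- character()
    while (length(pending)) {
        ready <- pending[vapply(pending, function(t)
            all(parentOf[[t]] %in% done), TRUE)]
        if (!length(ready)) {
            ## cycle: walk parent links from an arbitrary pending term
            path <- pending[1L]
            cur <- pending[1L]
            repeat {
                nxt <- intersect(parentOf[[cur]], pending)[1L]
                if (nxt %in% path) {
                    cyc <- c(path[which(path == nxt):length(path)], nxt)
                    stop("cycle detected in ontology: ",
                         paste(cyc, collapse = " -> "))
                }
                path <- c(path, nxt)
                cur <- nxt
            }
        }
        done <- c(done, ready)
        order <- c(order, ready)
        pending <- setdiff(pending, ready)
    }
    order
}

#' Propagate annotations through the ontology
#'
#' Closes every gene's term set under ancestor traversal along the declared
#' relations (by default \code{is_a} and \code{part_of}); other relation
#' types are ignored. The ontology restricted to the declared relations
#' must be acyclic.
#'
#' @param ann An \linkS4class{AnnotationTable}.
#' @param ontology \code{data.frame} with columns term/parent/relation.
#' @param relations Relation labels to traverse.
#' @return A propagated \linkS4class{AnnotationTable}.
#' @export
propagateAnnotations <- function(ann, ontology,
                                 relations = c("is_a", "part_of")) {
    ontology <- ontology[ontology$relation %in% relations, , drop = FALSE]
    if (nrow(ontology) == 0L)
        return(.annotationFromList(ann@geneToTerms, propagated = TRUE))
    terms <- unique(c(ontology$term, ontology$parent,
                      unlist(ann@geneToTerms, use.names = FALSE)))
    parentOf <- split(ontology$parent, factor(ontology$term, levels = terms))
    parentOf <- lapply(parentOf, unique)
    ord <- .topoOrder(terms, parentOf)
    ancestors <- stats::setNames(vector("list", length(terms)), terms)
    for (t in ord) {
        ps <- parentOf[[t]]
        ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
    }
    g2t <- lapply(ann@geneToTerms, function(ts)
        unique(c(ts, unlist(ancestors[ts], use.names = FALSE))))
    .annotationFromList(g2t, propagated = TRUE)
}
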