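## Seed plumbing. Every stochastic operation in the package draws from R's
## RNG inside withSeed(), which restores the caller's RNG state afterwards,
## so library code never perturbs a user's random stream. Stage seeds are
## derived from one master seed plus a string tag, which is what makes the
## alignment bidirectional: streams are keyed by content (network hashes),
## never by argument position.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates \code{expr}, and restores the previous
#' RNG state of the calling session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## 31-bit polynomial rolling hash over a character scalar. Used to key
## deterministic per-stage seeds and to give networks a content hash; not
## cryptographic, just stable across sessions and platforms.
.stringHash <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    codes <- utf8ToInt(x)
    p <- 2147483647 # 2^31 - 1
    h <- 0
    ## Horner in chunks keeps the loop short for long strings.
    for (start in seq(1L, length(codes), by = 4096L)) {
        chunk <- codes[start:min(start + 4095L, length(codes))]
        for (cd in chunk) h <- (h * 131 + cd) %% p
    }
    as.integer(h)
}

## Derive a child seed (< 2^31) from a master seed and a string tag.
.mixSeed <- function(seed, tag) {
    .stringHash(paste0(format(as.integer(seed)), "|", tag))
}
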