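# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do not
#' perturb the global random stream.
#'
#' @param seed Integer seed, or NULL to leave the RNG stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(expr)
    }
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            },
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a child seed from a parent seed so pipeline stages get independent but
# reproducible streams.  Kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
    if (is.null(seed)) {
        return(NULL)
    }
    as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

# Jukes-Cantor correction of a proportion of differing sites.  Returns NA when
# the proportion is outside the model's domain (p >= 3/4, saturation).
jcCorrect <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- is.finite(p) & p < 0.75
    out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
    out
}

# Canonical unordered-pair key ("a|b" with a < b lexicographically).
pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

writeTsv <- function(df, path) {
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
    )
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.table(path,
        sep = "\t", header = TRUE, stringsAsFactors = FALSE,
        check.names = FALSE, comment.char = "", quote = "", ...
    )
}

#' Random DNA of a given length
#'
#' Uniform i.i.d. bases, returned as a single character string.  Uses the
#' current RNG stream.
#'
#' @param n Length in bp.
#' @return A character string of length-`n` DNA.
#' @export
randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Duplication mode levels in priority order
#'
#' Highest priority first: WGD > TD > PD > RD > DD > DSD.  `SINGLETON` marks
#' genes with no homology hit at all and never labels a pair.
#'
#' @return Character vector of mode labels in priority order.
#' @export
#' @examples
#' modeLevels()
modeLevels <- function() {
    c("WGD", "TD", "PD", "RD", "DD", "DSD", "SINGLETON")
}
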