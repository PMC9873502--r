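# internal helpers shared across modules

# transparent text reader: plain or gzip, by magic bytes not extension
.readTextLines <- function(path) {
    if (!file.exists(path))
        stop("input file not found: ", path, call. = FALSE)
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
}

.num <- function(x) {
    # stable numeric formatting used by every text writer in the package
    sprintf("%.10g", x)
}

.sanitizeFilename <- function(x) {
    gsub("[^A-Za-z0-9._-]", "_", x)
}

# run an expression with a private RNG state seeded from `seed`,
# restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has)
            old <- get(".Random.seed", envir = globalenv())
        set.seed(as.integer(seed))
        on.exit({
            if (has)
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    force(expr)
}

.stopIfNot <- function(ok, ...) {
    if (!ok) stop(..., call. = FALSE)
}
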