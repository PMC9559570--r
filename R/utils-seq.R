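# Internal character-level sequence helpers. Sequences handled here are
# plain uppercase character scalars; CircularGenome wraps DNAString at the
# API surface.

.seqChr <- function(x) {
    if (is(x, "CircularGenome")) as.character(x@seq)
    else if (is(x, "DNAString") || is(x, "DNAStringSet")) as.character(x)
    else toupper(as.character(x))
}

.revcompChr <- function(s) {
    as.character(reverseComplement(DNAString(s)))
}

# rotate left by `off` characters (0 <= off < nchar)
.rotateLeft <- function(s, off) {
    n <- nchar(s)
    off <- off %% n
    if (off == 0L) return(s)
    paste0(substr(s, off + 1L, n), substr(s, 1L, off))
}

# integer coding: A=1 C=2 G=3 T=4 N=5 (anything else 0)
.CODE <- local({
    v <- integer(256)
    v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
    v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
    v[utf8ToInt("N")] <- 5L
    v
})

.seqToInt <- function(s) .CODE[utf8ToInt(s)]

# complement codes; N (5) maps to 0 so that N never matches anything
.COMP <- c(4L, 3L, 2L, 1L, 0L)

.compInt <- function(code) {
    out <- integer(length(code))
    nz <- code > 0L
    out[nz] <- .COMP[code[nz]]
    out
}

# circular substring: 1-based start, may wrap past the end
.circSubstr <- function(s, start, len) {
    n <- nchar(s)
    start <- ((start - 1L) %% n) + 1L
    if (len > n) stop("requested circular substring longer than sequence")
    if (start + len - 1L <= n) substr(s, start, start + len - 1L)
    else paste0(substr(s, start, n), substr(s, 1L, len - (n - start + 1L)))
}

# do two circular arcs (0-based start, length) on a circle of size L overlap?
.arcsOverlap <- function(s1, l1, s2, l2, L) {
    if (l1 <= 0L || l2 <= 0L) return(FALSE)
    # positions of arc1 relative to s2
    d <- (s1 - s2) %% L
    # arc1 starts within arc2, or arc2 starts within arc1
    d < l2 || ((s2 - s1) %% L) < l1
}

# structured error conditions
.noIRError <- function(msg) {
    stop(structure(class = c("noIRError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

.palindromeError <- function(msg) {
    stop(structure(class = c("palindromeError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}
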