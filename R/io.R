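# FASTA/FASTQ readers and writers (thin wrappers over Biostrings) and
# tabular/JSON report serialization. All human-facing coordinates are
# 1-based inclusive; every TSV carries a header comment saying so.

#' Read a genome from a FASTA file
#'
#' @param path FASTA file; the first record is used (a warning is emitted
#'   if there are more).
#' @param circular topology flag to set on the result.
#' @return a [CircularGenome-class].
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
    if (!file.exists(path)) stop("input not found: ", path)
    x <- readDNAStringSet(path)
    if (!length(x)) stop("no sequences in ", path)
    if (length(x) > 1L)
        warning("using the first of ", length(x), " records in ", path)
    id <- sub("\\s.*", "", names(x)[1L])
    circularGenome(x[[1L]], id = id, circular = circular)
}

#' Write sequences to FASTA
#'
#' @param x a [CircularGenome-class], [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param path output file.
#' @param width line-wrap column (default 70).
#' @return invisibly, `path`.
#' @export
writeFasta <- function(x, path, width = 70L) {
    if (is(x, "CircularGenome")) {
        set <- DNAStringSet(setNames(as.character(genomeSeq(x)),
                                     genomeId(x)))
    } else if (is.character(x)) {
        set <- DNAStringSet(x)
        if (is.null(names(set)))
            names(set) <- paste0("seq", seq_along(set))
    } else set <- x
    writeXStringSet(set, filepath = path, width = as.integer(width))
    invisible(path)
}

#' Read / write reads as FASTQ
#'
#' `writeFastq` writes constant quality (the simulator's error profile is
#' positionally uniform and classification never reads qualities);
#' `readFastq` returns the sequences as a named `DNAStringSet`.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path file path.
#' @return `readFastq`: a named `DNAStringSet`; `writeFastq`: `path`,
#'   invisibly.
#' @export
writeFastq <- function(reads, path) {
    if (is.character(reads)) reads <- DNAStringSet(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    q <- BStringSet(vapply(width(reads),
                           function(w) strrep("I", w), ""))
    x <- QualityScaledDNAStringSet(reads, PhredQuality(q))
    writeQualityScaledXStringSet(x, filepath = path)
    invisible(path)
}

#' @param path file path (for `readFastq`).
#' @rdname writeFastq
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("input not found: ", path)
    readDNAStringSet(path, format = "fastq")
}

#' Tabulate a quadripartite structure
#'
#' @param structure a [QuadripartiteStructure-class].
#' @return a `data.frame` with region, start, end, length (1-based
#'   inclusive coordinates) plus irMismatches on the IR rows.
#' @examples
#' structureReport(quadripartiteStructure(10, 10, 10))
#' @export
structureReport <- function(structure) {
    stopifnot(is(structure, "QuadripartiteStructure"))
    r <- structure@regions
    data.frame(region = toupper(names(r)), start = start(r), end = end(r),
               length = width(r),
               irMismatches = ifelse(grepl("ir", names(r)),
                                     structure@irMismatches, NA_integer_),
               stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV with a coordinate-convention header
#'
#' @param df a `data.frame`.
#' @param path output file.
#' @param comment header comment lines (written with a leading `#`).
#' @return invisibly, `path`.
#' @export
writeTsv <- function(df, path,
                     comment = "coordinates are 1-based inclusive") {
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comment) writeLines(paste0("# ", cm), con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

#' Serialize an OrientationReport to a list / JSON file
#'
#' @param report an [OrientationReport-class].
#' @param path optional output JSON file.
#' @return the report as a named list (invisibly when `path` is given).
#' @export
orientationReportJson <- function(report, path = NULL) {
    stopifnot(is(report, "OrientationReport"))
    x <- list(nForward = report@nForward, nReverse = report@nReverse,
              nAmbiguous = report@nAmbiguous,
              nNonJunction = report@nNonJunction,
              propForward = report@propForward,
              propReverse = report@propReverse,
              ratio = report@ratio, ratioPrinted = report@ratioPrinted,
              ci = list(method = report@ciMethod, level = report@ciLevel,
                        low = report@ciLow, high = report@ciHigh))
    if (!is.null(path)) {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
        return(invisible(x))
    }
    x
}

#' Percent identity in the printed convention
#'
#' Renders a matched/total fraction the way genome papers print identities
#' (e.g. 80505/80565 as 99.93, 447/505 as 89).
#'
#' @param matched,total counts.
#' @param digits decimal places (default 2).
#' @return numeric percentage rounded to `digits`.
#' @examples
#' identityPercent(80505, 80565)      # 99.93
#' identityPercent(447, 505, 0)       # 89
#' @export
identityPercent <- function(matched, total, digits = 2L) {
    round(100 * matched / total, digits)
}
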