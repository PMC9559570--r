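# Pipeline front end: one function per subcommand over the package API,
# plus a dispatcher with structured exit statuses. A thin Rscript wrapper
# (inst/scripts/plastidsv.R) exposes the same subcommands from a shell.

.PIPELINE_KEYS <- c(
    "input", "reads", "sam", "refSsc", "outDir", "seed",
    "k", "minLen", "maxMismatchRate", "minReadLen", "minReadFrac",
    "minIrCover", "minOverhang", "useIr2", "ciLevel",
    "motifF", "motifR", "maxMotifMismatch",
    "minUnit", "maxUnit", "minSupport", "flank",
    "lscLen", "irLen", "sscLen", "pReverse", "pIrDup", "nMolecules",
    "nReads", "readLenMedian", "readLenSigma", "errSub", "errIns", "errDel",
    "embedMotifs", "preset", "verbose")

#' Read and validate a pipeline configuration file
#'
#' The file is a flat key-value YAML subset; unknown keys are rejected and
#' basic range checks applied. Values given in `overrides` (e.g. parsed
#' command-line flags) take precedence.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides named list of values overriding the file.
#' @return a named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
    cfg <- list()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        cfg <- yaml::read_yaml(path)
        if (is.null(cfg)) cfg <- list()
    }
    bad <- setdiff(names(cfg), .PIPELINE_KEYS)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(names(overrides), .PIPELINE_KEYS)
    if (length(bad))
        stop("unknown option(s): ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
    num01 <- c("maxMismatchRate", "minReadFrac", "minIrCover", "ciLevel",
               "pReverse", "pIrDup", "errSub", "errIns", "errDel")
    for (key in intersect(names(cfg), num01)) {
        v <- as.numeric(cfg[[key]])
        if (is.na(v) || v < 0 || v > 1)
            stop("config key ", key, " must be a number in [0, 1]")
        cfg[[key]] <- v
    }
    cfg
}

.cfgGet <- function(cfg, key, default) {
    v <- cfg[[key]]
    if (is.null(v)) default else v
}

#' Run a pipeline subcommand
#'
#' Subcommands: `partition` (detect IRs, write structure TSV/JSON and the
#' canonical FASTA), `flip` (invert the SSC), `haplotypes` (write the F and
#' R haplotype FASTAs), `simulate` (genome + molecule pool + reads +
#' provenance), `classify` (map reads, classify junction reads, write
#' per-read TSV and orientation JSON), `screen` (junction signature verdicts
#' for a multi-FASTA of assemblies), `chimera` (junction/body conflict
#' call), `strscan` (STR loci of the input genome; with reads, copy-number
#' calls), `report` (aggregate prior JSON/TSV outputs into one JSON).
#'
#' @param subcommand one of the names above.
#' @param config named list, e.g. from [readPipelineConfig()]; recognised
#'   keys include `input`, `reads`, `sam`, `refSsc`, `outDir`, `seed` and
#'   the algorithm thresholds (see [readPipelineConfig()]).
#' @return invisibly, an integer exit status: 0 success, 2 missing or
#'   unreadable input, 3 structured no-IR failure.
#' @export
runPipeline <- function(subcommand, config = list()) {
    subcommand <- match.arg(subcommand,
        c("partition", "flip", "haplotypes", "simulate", "classify",
          "screen", "chimera", "strscan", "report"))
    outDir <- .cfgGet(config, "outDir", ".")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    status <- tryCatch({
        switch(subcommand,
               partition = .cmdPartition(config, outDir),
               flip = .cmdFlip(config, outDir),
               haplotypes = .cmdHaplotypes(config, outDir),
               simulate = .cmdSimulate(config, outDir),
               classify = .cmdClassify(config, outDir),
               screen = .cmdScreen(config, outDir),
               chimera = .cmdChimera(config, outDir),
               strscan = .cmdStrscan(config, outDir),
               report = .cmdReport(config, outDir))
        0L
    },
    noIRError = function(e) {
        message("partition failed: ", conditionMessage(e))
        jsonlite::write_json(list(error = "no-IR",
                                  message = conditionMessage(e)),
                             file.path(outDir, "partition_error.json"),
                             auto_unbox = TRUE)
        3L
    },
    missingInputError = function(e) {
        message(conditionMessage(e)); 2L
    })
    invisible(status)
}

.requireInput <- function(config, key = "input") {
    path <- config[[key]]
    if (is.null(path) || !file.exists(path))
        stop(structure(class = c("missingInputError", "error", "condition"),
                       list(message = paste0("missing or unreadable ",
                                             key, ": ",
                                             if (is.null(path)) "<unset>"
                                             else path),
                            call = sys.call(-1))))
    path
}

.loadPartitioned <- function(config) {
    g <- readGenomeFasta(.requireInput(config))
    st <- findInvertedRepeats(g,
        minLen = .cfgGet(config, "minLen", 1000L),
        maxMismatchRate = .cfgGet(config, "maxMismatchRate", 0.001),
        k = .cfgGet(config, "k", 15L))
    canonicalizeGenome(g, st)
}

.cmdPartition <- function(config, outDir) {
    can <- .loadPartitioned(config)
    rep <- structureReport(can$structure)
    writeTsv(rep, file.path(outDir, "structure.tsv"))
    jsonlite::write_json(rep, file.path(outDir, "structure.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeFasta(can$genome, file.path(outDir, "canonical.fasta"))
}

.cmdFlip <- function(config, outDir) {
    can <- .loadPartitioned(config)
    writeFasta(flipSsc(can$genome, can$structure),
               file.path(outDir, "flipped.fasta"))
}

.cmdHaplotypes <- function(config, outDir) {
    can <- .loadPartitioned(config)
    pair <- buildHaplotypePair(can$genome, can$structure)
    writeFasta(DNAStringSet(setNames(
        c(as.character(genomeSeq(hapF(pair))),
          as.character(genomeSeq(hapR(pair)))),
        c(genomeId(hapF(pair)), genomeId(hapR(pair))))),
        file.path(outDir, "haplotypes.fasta"))
}

.simConfigFromPipeline <- function(config) {
    args <- list()
    for (key in c("lscLen", "irLen", "sscLen", "pReverse", "pIrDup",
                  "nMolecules", "nReads", "readLenMedian", "readLenSigma",
                  "errSub", "errIns", "errDel", "embedMotifs",
                  "minReadLen", "preset"))
        if (!is.null(config[[key]])) args[[key]] <- config[[key]]
    do.call(simConfig, args)
}

.cmdSimulate <- function(config, outDir) {
    cfg <- .simConfigFromPipeline(config)
    seed <- as.integer(.cfgGet(config, "seed", 1L))
    sim <- simulateGenome(cfg, seed = seed)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = seed)
    rd <- simulateReads(mols, cfg, seed = seed)
    writeFasta(sim$genome, file.path(outDir, "reference.fasta"))
    writeTsv(structureReport(sim$structure),
             file.path(outDir, "structure.tsv"))
    writeFastq(rd$reads, file.path(outDir, "reads.fastq"))
    writeTsv(rd$provenance, file.path(outDir, "provenance.tsv"),
             comment = c("read provenance (ground truth)",
                         "coordinates are 1-based inclusive"))
    jsonlite::write_json(list(seed = seed,
                              lscLen = cfg@lscLen, irLen = cfg@irLen,
                              sscLen = cfg@sscLen, pReverse = cfg@pReverse,
                              pIrDup = cfg@pIrDup, nReads = cfg@nReads,
                              readLenMedian = cfg@readLenMedian,
                              readLenSigma = cfg@readLenSigma,
                              errSub = cfg@errSub, errIns = cfg@errIns,
                              errDel = cfg@errDel),
                         file.path(outDir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
}

.cmdClassify <- function(config, outDir) {
    can <- .loadPartitioned(config)
    reads <- readFastq(.requireInput(config, "reads"))
    pair <- buildHaplotypePair(can$genome, can$structure)
    calls <- classifyReads(reads, pair,
        minReadLen = .cfgGet(config, "minReadLen", 0L),
        k = .cfgGet(config, "k", 15L),
        minReadFrac = .cfgGet(config, "minReadFrac", 0.90),
        minIrCover = .cfgGet(config, "minIrCover", 1.00),
        minOverhang = .cfgGet(config, "minOverhang", 200L),
        useIr2 = isTRUE(.cfgGet(config, "useIr2", FALSE)))
    writeTsv(calls, file.path(outDir, "junction_calls.tsv"),
             comment = c("per-read junction classification",
                         "overhangs in aligned reference bp flanking IR1"))
    rep <- summarizeOrientation(calls,
                                ciLevel = .cfgGet(config, "ciLevel", 0.95))
    orientationReportJson(rep, file.path(outDir, "orientation.json"))
}

.cmdScreen <- function(config, outDir) {
    path <- .requireInput(config)
    seqs <- readDNAStringSet(path)
    rows <- lapply(seq_along(seqs), function(i) {
        v <- screenJunctionSignature(
            circularGenome(seqs[[i]], id = names(seqs)[i]),
            motifF = .cfgGet(config, "motifF", riceJunctionMotifs()[["F"]]),
            motifR = .cfgGet(config, "motifR", riceJunctionMotifs()[["R"]]),
            maxMismatch = .cfgGet(config, "maxMotifMismatch", 0L),
            minIrLen = .cfgGet(config, "minLen", 1000L))
        cbind(assembly = sub("\\s.*", "", names(seqs)[i]), v)
    })
    writeTsv(do.call(rbind, rows), file.path(outDir, "signature_screen.tsv"))
}

.cmdChimera <- function(config, outDir) {
    can <- .loadPartitioned(config)
    refSsc <- readGenomeFasta(.requireInput(config, "refSsc"),
                              circular = FALSE)
    v <- callChimera(can$genome, can$structure, genomeSeq(refSsc))
    writeTsv(v, file.path(outDir, "chimera.tsv"))
}

.cmdStrscan <- function(config, outDir) {
    can <- .loadPartitioned(config)
    loci <- findSTRLoci(can$genome,
                        minUnit = .cfgGet(config, "minUnit", 1L),
                        maxUnit = .cfgGet(config, "maxUnit", 6L))
    if (!is.null(config$reads)) {
        reads <- readFastq(.requireInput(config, "reads"))
        idx <- buildMapIndex(can$genome, k = .cfgGet(config, "k", 15L))
        alns <- lapply(seq_along(reads), function(i)
            mapRead(as.character(reads[[i]]), idx,
                    readId = names(reads)[i]))
        loci <- strCopyNumbers(loci, reads, alns, can$genome,
                               flank = .cfgGet(config, "flank", 10L),
                               minSupport = .cfgGet(config, "minSupport", 3L))
    }
    writeTsv(loci, file.path(outDir, "str_loci.tsv"))
}

.cmdReport <- function(config, outDir) {
    out <- list()
    tsv <- function(f) if (file.exists(f))
        read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
    f <- file.path(outDir, "structure.tsv")
    if (!is.null(tsv(f))) out$structure <- tsv(f)
    f <- file.path(outDir, "orientation.json")
    if (file.exists(f)) out$orientation <- jsonlite::read_json(f)
    f <- file.path(outDir, "signature_screen.tsv")
    if (!is.null(tsv(f))) out$signatures <- tsv(f)
    f <- file.path(outDir, "str_loci.tsv")
    if (!is.null(tsv(f))) out$strLoci <- tsv(f)
    f <- file.path(outDir, "chimera.tsv")
    if (!is.null(tsv(f))) out$chimera <- tsv(f)
    jsonlite::write_json(out, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
}
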