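# Reading, writing and standardizing annotated chemical series.
#
# Chemical interpretation (SMILES/molblock parsing, canonicalization,
# neutralization, InChI) is delegated to Open Babel; this file only
# handles record bookkeeping, label mapping and the SDF data fields.

.labelMap <- function(raw, where = "label") {
    v <- tolower(trimws(as.character(raw)))
    out <- rep(NA_integer_, length(v))
    out[v %in% c("1", "positive", "pos", "active", "mutagenic")] <- 1L
    out[v %in% c("0", "negative", "neg", "inactive", "nonmutagenic")] <- 0L
    bad <- which(is.na(out))
    if (length(bad))
        stop("unmappable ", where, " value(s): ",
             paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
    out
}

#' Construct an annotated series from SMILES
#'
#' Canonicalizes the SMILES and records parse failures; this is the
#' common entry point used by the readers and the synthetic-data
#' generator.
#'
#' @param ids character record ids (unique)
#' @param smiles character SMILES strings
#' @param labels 0/1 integer labels (or values mappable to them)
#' @param name series name
#' @param groundTruth optional list of generator ground truth
#' @param canonicalize canonicalize SMILES and flag parse failures
#'   (default TRUE)
#' @return an \code{\linkS4class{AnnotatedSeries}}
#' @export
annotatedSeries <- function(ids, smiles, labels, name = "series",
                            groundTruth = list(), canonicalize = TRUE) {
    ids <- as.character(ids)
    smiles <- as.character(smiles)
    stopifnot(length(ids) == length(smiles),
              length(labels) == length(smiles))
    labels <- if (is.numeric(labels)) as.integer(labels)
              else .labelMap(labels)
    if (canonicalize) {
        can <- canonicalSmiles(smiles)
    } else can <- smiles
    parseOk <- !is.na(can) & nzchar(can)
    reason <- ifelse(parseOk, NA_character_, "unparseable structure")
    mols <- data.frame(record_id = ids,
                       smiles = ifelse(parseOk, can, NA_character_),
                       parse_ok = parseOk,
                       failure_reason = reason,
                       stringsAsFactors = FALSE)
    new("AnnotatedSeries", name = name, molecules = mols,
        labels = labels, groundTruth = groundTruth)
}

# ---- SDF reading ----------------------------------------------------------

# Split SDF text into records (molblock text + data fields). Structural
# record delimiting only; molecule interpretation is Open Babel's job.
.splitSDFRecords <- function(lines) {
    ends <- which(trimws(lines) == "$$$$")
    if (!length(ends)) stop("not an SDF: no record terminator found",
                            call. = FALSE)
    starts <- c(1L, head(ends, -1L) + 1L)
    mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

.sdfRecordFields <- function(rec) {
    tags <- grep("^>\\s*<", rec)
    fields <- list()
    for (t in tags) {
        nm <- sub("^>\\s*<([^>]*)>.*$", "\\1", rec[t])
        val <- character()
        i <- t + 1L
        while (i <= length(rec) && nzchar(trimws(rec[i])) &&
               trimws(rec[i]) != "$$$$") {
            val <- c(val, rec[i]); i <- i + 1L
        }
        fields[[nm]] <- paste(val, collapse = "\n")
    }
    fields
}

# molblock records -> canonical SMILES, aligned, NA on failure (same
# prefix-retry strategy as .obBatchLines, over whole records)
.sdfRecordsToSmiles <- function(recs) {
    n <- length(recs)
    res <- rep(NA_character_, n)
    todo <- seq_len(n)
    while (length(todo)) {
        txt <- paste(unlist(recs[todo]), collapse = "\n")
        out <- .obConvert("SDF", "CAN", paste0(txt, "\n"))
        got <- strsplit(out, "\n", fixed = TRUE)[[1]]
        got <- sub("\t.*$", "", got)
        got <- got[!is.na(got)]
        k <- length(got)
        empt <- !nzchar(trimws(got))
        if (any(empt)) { k <- which(empt)[1] - 1L; got <- got[seq_len(k)] }
        if (k >= length(todo)) { res[todo] <- got[seq_along(todo)]; break }
        if (k > 0) res[todo[seq_len(k)]] <- got
        todo <- todo[-seq_len(k + 1L)]
    }
    res
}

#' Read an annotated series
#'
#' Reads either an SDF (V2000) with the activity annotation as a data
#' field, or a delimited SMILES table (CSV/TSV with header columns
#' \code{id,smiles,label}). Labels are mapped to \{0, 1\}
#' (\code{positive}/\code{negative} accepted case-insensitively).
#' Records with unparseable structures are kept with
#' \code{parse_ok = FALSE}; they are never silently dropped.
#'
#' @param path file path; format detected from the extension
#'   (\code{.sdf} vs \code{.csv}/\code{.tsv}/\code{.smi})
#' @param labelField name of the SDF data field (or table column)
#'   holding the activity annotation
#' @param name series name (default: file base name)
#' @param reportFile optional path; excluded/unparseable records are
#'   logged there as a sidecar text report
#' @return an \code{\linkS4class{AnnotatedSeries}}
#' @export
readSeries <- function(path, labelField = "activity", name = NULL,
                       reportFile = NULL) {
    if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("csv", "tsv", "smi", "txt")) {
        sep <- if (ext == "csv") "," else "\t"
        tab <- utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE,
                                 comment.char = "", quote = "\"")
        need <- c("id", "smiles")
        if (!all(need %in% names(tab)))
            stop("SMILES table must have header columns id, smiles, ",
                 "and the label column", call. = FALSE)
        labCol <- if (labelField %in% names(tab)) labelField else "label"
        if (!labCol %in% names(tab))
            stop("label column '", labelField, "' not found in ", path,
                 call. = FALSE)
        ser <- annotatedSeries(tab$id, tab$smiles,
                               .labelMap(tab[[labCol]]), name = name)
    } else {
        lines <- readLines(path, warn = FALSE)
        recs <- .splitSDFRecords(lines)
        titles <- vapply(recs, function(r) trimws(r[1]), character(1))
        fieldsList <- lapply(recs, .sdfRecordFields)
        rawLab <- vapply(seq_along(recs), function(i) {
            f <- fieldsList[[i]]
            if (is.null(f[[labelField]]))
                stop("record ", i, " (", titles[i],
                     ") is missing label field '", labelField, "'",
                     call. = FALSE)
            f[[labelField]]
        }, character(1))
        ids <- ifelse(nzchar(titles), titles,
                      sprintf("rec%04d", seq_along(recs)))
        ids <- make.unique(ids, sep = "_")
        smiles <- .sdfRecordsToSmiles(recs)
        parseOk <- !is.na(smiles) & nzchar(smiles)
        mols <- data.frame(record_id = ids,
                           smiles = ifelse(parseOk, smiles, NA_character_),
                           parse_ok = parseOk,
                           failure_reason = ifelse(parseOk, NA_character_,
                                                   "unparseable structure"),
                           stringsAsFactors = FALSE)
        ser <- new("AnnotatedSeries", name = name, molecules = mols,
                   labels = .labelMap(rawLab, labelField),
                   groundTruth = list())
    }
    bad <- which(!ser@molecules$parse_ok)
    if (length(bad)) {
        msg <- paste0("excluded record ", ser@molecules$record_id[bad],
                      ": ", ser@molecules$failure_reason[bad])
        if (!is.null(reportFile)) writeLines(msg, reportFile)
        warning(length(bad), " record(s) could not be parsed: ",
                paste(ser@molecules$record_id[bad], collapse = ", "),
                call. = FALSE)
    } else if (!is.null(reportFile)) {
        writeLines("no records excluded", reportFile)
    }
    ser
}

#' Write an annotated series
#'
#' Writes SDF (V2000, activity as a data field) or a SMILES table,
#' chosen by file extension. SDF output skips unparseable records (a
#' molblock cannot be produced for them) with a warning; the table
#' format round-trips every record.
#'
#' @param series an \code{\linkS4class{AnnotatedSeries}}
#' @param path output path (\code{.sdf}, \code{.csv} or \code{.tsv})
#' @param labelField data field / column name for the labels
#' @return invisibly, the path
#' @export
writeSeries <- function(series, path, labelField = "activity") {
    stopifnot(is(series, "AnnotatedSeries"))
    mols <- molecules(series)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("csv", "tsv")) {
        tab <- data.frame(id = mols$record_id, smiles = mols$smiles,
                          stringsAsFactors = FALSE)
        tab[[labelField]] <- seriesLabels(series)
        utils::write.table(tab, path, sep = if (ext == "csv") "," else "\t",
                           row.names = FALSE, quote = FALSE)
        return(invisible(path))
    }
    ok <- mols$parse_ok
    if (any(!ok))
        warning(sum(!ok), " unparseable record(s) skipped in SDF output")
    inp <- paste0(mols$smiles[ok], "\t", mols$record_id[ok])
    sdftxt <- .obConvert("SMI", "SDF",
                         paste0(paste(inp, collapse = "\n"), "\n"),
                         options = data.frame(names = "gen2D", args = "",
                                              stringsAsFactors = FALSE))
    lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
    recs <- .splitSDFRecords(lines)
    if (length(recs) != sum(ok))
        stop("internal error: SDF conversion dropped records",
             call. = FALSE)
    labs <- seriesLabels(series)[ok]
    out <- unlist(lapply(seq_along(recs), function(i) {
        r <- recs[[i]]
        end <- which(trimws(r) == "$$$$")[1]
        c(r[seq_len(end - 1L)],
          paste0(">  <", labelField, ">"),
          if (labs[i] == 1L) "positive" else "negative",
          "", "$$$$")
    }))
    writeLines(out, path)
    invisible(path)
}

# largest organic fragment of a (canonical) SMILES: fragments split on
# '.', preferring carbon-containing fragments, then most heavy atoms,
# ties to the first
.fragHeavyCount <- function(frag) {
    brackets <- gregexpr("\\[[^]]*\\]", frag)[[1]]
    nBr <- if (brackets[1] == -1L) 0L else length(brackets)
    rest <- gsub("\\[[^]]*\\]", "", frag)
    nTwo <- length(gregexpr("Cl|Br", rest)[[1]])
    if (gregexpr("Cl|Br", rest)[[1]][1] == -1L) nTwo <- 0L
    rest <- gsub("Cl|Br", "", rest)
    nOne <- nchar(gsub("[^BCNOPSFIbcnops]", "", rest))
    nBr + nTwo + nOne
}

.fragIsOrganic <- function(frag)
    grepl("C|c", gsub("\\[[^]]*\\]", "", frag)) ||
    grepl("\\[[0-9]*[Cc][^a-z]", frag) || grepl("\\[[0-9]*[Cc]\\]", frag)

.largestOrganicFragment <- function(smiles) {
    vapply(smiles, function(s) {
        if (is.na(s)) return(NA_character_)
        frags <- strsplit(s, ".", fixed = TRUE)[[1]]
        if (length(frags) == 1L) return(s)
        organic <- vapply(frags, .fragIsOrganic, logical(1))
        pool <- if (any(organic)) frags[organic] else frags
        pool[which.max(vapply(pool, .fragHeavyCount, integer(1)))]
    }, character(1), USE.NAMES = FALSE)
}

#' Standardize a series
#'
#' Minimal three-step structure standardization: keep the largest
#' organic fragment (stripping salts and solvents), neutralize charges
#' where chemically valid (zwitterionic groups such as nitro are
#' preserved), and canonicalize. Labels are untouched. The operation is
#' idempotent. A molecule destroyed by standardization is kept with
#' \code{parse_ok = FALSE} and a reason.
#'
#' @param series an \code{\linkS4class{AnnotatedSeries}}
#' @return the standardized series
#' @export
standardizeSeries <- function(series) {
    stopifnot(is(series, "AnnotatedSeries"))
    mols <- molecules(series)
    ok <- which(mols$parse_ok)
    if (length(ok)) {
        frag <- .largestOrganicFragment(mols$smiles[ok])
        neut <- .neutralizeSmiles(frag)
        dead <- is.na(neut) | !nzchar(neut)
        mols$smiles[ok] <- ifelse(dead, NA_character_, neut)
        mols$parse_ok[ok][dead] <- FALSE
        mols$failure_reason[ok][dead] <- "destroyed by standardization"
    }
    new("AnnotatedSeries", name = series@name, molecules = mols,
        labels = series@labels, groundTruth = series@groundTruth)
}
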