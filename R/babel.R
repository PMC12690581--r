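# Thin, failure-tolerant layer over ChemmineOB/Open Babel conversions.
#
# Open Babel aborts a multi-molecule conversion at the first unreadable
# record, so batch calls are retried recursively: the converted prefix is
# kept, the offending record is marked NA, and the remainder resubmitted.

.obNoOpts <- data.frame(names = character(), args = character(),
                        stringsAsFactors = FALSE)

.obConvert <- function(from, to, text, options = .obNoOpts) {
    out <- tryCatch(
        ChemmineOB::convertFormat(from, to, text, options = options),
        error = function(e) "")
    if (is.null(out) || !length(out)) "" else out
}

# Convert a vector of single-line inputs (e.g. SMILES) to a vector of
# single-line outputs, aligned with the input; NA where conversion failed.
.obBatchLines <- function(from, to, lines, options = .obNoOpts) {
    n <- length(lines)
    res <- rep(NA_character_, n)
    if (!n) return(res)
    todo <- seq_len(n)
    while (length(todo)) {
        blk <- lines[todo]
        out <- .obConvert(from, to, paste0(paste(blk, collapse = "\n"), "\n"),
                          options = options)
        got <- strsplit(out, "\n", fixed = TRUE)[[1]]
        got <- got[nzchar(trimws(got))]
        k <- length(got)
        if (k >= length(todo)) {
            res[todo] <- got[seq_along(todo)]
            break
        }
        if (k > 0) res[todo[seq_len(k)]] <- got
        # record k+1 failed; continue with the rest
        todo <- todo[-seq_len(k + 1L)]
    }
    res
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with Open Babel. Unparseable inputs give
#' \code{NA}.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES (\code{NA} on failure)
#' @export
canonicalSmiles <- function(smiles) {
    out <- .obBatchLines("SMI", "CAN", smiles)
    sub("\t.*$", "", out)
}

# Neutralize charges where chemically valid (Open Babel --neutralize);
# returns canonical SMILES, NA on failure.
.neutralizeSmiles <- function(smiles) {
    out <- .obBatchLines("SMI", "CAN", smiles,
                         options = data.frame(names = "neutralize",
                                              args = "",
                                              stringsAsFactors = FALSE))
    sub("\t.*$", "", out)
}

#' Standard InChIKeys
#'
#' Computes the 27-character standard InChIKey of each SMILES via the
#' reference InChI implementation bundled with Open Babel.
#'
#' @param smiles character vector of SMILES (or an
#'   \code{\linkS4class{AnnotatedSeries}})
#' @return character vector of InChIKeys; \code{NA} where the structure
#'   could not be parsed
#' @examples
#' \dontrun{inchiKey("CCO")  # "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"}
#' @export
inchiKey <- function(smiles) {
    if (is(smiles, "AnnotatedSeries")) {
        mols <- molecules(smiles)
        keys <- rep(NA_character_, nrow(mols))
        ok <- mols$parse_ok
        if (any(ok)) keys[ok] <- inchiKey(mols$smiles[ok])
        names(keys) <- mols$record_id
        return(keys)
    }
    if (!length(smiles)) return(character())
    if (anyNA(smiles)) {
        out <- rep(NA_character_, length(smiles))
        out[!is.na(smiles)] <- inchiKey(smiles[!is.na(smiles)])
        return(out)
    }
    keys <- .obBatchLines("SMI", "INCHIKEY", smiles)
    keys <- sub("\t.*$", "", keys)
    keys[!is.na(keys) & !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", keys)] <-
        NA_character_
    keys
}

# Parse SMILES into heavy-atom connection tables. Hydrogens are made
# explicit during conversion so that per-atom H counts need no valence
# model, then folded back into an nH column. Returns a list (one entry
# per input, NULL on parse failure) of lists with elements:
#   element (chr), charge (int), nH (int), bonds (matrix i, j, order).
.smilesToGraphs <- function(smiles) {
    n <- length(smiles)
    out <- vector("list", n)
    if (!n) return(out)
    okIdx <- which(!is.na(smiles))
    if (!length(okIdx)) return(out)
    lines <- paste0(smiles[okIdx], "\t", seq_along(okIdx))
    sdftxt <- .obBatchLines2sdf(lines)
    if (is.null(sdftxt)) return(out)
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    writeLines(sdftxt, tmp)
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    ids <- ChemmineR::sdfid(sdfs)
    for (s in seq_along(sdfs)) {
        pos <- suppressWarnings(as.integer(ids[s]))
        if (is.na(pos)) next
        g <- .sdfToGraph(sdfs[[s]])
        if (!is.null(g)) out[[okIdx[pos]]] <- g
    }
    out
}

# SMILES lines -> SDF text with explicit hydrogens; NULL if nothing
# converted. Same prefix-retry strategy as .obBatchLines but on blocks.
.obBatchLines2sdf <- function(lines) {
    optsH <- data.frame(names = c("h", "gen2D"), args = c("", ""),
                        stringsAsFactors = FALSE)
    chunks <- character()
    todo <- lines
    while (length(todo)) {
        out <- .obConvert("SMI", "SDF",
                          paste0(paste(todo, collapse = "\n"), "\n"),
                          options = optsH)
        k <- if (grepl("$$$$", out, fixed = TRUE))
            length(gregexpr("$$$$", out, fixed = TRUE)[[1]]) else 0L
        if (k > 0L) chunks <- c(chunks, out)
        if (k >= length(todo)) break
        todo <- todo[-seq_len(k + 1L)]
    }
    if (!length(chunks)) NULL else paste(chunks, collapse = "\n")
}

# MDL charge-column codes -> formal charges
.mdlChargeMap <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                   `5` = -1L, `6` = -2L, `7` = -3L)

.sdfToGraph <- function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(ab) || nrow(ab) == 0) return(NULL)
    elem <- sub("_.*$", "", rownames(ab))
    chcode <- if (ncol(ab) >= 5) as.character(ab[, 5]) else
        rep("0", nrow(ab))
    charge <- unname(.mdlChargeMap[chcode])
    charge[is.na(charge)] <- 0L
    nb <- if (is.null(bb)) 0L else nrow(bb)
    bi <- if (nb) as.integer(bb[, 1]) else integer()
    bj <- if (nb) as.integer(bb[, 2]) else integer()
    bo <- if (nb) as.integer(bb[, 3]) else integer()
    heavy <- elem != "H"
    idx <- cumsum(heavy)              # old -> new heavy index
    nH <- integer(sum(heavy))
    keep <- logical(nb)
    for (b in seq_len(nb)) {
        hi <- heavy[bi[b]]; hj <- heavy[bj[b]]
        if (hi && hj) keep[b] <- TRUE
        else if (hi && !hj) nH[idx[bi[b]]] <- nH[idx[bi[b]]] + 1L
        else if (!hi && hj) nH[idx[bj[b]]] <- nH[idx[bj[b]]] + 1L
    }
    list(element = elem[heavy], charge = charge[heavy], nH = nH,
         bonds = cbind(i = idx[bi[keep]], j = idx[bj[keep]],
                       order = bo[keep]))
}
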