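# Common-validation-set cleanup: each partner locally flags validation
# compounds present in its training series (by InChIKey, ignoring the
# protonation-sensitive tail, or by Tanimoto similarity of circular
# fingerprints), and the honest broker consolidates the flags. Only
# record ids and booleans cross company boundaries.

#' Ionization-insensitive InChIKey match
#'
#' Compares two standard 27-character InChIKeys on their first 25
#' characters, deliberately ignoring the final two characters, which
#' encode the protonation state and standardization version.
#'
#' @param keyA,keyB 27-character InChIKeys (vectorized, recycled)
#' @return logical
#' @export
inchikeyMatch <- function(keyA, keyB) {
    bad <- nchar(c(keyA, keyB)) != 27L
    if (any(bad, na.rm = TRUE))
        stop("InChIKeys must be 27 characters long", call. = FALSE)
    substr(keyA, 1L, 25L) == substr(keyB, 1L, 25L)
}

#' Tanimoto similarity of two bit vectors
#'
#' |A and B| / |A or B| over the on-bits. Defined as 1 when both
#' vectors are all-zero (with a warning).
#'
#' @param fpA,fpB 0/1 vectors of equal length
#' @return similarity in [0, 1]
#' @export
tanimoto <- function(fpA, fpB) {
    if (length(fpA) != length(fpB))
        stop("fingerprints must have equal length", call. = FALSE)
    both <- sum(fpA == 1L & fpB == 1L)
    either <- sum(fpA == 1L | fpB == 1L)
    if (either == 0L) {
        warning("both fingerprints are empty; similarity defined as 1")
        return(1)
    }
    both / either
}

# all-pairs Tanimoto between rows of two bit matrices (n x bits, m x bits)
.tanimotoMatrix <- function(A, B) {
    common <- A %*% t(B)
    na <- rowSums(A); nb <- rowSums(B)
    union <- outer(na, nb, "+") - common
    sim <- common / union
    sim[union == 0] <- 1
    sim
}

#' Flag validation compounds present in a local training series
#'
#' For each record of \code{cvd}: first check for an
#' ionization-insensitive InChIKey match against any local record; only
#' if there is no exact match, compute the maximum Tanimoto similarity
#' of circular fingerprints (2048 bits, radius 2) against the local
#' series and flag when it reaches \code{threshold}. The best
#' similarity is always reported, also for unflagged records.
#'
#' @param cvd the (standardized) common validation series
#' @param local the (standardized) local training series
#' @param threshold Tanimoto similarity threshold (default 0.95)
#' @return data.frame with columns \code{cvd_record_id}, \code{found},
#'   \code{reason} (\code{inchikey}/\code{tanimoto}/\code{none}) and
#'   \code{best_similarity}
#' @export
flagDuplicates <- function(cvd, local, threshold = 0.95) {
    stopifnot(is(cvd, "AnnotatedSeries"), is(local, "AnnotatedSeries"))
    cm <- molecules(cvd)
    n <- nrow(cm)
    out <- data.frame(cvd_record_id = cm$record_id,
                      found = logical(n),
                      reason = rep("none", n),
                      best_similarity = rep(0, n),
                      stringsAsFactors = FALSE)
    if (!n) return(out)
    lm <- molecules(local)
    lOk <- lm$parse_ok
    if (!nrow(lm) || !any(lOk)) return(out)
    cOk <- cm$parse_ok
    if (any(!cOk))
        warning(sum(!cOk), " unparseable validation record(s) left ",
                "unflagged")
    if (!any(cOk)) return(out)
    keysL <- inchiKey(lm$smiles[lOk])
    skelL <- substr(keysL[!is.na(keysL)], 1L, 25L)
    keysC <- rep(NA_character_, n)
    keysC[cOk] <- inchiKey(cm$smiles[cOk])
    keyHit <- !is.na(keysC) & substr(keysC, 1L, 25L) %in% skelL
    fpC <- morganFingerprints(cvd)
    fpL <- morganFingerprints(local)
    simBest <- rep(0, n)
    if (nrow(fpC@bits) && nrow(fpL@bits)) {
        sim <- .tanimotoMatrix(fpC@bits, fpL@bits)
        simBest[match(fpC@recordIds, cm$record_id)] <-
            apply(sim, 1, max)
    }
    out$best_similarity <- simBest
    out$found <- keyHit | simBest >= threshold
    out$reason <- ifelse(keyHit, "inchikey",
                         ifelse(simBest >= threshold, "tanimoto", "none"))
    out
}

#' Consolidate per-party duplicate flags (honest-broker step)
#'
#' Removes from the validation series the union of all records flagged
#' found by any party and reports per-party and overall counts.
#'
#' @param flagSets list of per-party flag data.frames (as returned by
#'   \code{\link{flagDuplicates}}), covering the same record ids
#' @param cvd the validation series the flags refer to
#' @return list with \code{series} (the cleaned
#'   \code{\linkS4class{AnnotatedSeries}}) and \code{report}
#'   (data.frame of kept/removed counts per party and overall)
#' @export
consolidateFlags <- function(flagSets, cvd) {
    stopifnot(is.list(flagSets), length(flagSets) >= 1L,
              is(cvd, "AnnotatedSeries"))
    ids <- molecules(cvd)$record_id
    for (i in seq_along(flagSets)) {
        f <- flagSets[[i]]
        if (!setequal(f$cvd_record_id, ids) ||
            nrow(f) != length(ids))
            stop("flag set ", i, " does not cover the validation series ",
                 "record ids exactly", call. = FALSE)
    }
    partyNames <- if (!is.null(names(flagSets)) &&
                      all(nzchar(names(flagSets)))) names(flagSets)
                  else paste0("party", seq_along(flagSets))
    foundBy <- vapply(flagSets, function(f)
        ids %in% f$cvd_record_id[f$found], logical(length(ids)))
    if (is.null(dim(foundBy))) foundBy <- matrix(foundBy, nrow = 1)
    removed <- rowSums(foundBy) > 0
    report <- data.frame(
        party = c(partyNames, "overall"),
        flagged = c(colSums(foundBy), sum(removed)),
        kept = length(ids) - c(colSums(foundBy), sum(removed)))
    list(series = cvd[!removed], report = report)
}

#' Read/write duplicate-flag TSV files
#'
#' The exchange format between a party and the broker: record ids,
#' booleans, matching reason and best similarity only — no structures.
#'
#' @param flags a flag data.frame
#' @param path TSV path
#' @return \code{readFlags}: the flag data.frame
#' @export
writeFlags <- function(flags, path) {
    utils::write.table(flags, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeFlags
#' @export
readFlags <- function(path) {
    f <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "logical",
                                          "character", "numeric"))
    names(f) <- c("cvd_record_id", "found", "reason", "best_similarity")
    f
}
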