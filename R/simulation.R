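# End-to-end four-partner collaborative exercise on synthetic data:
# partition -> per-partner dedup flags -> honest-broker consolidation ->
# four local models -> confidential exchange (export/audit/import) ->
# OR / majority / metamodel ensembles -> cutout validation.

#' Concatenate annotated series
#'
#' @param seriesList list of \code{\linkS4class{AnnotatedSeries}}
#' @param name name of the combined series
#' @return an \code{\linkS4class{AnnotatedSeries}}; record ids are
#'   prefixed with the source series name when needed to stay unique
#' @export
combineSeries <- function(seriesList, name = "combined") {
    stopifnot(length(seriesList) >= 1L)
    mols <- lapply(seriesList, molecules)
    ids <- unlist(lapply(mols, `[[`, "record_id"))
    if (anyDuplicated(ids))
        ids <- unlist(lapply(seriesList, function(s)
            paste0(seriesName(s), ":", molecules(s)$record_id)))
    m <- do.call(rbind, mols)
    m$record_id <- ids
    rownames(m) <- NULL
    new("AnnotatedSeries", name = name, molecules = m,
        labels = unlist(lapply(seriesList, seriesLabels)),
        groundTruth = list())
}

#' Run the full four-partner simulation
#'
#' Generates a multi-partner study, runs the deduplication protocol
#' against the shared validation series, trains one local model per
#' partner, exchanges them as audited confidential archives, builds
#' logical-OR, majority-voting and metamodel ensembles, evaluates
#' everything on the cleaned validation series, and validates cutout
#' ensembles on each partner's own series.
#'
#' @param seed master seed; all per-step seeds derive from it
#' @param sizes partner training-series sizes
#' @param cvdSize validation-series size before cleanup
#' @param overlaps planted partner copies inside the validation series
#' @param flipNoise label noise of the generator
#' @param kSelected number of selected features per local model
#' @param outDir optional directory for archives and result tables
#' @param verbose print progress and the metric tables
#' @return list with the partition, flags, cleaned validation series,
#'   local models, archives, member/ensemble/cutout metric tables
#' @export
runCollaborativeSimulation <- function(seed = 1L,
                                       sizes = rep(200L, 4L),
                                       cvdSize = 400L,
                                       overlaps = c(10L, 5L, 0L, 2L),
                                       flipNoise = 0.05,
                                       kSelected = 500L,
                                       outDir = NULL,
                                       verbose = FALSE) {
    say <- function(...) if (verbose) message("[simulation] ", ...)
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    say("generating partner partition")
    part <- generatePartnerPartition(4L, sizes = sizes, cvdSize = cvdSize,
                                     overlapWithCvd = overlaps,
                                     flipNoise = flipNoise, seed = seed)
    partners <- lapply(part$partners, standardizeSeries)
    cvd0 <- standardizeSeries(part$cvd)

    say("deduplicating the validation series")
    flags <- lapply(partners, function(p) flagDuplicates(cvd0, p))
    names(flags) <- LETTERS[seq_along(flags)]
    cons <- consolidateFlags(flags, cvd0)
    cvd <- cons$series

    say("training local models")
    archiveDir <- if (is.null(outDir)) tempfile("qcmsim")
                  else file.path(outDir, "archives")
    dir.create(archiveDir, showWarnings = FALSE, recursive = TRUE)
    models <- vector("list", 4L)
    archives <- character(4L)
    for (i in 1:4) {
        cfg <- modelConfig(kSelected = kSelected, seed = seed + i)
        models[[i]] <- fitPLSDA(partners[[i]], cfg)
        archives[i] <- file.path(archiveDir, paste0(LETTERS[i], ".qcm"))
        exportConfidential(models[[i]], archives[i],
                           originLabel = LETTERS[i])
        audit <- auditArchive(archives[i])
        if (!audit$pass)
            stop("confidential export failed its audit: ",
                 paste(audit$findings, collapse = "; "), call. = FALSE)
    }
    confidential <- lapply(archives, importConfidential)
    names(confidential) <- LETTERS[1:4]

    evalCalls <- function(calls, truth) {
        cc <- confusionCounts(calls, truth)
        c(sensitivity = suppressWarnings(sensitivity(cc)),
          specificity = suppressWarnings(specificity(cc)),
          mcc = suppressWarnings(mcc(cc)))
    }
    yCvd <- seriesLabels(cvd)

    say("evaluating individual models on the cleaned validation series")
    memberPred <- lapply(confidential, function(m)
        .predictLinear(m, cvd)$call)
    memberMetrics <- do.call(rbind, lapply(memberPred, evalCalls,
                                           truth = yCvd))

    say("building and evaluating ensembles")
    ensembles <- list(
        logical_or = buildEnsemble(confidential, "LOGICAL_OR"),
        majority = buildEnsemble(confidential, "MAJORITY"),
        RF = trainMetamodel(confidential, cvd, "RF", seed = seed),
        SVM = trainMetamodel(confidential, cvd, "SVM", seed = seed),
        XGBoost = trainMetamodel(confidential, cvd, "XGBoost",
                                 seed = seed))
    ensembleMetrics <- do.call(rbind, lapply(ensembles, function(e)
        evalCalls(predictEnsemble(e, cvd)$predictions$call, yCvd)))

    say("cutout validation on partner series")
    cutoutMetrics <- do.call(rbind, unlist(lapply(1:4, function(i) {
        lapply(c("logical_or", "majority"), function(rule) {
            ce <- cutout(ensembles[[rule]], LETTERS[i])
            pr <- predictEnsemble(ce, partners[[i]])$predictions$call
            m <- evalCalls(pr, seriesLabels(partners[[i]]))
            data.frame(company = LETTERS[i], method = rule,
                       n = length(partners[[i]]), t(m))
        })
    }), recursive = FALSE))

    if (!is.null(outDir)) {
        utils::write.csv(data.frame(model = rownames(memberMetrics),
                                    memberMetrics),
                         file.path(outDir, "member_metrics.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(ensemble = rownames(ensembleMetrics),
                                    ensembleMetrics),
                         file.path(outDir, "ensemble_metrics.csv"),
                         row.names = FALSE)
        utils::write.csv(cutoutMetrics,
                         file.path(outDir, "cutout_metrics.csv"),
                         row.names = FALSE)
    }
    if (verbose) {
        print(round(memberMetrics, 2))
        print(round(ensembleMetrics, 2))
        print(cbind(cutoutMetrics[1:3],
                    round(cutoutMetrics[4:6], 2)))
    }
    invisible(list(partition = part, partners = partners, flags = flags,
                   dedupReport = cons$report, cvd = cvd,
                   models = models, archives = archives,
                   confidential = confidential, ensembles = ensembles,
                   memberMetrics = memberMetrics,
                   ensembleMetrics = ensembleMetrics,
                   cutoutMetrics = cutoutMetrics))
}
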