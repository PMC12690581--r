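# Confidential model exchange: serialize a fitted model as three
# human-readable text files (modeling parameters, per-feature scaling
# statistics, coefficients) bundled into a single compressed .qcm
# archive, reimport it as a locked model, and audit archives for
# structural leaks.
#
# The archive carries the bare minimum needed to predict: nothing about
# the training molecules except their count survives the export.

.qcmMembers <- c("parameters.txt", "scaler.tsv", "coefficients.tsv")
.num12 <- function(x) sprintf("%.12g", x)

# ---- the three member files ----------------------------------------------

.writeParameters <- function(model, path, originLabel = NULL) {
    cfg <- model@config
    kv <- c(
        format_version = "1",
        n_bits = as.character(cfg@nBits),
        radius = as.character(cfg@radius),
        k_selected = as.character(cfg@kSelected),
        cv_folds = as.character(cfg@cvFolds),
        lv_grid = paste(cfg@lvGrid, collapse = ","),
        threshold_grid = paste(.num12(cfg@thresholdGrid), collapse = ","),
        seed = as.character(cfg@seed),
        n_latent = as.character(model@nLatent),
        threshold = .num12(model@threshold),
        training_size = as.character(model@trainingSize)
    )
    if (!is.null(originLabel)) kv <- c(kv, origin_label = originLabel)
    writeLines(paste(names(kv), "=", kv), path)
}

.writeScaler <- function(model, path) {
    sc <- model@scaling
    writeLines(c("bit_index\tmean\tsd",
                 paste(sc$bit_index, .num12(sc$mean), .num12(sc$sd),
                       sep = "\t")), path)
}

.writeCoefficients <- function(model, path) {
    sc <- model@scaling
    writeLines(c("bit_index\tcoefficient",
                 paste(sc$bit_index, .num12(model@coefficients),
                       sep = "\t"),
                 paste("intercept", .num12(model@intercept), sep = "\t")),
               path)
}

.parseKV <- function(lines, file) {
    ok <- grepl("^[a-z_]+ = .*$", lines)
    if (any(!ok))
        stop("malformed line ", which(!ok)[1], " in ", file, ": '",
             lines[which(!ok)[1]], "'", call. = FALSE)
    kv <- sub("^([a-z_]+) = (.*)$", "\\1\x01\\2", lines)
    parts <- strsplit(kv, "\x01", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, character(1), 2),
                    vapply(parts, `[`, character(1), 1))
}

.parseNum <- function(x, what, file) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
        stop("non-numeric ", what, " in ", file, call. = FALSE)
    v
}

# ---- archive container ----------------------------------------------------

# write the three member files for `model` into a .qcm (gzipped tar)
.writeQcm <- function(model, path, originLabel) {
    staging <- tempfile("qcm")
    dir.create(staging)
    on.exit(unlink(staging, recursive = TRUE))
    .writeParameters(model, file.path(staging, "parameters.txt"),
                     originLabel = originLabel)
    .writeScaler(model, file.path(staging, "scaler.tsv"))
    .writeCoefficients(model, file.path(staging, "coefficients.tsv"))
    # fixed timestamps make the archive reproducible byte-for-byte
    epoch <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
    for (f in .qcmMembers) Sys.setFileTime(file.path(staging, f), epoch)
    # anchor relative output paths before changing directory
    path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                      basename(path))
    owd <- setwd(staging)
    on.exit(setwd(owd), add = TRUE, after = FALSE)
    utils::tar(path, files = .qcmMembers, compression = "gzip",
               tar = "internal")
    invisible(path)
}

.readQcmMembers <- function(path) {
    if (!file.exists(path))
        stop("archive not found: ", path, call. = FALSE)
    ex <- tempfile("qcmx")
    dir.create(ex)
    members <- tryCatch(utils::untar(path, list = TRUE, tar = "internal"),
                        error = function(e)
                            stop("not a readable model archive: ", path,
                                 call. = FALSE))
    utils::untar(path, exdir = ex, tar = "internal")
    list(dir = ex, members = sort(members))
}

# ---- export / import ------------------------------------------------------

#' Export a model as a confidential archive
#'
#' Writes a single compressed \code{.qcm} file containing exactly
#' \code{parameters.txt}, \code{scaler.tsv} and \code{coefficients.tsv},
#' all human-readable text. The training-series reference and every
#' piece of structural provenance are omitted; only the training-series
#' size (needed for chemical-space visualization) is retained. Exports
#' of the same model are byte-identical.
#'
#' @param model a fitted \code{\linkS4class{LocalModel}} (open lock)
#' @param path output path (conventionally ending in \code{.qcm})
#' @param originLabel anonymized origin token stored in the archive
#'   (default "A")
#' @return invisibly, the path
#' @export
exportConfidential <- function(model, path, originLabel = "A") {
    if (!is(model, "LocalModel"))
        stop("only fitted open (LocalModel) models can be exported",
             call. = FALSE)
    if (!length(model@coefficients))
        stop("model is not fitted", call. = FALSE)
    .writeQcm(model, path, originLabel = originLabel)
}

#' Import a confidential archive
#'
#' Reconstructs a locked \code{\linkS4class{ConfidentialModel}} from a
#' \code{.qcm} archive. The model predicts exactly like the original
#' (identical calls, scores equal to the serialized precision), but no
#' depiction of the training structures is possible by construction:
#' the archive never contained them.
#'
#' @param path path to a \code{.qcm} archive
#' @return a \code{\linkS4class{ConfidentialModel}}
#' @export
importConfidential <- function(path) {
    x <- .readQcmMembers(path)
    on.exit(unlink(x$dir, recursive = TRUE))
    if (!identical(x$members, sort(.qcmMembers)))
        stop("archive must contain exactly ",
             paste(.qcmMembers, collapse = ", "), "; found: ",
             paste(x$members, collapse = ", "), call. = FALSE)
    kv <- .parseKV(readLines(file.path(x$dir, "parameters.txt")),
                   "parameters.txt")
    need <- c("n_bits", "radius", "k_selected", "cv_folds", "lv_grid",
              "threshold_grid", "seed", "n_latent", "threshold",
              "training_size")
    miss <- setdiff(need, names(kv))
    if (length(miss))
        stop("parameters.txt is missing key(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    cfg <- modelConfig(
        nBits = .parseNum(kv["n_bits"], "n_bits", "parameters.txt"),
        radius = .parseNum(kv["radius"], "radius", "parameters.txt"),
        kSelected = .parseNum(kv["k_selected"], "k_selected",
                              "parameters.txt"),
        cvFolds = .parseNum(kv["cv_folds"], "cv_folds", "parameters.txt"),
        lvGrid = .parseNum(strsplit(kv["lv_grid"], ",")[[1]], "lv_grid",
                           "parameters.txt"),
        thresholdGrid = .parseNum(strsplit(kv["threshold_grid"], ",")[[1]],
                                  "threshold_grid", "parameters.txt"),
        seed = .parseNum(kv["seed"], "seed", "parameters.txt"))

    scLines <- readLines(file.path(x$dir, "scaler.tsv"))
    if (length(scLines) < 2L || scLines[1] != "bit_index\tmean\tsd")
        stop("scaler.tsv: missing or malformed header line 1",
             call. = FALSE)
    scParts <- strsplit(scLines[-1], "\t", fixed = TRUE)
    if (any(lengths(scParts) != 3L))
        stop("scaler.tsv: malformed line ",
             which(lengths(scParts) != 3L)[1] + 1L, call. = FALSE)
    sc <- data.frame(
        bit_index = as.integer(.parseNum(vapply(scParts, `[`, "", 1),
                                         "bit_index", "scaler.tsv")),
        mean = .parseNum(vapply(scParts, `[`, "", 2), "mean",
                         "scaler.tsv"),
        sd = .parseNum(vapply(scParts, `[`, "", 3), "sd", "scaler.tsv"))

    cfLines <- readLines(file.path(x$dir, "coefficients.tsv"))
    if (length(cfLines) < 3L || cfLines[1] != "bit_index\tcoefficient")
        stop("coefficients.tsv: missing or malformed header line 1",
             call. = FALSE)
    cfParts <- strsplit(cfLines[-1], "\t", fixed = TRUE)
    if (any(lengths(cfParts) != 2L))
        stop("coefficients.tsv: malformed line ",
             which(lengths(cfParts) != 2L)[1] + 1L, call. = FALSE)
    keys <- vapply(cfParts, `[`, "", 1)
    if (keys[length(keys)] != "intercept")
        stop("coefficients.tsv: final line must carry the intercept ",
             "(file truncated?)", call. = FALSE)
    intercept <- .parseNum(cfParts[[length(cfParts)]][2], "intercept",
                           "coefficients.tsv")
    cfIdx <- as.integer(.parseNum(keys[-length(keys)], "bit_index",
                                  "coefficients.tsv"))
    cfVal <- .parseNum(vapply(cfParts[-length(cfParts)], `[`, "", 2),
                       "coefficient", "coefficients.tsv")
    if (!identical(cfIdx, sc$bit_index))
        stop("coefficient/scaling feature indices do not match between ",
             "scaler.tsv and coefficients.tsv", call. = FALSE)
    origin <- if ("origin_label" %in% names(kv)) unname(kv["origin_label"])
              else "unknown"
    new("ConfidentialModel",
        config = cfg, scaling = sc, coefficients = cfVal,
        intercept = intercept,
        threshold = .parseNum(kv["threshold"], "threshold",
                              "parameters.txt"),
        nLatent = as.integer(.parseNum(kv["n_latent"], "n_latent",
                                       "parameters.txt")),
        trainingSize = as.integer(.parseNum(kv["training_size"],
                                            "training_size",
                                            "parameters.txt")),
        originLabel = origin)
}

#' @rdname predict-PLSLinearModel-method
#' @param cmodel a \code{\linkS4class{ConfidentialModel}}
#' @param series an \code{\linkS4class{AnnotatedSeries}}
#' @export
predictConfidential <- function(cmodel, series) {
    stopifnot(is(cmodel, "ConfidentialModel"))
    .predictLinear(cmodel, series)
}

# ---- audit ----------------------------------------------------------------

.structureTokenFindings <- function(tokens, file) {
    findings <- character()
    for (tok in unique(tokens)) {
        if (!nzchar(tok)) next
        if (grepl("^[-+]?[0-9.eE+-]+$", tok)) next        # plain number
        if (grepl("InChI=", tok, fixed = TRUE))
            findings <- c(findings, paste0(file, ": InChI string '",
                                           tok, "'"))
        if (grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", tok))
            findings <- c(findings, paste0(file, ": InChIKey '", tok, "'"))
        if (grepl("V2000|V3000|^M  END$|\\$\\$\\$\\$", tok))
            findings <- c(findings, paste0(file,
                                           ": molblock signature '",
                                           tok, "'"))
        # anything that Open Babel reads as a multi-atom structure
        if (grepl("^[A-Za-z0-9@+\\-\\[\\]()=#$%./\\\\]+$", tok)) {
            can <- suppressWarnings(canonicalSmiles(tok))
            if (!is.na(can) && nzchar(can) &&
                .fragHeavyCount(can) >= 2L)
                findings <- c(findings,
                              paste0(file, ": token '", tok,
                                     "' parses as a chemical structure"))
        }
    }
    findings
}

#' Audit a confidential archive
#'
#' Verifies the member list, the line grammar of every member, the
#' cross-file consistency of feature indices, and the absence of any
#' token that looks like structural information (SMILES, InChI,
#' InChIKey, molblock signatures). Failures are reported as findings,
#' never as errors.
#'
#' @param path path to a \code{.qcm} archive
#' @return list with elements \code{pass} (logical) and
#'   \code{findings} (character vector of problems; empty on pass)
#' @export
auditArchive <- function(path) {
    findings <- character()
    x <- tryCatch(.readQcmMembers(path), error = function(e)
        conditionMessage(e))
    if (is.character(x))
        return(list(pass = FALSE, findings = x))
    on.exit(unlink(x$dir, recursive = TRUE))
    if (!identical(x$members, sort(.qcmMembers)))
        findings <- c(findings,
                      paste0("member list is {",
                             paste(x$members, collapse = ", "),
                             "}, expected {",
                             paste(.qcmMembers, collapse = ", "), "}"))
    readMember <- function(f) {
        p <- file.path(x$dir, f)
        if (file.exists(p)) readLines(p) else NULL
    }
    parKeys <- c("format_version", "n_bits", "radius", "k_selected",
                 "cv_folds", "lv_grid", "threshold_grid", "seed",
                 "n_latent", "threshold", "training_size", "origin_label")
    par <- readMember("parameters.txt")
    scIdx <- cfIdx <- integer()
    if (!is.null(par)) {
        bad <- !grepl("^[a-z_]+ = .*$", par)
        for (b in which(bad))
            findings <- c(findings, paste0("parameters.txt line ", b,
                                           ": not a 'key = value' line: '",
                                           par[b], "'"))
        if (!all(bad)) {
            kv <- .parseKV(par[!bad], "parameters.txt")
            unknown <- setdiff(names(kv), parKeys)
            for (u in unknown)
                findings <- c(findings,
                              paste0("parameters.txt: unknown key '", u,
                                     "'"))
            vals <- unlist(strsplit(unname(kv), ","))
            findings <- c(findings,
                          .structureTokenFindings(vals, "parameters.txt"))
        }
    }
    sc <- readMember("scaler.tsv")
    if (!is.null(sc)) {
        if (!length(sc) || sc[1] != "bit_index\tmean\tsd")
            findings <- c(findings, "scaler.tsv: malformed header")
        body <- if (length(sc) > 1) sc[-1] else character()
        badRow <- !grepl("^[0-9]+\t[-+0-9.eE]+\t[-+0-9.eE]+$", body)
        for (b in which(badRow))
            findings <- c(findings, paste0("scaler.tsv line ", b + 1L,
                                           ": malformed row: '", body[b],
                                           "'"))
        if (!all(badRow))
            scIdx <- as.integer(sub("\t.*", "", body[!badRow]))
        findings <- c(findings,
                      .structureTokenFindings(
                          unlist(strsplit(body[badRow], "\t")),
                          "scaler.tsv"))
    }
    cf <- readMember("coefficients.tsv")
    if (!is.null(cf)) {
        if (!length(cf) || cf[1] != "bit_index\tcoefficient")
            findings <- c(findings, "coefficients.tsv: malformed header")
        body <- if (length(cf) > 1) cf[-1] else character()
        isIntercept <- grepl("^intercept\t[-+0-9.eE]+$", body)
        badRow <- !grepl("^[0-9]+\t[-+0-9.eE]+$", body) & !isIntercept
        for (b in which(badRow))
            findings <- c(findings, paste0("coefficients.tsv line ",
                                           b + 1L, ": malformed row: '",
                                           body[b], "'"))
        if (sum(isIntercept) != 1L || !isIntercept[length(body)])
            findings <- c(findings, paste0("coefficients.tsv: exactly ",
                          "one final intercept line required"))
        good <- !badRow & !isIntercept
        if (any(good))
            cfIdx <- as.integer(sub("\t.*", "", body[good]))
        findings <- c(findings,
                      .structureTokenFindings(
                          unlist(strsplit(body[badRow], "\t")),
                          "coefficients.tsv"))
    }
    if (length(scIdx) && length(cfIdx) && !identical(scIdx, cfIdx))
        findings <- c(findings, paste0("feature indices differ between ",
                      "scaler.tsv and coefficients.tsv"))
    list(pass = length(findings) == 0L, findings = findings)
}

# ---- open-model directory format ------------------------------------------

#' Save / load an open local model as a directory
#'
#' The on-disk form of an open model is the same three text files as a
#' confidential export plus the training-series reference that the
#' export deliberately omits.
#'
#' @param model a \code{\linkS4class{LocalModel}}
#' @param dir directory to create
#' @return invisibly, \code{dir}
#' @export
saveLocalModel <- function(model, dir) {
    stopifnot(is(model, "LocalModel"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    .writeParameters(model, file.path(dir, "parameters.txt"))
    .writeScaler(model, file.path(dir, "scaler.tsv"))
    .writeCoefficients(model, file.path(dir, "coefficients.tsv"))
    writeLines(paste("training_series =", model@provenance),
               file.path(dir, "training_series.txt"))
    invisible(dir)
}

#' @rdname saveLocalModel
#' @export
loadLocalModel <- function(dir) {
    need <- file.path(dir, c(.qcmMembers, "training_series.txt"))
    if (!all(file.exists(need)))
        stop("not a model directory (expected ",
             paste(basename(need), collapse = ", "), "): ", dir,
             call. = FALSE)
    staging <- tempfile(fileext = ".qcm")
    owd <- setwd(dir)
    on.exit(setwd(owd))
    utils::tar(staging, files = .qcmMembers, compression = "gzip",
               tar = "internal")
    setwd(owd)
    cm <- importConfidential(staging)
    unlink(staging)
    prov <- sub("^training_series = ", "",
                readLines(file.path(dir, "training_series.txt"))[1])
    new("LocalModel", config = cm@config, scaling = cm@scaling,
        coefficients = cm@coefficients, intercept = cm@intercept,
        threshold = cm@threshold, nLatent = cm@nLatent,
        trainingSize = cm@trainingSize, provenance = prov,
        cvSummary = data.frame())
}
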