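# Approximate chemical-space coverage for locked models: synthetic
# descriptor objects drawn from the stored per-feature means/SDs,
# projected together with a predicted series onto a 2-component PCA
# plane. Only aggregate statistics are involved; no structures.

#' Synthetic descriptor cloud of a confidential model
#'
#' Draws as many synthetic objects as the model's training-series size,
#' one column per selected feature, from Normal(mean, sd) with the
#' stored scaling statistics (in original, unscaled descriptor units).
#' Columns with sd = 0 are constant at their mean. The cloud is a
#' function of (means, SDs, training size, seed) only — identical
#' statistics give identical draws, whatever molecules produced them.
#'
#' @param cmodel a \code{\linkS4class{ConfidentialModel}} (a
#'   \code{\linkS4class{LocalModel}} is also accepted)
#' @param seed integer seed
#' @return list with \code{originLabel}, \code{count} and \code{values}
#'   (count x k matrix, columns named by bit index)
#' @export
generateSyntheticObjects <- function(cmodel, seed = 1L) {
    stopifnot(is(cmodel, "PLSLinearModel"))
    n <- cmodel@trainingSize
    if (is.na(n) || n < 1L)
        stop("model carries no training size", call. = FALSE)
    sc <- cmodel@scaling
    values <- .withSeed(seed, {
        m <- matrix(stats::rnorm(n * nrow(sc)), nrow = n, byrow = FALSE)
        sweep(sweep(m, 2, sc$sd, "*"), 2, sc$mean, "+")
    })
    colnames(values) <- as.character(sc$bit_index)
    origin <- if (is(cmodel, "ConfidentialModel")) cmodel@originLabel
              else "local"
    list(originLabel = origin, count = n, values = values)
}

# scores of the predicted series + one cloud in a single model's scaled
# feature space
.projectOne <- function(model, fp, mols, labels, cloud) {
    sc <- model@scaling
    Z <- .applyScaler(fp@bits[, sc$bit_index + 1L, drop = FALSE], sc)
    pca <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = 2)
    vartot <- sum(pca$sdev^2)
    explained <- if (vartot > 0) sum(pca$sdev[1:2]^2) / vartot else 1
    predScores <- pca$x[, 1:2, drop = FALSE]
    rows <- match(fp@recordIds, mols$record_id)
    predDF <- data.frame(record_id = fp@recordIds,
                         synthetic = FALSE,
                         pc1 = predScores[, 1], pc2 = predScores[, 2],
                         label = labels[rows],
                         stringsAsFactors = FALSE)
    cloudDF <- NULL
    if (!is.null(cloud)) {
        Zc <- .applyScaler(cloud$values, sc)
        cs <- stats::predict(pca, Zc)[, 1:2, drop = FALSE]
        cloudDF <- data.frame(record_id = paste0("synthetic_",
                                                 seq_len(nrow(cs))),
                              synthetic = TRUE,
                              pc1 = cs[, 1], pc2 = cs[, 2],
                              label = NA_integer_,
                              stringsAsFactors = FALSE)
    }
    list(coordinates = rbind(predDF, cloudDF), explained = explained)
}

#' Project a predicted series and synthetic clouds onto PCA planes
#'
#' For each member model, the predicted series' selected features are
#' scaled with that model's stored statistics, a 2-component PCA is
#' fitted on these scaled descriptors, and the model's synthetic cloud
#' is projected onto the same plane (scaled with the same statistics).
#' A pooled view concatenating the per-model scaled blocks is also
#' produced; in it, each cloud occupies its own block with the other
#' blocks at 0 (the scaled-space mean). The pooled construction is an
#' approximation and labeled as such.
#'
#' @param models a named list of models (or an
#'   \code{\linkS4class{EnsembleModel}}, whose members are used)
#' @param predicted the predicted \code{\linkS4class{AnnotatedSeries}}
#'   (at least 3 parseable compounds)
#' @param clouds named list of clouds from
#'   \code{\link{generateSyntheticObjects}}, one per model (generated
#'   automatically when NULL)
#' @param seed seed used when clouds are generated here
#' @param pooled also compute the pooled all-model view (default TRUE)
#' @return list with \code{perModel} (named list of
#'   \code{list(coordinates, explained)}) and optionally \code{pooled}
#' @export
projectChemicalSpace <- function(models, predicted, clouds = NULL,
                                 seed = 1L, pooled = TRUE) {
    if (is(models, "EnsembleModel")) models <- members(models)
    if (is(models, "PLSLinearModel")) models <- list(model = models)
    stopifnot(is.list(models), is(predicted, "AnnotatedSeries"))
    mols <- molecules(predicted)
    labels <- seriesLabels(predicted)
    cfg <- models[[1]]@config
    fp <- morganFingerprints(predicted, nBits = cfg@nBits,
                             radius = cfg@radius)
    if (nrow(fp@bits) < 3L)
        stop("at least 3 parseable predicted compounds required",
             call. = FALSE)
    if (is.null(clouds))
        clouds <- lapply(models, generateSyntheticObjects, seed = seed)
    stopifnot(length(clouds) == length(models))
    perModel <- lapply(seq_along(models), function(i)
        .projectOne(models[[i]], fp, mols, labels, clouds[[i]]))
    names(perModel) <- names(models)
    out <- list(perModel = perModel)
    if (pooled && length(models) > 1L) {
        blocks <- lapply(models, function(m) {
            sc <- m@scaling
            .applyScaler(fp@bits[, sc$bit_index + 1L, drop = FALSE], sc)
        })
        Zall <- do.call(cbind, blocks)
        pca <- stats::prcomp(Zall, center = TRUE, scale. = FALSE,
                             rank. = 2)
        vartot <- sum(pca$sdev^2)
        offsets <- c(0, cumsum(vapply(blocks, ncol, integer(1))))
        rows <- match(fp@recordIds, mols$record_id)
        coords <- data.frame(record_id = fp@recordIds,
                             synthetic = FALSE, origin = "predicted",
                             pc1 = pca$x[, 1], pc2 = pca$x[, 2],
                             label = labels[rows],
                             stringsAsFactors = FALSE)
        for (i in seq_along(models)) {
            sc <- models[[i]]@scaling
            Zc <- matrix(0, nrow(clouds[[i]]$values), ncol(Zall))
            Zc[, (offsets[i] + 1L):offsets[i + 1L]] <-
                .applyScaler(clouds[[i]]$values, sc)
            cs <- stats::predict(pca, Zc)[, 1:2, drop = FALSE]
            coords <- rbind(coords, data.frame(
                record_id = paste0(names(models)[i], "_synthetic_",
                                   seq_len(nrow(cs))),
                synthetic = TRUE, origin = names(models)[i],
                pc1 = cs[, 1], pc2 = cs[, 2], label = NA_integer_,
                stringsAsFactors = FALSE))
        }
        out$pooled <- list(coordinates = coords,
                           explained = if (vartot > 0)
                               sum(pca$sdev[1:2]^2) / vartot else 1,
                           note = "approximate pooled construction")
    }
    out
}

#' Write projection coordinates as CSV
#'
#' @param projection result of \code{\link{projectChemicalSpace}}
#' @param dir output directory (one CSV per model, plus pooled view)
#' @return invisibly, the files written
#' @export
writeProjection <- function(projection, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (nm in names(projection$perModel)) {
        f <- file.path(dir, paste0("adspace_", nm, ".csv"))
        utils::write.csv(projection$perModel[[nm]]$coordinates, f,
                         row.names = FALSE)
        files <- c(files, f)
    }
    if (!is.null(projection$pooled)) {
        f <- file.path(dir, "adspace_pooled.csv")
        utils::write.csv(projection$pooled$coordinates, f,
                         row.names = FALSE)
        files <- c(files, f)
    }
    invisible(files)
}

#' Static plot of a projection panel
#'
#' Draws predicted compounds colored by label (red positive, blue
#' negative) and synthetic objects in transparent green, one panel per
#' model. Requires ggplot2.
#'
#' @param projection result of \code{\link{projectChemicalSpace}}
#' @param file optional output image path (png)
#' @return the ggplot object, invisibly
#' @export
plotProjection <- function(projection, file = NULL) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting", call. = FALSE)
    dfs <- lapply(names(projection$perModel), function(nm) {
        d <- projection$perModel[[nm]]$coordinates
        d$model <- nm
        d
    })
    d <- do.call(rbind, dfs)
    d$what <- ifelse(d$synthetic, "synthetic",
                     ifelse(d$label == 1L, "positive", "negative"))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = pc1, y = pc2,
                                         color = what)) +
        ggplot2::geom_point(alpha = 0.6, size = 1) +
        ggplot2::scale_color_manual(values = c(positive = "red",
                                               negative = "blue",
                                               synthetic = "darkgreen")) +
        ggplot2::facet_wrap(~model) +
        ggplot2::theme_minimal()
    if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 6)
    invisible(p)
}
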