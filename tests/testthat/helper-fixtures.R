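# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code; no data files are read.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (is.null(.fixtures[[name]]))
        .fixtures[[name]] <- suppressWarnings(builder())
    .fixtures[[name]]
}

# a fast configuration for tests that only need a fitted model, not the
# full default grid
fastConfig <- function(seed = 101L)
    modelConfig(lvGrid = 2:4, thresholdGrid = c(0.3, 0.5, 0.7),
                seed = seed)

fixSeries60 <- function()
    fixture("series60", function()
        generateSeries(60, 0.5, 0, "benzenoid", seed = 101))

fixModel60 <- function()
    fixture("model60", function() fitPLSDA(fixSeries60(), fastConfig()))

fixTest100 <- function()
    fixture("test100", function()
        generateSeries(100, 0.5, 0, "benzenoid", seed = 202,
                       comboHalf = "cvd"))

# ---- independent fingerprint oracle ---------------------------------------
# A from-scratch recomputation of the documented fingerprint: same
# published definition (pharmacophore invariants, polynomial hash mod
# 2^31 - 1, per-atom-ball dedup by smallest identifier), but computed by
# a different path: recursive ball expansion per atom instead of
# iterative relabeling, and ring perception by edge-removal
# connectivity instead of bridge detection.

oracleHash <- function(v) {
    h <- 17
    for (x in v) h <- (h * 1000003 + x + 131) %% 2147483647
    h
}

oracleFingerprint <- function(smiles, nBits = 2048L, radius = 2L) {
    g <- ConfQSAR:::.smilesToGraphs(canonicalSmiles(smiles))[[1]]
    stopifnot(!is.null(g))
    n <- length(g$element)
    bonds <- g$bonds
    nb <- nrow(bonds)
    # ring bonds: removing the edge leaves its endpoints connected
    gr <- igraph::graph_from_edgelist(cbind(bonds[, "i"], bonds[, "j"]),
                                      directed = FALSE)
    if (igraph::vcount(gr) < n)
        gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
    ringBond <- vapply(seq_len(nb), function(b) {
        g2 <- igraph::delete_edges(gr, b)
        is.finite(igraph::distances(g2, v = bonds[b, "i"],
                                    to = bonds[b, "j"]))
    }, logical(1))
    inRing <- rep(FALSE, n)
    inRing[unique(as.vector(bonds[ringBond, c("i", "j")]))] <- TRUE
    # ring systems = connected components of the ring-bond subgraph
    hasMultiple <- rep(FALSE, n)
    deg <- integer(n)
    for (b in seq_len(nb)) {
        i <- bonds[b, "i"]; j <- bonds[b, "j"]
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        if (bonds[b, "order"] >= 2) hasMultiple[i] <- hasMultiple[j] <- TRUE
    }
    aromatic <- rep(FALSE, n)
    if (any(ringBond)) {
        rg <- igraph::graph_from_edgelist(
            bonds[ringBond, c("i", "j"), drop = FALSE], directed = FALSE)
        if (igraph::vcount(rg) < n)
            rg <- igraph::add_vertices(rg, n - igraph::vcount(rg))
        comp <- igraph::components(rg)$membership
        for (cid in unique(comp[inRing])) {
            at <- which(comp == cid & inRing)
            if (length(at) < 3) next
            ok <- g$element[at] %in% c("N", "O", "S") |
                (g$element[at] == "C" & hasMultiple[at])
            if (all(ok)) aromatic[at] <- TRUE
        }
    }
    # acidic O: O-H whose neighbor bears =O
    nbrIdx <- lapply(seq_len(n), function(a)
        which(bonds[, "i"] == a | bonds[, "j"] == a))
    other <- function(b, a) if (bonds[b, "i"] == a) bonds[b, "j"]
                            else bonds[b, "i"]
    dblO <- rep(FALSE, n)
    for (b in seq_len(nb))
        if (bonds[b, "order"] == 2) {
            if (g$element[bonds[b, "j"]] == "O") dblO[bonds[b, "i"]] <- TRUE
            if (g$element[bonds[b, "i"]] == "O") dblO[bonds[b, "j"]] <- TRUE
        }
    acidic <- vapply(seq_len(n), function(a) {
        if (g$element[a] != "O" || g$nH[a] < 1) return(FALSE)
        any(vapply(nbrIdx[[a]], function(b) dblO[other(b, a)], logical(1)))
    }, logical(1))
    donor <- g$element %in% c("N", "O") & g$nH >= 1
    acceptor <- g$element %in% c("N", "O") & g$charge <= 0
    posIon <- g$charge > 0 |
        (g$element == "N" & !aromatic & !hasMultiple & g$charge == 0)
    negIon <- g$charge < 0 | acidic
    halogen <- g$element %in% c("F", "Cl", "Br", "I")
    invariant <- 1 * donor + 2 * acceptor + 4 * posIon + 8 * negIon +
        16 * aromatic + 32 * halogen
    border <- vapply(seq_len(nb), function(b)
        if (ringBond[b] && aromatic[bonds[b, "i"]] &&
            aromatic[bonds[b, "j"]]) 4 else bonds[b, "order"],
        numeric(1))
    # recursive identifier of atom a at radius r
    idOf <- function(a, r) {
        if (r == 0) return(oracleHash(c(0, invariant[a])))
        bs <- nbrIdx[[a]]
        if (!length(bs)) return(oracleHash(c(r, idOf(a, r - 1))))
        pairs <- cbind(border[bs],
                       vapply(bs, function(b) idOf(other(b, a), r - 1),
                              numeric(1)))
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        oracleHash(c(r, idOf(a, r - 1), t(pairs)))
    }
    ballOf <- function(a, r) {
        ball <- a
        for (i in seq_len(r)) {
            ball <- unique(c(ball, unlist(lapply(ball, function(x)
                vapply(nbrIdx[[x]], function(b) other(b, x),
                       integer(1))))))
        }
        sort(ball)
    }
    ids <- numeric(); sigs <- character()
    for (a in seq_len(n)) for (r in 0:radius) {
        ids <- c(ids, idOf(a, r))
        sigs <- c(sigs, paste(ballOf(a, r), collapse = ","))
    }
    keep <- as.numeric(tapply(ids, sigs, min))
    v <- integer(nBits)
    v[(keep %% nBits) + 1L] <- 1L
    v
}

# four confidential members trained on distinct scaffold regions
fixMembers <- function()
    fixture("members4", function() {
        pools <- c("benzenoid", "azines", "fivering", "fused")
        lapply(seq_along(pools), function(i) {
            s <- generateSeries(80, 0.5, 0.05, pools[i], seed = 300 + i,
                                comboHalf = "train")
            m <- fitPLSDA(s, fastConfig(seed = 300 + i))
            f <- tempfile(fileext = ".qcm")
            exportConfidential(m, f, originLabel = LETTERS[i])
            importConfidential(f)
        })
    })

fixEvalSeries <- function()
    fixture("evalSeries", function()
        combineSeries(lapply(1:4, function(i)
            generateSeries(50, 0.5, 0.05,
                           c("benzenoid", "azines", "fivering",
                             "fused")[i],
                           seed = 400 + i, comboHalf = "cvd")),
            name = "eval"))


fixDedupPair <- function()
    fixture("dedupPair", function() {
        local <- generateSeries(60, 0.5, 0, "benzenoid", seed = 501,
                                comboHalf = "train")
        cvd <- generateSeries(80, 0.5, 0, "benzenoid", seed = 502,
                              comboHalf = "cvd")
        lm <- molecules(local); cm <- molecules(cvd)
        # plant 6 exact copies (records 1..6) and 3 near analogs
        # (chain homologation changes the InChIKey skeleton but barely
        # perturbs the fingerprint)
        base <- paste0("CCCCCCCCCCCCCCCC",
                       c("c1ccccc1", "c1ccncc1", "c1cccs1"))
        analog <- paste0("CCCCCCCCCCCCCCCCC",
                         c("c1ccccc1", "c1ccncc1", "c1cccs1"))
        cvd2 <- annotatedSeries(
            c(cm$record_id, paste0("NEAR", 1:3)),
            c(lm$smiles[1:6], cm$smiles[-(1:6)], analog),
            c(seriesLabels(local)[1:6], seriesLabels(cvd)[-(1:6)],
              rep(0L, 3)),
            name = "cvd")
        local2 <- annotatedSeries(
            c(lm$record_id, paste0("LOCN", 1:3)),
            c(lm$smiles, base),
            c(seriesLabels(local), rep(0L, 3)), name = "local")
        list(cvd = cvd2, local = local2,
             planted_exact = molecules(cvd2)$record_id[1:6],
             planted_near = paste0("NEAR", 1:3))
    })


fixConfModel <- function()
    fixture("confModel", function() {
        f <- tempfile(fileext = ".qcm")
        exportConfidential(fixModel60(), f, originLabel = "A")
        importConfidential(f)
    })

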