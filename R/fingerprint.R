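# Feature-typed (pharmacophoric) circular fingerprints.
#
# Each atom starts from a 6-bit pharmacophore invariant (donor, acceptor,
# positively ionizable, negatively ionizable, aromatic, halogen). The
# invariant is then iteratively refined: at round r each atom's
# identifier is rehashed together with the sorted (bond order, neighbor
# identifier) pairs of its heavy-atom neighbors, so that after r rounds
# the identifier encodes the circular environment of radius r. All
# identifiers from rounds 0..radius are collected (environments covering
# an atom set already seen in an earlier round are dropped) and folded
# onto a fixed number of bits.
#
# Everything is computed from the canonical SMILES, which makes the bit
# vector a pure function of the standardized structure.

# Deterministic polynomial hash over non-negative integers, modulo the
# Mersenne prime 2^31 - 1. Intermediate products stay below 2^53, so the
# arithmetic is exact in doubles on every platform.
.hashInts <- function(v) {
    h <- 17
    for (x in v) h <- (h * 1000003 + x + 131) %% 2147483647
    h
}

.halogens <- c("F", "Cl", "Br", "I")

# Per-atom pharmacophore invariants + aromatic perception for one graph
# (as returned by .sdfToGraph).
.atomInvariants <- function(g) {
    n <- length(g$element)
    el <- g$element
    ch <- g$charge
    nH <- g$nH
    bonds <- g$bonds
    nb <- nrow(bonds)

    deg <- integer(n)
    hasMultiple <- logical(n)   # any double/triple bond on the atom
    if (nb) {
        for (b in seq_len(nb)) {
            i <- bonds[b, "i"]; j <- bonds[b, "j"]
            deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
            if (bonds[b, "order"] >= 2L)
                hasMultiple[i] <- hasMultiple[j] <- TRUE
        }
    }

    inRing <- logical(n)
    ringBond <- logical(nb)
    aromatic <- logical(n)
    if (nb) {
        gr <- igraph::graph_from_edgelist(
            cbind(bonds[, "i"], bonds[, "j"]), directed = FALSE)
        if (igraph::vcount(gr) < n)
            gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
        bridges <- igraph::bridges(gr)
        ringBond <- !(seq_len(nb) %in% as.integer(bridges))
        inRing[unique(as.vector(bonds[ringBond, c("i", "j")]))] <- TRUE
        # ring system = biconnected component with >= 3 atoms; flagged
        # aromatic-like when every member atom is sp2-capable: carbons
        # must carry at least one double bond, heteroatoms (N, O, S)
        # may contribute a lone pair
        bc <- igraph::biconnected_components(gr)
        for (comp in bc$components) {
            at <- as.integer(comp)
            if (length(at) < 3L) next
            sp2ok <- el[at] %in% c("N", "O", "S") |
                (el[at] == "C" & hasMultiple[at])
            if (all(sp2ok)) aromatic[at] <- TRUE
        }
    }

    # acidic oxygen: O-H whose neighbor also bears =O (carboxylic,
    # sulfonic, phosphonic...)
    acidic <- logical(n)
    if (nb) {
        nbrList <- vector("list", n)
        for (b in seq_len(nb)) {
            i <- bonds[b, "i"]; j <- bonds[b, "j"]
            nbrList[[i]] <- c(nbrList[[i]], b)
            nbrList[[j]] <- c(nbrList[[j]], b)
        }
        dblO <- logical(n)  # atom has =O
        for (b in seq_len(nb)) {
            if (bonds[b, "order"] == 2L) {
                i <- bonds[b, "i"]; j <- bonds[b, "j"]
                if (el[j] == "O") dblO[i] <- TRUE
                if (el[i] == "O") dblO[j] <- TRUE
            }
        }
        for (a in seq_len(n)) {
            if (el[a] == "O" && nH[a] >= 1L) {
                nbrs <- vapply(nbrList[[a]], function(b)
                    if (bonds[b, "i"] == a) bonds[b, "j"] else bonds[b, "i"],
                    integer(1))
                if (any(dblO[nbrs])) acidic[a] <- TRUE
            }
        }
    }

    donor <- el %in% c("N", "O") & nH >= 1L
    acceptor <- el %in% c("N", "O") & ch <= 0L
    posIon <- ch > 0L | (el == "N" & !aromatic & !hasMultiple & ch == 0L)
    negIon <- ch < 0L | acidic
    halogen <- el %in% .halogens

    invariant <- 1L * donor + 2L * acceptor + 4L * posIon + 8L * negIon +
        16L * aromatic + 32L * halogen

    list(invariant = as.numeric(invariant), aromatic = aromatic,
         ringBond = ringBond, degree = deg)
}

# All hashed environment identifiers (rounds 0..radius) of one graph.
.moleculeEnvironmentIds <- function(g, radius) {
    n <- length(g$element)
    if (n == 0L) return(numeric())
    inv <- .atomInvariants(g)
    bonds <- g$bonds
    nb <- nrow(bonds)
    # aromatic bonds hash with order 4, making the identifiers
    # independent of the kekulization
    border <- if (nb) ifelse(inv$ringBond &
                             inv$aromatic[bonds[, "i"]] &
                             inv$aromatic[bonds[, "j"]],
                             4L, bonds[, "order"]) else integer()
    nbr <- vector("list", n)     # list of (neighbor, order) rows
    if (nb) {
        for (b in seq_len(nb)) {
            i <- bonds[b, "i"]; j <- bonds[b, "j"]; o <- border[b]
            nbr[[i]] <- rbind(nbr[[i]], c(j, o))
            nbr[[j]] <- rbind(nbr[[j]], c(i, o))
        }
    }
    ids <- vapply(inv$invariant, function(x) .hashInts(c(0, x)), numeric(1))
    ball <- lapply(seq_len(n), function(a) a)   # atoms covered by env
    envIds <- ids
    envBalls <- ball
    cur <- ids
    for (r in seq_len(radius)) {
        nxt <- numeric(n)
        nxtBall <- vector("list", n)
        for (a in seq_len(n)) {
            nb_a <- nbr[[a]]
            if (is.null(nb_a)) {
                nxt[a] <- .hashInts(c(r, cur[a]))
                nxtBall[[a]] <- ball[[a]]
            } else {
                pairs <- cbind(nb_a[, 2], cur[nb_a[, 1]])
                ord <- order(pairs[, 1], pairs[, 2])
                nxt[a] <- .hashInts(c(r, cur[a], t(pairs[ord, , drop = FALSE])))
                nxtBall[[a]] <- sort(unique(c(ball[[a]],
                    unlist(ball[nb_a[, 1]]))))
            }
        }
        cur <- nxt
        ball <- nxtBall
        envIds <- c(envIds, cur)
        envBalls <- c(envBalls, ball)
    }
    # one environment per distinct atom set: when several environments
    # cover the same atoms, the smallest identifier is kept (order
    # independent)
    sig <- vapply(envBalls, function(s) paste(s, collapse = ","),
                  character(1))
    as.numeric(tapply(envIds, sig, min))
}

# Fold environment identifiers of one molecule onto nBits bits.
.foldBits <- function(envIds, nBits) {
    v <- integer(nBits)
    if (length(envIds)) v[(envIds %% nBits) + 1L] <- 1L
    v
}

# cache: canonical SMILES + settings -> bit vector
.fpCache <- new.env(parent = emptyenv())

.fingerprintOne <- function(graph, radius, nBits) {
    .foldBits(.moleculeEnvironmentIds(graph, radius), nBits)
}

#' Circular fingerprints of a series
#'
#' Computes feature-typed (pharmacophoric) circular fingerprints, radius
#' 2, folded to 2048 bits by default, for every parseable molecule of a
#' series. The bit vector is a deterministic function of the canonical
#' SMILES. Records with \code{parse_ok = FALSE} are excluded and their
#' positions reported in the result.
#'
#' @param series an \code{\linkS4class{AnnotatedSeries}} (or a character
#'   vector of SMILES)
#' @param nBits folded length (default 2048)
#' @param radius circular radius (default 2)
#' @return a \code{\linkS4class{FingerprintMatrix}}
#' @export
morganFingerprints <- function(series, nBits = 2048L, radius = 2L) {
    nBits <- as.integer(nBits); radius <- as.integer(radius)
    if (is.character(series)) {
        smiles <- series
        ids <- as.character(seq_along(smiles))
        okMask <- !is.na(smiles)
    } else {
        stopifnot(is(series, "AnnotatedSeries"))
        mols <- molecules(series)
        smiles <- mols$smiles
        ids <- mols$record_id
        okMask <- mols$parse_ok & !is.na(smiles)
    }
    excluded <- which(!okMask)
    smilesOk <- smiles[okMask]
    keys <- paste0(radius, "/", nBits, "#", smilesOk)
    need <- !vapply(keys, exists, logical(1), envir = .fpCache,
                    USE.NAMES = FALSE)
    if (any(need)) {
        graphs <- .smilesToGraphs(unique(smilesOk[need]))
        usm <- unique(smilesOk[need])
        for (u in seq_along(usm)) {
            g <- graphs[[u]]
            bits <- if (is.null(g)) rep(NA_integer_, nBits)
                    else .fingerprintOne(g, radius, nBits)
            assign(paste0(radius, "/", nBits, "#", usm[u]), bits,
                   envir = .fpCache)
        }
    }
    m <- matrix(0L, nrow = length(smilesOk), ncol = nBits)
    bad <- logical(length(smilesOk))
    for (r in seq_along(smilesOk)) {
        bits <- get(keys[r], envir = .fpCache)
        if (anyNA(bits)) bad[r] <- TRUE else m[r, ] <- bits
    }
    if (any(bad)) {
        warning(sum(bad), " molecule(s) could not be fingerprinted and ",
                "were excluded")
        excluded <- sort(c(excluded, which(okMask)[bad]))
        m <- m[!bad, , drop = FALSE]
        idsKept <- ids[okMask][!bad]
    } else idsKept <- ids[okMask]
    new("FingerprintMatrix", bits = m, recordIds = idsKept,
        excluded = as.integer(excluded))
}
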