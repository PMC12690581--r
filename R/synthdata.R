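# Fragment-grammar generator of labeled chemical series.
#
# Molecules are enumerated as scaffold x substituent combinations from
# curated pools ("chemical-space regions"), which guarantees valid,
# standardizer-stable SMILES. The activity signal is substructure
# driven: the default rule labels a molecule positive when it carries a
# nitro group on an aromatic ring — a classic mutagenicity-like
# structural alert that circular fingerprints can learn. Label noise is
# injected as seeded binomial flips, and the pre-noise rule labels plus
# any planted duplicates are recorded as ground truth.

# Substituents in two attachment notations: the leading template slot
# bonds the scaffold to the LAST atom of the fragment string (prefix
# form), every other slot bonds it to the FIRST atom (suffix/branch
# form). Both columns describe valid fragments for their position.
.subTable <- data.frame(
    prefix = c("C", "CC", "CCC", "CC(C)", "CC(C)(C)", "O", "CO", "OCC",
               "N", "CN", "CN(C)", "C[N+](C)(C)", "Cl", "F", "Br",
               "N#C", "CC(=O)", "OC(=O)", "COC(=O)", "CC(=O)O",
               "NC(=O)", "CC(=O)N", "O=N", "CS", "CS(=O)(=O)",
               "NS(=O)(=O)", "OS(=O)(=O)", "FC(F)(F)",
               "C=C", "C#C", "O=C", "FC(F)(F)O", "NC(=O)N",
               "CS(=O)", "NN", "CC(O)",
               "c8ccccc8", "c8ccncc8", "o8cccc8", "C8COCCN8",
               "C8CCCCN8", "c8ccsc8", "c8cccn8", "[nH]8ccnc8",
               "C8CC8", "C8CCC8", "C8COC8", "C8CCOCC8",
               "C8CN(C)CCN8"),
    suffix = c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "O", "OC", "CCO",
               "N", "NC", "N(C)C", "[N+](C)(C)C", "Cl", "F", "Br",
               "C#N", "C(C)=O", "C(=O)O", "C(=O)OC", "OC(C)=O",
               "C(N)=O", "NC(C)=O", "N=O", "SC", "S(C)(=O)=O",
               "S(N)(=O)=O", "S(O)(=O)=O", "C(F)(F)F",
               "C=C", "C#C", "C=O", "OC(F)(F)F", "NC(N)=O",
               "S(C)=O", "NN", "C(O)C",
               "c8ccccc8", "c8ccncc8", "c8ccco8", "N8CCOCC8",
               "N8CCCCC8", "c8ccsc8", "n8cccc8", "n8ccnc8",
               "C8CC8", "C8CCC8", "C8COC8", "C8CCOCC8",
               "N8CCN(C)CC8"),
    stringsAsFactors = FALSE)
.nitroSub <- c(prefix = "[O-][N+](=O)", suffix = "[N+](=O)[O-]")

# scaffold cores as sprintf templates; `slots` = number of %s sites
# (the first is a leading/prefix site, the rest branch/suffix sites);
# `aromatic` = the slots sit on aromatic ring atoms
.scaffoldPools <- list(
    benzenoid = list(
        list(core = "%sc1ccc(%s)c(%s)c1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccccc1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccccc1%s", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)cc1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cccc(%s)c1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)cc(%s)c1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccc(Cc2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(Oc2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(CCc2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE)
    ),
    azines = list(
        list(core = "%sc1nc(%s)nc(%s)n1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)nn1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cnc(%s)cn1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)c(%s)cn1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccncc1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)nc1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cncnc1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)cn1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)nc(%s)c1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccc(Cc2ccncc2)c(%s)c1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(Nc2ccncc2)c(%s)c1", slots = 2L,
             aromatic = TRUE)
    ),
    fivering = list(
        list(core = "%sc1nnc(%s)s1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1nnc(%s)o1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1nnn(C)n1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1cc(%s)n(C)n1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cnc(%s)[nH]1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1oc(%s)nc1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)on1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)sn1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1nc(%s)n(C)n1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1cc(%s)c(%s)s1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1cccs1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)s1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)o1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc(%s)[nH]1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1csc(%s)n1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc(Cc2ccc(%s)s2)cc1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(-c2ccc(%s)o2)cc1", slots = 2L,
             aromatic = TRUE)
    ),
    fused = list(
        list(core = "%sc1ccc2c(c1)cc(%s)[nH]2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)cc(%s)o2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)cc(%s)s2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)ncc(%s)c2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)nc(%s)[nH]2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)nc(%s)s2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)nc(%s)o2", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc2c(c1)OCO2", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccc2cc(%s)c(%s)cc2c1", slots = 3L, aromatic = TRUE),
        list(core = "%sc1ccc2ccccc2c1", slots = 1L, aromatic = TRUE),
        list(core = "%sc1ccc2cc(%s)ccc2c1", slots = 2L, aromatic = TRUE),
        list(core = "%sc1ccc(-c2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(-c2ccc(%s)c(%s)c2)cc1", slots = 3L,
             aromatic = TRUE),
        list(core = "%sc1ccc(N=Nc2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE),
        list(core = "%sc1ccc(C(=O)Nc2ccc(%s)cc2)cc1", slots = 2L,
             aromatic = TRUE)
    ),
    aliphatic = list(
        list(core = "%sC1CCN(%s)CC1", slots = 2L, aromatic = FALSE),
        list(core = "%sC1CCN(C(%s)=O)CC1", slots = 2L, aromatic = FALSE),
        list(core = "%sC1CCCCC1", slots = 1L, aromatic = FALSE),
        list(core = "%sC1CCC(%s)CC1", slots = 2L, aromatic = FALSE),
        list(core = "%sC1CCCC1", slots = 1L, aromatic = FALSE),
        list(core = "%sC1CCOC1", slots = 1L, aromatic = FALSE)
    )
)

#' Names of the built-in scaffold pools
#' @return character vector of pool identifiers
#' @export
scaffoldPools <- function() names(.scaffoldPools)

# Enumerate the combos of one pool by kind: "negative" (no nitro),
# "positive" (nitro in an activating slot), or "decoy" (nitro in an
# ortho-deactivated slot; rule label 0). Slot classification comes from
# .nitroSlotClass, i.e. from the rule detector itself.
.enumerateCombos <- function(pool,
                             kind = c("negative", "positive", "decoy")) {
    if (isTRUE(kind) || identical(kind, FALSE))   # legacy logical form
        kind <- if (isTRUE(kind)) "positive" else "negative"
    kind <- match.arg(kind)
    cores <- .scaffoldPools[[pool]]
    if (is.null(cores)) stop("unknown scaffold pool: ", pool,
                             call. = FALSE)
    subFor <- function(slot) if (slot == 1L) .subTable$prefix
                             else .subTable$suffix
    nitroFor <- function(slot) unname(.nitroSub[if (slot == 1L) "prefix"
                                                else "suffix"])
    slotClass <- if (kind != "negative") .nitroSlotClass(pool)
    out <- character()
    for (ci in seq_along(cores)) {
        core <- cores[[ci]]
        ns <- core$slots
        if (kind == "negative") {
            grid <- do.call(expand.grid,
                            c(lapply(seq_len(ns), subFor),
                              list(stringsAsFactors = FALSE)))
            out <- c(out, do.call(sprintf, c(list(core$core),
                                             as.list(grid))))
        } else {
            if (!core$aromatic) next
            want <- if (kind == "positive") which(slotClass[[ci]])
                    else which(!slotClass[[ci]])
            for (p in want) {
                cols <- lapply(seq_len(ns), function(s)
                    if (s == p) nitroFor(s) else subFor(s))
                grid <- do.call(expand.grid,
                                c(cols, list(stringsAsFactors = FALSE)))
                out <- c(out, do.call(sprintf, c(list(core$core),
                                                 as.list(grid))))
            }
        }
    }
    unique(unname(out))
}

# shared scan: for each graph, find nitro groups (N+ with two O
# neighbors) attached to aromatic atoms, and whether any of them sits
# in an "activating" context, i.e. with no heavy substituent on an
# ortho ring atom (substituent = neighbor reached through a non-ring
# bond)
.nitroScan <- function(g) {
    inv <- .atomInvariants(g)
    bonds <- g$bonds
    nb <- nrow(bonds)
    ringBond <- inv$ringBond
    nbrsOf <- function(a) {
        sel <- bonds[, "i"] == a | bonds[, "j"] == a
        list(atoms = ifelse(bonds[sel, "i"] == a, bonds[sel, "j"],
                            bonds[sel, "i"]),
             ring = ringBond[sel])
    }
    aromaticNitro <- FALSE
    activating <- FALSE
    for (a in which(g$element == "N" & g$charge == 1L)) {
        nn <- nbrsOf(a)
        if (sum(g$element[nn$atoms] == "O") < 2L) next
        for (r in nn$atoms[inv$aromatic[nn$atoms]]) {
            aromaticNitro <- TRUE
            orthoAtoms <- {
                rr <- nbrsOf(r)
                rr$atoms[rr$ring]
            }
            deactivated <- FALSE
            for (o in orthoAtoms) {
                oo <- nbrsOf(o)
                if (any(!oo$ring & oo$atoms != a))
                    deactivated <- TRUE
            }
            if (!deactivated) activating <- TRUE
        }
    }
    c(aromaticNitro = aromaticNitro, activating = activating)
}

#' Detect nitro groups on aromatic rings
#'
#' \code{hasAromaticNitro} is TRUE when the molecule carries N(+)
#' bonded to two oxygens and attached to an aromatic atom.
#' \code{hasActivatingNitro} — the generator's activity rule — further
#' requires at least one such nitro with no heavy substituent on an
#' ortho ring atom: ortho-substituted ("sterically deactivated") nitro
#' groups do not count, mirroring a classic structure-activity
#' exception.
#'
#' @param smiles character vector of SMILES
#' @return logical vector (NA for unparseable input)
#' @export
hasAromaticNitro <- function(smiles) {
    graphs <- .smilesToGraphs(canonicalSmiles(smiles))
    vapply(graphs, function(g) {
        if (is.null(g)) return(NA)
        .nitroScan(g)[["aromaticNitro"]]
    }, logical(1))
}

#' @rdname hasAromaticNitro
#' @export
hasActivatingNitro <- function(smiles) {
    graphs <- .smilesToGraphs(canonicalSmiles(smiles))
    vapply(graphs, function(g) {
        if (is.null(g)) return(NA)
        .nitroScan(g)[["activating"]]
    }, logical(1))
}

# classify each (core, slot) of a pool as activating (TRUE) or
# ortho-deactivated (FALSE) for a nitro placed there, by running the
# rule detector on one representative instantiation (methyls in the
# other slots; any heavy ortho substituent deactivates equally)
.nitroSlotCache <- new.env(parent = emptyenv())
.nitroSlotClass <- function(pool) {
    if (!is.null(.nitroSlotCache[[pool]])) return(.nitroSlotCache[[pool]])
    cores <- .scaffoldPools[[pool]]
    cls <- lapply(seq_along(cores), function(ci) {
        core <- cores[[ci]]
        if (!core$aromatic) return(logical(0))
        vapply(seq_len(core$slots), function(p) {
            subs <- rep("C", core$slots)
            subs[p] <- unname(.nitroSub[if (p == 1L) "prefix"
                                        else "suffix"])
            smi <- do.call(sprintf, c(list(core$core), as.list(subs)))
            isTRUE(hasActivatingNitro(smi))
        }, logical(1))
    })
    .nitroSlotCache[[pool]] <- cls
    cls
}

# Deterministic halves of a pool's combo space, so that validation and
# training compounds never coincide by accident. The half is assigned
# from a permutation-invariant character signature: symmetric scaffold
# positions can yield the same molecule from differently ordered
# substituent tuples, and those must land in the same half.
.comboDomainCache <- new.env(parent = emptyenv())
.comboDomain <- function(pool, kind, half = c("all", "train", "cvd")) {
    half <- match.arg(half)
    key <- paste(pool, kind, sep = "/")
    combos <- .comboDomainCache[[key]]
    if (is.null(combos)) {
        combos <- .enumerateCombos(pool, kind)
        .comboDomainCache[[key]] <- combos
    }
    if (half == "all") return(combos)
    sig <- vapply(combos, function(s) {
        v <- utf8ToInt(s)
        (sum(v) + 3 * sum(v * v)) %% 4
    }, numeric(1), USE.NAMES = FALSE)
    if (half == "train") combos[sig >= 2] else combos[sig < 2]
}

#' Generate a labeled synthetic series
#'
#' Samples molecules without replacement from the scaffold-substituent
#' grammar of one pool. A fraction \code{positiveFraction} carries an
#' activating aromatic nitro (rule label 1, see
#' \code{\link{hasActivatingNitro}}); the rest are rule-negative — a
#' mixture of alert-free molecules and ortho-deactivated nitro decoys
#' (fraction \code{decoyFraction} of the negatives, where the pool
#' provides them). The observed label is the rule label XOR a seeded
#' binomial flip with probability \code{flipNoise}. Deterministic per
#' seed; ground truth (rule labels, flip positions) is stored in the
#' series.
#'
#' @param n number of molecules
#' @param positiveFraction fraction built with the activating alert
#'   (0..1)
#' @param flipNoise label-flip probability in [0, 0.5)
#' @param scaffoldPool pool identifier (see \code{\link{scaffoldPools}})
#' @param seed integer seed
#' @param name series name
#' @param comboHalf reserved-domain selector ("all", "train" or "cvd");
#'   series generated on different halves share no structure
#' @param decoyFraction target fraction of deactivated-nitro decoys
#'   among the rule-negative molecules
#' @return an \code{\linkS4class{AnnotatedSeries}}
#' @export
generateSeries <- function(n, positiveFraction = 0.5, flipNoise = 0,
                           scaffoldPool = "benzenoid", seed = 1L,
                           name = NULL,
                           comboHalf = c("all", "train", "cvd"),
                           decoyFraction = 0.25) {
    comboHalf <- match.arg(comboHalf)
    stopifnot(flipNoise >= 0, flipNoise < 0.5,
              decoyFraction >= 0, decoyFraction <= 1)
    if (is.null(name))
        name <- paste0("synthetic_", scaffoldPool, "_", seed)
    nPos <- round(n * positiveFraction)
    nNeg <- n - nPos
    posDomain <- .comboDomain(scaffoldPool, "positive", comboHalf)
    negDomain <- .comboDomain(scaffoldPool, "negative", comboHalf)
    decoyDomain <- .comboDomain(scaffoldPool, "decoy", comboHalf)
    if (nPos > 0L && length(posDomain) == 0L)
        stop("pool '", scaffoldPool, "' cannot express positives ",
             "(no aromatic scaffolds)", call. = FALSE)
    nDecoy <- min(round(nNeg * decoyFraction), length(decoyDomain))
    nPlain <- nNeg - nDecoy
    if (nPos > length(posDomain) || nPlain > length(negDomain))
        stop("requested series larger than the '", scaffoldPool,
             "' grammar can provide without replacement (",
             length(posDomain), " positives, ", length(negDomain),
             " negatives available)", call. = FALSE)
    .withSeed(seed, {
        smiPos <- sample(posDomain, nPos)
        smiNeg <- c(sample(negDomain, nPlain),
                    if (nDecoy > 0L) sample(decoyDomain, nDecoy))
        smiles <- c(smiPos, smiNeg)
        rule <- c(rep(1L, nPos), rep(0L, nNeg))
        ord <- sample(n)
        smiles <- smiles[ord]; rule <- rule[ord]
        flips <- stats::rbinom(n, 1L, flipNoise) == 1L
        labels <- as.integer(xor(rule == 1L, flips))
        ids <- sprintf("%s_%04d", name, seq_len(n))
        annotatedSeries(ids, smiles, labels, name = name,
                        groundTruth = list(ruleLabels = rule,
                                           flipped = which(flips),
                                           rule = "activating_aromatic_nitro",
                                           pool = scaffoldPool))
    })
}

#' Generate a multi-partner study: partner series plus a validation set
#'
#' Partners draw from distinct scaffold pools (distinct chemical-space
#' regions); the common validation series mixes all partner pools but
#' is enumerated from the reserved half of each grammar, so that no
#' validation compound coincides with a training compound by accident.
#' Controlled overlap is then planted: for each partner,
#' \code{overlapWithCvd[i]} exact copies of its compounds are inserted
#' into the validation series (ids recorded as ground truth), which is
#' what the deduplication protocol must find and remove.
#'
#' @param nPartners number of partners (max 4)
#' @param sizes integer vector of partner series sizes
#' @param cvdSize size of the validation series before planting
#' @param overlapWithCvd integer vector: planted copies per partner
#' @param positiveFraction,flipNoise,seed as in
#'   \code{\link{generateSeries}}
#' @return list with \code{partners} (list of series), \code{cvd}
#'   (series with planted duplicates; ground truth in
#'   \code{groundTruth$planted})
#' @export
generatePartnerPartition <- function(nPartners = 4L,
                                     sizes = rep(200L, nPartners),
                                     cvdSize = 400L,
                                     overlapWithCvd = rep(0L, nPartners),
                                     positiveFraction = 0.5,
                                     flipNoise = 0.05,
                                     seed = 1L) {
    pools <- c("benzenoid", "azines", "fivering", "fused")
    stopifnot(nPartners >= 2L, nPartners <= length(pools),
              length(sizes) == nPartners,
              length(overlapWithCvd) == nPartners)
    if (sum(overlapWithCvd) > cvdSize)
        stop("planted overlap larger than the validation series",
             call. = FALSE)
    partners <- lapply(seq_len(nPartners), function(i)
        generateSeries(sizes[i], positiveFraction, flipNoise,
                       scaffoldPool = pools[i], seed = seed + i,
                       name = paste0("partner_", LETTERS[i]),
                       comboHalf = "train"))
    # validation series: equal shares from every partner pool,
    # reserved half of each grammar
    share <- ceiling(cvdSize / nPartners)
    cvdParts <- lapply(seq_len(nPartners), function(i)
        generateSeries(min(share, cvdSize - share * (i - 1L)),
                       positiveFraction, flipNoise,
                       scaffoldPool = pools[i], seed = seed + 100L + i,
                       name = paste0("cvdpart_", i),
                       comboHalf = "cvd"))
    smiles <- unlist(lapply(cvdParts, function(s) molecules(s)$smiles))
    labels <- unlist(lapply(cvdParts, seriesLabels))
    ruleLab <- unlist(lapply(cvdParts, function(s)
        s@groundTruth$ruleLabels))
    .withSeed(seed + 999L, {
        ord <- sample(length(smiles))
        smiles <- smiles[ord]; labels <- labels[ord]
        ruleLab <- ruleLab[ord]
        planted <- data.frame(cvd_record_id = character(),
                              partner = character(),
                              partner_record_id = character(),
                              stringsAsFactors = FALSE)
        slot <- 1L
        for (i in seq_len(nPartners)) {
            k <- overlapWithCvd[i]
            if (k == 0L) next
            pm <- molecules(partners[[i]])
            pick <- sample(nrow(pm), k)
            smiles[slot:(slot + k - 1L)] <- pm$smiles[pick]
            labels[slot:(slot + k - 1L)] <-
                seriesLabels(partners[[i]])[pick]
            ruleLab[slot:(slot + k - 1L)] <-
                partners[[i]]@groundTruth$ruleLabels[pick]
            planted <- rbind(planted, data.frame(
                cvd_record_id = sprintf("CVD_%04d",
                                        slot:(slot + k - 1L)),
                partner = LETTERS[i],
                partner_record_id = pm$record_id[pick],
                stringsAsFactors = FALSE))
            slot <- slot + k
        }
        ids <- sprintf("CVD_%04d", seq_along(smiles))
        cvd <- annotatedSeries(ids, smiles, labels, name = "cvd",
                               groundTruth = list(ruleLabels = ruleLab,
                                                  planted = planted))
        list(partners = partners, cvd = cvd)
    })
}
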