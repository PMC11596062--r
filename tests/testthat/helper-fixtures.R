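# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

# Quick LigandPose from a coordinate matrix.
makePose <- function(ligand, model, pts, names = NULL, score = NA_real_,
                     elements = NULL, hydrogen = NULL) {
    n <- nrow(pts)
    if (is.null(names)) names <- paste0("C", seq_len(n))
    if (is.null(elements)) elements <- rep("C", n)
    if (is.null(hydrogen)) hydrogen <- elements == "H"
    new("LigandPose", ligandId = ligand, modelIndex = as.integer(model),
        dockingScore = score,
        atoms = data.frame(serial = seq_len(n), name = names,
                           element = elements, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3], hydrogen = hydrogen,
                           stringsAsFactors = FALSE))
}

makeCore <- function(ligand, model, pts) {
    new("CoreCoordinates", ligandId = ligand, modelIndex = as.integer(model),
        points = as.matrix(pts))
}

# Independent RMSD oracle: explicit per-atom loop over the three squared
# coordinate differences.
oracleRmsd <- function(a, b) {
    stopifnot(nrow(a) == nrow(b))
    acc <- 0
    for (i in seq_len(nrow(a)))
        acc <- acc + (b[i, 1] - a[i, 1])^2 + (a[i, 2] - b[i, 2])^2 +
               (a[i, 3] - b[i, 3])^2
    sqrt(acc / nrow(a))
}

# Random RmsdMatrix over L ligands x M models (symmetric, zero diagonal).
randomRmsdMatrix <- function(L, M, max = 10) {
    n <- L * M
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0, max)
    v <- v + t(v)
    labels <- data.frame(ligandId = rep(paste0("lig", seq_len(L)), each = M),
                         modelIndex = rep(seq_len(M), times = L),
                         stringsAsFactors = FALSE)
    new("RmsdMatrix", labels = labels, values = v)
}

# Brute-force constellation oracle: nested enumeration over all
# combinations, mean over explicit pair loops, canonical sort.
oracleConstellations <- function(matrix) {
    ids <- unique(matrix@labels$ligandId)
    L <- length(ids)
    rows <- lapply(ids, function(l) which(matrix@labels$ligandId == l))
    grid <- expand.grid(rev(lapply(rows, seq_along)))[, L:1, drop = FALSE]
    means <- numeric(nrow(grid))
    mods <- matrix(0L, nrow(grid), L)
    for (r in seq_len(nrow(grid))) {
        pos <- vapply(seq_len(L), function(i) rows[[i]][grid[r, i]],
                      integer(1))
        acc <- 0; np <- 0L
        for (i in seq_len(L - 1)) for (j in seq(i + 1, L)) {
            acc <- acc + matrix@values[pos[i], pos[j]]; np <- np + 1L
        }
        means[r] <- acc / np
        mods[r, ] <- matrix@labels$modelIndex[pos]
    }
    tab <- as.data.frame(mods)
    names(tab) <- ids
    tab$meanRmsd <- means
    ord <- do.call(order, c(list(means), lapply(seq_len(L),
                                                function(i) mods[, i])))
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

# Exhaustive recursive subgraph matcher (independent of igraph): all
# injective label-order mappings of template atoms onto pose atoms that
# respect elements and bonds.
oracleEmbeddings <- function(template, heavyAtoms, bondTol = 0.45) {
    radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)
    n <- nrow(heavyAtoms)
    xyz <- as.matrix(heavyAtoms[, c("x", "y", "z")])
    d <- as.matrix(dist(xyz))
    r <- radii[heavyAtoms$element]
    bonded <- d < outer(r, r, `+`) + bondTol & upper.tri(d)
    bonded <- bonded | t(bonded)
    labels <- template@atoms$label
    elem <- template@atoms$element
    adj <- lapply(seq_along(labels), function(i) {
        nb <- c(template@bonds$to[template@bonds$from == labels[i]],
                template@bonds$from[template@bonds$to == labels[i]])
        match(nb, labels)
    })
    found <- list()
    recurse <- function(assign) {
        k <- length(assign) + 1L
        if (k > length(labels)) {
            found[[length(found) + 1L]] <<- assign
            return()
        }
        for (cand in seq_len(n)) {
            if (cand %in% assign) next
            if (heavyAtoms$element[cand] != elem[k]) next
            ok <- TRUE
            for (nb in adj[[k]]) {
                if (nb < k && !bonded[assign[nb], cand]) { ok <- FALSE; break }
            }
            if (ok) recurse(c(assign, cand))
        }
    }
    recurse(integer(0))
    found
}

# Planted-consensus generator run bundled for recovery tests.
recoveryRun <- function(seed, sigmaIn = 0.5, decoyShift = c(5, 20), k = 15) {
    gen <- generatePoseSet(L = 5, M = 9, sigmaIn = sigmaIn,
                           decoyShift = decoyShift, seed = seed)
    ints <- generateInteractions(gen$poseSet, gen$truth, seed = seed)
    mat <- pairwiseMatrix(poseSetCores(gen$poseSet))
    report <- selectConstellation(gen$poseSet, mat, ints$records, k = k)
    list(report = report, truth = gen$truth, matrix = mat,
         poseSet = gen$poseSet, records = ints$records)
}
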