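#' @include AllClasses.R utils.R
NULL

# Per-ligand row positions of an RmsdMatrix, preserving ligand order.
.ligandRows <- function(matrix) {
    ids <- matrix@labels$ligandId
    split(seq_along(ids), factor(ids, levels = unique(ids)))
}

#' Mean pairwise core RMSD of a constellation
#'
#' Arithmetic mean of the core RMSD over all C(L,2) unordered pairs of the
#' constellation's member poses -- all pairs, not pairs to a reference,
#' because congruence asks whether every ligand converges on one region.
#'
#' @param members named integer vector (ligand id -> model index).
#' @param matrix an [RmsdMatrix-class] covering the members.
#' @return mean RMSD in Angstrom
#' @export
meanPairRmsd <- function(members, matrix) {
    if (length(members) < 2L)
        stop("a constellation needs at least 2 ligands", call. = FALSE)
    lab <- matrix@labels
    rows <- match(paste0(names(members), "/", members), poseLabels(lab))
    if (anyNA(rows))
        stop("member pose(s) not in matrix: ",
             paste(paste0(names(members), "/", members)[is.na(rows)],
                   collapse = ", "), call. = FALSE)
    sub <- matrix@values[rows, rows, drop = FALSE]
    mean(sub[upper.tri(sub)])
}

.canonicalSort <- function(tab, ligandIds) {
    ord <- do.call(order, c(list(tab$meanRmsd),
                            lapply(ligandIds, function(l) tab[[l]])))
    tab <- tab[ord, , drop = FALSE]
    tab$index <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    tab
}

#' Enumerate one-pose-per-ligand constellations
#'
#' Builds every (or, in beam mode, a searched subset of) combination of one
#' docking model per ligand and ranks them by mean pairwise core RMSD --
#' the congruence step of consensus selection. The canonical order is
#' ascending mean RMSD with ties broken by the lexicographic member tuple;
#' `index` is the 1-based rank in that order (this package's own, fully
#' reproducible numbering).
#'
#' Full mode enumerates all combinations (feasible up to `cap`
#' combinations; the default cap of 1e6 comfortably covers the 9^5 = 59049
#' of a 5-ligand x 9-model screen). Beam mode keeps at each stage the
#' `beamWidth` best partial assignments scored by their realized pair sum
#' plus an optimistic (minimum-possible) completion bound, and is validated
#' against full enumeration.
#'
#' @param poseSet a [PoseSet-class] (defines ligand order and models).
#' @param matrix an [RmsdMatrix-class] covering all poses.
#' @param mode `"full"` or `"beam"`.
#' @param beamWidth beam mode: number of partial assignments retained.
#' @param cap full mode: maximum combination count.
#' @return a [ConstellationSet-class] in canonical order
#' @export
enumerateConstellations <- function(poseSet, matrix, mode = c("full", "beam"),
                                    beamWidth = 200L, cap = 1e6) {
    mode <- match.arg(mode)
    rowsByLigand <- .ligandRows(matrix)
    ligandIds <- names(rowsByLigand)
    if (!is.null(poseSet)) {
        psIds <- ligandIds(poseSet)
        if (!setequal(psIds, ligandIds))
            stop("matrix does not cover the pose set's ligands",
                 call. = FALSE)
        rowsByLigand <- rowsByLigand[psIds]
        ligandIds <- psIds
    }
    L <- length(ligandIds)
    if (L < 2L) stop("need at least 2 ligands", call. = FALSE)
    v <- matrix@values
    modelIdx <- lapply(rowsByLigand, function(r) matrix@labels$modelIndex[r])
    if (mode == "full") {
        total <- prod(vapply(rowsByLigand, length, integer(1)))
        if (total > cap)
            stop("full enumeration cap exceeded: ", format(total),
                 " combinations > cap ", format(cap),
                 "; use beam mode", call. = FALSE)
        # positions grid: last ligand varies fastest => lexicographic rows
        grid <- as.matrix(rev(expand.grid(
            rev(lapply(rowsByLigand, seq_along)))))
        colnames(grid) <- ligandIds
        sums <- numeric(nrow(grid))
        for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
            block <- v[rowsByLigand[[i]], rowsByLigand[[j]], drop = FALSE]
            sums <- sums + block[cbind(grid[, i], grid[, j])]
        }
        tab <- as.data.frame(lapply(seq_len(L), function(i)
            modelIdx[[i]][grid[, i]]))
        names(tab) <- ligandIds
        tab$meanRmsd <- sums / choose(L, 2)
    } else {
        tab <- .beamSearch(rowsByLigand, modelIdx, v, beamWidth)
        names(tab)[seq_len(L)] <- ligandIds
    }
    tab <- .canonicalSort(tab, ligandIds)
    new("ConstellationSet", ligandIds = ligandIds, table = tab)
}

# Beam search over ligand stages. States carry realized pair sum g; ranking
# uses g + h where h lower-bounds the contribution of all pairs involving
# ligands not yet assigned.
.beamSearch <- function(rowsByLigand, modelIdx, v, beamWidth) {
    L <- length(rowsByLigand)
    # minimum entry of each future-future ligand block
    blockMin <- matrix(0, L, L)
    for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L))
        blockMin[i, j] <- min(v[rowsByLigand[[i]], rowsByLigand[[j]]])
    pos <- matrix(seq_along(rowsByLigand[[1]]), ncol = 1L)
    g <- numeric(nrow(pos))
    for (t in seq(2L, L)) {
        nm <- length(rowsByLigand[[t]])
        reps <- nrow(pos)
        newPos <- cbind(pos[rep(seq_len(reps), each = nm), , drop = FALSE],
                        rep(seq_len(nm), times = reps))
        newG <- rep(g, each = nm)
        for (i in seq_len(t - 1L)) {
            block <- v[rowsByLigand[[i]], rowsByLigand[[t]], drop = FALSE]
            newG <- newG + block[cbind(newPos[, i], newPos[, t])]
        }
        h <- 0
        if (t < L) {
            # fixed-to-future: cheapest partner per assigned pose
            for (i in seq_len(t)) for (j in seq(t + 1L, L)) {
                rowMins <- apply(v[rowsByLigand[[i]], rowsByLigand[[j]],
                                   drop = FALSE], 1, min)
                h <- h + rowMins[newPos[, i]]
            }
            if (t + 1L < L)
                for (i in seq(t + 1L, L - 1L)) for (j in seq(i + 1L, L))
                    h <- h + blockMin[i, j]
        }
        keep <- order(newG + h)[seq_len(min(beamWidth, nrow(newPos)))]
        pos <- newPos[keep, , drop = FALSE]
        g <- newG[keep]
    }
    tab <- as.data.frame(lapply(seq_len(L), function(i)
        modelIdx[[i]][pos[, i]]))
    tab$meanRmsd <- g / choose(L, 2)
    tab
}

#' Top-k most congruent constellations
#'
#' First `k` constellations of a canonically sorted set (fewer when fewer
#' exist); the candidate pool handed to the similarity step.
#'
#' @param constellations a [ConstellationSet-class].
#' @param k number of candidates (default 15).
#' @return a [ConstellationSet-class] with at most `k` rows
#' @export
topK <- function(constellations, k = 15L) {
    stopifnot(k >= 1L)
    tab <- constellations@table
    new("ConstellationSet", ligandIds = constellations@ligandIds,
        table = tab[seq_len(min(k, nrow(tab))), , drop = FALSE])
}
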