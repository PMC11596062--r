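#' @include AllClasses.R constellation.R similarity.R
NULL

#' Two-step consensus constellation selection
#'
#' Implements the two-step consensus binding-region procedure: (1) rank all
#' one-pose-per-ligand constellations by mean pairwise core RMSD and keep
#' the `k` most congruent; (2) among those candidates, choose the one with
#' the highest interaction similarity factor. Similarity has priority over
#' congruence -- the chosen constellation is the Sf argmax, with ties
#' broken by lower mean RMSD, then lower index. When no interaction
#' records exist at all, selection degenerates to the congruence rank-1
#' constellation with a warning.
#'
#' @param poseSet a [PoseSet-class].
#' @param matrix an [RmsdMatrix-class] over the pose set (e.g. from
#'   [pairwiseMatrix()] on [poseSetCores()]).
#' @param records interaction data.frame (see [readInteractionTable()]).
#' @param k candidate pool size from the congruence step (default 15).
#' @param keyMode passed to [constellationSimilarity()].
#' @param mode,beamWidth passed to [enumerateConstellations()].
#' @return a [SelectionReport-class]
#' @export
selectConstellation <- function(poseSet, matrix, records, k = 15L,
                                keyMode = c("residue_and_class",
                                            "residue_only"),
                                mode = c("full", "beam"),
                                beamWidth = 200L) {
    keyMode <- match.arg(keyMode)
    mode <- match.arg(mode)
    if (length(poseSet@poses) == 0L) stop("empty pose set", call. = FALSE)
    cs <- enumerateConstellations(poseSet, matrix, mode = mode,
                                  beamWidth = beamWidth)
    cand <- topK(cs, k)
    tab <- cand@table
    nCand <- nrow(tab)
    noRecords <- is.null(records) || nrow(records) == 0L
    if (noRecords)
        warning("no interaction records: selection degenerates to the ",
                "congruence rank-1 constellation")
    sims <- lapply(seq_len(nCand), function(i) {
        if (noRecords)
            new("SimilarityResult", bTotal = 0L, bSimilar = 0L, sf = 0)
        else suppressMessages(
            constellationSimilarity(cand[[i]], records, keyMode))
    })
    tab$bTotal <- vapply(sims, function(s) s@bTotal, integer(1))
    tab$bSimilar <- vapply(sims, function(s) s@bSimilar, integer(1))
    tab$sf <- vapply(sims, function(s) s@sf, numeric(1))
    pick <- order(-tab$sf, tab$meanRmsd, tab$index)[1]
    chosen <- cand[[pick]]
    scores <- dockingScores(poseSet)
    mem <- chosen@members
    memScores <- scores[paste0(names(mem), "/", mem)]
    names(memScores) <- names(mem)
    new("SelectionReport", chosen = chosen, similarity = sims[[pick]],
        scores = memScores, candidates = tab)
}

#' Write a selection report as TSV plus a text summary
#'
#' Serializes the candidate table (index, members, mean RMSD, interaction
#' counts, Sf, per-ligand docking scores) as tab-delimited text, and an
#' accompanying human-readable summary naming the chosen constellation.
#'
#' @param report a [SelectionReport-class].
#' @param path output TSV path; the summary goes to `<path>.txt`.
#' @param poseSet optional [PoseSet-class] to add per-candidate member
#'   docking scores.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(report, path, poseSet = NULL) {
    tab <- report@candidates
    ligands <- names(report@chosen@members)
    if (!is.null(poseSet)) {
        scores <- dockingScores(poseSet)
        for (l in ligands)
            tab[[paste0("score_", l)]] <-
                unname(scores[paste0(l, "/", tab[[l]])])
    }
    tab$chosen <- ifelse(tab$index == report@chosen@index, "*", "")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mem <- report@chosen@members
    txt <- c(
        sprintf("Consensus constellation: #%d", report@chosen@index),
        sprintf("  members: %s",
                paste(sprintf("%s/model %d", names(mem), mem),
                      collapse = ", ")),
        sprintf("  mean core RMSD: %.2f A", report@chosen@meanRmsd),
        sprintf("  interactions: %d total, %d shared, Sf = %.2f",
                report@similarity@bTotal, report@similarity@bSimilar,
                roundHalfUp(report@similarity@sf, 2L)),
        sprintf("  docking scores [kcal/mol]: %s",
                paste(sprintf("%s %.1f", names(report@scores),
                              report@scores), collapse = ", ")))
    writeLines(txt, paste0(path, ".txt"))
    invisible(path)
}
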