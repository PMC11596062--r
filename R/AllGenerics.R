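#' @include AllClasses.R
NULL

#' Ligand identifiers of an object
#' @param x a PoseSet, RmsdMatrix or ConstellationSet
#' @return character vector of ligand ids, in container order
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' Poses of a pose set
#' @param x a PoseSet
#' @param ligand optional ligand id to restrict to
#' @return list of LigandPose
#' @export
setGeneric("poses", function(x, ligand = NULL) standardGeneric("poses"))

#' Docking scores of a pose set
#' @param x a PoseSet
#' @return named numeric vector ("ligand/model"), kcal/mol, NA when absent
#' @export
setGeneric("dockingScores", function(x) standardGeneric("dockingScores"))

#' Members of a constellation
#' @param x a Constellation
#' @return named integer vector (ligand id -> model index)
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Mean pairwise core RMSD of a constellation
#' @param x a Constellation
#' @return numeric(1), Angstrom
#' @export
setGeneric("meanRmsd", function(x) standardGeneric("meanRmsd"))

#' RMSD values of a matrix object
#' @param x an RmsdMatrix
#' @return numeric matrix with "ligand/model" dimnames
#' @export
setGeneric("rmsdValues", function(x) standardGeneric("rmsdValues"))

#' Pose labels of an RMSD matrix
#' @param x an RmsdMatrix
#' @return data.frame with columns ligandId, modelIndex
#' @export
setGeneric("rmsdLabels", function(x) standardGeneric("rmsdLabels"))

#' Similarity factor of a result
#' @param x a SimilarityResult or SelectionReport
#' @return numeric(1) in [0, 1]
#' @export
setGeneric("similarityFactor", function(x) standardGeneric("similarityFactor"))

setMethod("ligandIds", "PoseSet", function(x)
    unique(vapply(x@poses, function(p) p@ligandId, character(1))))

setMethod("ligandIds", "RmsdMatrix", function(x) unique(x@labels$ligandId))

setMethod("ligandIds", "ConstellationSet", function(x) x@ligandIds)

setMethod("poses", "PoseSet", function(x, ligand = NULL) {
    if (is.null(ligand)) return(x@poses)
    x@poses[vapply(x@poses, function(p) p@ligandId, character(1)) == ligand]
})

setMethod("dockingScores", "PoseSet", function(x) {
    s <- vapply(x@poses, function(p) p@dockingScore, numeric(1))
    names(s) <- vapply(x@poses, function(p)
        paste0(p@ligandId, "/", p@modelIndex), character(1))
    s
})

setMethod("members", "Constellation", function(x) x@members)
setMethod("meanRmsd", "Constellation", function(x) x@meanRmsd)
setMethod("rmsdValues", "RmsdMatrix", function(x) {
    v <- x@values
    dimnames(v) <- list(poseLabels(x@labels), poseLabels(x@labels))
    v
})
setMethod("rmsdLabels", "RmsdMatrix", function(x) x@labels)
setMethod("similarityFactor", "SimilarityResult", function(x) x@sf)
setMethod("similarityFactor", "SelectionReport", function(x) x@similarity@sf)

#' @describeIn ConstellationSet-class number of constellations
#' @param x a ConstellationSet
#' @export
setMethod("length", "ConstellationSet", function(x) nrow(x@table))

#' Constellation table of a set
#'
#' @param x a [ConstellationSet-class]
#' @return the backing data.frame (member columns, meanRmsd, index)
#' @export
constellationTable <- function(x) {
    stopifnot(is(x, "ConstellationSet"))
    x@table
}

#' Extract one constellation from a set
#'
#' @param x a [ConstellationSet-class]
#' @param i row position in canonical order
#' @param j,drop,... ignored
#' @return a [Constellation-class]
#' @export
setMethod("[[", "ConstellationSet", function(x, i, j, ...) {
    row <- x@table[i, , drop = FALSE]
    mem <- as.integer(row[, x@ligandIds])
    names(mem) <- x@ligandIds
    new("Constellation", members = mem, meanRmsd = row$meanRmsd,
        index = as.integer(row$index))
})

setMethod("show", "LigandPose", function(object) {
    cat(sprintf("LigandPose %s/%d: %d atoms (%d heavy), score %s kcal/mol\n",
                object@ligandId, object@modelIndex, nrow(object@atoms),
                sum(!object@atoms$hydrogen),
                ifelse(is.na(object@dockingScore), "NA",
                       format(object@dockingScore))))
})

setMethod("show", "PoseSet", function(object) {
    ids <- vapply(object@poses, function(p) p@ligandId, character(1))
    cat(sprintf("PoseSet: %d poses over %d ligands\n",
                length(object@poses), length(unique(ids))))
    print(table(factor(ids, levels = unique(ids))))
})

setMethod("show", "ScaffoldTemplate", function(object) {
    cat(sprintf("ScaffoldTemplate '%s': %d atoms (%s), %d bonds\n",
                object@name, nrow(object@atoms),
                paste(sprintf("%d %s", table(object@atoms$element),
                              names(table(object@atoms$element))),
                      collapse = ", "),
                nrow(object@bonds)))
})

setMethod("show", "RmsdMatrix", function(object) {
    cat(sprintf("RmsdMatrix: %d poses, %d ligands, RMSD range [%.2f, %.2f] A\n",
                nrow(object@values), length(unique(object@labels$ligandId)),
                min(object@values[upper.tri(object@values)]),
                max(object@values)))
})

setMethod("show", "Constellation", function(object) {
    cat(sprintf("Constellation #%d (mean core RMSD %.2f A):\n",
                object@index, object@meanRmsd))
    cat(" ", paste(sprintf("%s/%d", names(object@members), object@members),
                   collapse = "  "), "\n")
})

setMethod("show", "ConstellationSet", function(object) {
    cat(sprintf("ConstellationSet: %d constellations over %d ligands, mean RMSD %.2f-%.2f A\n",
                nrow(object@table), length(object@ligandIds),
                min(object@table$meanRmsd), max(object@table$meanRmsd)))
})

setMethod("show", "SimilarityResult", function(object) {
    cat(sprintf("SimilarityResult: %d/%d shared interactions, Sf = %.2f\n",
                object@bSimilar, object@bTotal, object@sf))
})

setMethod("show", "SelectionReport", function(object) {
    cat(sprintf("SelectionReport: constellation #%d chosen among %d candidates\n",
                object@chosen@index, nrow(object@candidates)))
    show(object@chosen)
    show(object@similarity)
    sc <- object@scores
    cat("  docking scores [kcal/mol]:",
        paste(sprintf("%s %.1f", names(sc), sc), collapse = "  "), "\n")
})

setMethod("show", "KineticFit", function(object) {
    cat(sprintf("KineticFit: Vmax %.2f +/- %.2f, Km %.2f +/- %.2f uM (n = %d, RSS = %.3g)\n",
                object@vmax, object@vmaxSE, object@km, object@kmSE,
                object@n, object@rss))
})

setMethod("show", "DoseResponse", function(object) {
    cat(sprintf("DoseResponse '%s': %d rows, %d concentrations (%g-%g uM), %d replicates\n",
                object@substrate, nrow(object@data),
                length(unique(object@data$concentration)),
                min(object@data$concentration),
                max(object@data$concentration),
                length(unique(object@data$replicate))))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth (seed %d): planted %s; sigma_in %.2f A, decoy shift [%g, %g] A\n",
                object@seed,
                paste(sprintf("%s/%d", names(object@members), object@members),
                      collapse = " "),
                object@sigmaIn, object@decoyShift[1], object@decoyShift[2]))
})
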