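#' @include AllClasses.R utils.R
NULL

.rmsdPoints <- function(a, b) {
    if (nrow(a) != nrow(b))
        stop("coordinate lists differ in length (", nrow(a), " vs ",
             nrow(b), ")", call. = FALSE)
    sqrt(sum((a - b)^2) / nrow(a))
}

#' Scaffold RMSD between two poses in the shared receptor frame
#'
#' Root-mean-square deviation over corresponding scaffold atoms,
#' `sqrt(sum_i |a_i - b_i|^2 / N)`, computed in the raw receptor coordinate
#' frame. No superposition is applied by default: all poses were docked
#' into one fixed receptor model, so frame-raw RMSD measures whether two
#' poses occupy the same binding region -- the quantity a fit-then-compare
#' RMSD would destroy. An optional Kabsch superposition (`superpose =
#' TRUE`) exists for shape-only comparisons and is off by default.
#'
#' @param a,b [CoreCoordinates-class] objects built against the same
#'   template (identical atom order).
#' @param superpose logical; superpose `b` onto `a` (least-squares rigid
#'   fit) before computing the deviation.
#' @return RMSD in Angstrom
#' @export
#' @examples
#' tpl <- cardenolideTemplate()
#' a <- new("CoreCoordinates", ligandId = "x", modelIndex = 1L,
#'          points = tpl@coords)
#' b <- new("CoreCoordinates", ligandId = "y", modelIndex = 1L,
#'          points = tpl@coords + rep(c(3, 4, 0), each = 25))
#' coreRmsd(a, b)  # 5: every atom displaced by 5 Angstrom
coreRmsd <- function(a, b, superpose = FALSE) {
    pa <- a@points; pb <- b@points
    if (superpose) pb <- .kabschFit(pa, pb)
    .rmsdPoints(pa, pb)
}

# Least-squares rigid fit of b onto a (Kabsch); returns transformed b.
.kabschFit <- function(a, b) {
    ca <- colMeans(a); cb <- colMeans(b)
    a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
    s <- svd(crossprod(b0, a0))
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    sweep(b0 %*% t(rot), 2, ca, `+`)
}

#' All-vs-all scaffold RMSD matrix over a pose collection
#'
#' Computes [coreRmsd()] for every unordered pair of core coordinate sets
#' -- the matrix rendered as a convergence heat map. Labels preserve input
#' order (ligands grouped, model indices ascending as supplied).
#'
#' @param cores list of [CoreCoordinates-class], all with the same atom
#'   count and template order.
#' @return an [RmsdMatrix-class]
#' @export
pairwiseMatrix <- function(cores) {
    n <- length(cores)
    if (n < 1L) stop("need at least one core coordinate set", call. = FALSE)
    sizes <- vapply(cores, function(cc) nrow(cc@points), integer(1))
    if (length(unique(sizes)) != 1L)
        stop("mixed core sizes: ", paste(unique(sizes), collapse = ", "),
             call. = FALSE)
    # flatten to an n x 3N matrix: squared pair distance is a row distance
    flat <- t(vapply(cores, function(cc) as.numeric(cc@points),
                     numeric(3L * sizes[1])))
    v <- as.matrix(stats::dist(flat)) / sqrt(sizes[1])
    labels <- data.frame(
        ligandId = vapply(cores, function(cc) cc@ligandId, character(1)),
        modelIndex = vapply(cores, function(cc) cc@modelIndex, integer(1)),
        stringsAsFactors = FALSE)
    new("RmsdMatrix", labels = labels, values = unname(v))
}

#' Core coordinates of every pose in a set
#'
#' Convenience wrapper: resolves the scaffold correspondence for each pose
#' of a [PoseSet-class] against one template.
#'
#' @param poseSet a [PoseSet-class].
#' @param template a [ScaffoldTemplate-class];
#'   default [cardenolideTemplate()].
#' @param mode,nameMaps passed to [resolveCorrespondence()]; `nameMaps` may
#'   be a per-ligand list of name maps.
#' @return list of [CoreCoordinates-class] in pose-set order
#' @export
poseSetCores <- function(poseSet, template = cardenolideTemplate(),
                         mode = c("by_name", "by_graph"), nameMaps = NULL) {
    mode <- match.arg(mode)
    lapply(poseSet@poses, function(p)
        resolveCorrespondence(p, template, mode,
                              nameMap = nameMaps[[p@ligandId]]))
}

#' Redocking RMSD against a reference pose
#'
#' Validation metric for a docking protocol: RMSD of a redocked model to
#' the experimentally determined reference pose of the same molecule, over
#' a named heavy-atom subset (for ATP, the 31 non-hydrogen atoms), in the
#' shared receptor frame. A model is called congruent with the reference
#' binding site when its RMSD is below the threshold (default 4 Angstrom).
#'
#' @param model,reference [LigandPose-class] objects of the same molecule.
#' @param atomSubset character vector of atom names to compare; `NULL`
#'   means all heavy atoms shared by name.
#' @param threshold congruence call threshold in Angstrom.
#' @return list with elements `rmsd` (Angstrom), `congruent` (logical) and
#'   `threshold`
#' @export
redockRmsd <- function(model, reference, atomSubset = NULL, threshold = 4) {
    hm <- model@atoms[!model@atoms$hydrogen, , drop = FALSE]
    hr <- reference@atoms[!reference@atoms$hydrogen, , drop = FALSE]
    if (is.null(atomSubset)) atomSubset <- intersect(hr$name, hm$name)
    im <- match(atomSubset, hm$name)
    ir <- match(atomSubset, hr$name)
    if (anyNA(im) || anyNA(ir))
        stop("subset atom(s) missing from pose: ",
             paste(atomSubset[is.na(im) | is.na(ir)], collapse = ", "),
             call. = FALSE)
    r <- .rmsdPoints(as.matrix(hm[im, c("x", "y", "z")]),
                     as.matrix(hr[ir, c("x", "y", "z")]))
    list(rmsd = r, congruent = r < threshold, threshold = threshold)
}

#' Render an RMSD matrix as a heat map
#'
#' Pure visualization of the convergence heat map; requires the pheatmap
#' package. Not part of the numeric contract.
#'
#' @param x an [RmsdMatrix-class].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly
#' @export
plotRmsdHeatmap <- function(x, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("pheatmap is required for plotting", call. = FALSE)
    invisible(pheatmap::pheatmap(rmsdValues(x), cluster_rows = FALSE,
                                 cluster_cols = FALSE, ...))
}
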