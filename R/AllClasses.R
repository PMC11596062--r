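#' @import methods
NULL

.validAtomsDf <- function(atoms) {
    need <- c("serial", "name", "element", "x", "y", "z", "hydrogen")
    if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
        return(sprintf("atoms must be a data.frame with columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(atoms) == 0L) return("pose has no atoms")
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("atom coordinates must be finite")
    if (any(!nzchar(atoms$element))) return("empty element symbol")
    if (sum(!atoms$hydrogen) < 1L) return("pose needs at least one heavy atom")
    TRUE
}

#' One docked conformation of one ligand
#'
#' A `LigandPose` holds the atoms of a single docking model (one MODEL block
#' of a multi-model PDB/PDBQT file), its 1-based model index within the
#' ligand's docking run, and the docking score in kcal/mol when the file
#' carried one (more negative = more favourable). Hydrogens are kept on the
#' object but flagged, so that scaffold extraction and RMSD work on heavy
#' atoms only.
#'
#' @slot ligandId character(1) ligand identifier.
#' @slot modelIndex integer(1), >= 1, unique within the ligand.
#' @slot dockingScore numeric(1) kcal/mol, `NA` when the file had no score.
#' @slot atoms data.frame with columns serial, name, element, x, y, z
#'   (Angstrom) and logical hydrogen.
#'
#' @exportClass LigandPose
setClass("LigandPose",
    representation(ligandId = "character", modelIndex = "integer",
                   dockingScore = "numeric", atoms = "data.frame"),
    prototype(dockingScore = NA_real_))

setValidity("LigandPose", function(object) {
    msgs <- character()
    if (length(object@ligandId) != 1L || !nzchar(object@ligandId))
        msgs <- c(msgs, "ligandId must be a non-empty string")
    if (length(object@modelIndex) != 1L || is.na(object@modelIndex) ||
        object@modelIndex < 1L)
        msgs <- c(msgs, "modelIndex must be a single integer >= 1")
    ok <- .validAtomsDf(object@atoms)
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
    if (length(msgs)) msgs else TRUE
})

#' A set of docked poses for several ligands in one receptor frame
#'
#' Container for all docking models of a screening run against one receptor
#' model. All poses share the receptor coordinate frame, which is what makes
#' raw (superposition-free) scaffold RMSD between poses of different ligands
#' meaningful.
#'
#' @slot poses list of [LigandPose-class], grouped by ligand, model indices
#'   ascending within ligand.
#'
#' @exportClass PoseSet
setClass("PoseSet", representation(poses = "list"))

setValidity("PoseSet", function(object) {
    if (length(object@poses) == 0L) return("pose set is empty")
    if (!all(vapply(object@poses, is, logical(1), "LigandPose")))
        return("all elements must be LigandPose objects")
    ids <- vapply(object@poses, function(p) p@ligandId, character(1))
    idx <- vapply(object@poses, function(p) p@modelIndex, integer(1))
    if (anyDuplicated(paste(ids, idx)))
        return("duplicated (ligandId, modelIndex)")
    TRUE
})

#' Common scaffold template shared by the docked ligands
#'
#' Named atoms and bonds of the ligand-family core used for congruence
#' comparison -- for cardenolides, the tetracyclic steroid nucleus plus the
#' butenolide (lactone) ring. `coords` is an idealized reference geometry
#' (Angstrom) used by the synthetic-pose generator; correspondence
#' resolution uses only labels, elements and bonds.
#'
#' @slot name character(1).
#' @slot atoms data.frame with columns label, element; row order defines the
#'   core-coordinate order.
#' @slot bonds data.frame with columns from, to (atom labels).
#' @slot coords numeric matrix, one row per atom, columns x, y, z.
#'
#' @exportClass ScaffoldTemplate
setClass("ScaffoldTemplate",
    representation(name = "character", atoms = "data.frame",
                   bonds = "data.frame", coords = "matrix"))

setValidity("ScaffoldTemplate", function(object) {
    a <- object@atoms; b <- object@bonds
    if (!all(c("label", "element") %in% names(a)))
        return("atoms needs columns label, element")
    if (anyDuplicated(a$label)) return("duplicated atom labels")
    if (!all(c("from", "to") %in% names(b)))
        return("bonds needs columns from, to")
    if (!all(c(b$from, b$to) %in% a$label))
        return("bond endpoint not among atom labels")
    if (!identical(dim(object@coords), c(nrow(a), 3L)))
        return("coords must be an N x 3 matrix matching atoms")
    g <- igraph::graph_from_data_frame(b, directed = FALSE,
                                       vertices = a$label)
    if (!igraph::is_connected(g)) return("template graph must be connected")
    TRUE
})

#' Ordered scaffold coordinates of one pose
#'
#' The N core-atom coordinates of a pose, in template atom order, as used by
#' the superposition-free RMSD. Row order is the contract: row i of two
#' `CoreCoordinates` objects built against the same template refers to the
#' same scaffold atom.
#'
#' @slot ligandId character(1).
#' @slot modelIndex integer(1).
#' @slot points numeric N x 3 matrix (Angstrom), rownames = template labels.
#'
#' @exportClass CoreCoordinates
setClass("CoreCoordinates",
    representation(ligandId = "character", modelIndex = "integer",
                   points = "matrix"))

setValidity("CoreCoordinates", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L || nrow(p) < 1L)
        return("points must be an N x 3 numeric matrix")
    if (!all(is.finite(p))) return("points must be finite")
    TRUE
})

#' All-vs-all scaffold RMSD matrix
#'
#' Symmetric matrix of pairwise core RMSD values (Angstrom) over all poses
#' of a [PoseSet-class]; the quantity rendered as a convergence heat map.
#'
#' @slot labels data.frame with columns ligandId, modelIndex, one row per
#'   pose, in matrix order.
#' @slot values symmetric numeric matrix, zero diagonal, Angstrom.
#'
#' @exportClass RmsdMatrix
setClass("RmsdMatrix",
    representation(labels = "data.frame", values = "matrix"))

setValidity("RmsdMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("values must be square")
    if (nrow(object@labels) != nrow(v))
        return("labels must match matrix dimension")
    if (!all(c("ligandId", "modelIndex") %in% names(object@labels)))
        return("labels needs columns ligandId, modelIndex")
    if (any(v < 0)) return("RMSD values must be >= 0")
    if (max(abs(v - t(v))) > 1e-9) return("values must be symmetric")
    if (any(abs(diag(v)) > 1e-9)) return("diagonal must be zero")
    TRUE
})

#' One pose per ligand
#'
#' A constellation picks exactly one docking model per ligand and carries
#' the arithmetic mean of all pairwise core RMSD values among its members,
#' plus its 1-based rank under the canonical ordering (ascending mean RMSD,
#' ties by lexicographic member tuple).
#'
#' @slot members named integer vector, names = ligand ids, values = model
#'   indices.
#' @slot meanRmsd numeric(1), Angstrom.
#' @slot index integer(1) rank id.
#'
#' @exportClass Constellation
setClass("Constellation",
    representation(members = "integer", meanRmsd = "numeric",
                   index = "integer"))

setValidity("Constellation", function(object) {
    if (is.null(names(object@members)) || anyDuplicated(names(object@members)))
        return("members must be uniquely named by ligand id")
    if (length(object@meanRmsd) != 1L || object@meanRmsd < 0)
        return("meanRmsd must be a single value >= 0")
    TRUE
})

#' Ranked collection of constellations
#'
#' Data-frame-backed container for an enumerated (or beam-searched) set of
#' constellations in canonical order. One row per constellation: one model
#' index column per ligand, then `meanRmsd` and `index`.
#'
#' @slot ligandIds character, the member column names.
#' @slot table data.frame in canonical sort order.
#'
#' @exportClass ConstellationSet
setClass("ConstellationSet",
    representation(ligandIds = "character", table = "data.frame"))

setValidity("ConstellationSet", function(object) {
    if (!all(c(object@ligandIds, "meanRmsd", "index") %in%
             names(object@table)))
        return("table must have one column per ligand plus meanRmsd, index")
    if (is.unsorted(object@table$meanRmsd)) return("table must be sorted")
    TRUE
})

#' Interaction similarity of a constellation
#'
#' Counts behind the similarity factor: `bTotal` protein--ligand interaction
#' records across the member poses, of which `bSimilar` have a residue (or
#' residue+class) key recurring in at least two distinct ligands' members;
#' `sf = bSimilar / bTotal`.
#'
#' @slot bTotal integer(1).
#' @slot bSimilar integer(1).
#' @slot sf numeric(1) in [0, 1].
#'
#' @exportClass SimilarityResult
setClass("SimilarityResult",
    representation(bTotal = "integer", bSimilar = "integer", sf = "numeric"))

setValidity("SimilarityResult", function(object) {
    if (object@bSimilar < 0L || object@bSimilar > object@bTotal)
        return("need 0 <= bSimilar <= bTotal")
    if (object@bTotal > 0L &&
        abs(object@sf - object@bSimilar / object@bTotal) > 1e-12)
        return("sf must equal bSimilar / bTotal")
    if (object@sf < 0 || object@sf > 1) return("sf must lie in [0, 1]")
    TRUE
})

#' Consensus binding-region selection report
#'
#' Result of the two-step selection: among the top-k most congruent
#' constellations, the one with the highest similarity factor (similarity
#' has priority over mean RMSD). `candidates` is the runner-up table for
#' all k candidates; `scores` carries the chosen members' docking scores.
#'
#' @slot chosen [Constellation-class].
#' @slot similarity [SimilarityResult-class].
#' @slot scores named numeric, kcal/mol per ligand (NA when absent).
#' @slot candidates data.frame: member columns, meanRmsd, index, bTotal,
#'   bSimilar, sf.
#'
#' @exportClass SelectionReport
setClass("SelectionReport",
    representation(chosen = "Constellation", similarity = "SimilarityResult",
                   scores = "numeric", candidates = "data.frame"))

#' Michaelis--Menten fit
#'
#' Converged least-squares estimates of a Michaelis--Menten curve
#' v = Vmax * S / (Km + S): maximal velocity (activity units) and Michaelis
#' constant (uM), each with a standard error from the curvature of the
#' squared-error surface at the optimum, plus residual sum of squares and
#' the number of points fitted.
#'
#' @slot vmax,vmaxSE numeric(1), nmol Pi/mg protein/min.
#' @slot km,kmSE numeric(1), uM.
#' @slot rss numeric(1) residual sum of squares.
#' @slot n integer(1) number of observations.
#'
#' @exportClass KineticFit
setClass("KineticFit",
    representation(vmax = "numeric", vmaxSE = "numeric", km = "numeric",
                   kmSE = "numeric", rss = "numeric", n = "integer"))

setValidity("KineticFit", function(object) {
    if (object@vmax <= 0 || object@km <= 0)
        return("vmax and km must be positive at convergence")
    if (object@vmaxSE < 0 || object@kmSE < 0) return("SEs must be >= 0")
    TRUE
})

#' Paired dose--response table of an ATPase assay
#'
#' Phosphate-release activities measured at a shared substrate
#' concentration grid, with and without the ABC-transporter inhibitor
#' orthovanadate; the per-pair difference is the vanadate-sensitive
#' (transporter-attributable) activity.
#'
#' @slot substrate character(1).
#' @slot data data.frame with columns concentration (uM), replicate,
#'   activityNoVanadate, activityVanadate (nmol Pi/mg protein/min).
#' @slot metadata list (e.g. vanadate_uM = 500, dmso_percent = 2).
#'
#' @exportClass DoseResponse
setClass("DoseResponse",
    representation(substrate = "character", data = "data.frame",
                   metadata = "list"),
    prototype(metadata = list(vanadate_uM = 500, dmso_percent = 2)))

setValidity("DoseResponse", function(object) {
    need <- c("concentration", "replicate", "activityNoVanadate",
              "activityVanadate")
    if (!all(need %in% names(object@data)))
        return(sprintf("data needs columns %s", paste(need, collapse = ", ")))
    if (any(object@data$concentration < 0))
        return("concentrations must be >= 0")
    if (any(is.na(object@data$activityNoVanadate)) ||
        any(is.na(object@data$activityVanadate)))
        return("unpaired measurement: both arms required per row")
    TRUE
})

#' Ground truth of a synthetic pose-set run
#'
#' Everything the generator decided, sufficient to regenerate the data
#' byte-for-byte and to score recovery: the planted model index per ligand,
#' the consensus centroid, jitter and decoy-displacement parameters, the
#' shared interaction keys at the consensus site, kinetic truth and the
#' master seed.
#'
#' @slot members named integer, planted model index per ligand.
#' @slot centroid numeric(3), Angstrom.
#' @slot sigmaIn numeric(1), Angstrom.
#' @slot decoyShift numeric(2), min/max displacement, Angstrom.
#' @slot sharedKeys data.frame: chain, resnum, resname, interactionClass.
#' @slot kinetics list of per-substrate/transporter (vmax, km).
#' @slot seed integer(1).
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(members = "integer", centroid = "numeric",
                   sigmaIn = "numeric", decoyShift = "numeric",
                   sharedKeys = "data.frame", kinetics = "list",
                   seed = "integer"))
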