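#' @include AllClasses.R scaffold.R pose-io.R utils.R
NULL

# Uniform random rotation matrix (unit-quaternion construction).
.randomRotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

.placeTemplate <- function(coords, rot, shift) {
    ctr <- colMeans(coords)
    sweep(sweep(coords, 2, ctr) %*% t(rot), 2, shift, `+`)
}

#' Generate a synthetic pose set with a planted consensus
#'
#' Emulates a multi-ligand docking screen against one receptor model: for
#' each of `L` ligands, one planted pose places the scaffold template at a
#' shared consensus site (common orientation, per-coordinate Gaussian
#' jitter such that the per-atom displacement SD is `sigmaIn`), and the
#' remaining `M - 1` decoy poses are rigidly displaced from the site by a
#' random direction and distance in `decoyShift` with a random orientation.
#' Each pose also carries three glycone-like substituent atoms (excluded
#' from any scaffold correspondence) so that core extraction is exercised.
#'
#' Docking scores are drawn so that planted poses are never the
#' best-scored pose of their ligand: consensus selection must work from
#' geometry and interactions, and an implementation shortcutting through
#' scores fails the recovery tests by construction.
#'
#' @param L number of ligands (>= 2).
#' @param M poses per ligand (>= 1).
#' @param sigmaIn per-atom jitter SD at the consensus site, Angstrom.
#' @param decoyShift length-2 displacement range for decoys, Angstrom.
#' @param seed integer master seed; the run is a pure function of
#'   (parameters, seed).
#' @param dir optional directory; when given, one multi-model PDB per
#'   ligand is written there (byte-identical across reruns).
#' @param template a [ScaffoldTemplate-class] providing the reference
#'   geometry.
#' @param ligands optional ligand names (default `ligand_A`, `ligand_B`,
#'   ...).
#' @return list with `poseSet` ([PoseSet-class]), `truth`
#'   ([SyntheticTruth-class]) and `files` (paths or `NULL`)
#' @export
generatePoseSet <- function(L = 5L, M = 9L, sigmaIn = 0.5,
                            decoyShift = c(5, 20), seed = 1L, dir = NULL,
                            template = cardenolideTemplate(),
                            ligands = NULL) {
    stopifnot(L >= 2L, M >= 1L, sigmaIn >= 0, decoyShift[1] <= decoyShift[2])
    set.seed(deriveSeed(seed, 1L))
    if (is.null(ligands))
        ligands <- paste0("ligand_", LETTERS[seq_len(L)])
    centroid <- stats::runif(3, 10, 30)
    baseRot <- .randomRotation()
    planted <- stats::setNames(sample.int(M, L, replace = TRUE), ligands)
    tc <- template@coords
    labels <- template@atoms$label
    allPoses <- list()
    for (li in seq_len(L)) {
        lig <- ligands[li]
        for (m in seq_len(M)) {
            if (m == planted[[lig]]) {
                pts <- .placeTemplate(tc, baseRot, centroid) +
                    matrix(stats::rnorm(length(tc), 0, sigmaIn / sqrt(3)),
                           nrow(tc), 3)
                score <- round(stats::runif(1, -8.5, -7.5), 1)
            } else {
                shift <- centroid + .randomRotation()[, 1] *
                    stats::runif(1, decoyShift[1], decoyShift[2])
                pts <- .placeTemplate(tc, .randomRotation(), shift)
                score <- round(stats::runif(1, -10.0, -8.6), 1)
            }
            # glycone-like substituents chained off C3 (not template atoms)
            c3 <- pts[match("C3", labels), ]
            dirv <- c3 - colMeans(pts)
            dirv <- dirv / sqrt(sum(dirv^2))
            gly <- rbind(c3 + 1.43 * dirv, c3 + 2.9 * dirv, c3 + 4.4 * dirv)
            atoms <- data.frame(
                serial = seq_len(nrow(tc) + 3L),
                name = c(labels, "O3G", "C1G", "C2G"),
                element = c(template@atoms$element, "O", "C", "C"),
                x = c(pts[, 1], gly[, 1]), y = c(pts[, 2], gly[, 2]),
                z = c(pts[, 3], gly[, 3]),
                hydrogen = FALSE, stringsAsFactors = FALSE)
            allPoses[[length(allPoses) + 1L]] <- new("LigandPose",
                ligandId = lig, modelIndex = m, dockingScore = score,
                atoms = atoms)
        }
    }
    poseSet <- new("PoseSet", poses = allPoses)
    files <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        files <- vapply(ligands, function(lig) {
            p <- file.path(dir, paste0(lig, ".pdb"))
            writePoseFile(poses(poseSet, lig), p)
            p
        }, character(1))
    }
    truth <- new("SyntheticTruth", members = planted, centroid = centroid,
                 sigmaIn = sigmaIn, decoyShift = as.numeric(decoyShift),
                 sharedKeys = data.frame(), kinetics = list(),
                 seed = as.integer(seed))
    list(poseSet = poseSet, truth = truth, files = files)
}

.resnamePool <- c("LYS", "GLN", "ALA", "PHE", "VAL", "TYR")

#' Generate a proximity-consistent interaction table
#'
#' Fabricates the residue-interaction records a structure-analysis tool
#' would report: every planted pose receives the same `sharedSiteKeys`
#' consensus-site residue keys (fixed residue and bond class per key, so
#' they recur across ligands under either key mode) plus `noiseKeys`
#' globally unique private keys; decoy poses receive only private keys.
#' The planted constellation therefore has a high similarity factor and
#' decoy constellations a near-zero one, mirroring how a true common
#' binding region manifests in interaction tables.
#'
#' @param poseSet a [PoseSet-class] from [generatePoseSet()].
#' @param truth the matching [SyntheticTruth-class].
#' @param sharedSiteKeys number of consensus-site residue keys.
#' @param noiseKeys private keys per pose.
#' @param seed integer seed.
#' @return list with `records` (interaction data.frame) and `truth`
#'   (updated with the shared keys)
#' @export
generateInteractions <- function(poseSet, truth, sharedSiteKeys = 4L,
                                 noiseKeys = 2L, seed = 1L) {
    set.seed(deriveSeed(seed, 2L))
    hbClasses <- c("conventional_hbond", "carbon_hbond")
    npClasses <- c("pi_alkyl", "alkyl", "van_der_waals")
    shared <- data.frame(
        chain = "A",
        resnum = sample(200:899, sharedSiteKeys),
        resname = sample(.resnamePool, sharedSiteKeys, replace = TRUE),
        interactionClass = c(hbClasses[1],
                             sample(npClasses, max(0, sharedSiteKeys - 1L),
                                    replace = TRUE))[seq_len(sharedSiteKeys)],
        stringsAsFactors = FALSE)
    nextPrivate <- 1000L
    rows <- list()
    for (p in poseSet@poses) {
        isPlanted <- identical(truth@members[[p@ligandId]], p@modelIndex)
        if (isPlanted && sharedSiteKeys > 0L)
            rows[[length(rows) + 1L]] <- data.frame(
                ligand_id = p@ligandId, model_index = p@modelIndex,
                chain = shared$chain, resnum = shared$resnum,
                resname = shared$resname,
                interaction_class = shared$interactionClass,
                stringsAsFactors = FALSE)
        if (noiseKeys > 0L) {
            rows[[length(rows) + 1L]] <- data.frame(
                ligand_id = p@ligandId, model_index = p@modelIndex,
                chain = "A",
                resnum = seq(nextPrivate, length.out = noiseKeys),
                resname = sample(.resnamePool, noiseKeys, replace = TRUE),
                interaction_class = sample(interactionClasses(), noiseKeys,
                                           replace = TRUE),
                stringsAsFactors = FALSE)
            nextPrivate <- nextPrivate + noiseKeys
        }
    }
    records <- if (length(rows)) do.call(rbind, rows) else
        stats::setNames(data.frame(matrix(ncol = 6, nrow = 0)),
                        .interactionCols)
    truth@sharedKeys <- shared
    list(records = records, truth = truth)
}

#' Generate noisy Michaelis--Menten dose--response data
#'
#' Simulates a paired ATPase assay: without vanadate the activity is
#' baseline + Vmax * S / (Km + S) + Gaussian noise; with vanadate the
#' transporter is modelled as fully inhibited, leaving baseline + noise.
#' The pairwise difference therefore recovers the Michaelis--Menten curve
#' exactly in expectation (a documented simplification of partial
#' inhibition).
#'
#' @param vmax,km kinetic truth (activity units, uM); both positive.
#' @param grid concentration grid, uM.
#' @param replicates replicates per concentration.
#' @param sigmaFrac noise SD as a fraction of `vmax`.
#' @param baseline vanadate-insensitive background activity.
#' @param seed integer seed.
#' @param substrate substrate label.
#' @return a [DoseResponse-class]
#' @export
generateMmData <- function(vmax, km,
                           grid = c(0, 1, 5, 10, 25, 50, 100, 200, 400, 800),
                           replicates = 5L, sigmaFrac = 0.05, baseline = 2,
                           seed = 1L, substrate = "substrate") {
    stopifnot(vmax > 0, km > 0)
    set.seed(deriveSeed(seed, 3L))
    conc <- rep(grid, each = replicates)
    repl <- rep(seq_len(replicates), times = length(grid))
    sd <- sigmaFrac * vmax
    mm <- vmax * conc / (km + conc)
    noVan <- baseline + mm + stats::rnorm(length(conc), 0, sd)
    van <- baseline + stats::rnorm(length(conc), 0, sd)
    new("DoseResponse", substrate = substrate,
        data = data.frame(concentration = conc, replicate = repl,
                          activityNoVanadate = noVan,
                          activityVanadate = van),
        metadata = list(vanadate_uM = 500, dmso_percent = 2,
                        truth = list(vmax = vmax, km = km,
                                     baseline = baseline),
                        seed = as.integer(seed)))
}

#' Materialize a complete demo workspace
#'
#' Writes everything the pipeline consumes into `dir`: one multi-model PDB
#' per ligand (5 ligands x 9 poses with a planted consensus), the matching
#' interaction table, and paired dose--response CSVs for two transporters
#' x two substrates with realistic kinetic magnitudes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @return named list of generated paths, plus the `truth` objects,
#'   invisibly
#' @export
makeFixtures <- function(dir, seed = 1L) {
    gen <- generatePoseSet(L = 5L, M = 9L, seed = seed, dir = dir)
    ints <- generateInteractions(gen$poseSet, gen$truth, seed = seed)
    intPath <- file.path(dir, "interactions.tsv")
    writeInteractionTable(ints$records, intPath)
    kinetics <- list(
        "digoxin.T1" = list(vmax = 21.08, km = 33.73),
        "ouabain.T1" = list(vmax = 11.78, km = 48.56),
        "digoxin.T2" = list(vmax = 12.54, km = 9.33),
        "ouabain.T2" = list(vmax = 13.30, km = 7.05))
    dr <- lapply(names(kinetics), function(nm) {
        k <- kinetics[[nm]]
        generateMmData(k$vmax, k$km, seed = deriveSeed(seed, match(nm, names(kinetics))),
                       substrate = nm)
    })
    drPath <- file.path(dir, "dose_response.csv")
    writeDoseResponse(dr, drPath)
    # per-transporter docking scores for the delta report (kcal/mol,
    # magnitudes typical of a cardenolide screen)
    scores <- data.frame(
        substrate = rep(c("ouabain", "digoxin", "cymarin", "frugoside",
                          "oleandrin"), each = 2),
        transporter = rep(c("T1", "T2"), times = 5),
        score = c(-7.8, -8.6, -9.7, -10.4, -8.3, -8.0, -8.4, -8.5,
                  -8.8, -8.2))
    scPath <- file.path(dir, "docking_scores.csv")
    utils::write.csv(scores, scPath, row.names = FALSE, quote = FALSE)
    truth <- ints$truth
    truth@kinetics <- kinetics
    invisible(list(poseFiles = gen$files, interactions = intPath,
                   doseResponse = drPath, dockingScores = scPath,
                   truth = truth))
}
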