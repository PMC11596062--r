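#' @include AllClasses.R utils.R
NULL

# Map AutoDock atom types (PDBQT last column) to element symbols.
.adTypeToElement <- function(type) {
    map <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
             HD = "H", HS = "H", H = "H", SA = "S", S = "S", P = "P",
             F = "F", Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I")
    key <- ifelse(type == "NA", "NA.", type)
    out <- unname(map[key])
    miss <- is.na(out)
    # fall back to the alphabetic prefix of the type
    out[miss] <- sub("^([A-Za-z]+).*$", "\\1", type[miss])
    out
}

.parseAtomLine <- function(line, lineno, dialect) {
    serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
    name <- trimws(substr(line, 13, 16))
    x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
    if (is.na(serial) || !nzchar(name) || anyNA(c(x, y, z)))
        stop(sprintf("unparseable %s record at line %d",
                     trimws(substr(line, 1, 6)), lineno), call. = FALSE)
    if (dialect == "pdbqt") {
        # trailing token is the AutoDock atom type; the Gasteiger charge in
        # cols 71-76 is parsed but unused (docking-stage detail)
        toks <- strsplit(trimws(substr(line, 67, nchar(line))), "\\s+")[[1]]
        element <- .adTypeToElement(toks[length(toks)])
    } else {
        element <- trimws(substr(line, 77, 78))
        if (!nzchar(element))  # fall back to the atom-name prefix
            element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
    }
    list(serial = serial, name = name, element = element,
         x = x, y = y, z = z)
}

#' Read a multi-model ligand pose file
#'
#' Parses a docking-output ligand file in PDB or PDBQT dialect into one
#' [LigandPose-class] per MODEL/ENDMDL block, in file order. A
#' `REMARK VINA RESULT` line inside a block supplies that model's docking
#' score (kcal/mol); models without one carry `NA`. PDBQT is treated as PDB
#' columns plus extra fields (partial charge, AutoDock atom type); the atom
#' type determines the element. Hydrogens are read and flagged so that
#' downstream scaffold extraction can exclude them. A file with coordinate
#' records but no MODEL lines is read as a single model.
#'
#' @param path path to the pose file.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @param ligandId ligand identifier; defaults to the file name without
#'   extension.
#' @return list of [LigandPose-class], model indices following the file's
#'   MODEL numbering (or 1 for an unnumbered single-model file).
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' ps <- generatePoseSet(L = 2, M = 2, seed = 1, dir = dirname(f))
#' readPoseFile(file.path(dirname(f), "ligand_A.pdb"))
readPoseFile <- function(path, dialect = c("pdb", "pdbqt"), ligandId = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (is.null(ligandId))
        ligandId <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    modelIdx <- NA_integer_
    sawModel <- FALSE
    cur <- list(); curScore <- NA_real_
    out <- list()
    flush <- function() {
        if (length(cur) == 0L) return()
        atoms <- do.call(rbind.data.frame, cur)
        atoms$hydrogen <- atoms$element == "H"
        out[[length(out) + 1L]] <<- new("LigandPose",
            ligandId = ligandId,
            modelIndex = if (is.na(modelIdx)) 1L else modelIdx,
            dockingScore = curScore, atoms = atoms)
        cur <<- list(); curScore <<- NA_real_
    }
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        rec <- substr(ln, 1, 6)
        if (startsWith(rec, "MODEL")) {
            flush()
            sawModel <- TRUE
            modelIdx <- suppressWarnings(as.integer(trimws(substr(ln, 7, 20))))
            if (is.na(modelIdx)) modelIdx <- length(out) + 1L
        } else if (startsWith(ln, "REMARK VINA RESULT")) {
            toks <- strsplit(sub("^REMARK VINA RESULT:?", "", ln), "\\s+")[[1]]
            toks <- toks[nzchar(toks)]
            curScore <- suppressWarnings(as.numeric(toks[1]))
        } else if (rec == "ATOM  " || startsWith(rec, "HETATM")) {
            cur[[length(cur) + 1L]] <- .parseAtomLine(ln, i, dialect)
        } else if (startsWith(rec, "ENDMDL")) {
            flush()
            modelIdx <- NA_integer_
        }
    }
    flush()
    if (length(out) == 0L)
        stop("empty input: no models in ", path, call. = FALSE)
    if (!sawModel && length(out) == 1L) out[[1]]@modelIndex <- 1L
    out
}

#' Write poses as a multi-model PDB/PDBQT file
#'
#' Inverse of [readPoseFile()]: one MODEL/ENDMDL block per pose, with a
#' `REMARK VINA RESULT` line when the pose carries a docking score.
#' Coordinates are written at 3 decimals (PDB precision).
#'
#' @param poseList list of [LigandPose-class].
#' @param path output file path.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @return `path`, invisibly.
#' @export
writePoseFile <- function(poseList, path, dialect = c("pdb", "pdbqt")) {
    dialect <- match.arg(dialect)
    con <- file(path, "w")
    on.exit(close(con))
    for (p in poseList) {
        cat(sprintf("MODEL %8d\n", p@modelIndex), file = con)
        if (!is.na(p@dockingScore))
            cat(sprintf("REMARK VINA RESULT:  %8.1f      0.000      0.000\n",
                        p@dockingScore), file = con)
        a <- p@atoms
        for (i in seq_len(nrow(a))) {
            nm <- if (nchar(a$name[i]) < 4L)
                sprintf(" %-3s", a$name[i]) else substr(a$name[i], 1, 4)
            if (dialect == "pdbqt") {
                adt <- ifelse(a$element[i] == "H", "HD",
                       ifelse(a$element[i] == "O", "OA",
                       ifelse(a$element[i] == "N", "NA", a$element[i])))
                cat(sprintf(
                    "ATOM  %5d %s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s\n",
                    a$serial[i], nm, a$x[i], a$y[i], a$z[i], 0, adt),
                    file = con)
            } else {
                cat(sprintf(
                    "ATOM  %5d %s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s\n",
                    a$serial[i], nm, a$x[i], a$y[i], a$z[i],
                    a$element[i]), file = con)
            }
        }
        cat("ENDMDL\n", file = con)
    }
    invisible(path)
}

#' Read poses for several ligands into a pose set
#'
#' @param paths named character vector of pose-file paths; names (or file
#'   basenames) become ligand ids.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @return a [PoseSet-class]
#' @export
readPoseSet <- function(paths, dialect = c("pdb", "pdbqt")) {
    dialect <- match.arg(dialect)
    ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
    allPoses <- list()
    for (i in seq_along(paths))
        allPoses <- c(allPoses,
                      readPoseFile(paths[[i]], dialect, ligandId = ids[[i]]))
    new("PoseSet", poses = allPoses)
}

.interactionCols <- c("ligand_id", "model_index", "chain", "resnum",
                      "resname", "interaction_class")

#' Read a residue-interaction table
#'
#' Reads the delimited (CSV or TSV, auto-detected from the header) table of
#' per-pose protein--ligand interactions: which residue each docking model
#' contacts and by which bond class. Classes are validated against the
#' closed vocabulary of [interactionClasses()].
#'
#' @param path file path.
#' @return data.frame with columns ligand_id, model_index, chain, resnum,
#'   resname, interaction_class (zero rows for a header-only file).
#' @export
readInteractionTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    missing <- setdiff(.interactionCols, names(df))
    if (length(missing))
        stop("interaction table missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    df <- df[, .interactionCols]
    df$model_index <- as.integer(df$model_index)
    df$resnum <- as.integer(df$resnum)
    bad <- setdiff(unique(df$interaction_class), interactionClasses())
    if (length(bad))
        stop("unknown interaction class(es): ",
             paste(bad, collapse = ", "), "; valid classes are: ",
             paste(interactionClasses(), collapse = ", "), call. = FALSE)
    df
}

#' Write a residue-interaction table
#'
#' @param records interaction data.frame as returned by
#'   [readInteractionTable()].
#' @param path output path; extension `.csv` selects comma, else tab.
#' @return `path`, invisibly.
#' @export
writeInteractionTable <- function(records, path) {
    missing <- setdiff(.interactionCols, names(records))
    if (length(missing))
        stop("interaction table missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    bad <- setdiff(unique(records$interaction_class), interactionClasses())
    if (length(bad))
        stop("unknown interaction class(es): ",
             paste(bad, collapse = ", "), call. = FALSE)
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    utils::write.table(records[, .interactionCols], path, sep = sep,
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a labelled symmetric RMSD matrix
#'
#' Serializes an all-vs-all RMSD matrix as tab-delimited text with
#' "ligand/model" row and column labels and values at 3 decimals
#' (losslessly re-readable at that precision). The input must be square and
#' symmetric within 1e-9.
#'
#' @param x an [RmsdMatrix-class], or a plain labelled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRmsdMatrix <- function(x, path) {
    if (is(x, "RmsdMatrix")) {
        v <- x@values
        labels <- poseLabels(x@labels)
    } else {
        v <- as.matrix(x)
        labels <- rownames(v) %||% as.character(seq_len(nrow(v)))
    }
    if (nrow(v) != ncol(v)) stop("matrix must be square", call. = FALSE)
    if (max(abs(v - t(v))) > 1e-9)
        stop("matrix must be symmetric within 1e-9", call. = FALSE)
    out <- cbind(pose = labels,
                 matrix(sprintf("%.3f", v), nrow(v), dimnames = list(NULL, labels)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read back a serialized RMSD matrix
#'
#' @param path path written by [writeRmsdMatrix()].
#' @return an [RmsdMatrix-class]
#' @export
readRmsdMatrix <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    labels <- df$pose
    v <- as.matrix(df[, -1, drop = FALSE])
    rownames(v) <- labels
    parts <- strsplit(labels, "/", fixed = TRUE)
    lab <- data.frame(
        ligandId = vapply(parts, `[`, character(1), 1),
        modelIndex = as.integer(vapply(parts, `[`, character(1), 2)),
        stringsAsFactors = FALSE)
    v <- (v + t(v)) / 2  # absorb the 1e-3 serialization rounding
    diag(v) <- 0
    new("RmsdMatrix", labels = lab, values = unname(v))
}

#' Read a paired dose--response CSV
#'
#' Reads an ATPase assay table (columns substrate, concentration_uM,
#' replicate, activity_no_vanadate, activity_vanadate) into one
#' [DoseResponse-class] per substrate.
#'
#' @param path CSV file path.
#' @return named list of [DoseResponse-class]
#' @export
readDoseResponse <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("substrate", "concentration_uM", "replicate",
              "activity_no_vanadate", "activity_vanadate")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("dose-response table missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    lapply(split(df, df$substrate), function(d)
        new("DoseResponse", substrate = d$substrate[1],
            data = data.frame(concentration = d$concentration_uM,
                              replicate = d$replicate,
                              activityNoVanadate = d$activity_no_vanadate,
                              activityVanadate = d$activity_vanadate)))
}

#' Write paired dose--response data as CSV
#'
#' @param drList a [DoseResponse-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDoseResponse <- function(drList, path) {
    if (is(drList, "DoseResponse")) drList <- list(drList)
    rows <- do.call(rbind, lapply(drList, function(d)
        data.frame(substrate = d@substrate,
                   concentration_uM = d@data$concentration,
                   replicate = d@data$replicate,
                   activity_no_vanadate = d@data$activityNoVanadate,
                   activity_vanadate = d@data$activityVanadate)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
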