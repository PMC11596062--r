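test_that("multi-model pose files round-trip field by field", {
    tpl <- cardenolideTemplate()
    poseList <- lapply(1:9, function(m)
        makePose("dig", m, tpl@coords + m, names = tpl@atoms$label,
                 elements = tpl@atoms$element,
                 score = c(-9.7, -8.2, -8.0, -7.9, -7.8, -7.7, -7.6,
                           -7.5, -7.4)[m]))
    f <- withr::local_tempfile(fileext = ".pdb")
    writePoseFile(poseList, f)
    back <- readPoseFile(f, ligandId = "dig")
    expect_length(back, 9L)
    expect_equal(vapply(back, function(p) p@modelIndex, integer(1)), 1:9)
    expect_equal(vapply(back, function(p) p@dockingScore, numeric(1))[1:2],
                 c(-9.7, -8.2))
    for (m in c(1L, 5L, 9L)) {
        expect_equal(back[[m]]@atoms$name, poseList[[m]]@atoms$name)
        expect_equal(back[[m]]@atoms$element, poseList[[m]]@atoms$element)
        expect_equal(as.matrix(back[[m]]@atoms[, c("x", "y", "z")]),
                     as.matrix(poseList[[m]]@atoms[, c("x", "y", "z")]),
                     tolerance = 1e-3, ignore_attr = TRUE)
    }
})

test_that("single unnumbered model without score remark parses as one pose", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  C1  LIG A   1       1.000   2.000   3.000           C",
        "ATOM      2  O1  LIG A   1       2.000   2.000   3.000           O"),
        f)
    got <- readPoseFile(f)
    expect_length(got, 1L)
    expect_identical(got[[1]]@modelIndex, 1L)
    expect_true(is.na(got[[1]]@dockingScore))
})

test_that("pdbqt dialect maps AutoDock atom types and flags hydrogens", {
    tpl <- cardenolideTemplate()
    pose <- makePose("oua", 1, tpl@coords, names = tpl@atoms$label,
                     elements = tpl@atoms$element, score = -8.5)
    f <- withr::local_tempfile(fileext = ".pdbqt")
    writePoseFile(list(pose), f, dialect = "pdbqt")
    back <- readPoseFile(f, dialect = "pdbqt")[[1]]
    expect_equal(back@atoms$element, tpl@atoms$element)
    expect_equal(back@dockingScore, -8.5)
    # explicit HD hydrogen line is flagged
    lines <- readLines(f)
    hline <- sub("C1 ", "H1 ", lines[3])
    hline <- paste0(substr(hline, 1, 77), "HD")
    writeLines(c(lines[1:2], hline, lines[3:length(lines)]), f)
    withH <- readPoseFile(f, dialect = "pdbqt")[[1]]
    expect_true(any(withH@atoms$hydrogen))
})

test_that("malformed and empty pose files raise named errors", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c("MODEL        1",
                 "ATOM      1  C1  LIG A   1         bad   2.000   3.000",
                 "ENDMDL"), f)
    expect_error(readPoseFile(f), "line 2")
    writeLines(c("REMARK nothing here"), f)
    expect_error(readPoseFile(f), "empty input")
})

test_that("interaction tables round-trip and reject unknown classes", {
    rec <- data.frame(
        ligand_id = c("a", "a", "b"), model_index = c(1L, 1L, 2L),
        chain = "A", resnum = c(214L, 880L, 888L),
        resname = c("LYS", "GLN", "ALA"),
        interaction_class = c("conventional_hbond", "pi_alkyl", "alkyl"),
        stringsAsFactors = FALSE)
    for (ext in c(".tsv", ".csv")) {
        f <- withr::local_tempfile(fileext = ext)
        writeInteractionTable(rec, f)
        expect_equal(readInteractionTable(f), rec, ignore_attr = TRUE)
    }
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste(c("ligand_id", "model_index", "chain", "resnum",
                       "resname", "interaction_class"), collapse = "\t"), f)
    expect_identical(nrow(readInteractionTable(f)), 0L)
    writeLines(c(paste(c("ligand_id", "model_index", "chain", "resnum",
                         "resname", "interaction_class"), collapse = "\t"),
                 "a\t1\tA\t5\tLYS\tmagnetic"), f)
    expect_error(readInteractionTable(f), "magnetic")
    writeLines("ligand_id\tmodel_index", f)
    expect_error(readInteractionTable(f), "missing column")
})

test_that("RMSD matrices serialize losslessly at 3 decimals", {
    m <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = list(c("a/1", "b/1"),
                                                      c("a/1", "b/1")))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeRmsdMatrix(m, f)
    back <- readRmsdMatrix(f)
    expect_equal(unname(rmsdValues(back)), unname(m))
    expect_error(writeRmsdMatrix(matrix(1:6, 2), f), "square")
    asym <- m; asym[1, 2] <- 2
    expect_error(writeRmsdMatrix(asym, f), "symmetric")
    # 5 ligands x 9 poses: 45 labels
    gen <- generatePoseSet(L = 5, M = 9, seed = 3)
    mat <- pairwiseMatrix(poseSetCores(gen$poseSet))
    writeRmsdMatrix(mat, f)
    back <- readRmsdMatrix(f)
    expect_identical(nrow(rmsdLabels(back)), 45L)
    expect_equal(back@values, mat@values, tolerance = 2e-3)
})

test_that("pose order and model indices follow file MODEL numbering", {
    tpl <- cardenolideTemplate()
    poseList <- lapply(c(3L, 1L, 7L), function(m)
        makePose("x", m, tpl@coords, names = tpl@atoms$label,
                 elements = tpl@atoms$element))
    f <- withr::local_tempfile(fileext = ".pdb")
    writePoseFile(poseList, f)
    back <- readPoseFile(f)
    expect_equal(vapply(back, function(p) p@modelIndex, integer(1)),
                 c(3L, 1L, 7L))
})

test_that("dose-response CSVs round-trip per substrate", {
    dr <- generateMmData(20, 10, seed = 4, substrate = "dig.T1")
    f <- withr::local_tempfile(fileext = ".csv")
    writeDoseResponse(dr, f)
    back <- readDoseResponse(f)
    expect_named(back, "dig.T1")
    expect_equal(back[["dig.T1"]]@data$activityNoVanadate,
                 dr@data$activityNoVanadate, tolerance = 1e-6)
})
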