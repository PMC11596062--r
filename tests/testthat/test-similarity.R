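test_that("similarity factor bounds and errors", {
    for (n in c(1L, 5L, 19L)) {
        expect_equal(similarityFactor(sfFromCounts(n, n)), 1)
        expect_equal(similarityFactor(sfFromCounts(0, n)), 0)
    }
    expect_error(sfFromCounts(1, 0), "zero total")
    expect_error(sfFromCounts(5, 3), "bSimilar <= bTotal")
})

.simRecords <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(ligand_id = r[[1]], model_index = as.integer(r[[2]]),
                   chain = "A", resnum = as.integer(r[[3]]),
                   resname = r[[4]], interaction_class = r[[5]],
                   stringsAsFactors = FALSE)))
}

test_that("constellation similarity counts keys shared across ligands", {
    mem <- setNames(rep(1L, 5), paste0("l", 1:5))
    # same single key in all five members
    shared <- do.call(.simRecords, lapply(1:5, function(i)
        list(paste0("l", i), 1, 214, "LYS", "conventional_hbond")))
    res <- constellationSimilarity(mem, shared)
    expect_identical(res@bTotal, 5L)
    expect_identical(res@bSimilar, 5L)
    expect_equal(res@sf, 1)
    # pairwise-disjoint keys
    disjoint <- do.call(.simRecords, lapply(1:5, function(i)
        list(paste0("l", i), 1, 100 + i, "ALA", "alkyl")))
    expect_equal(constellationSimilarity(mem, disjoint)@sf, 0)
})

test_that("a constructed 19-record set yields 13 shared and Sf 0.68", {
    mem <- setNames(rep(1L, 5), paste0("l", 1:5))
    rows <- list()
    # key K1 in ligands 1-5 (5 records), K2 in 1-4 (4), K3 in 1-2 (2),
    # K4 in 3-4 (2): 13 shared records
    for (i in 1:5) rows <- c(rows, list(list(paste0("l", i), 1, 214, "LYS",
                                             "conventional_hbond")))
    for (i in 1:4) rows <- c(rows, list(list(paste0("l", i), 1, 888, "ALA",
                                             "pi_alkyl")))
    for (i in 1:2) rows <- c(rows, list(list(paste0("l", i), 1, 361, "PHE",
                                             "alkyl")))
    for (i in 3:4) rows <- c(rows, list(list(paste0("l", i), 1, 880, "GLN",
                                             "van_der_waals")))
    # six private records
    for (i in 1:5) rows <- c(rows, list(list(paste0("l", i), 1, 10 + i,
                                             "VAL", "alkyl")))
    rows <- c(rows, list(list("l5", 1, 99, "TYR", "pi_pi")))
    rec <- do.call(.simRecords, rows)
    # independent hand count: keys occurring in >= 2 distinct ligands
    key <- paste(rec$resnum, rec$interaction_class)
    nlig <- tapply(rec$ligand_id, key, function(x) length(unique(x)))
    expectSimilar <- sum(nlig[key] >= 2)
    expect_identical(expectSimilar, 13L)
    res <- constellationSimilarity(mem, rec)
    expect_identical(res@bTotal, 19L)
    expect_identical(res@bSimilar, 13L)
    expect_equal(round(res@sf, 2), 0.68)
})

test_that("records outside the member poses are ignored", {
    mem <- c(l1 = 1L, l2 = 1L)
    rec <- .simRecords(list("l1", 1, 214, "LYS", "conventional_hbond"),
                       list("l2", 1, 214, "LYS", "conventional_hbond"),
                       list("l1", 2, 500, "ALA", "alkyl"),
                       list("l9", 1, 214, "LYS", "conventional_hbond"))
    res <- constellationSimilarity(mem, rec)
    expect_identical(res@bTotal, 2L)
    expect_equal(res@sf, 1)
})

test_that("adding an already-shared key never decreases Sf", {
    set.seed(12)
    mem <- setNames(rep(1L, 4), paste0("l", 1:4))
    base <- .simRecords(list("l1", 1, 214, "LYS", "conventional_hbond"),
                        list("l2", 1, 214, "LYS", "conventional_hbond"),
                        list("l3", 1, 7, "ALA", "alkyl"),
                        list("l4", 1, 8, "VAL", "alkyl"))
    sf0 <- constellationSimilarity(mem, base)@sf
    grown <- rbind(base, .simRecords(list("l3", 1, 214, "LYS",
                                          "conventional_hbond")))
    expect_gte(constellationSimilarity(mem, grown)@sf, sf0)
})

test_that("residue-only keys give Sf at least that of residue-and-class", {
    set.seed(30)
    mem <- setNames(rep(1L, 5), paste0("l", 1:5))
    for (rep in 1:10) {
        rows <- lapply(seq_len(12), function(i)
            list(paste0("l", sample(5, 1)), 1, sample(c(214, 880, 888), 1),
                 "LYS", sample(interactionClasses(), 1)))
        rec <- do.call(.simRecords, rows)
        coarse <- constellationSimilarity(mem, rec, "residue_only")@sf
        fine <- constellationSimilarity(mem, rec, "residue_and_class")@sf
        expect_gte(coarse, fine)
    }
})

test_that("member poses without records are reported and count zero", {
    mem <- c(l1 = 1L, l2 = 1L)
    rec <- .simRecords(list("l1", 1, 214, "LYS", "conventional_hbond"))
    expect_message(res <- constellationSimilarity(mem, rec), "l2/1")
    expect_identical(res@bTotal, 1L)
})

test_that("bond class summary tallies classes and the H/alkyl ratio", {
    rec <- do.call(.simRecords, c(
        lapply(1:5, function(i) list("l1", 1, i, "LYS",
                                     "conventional_hbond")),
        lapply(6:15, function(i) list("l1", 1, i, "ALA", "alkyl"))))
    s <- bondClassSummary(rec)
    expect_equal(s$hbAlkylRatio, 0.5)
    vdw <- .simRecords(list("l1", 1, 1, "GLY", "van_der_waals"))
    expect_true(is.na(bondClassSummary(vdw)$hbAlkylRatio))
    expect_error(bondClassSummary(vdw[0, ]), "no interaction records")
    # independent grouping oracle on a mixed random table
    set.seed(6)
    mixed <- do.call(.simRecords, lapply(1:40, function(i)
        list("l1", 1, i, "ALA", sample(interactionClasses(), 1))))
    s2 <- bondClassSummary(mixed)
    oracle <- table(mixed$interaction_class)
    for (cl in names(oracle))
        expect_identical(s2$counts[[cl]], as.integer(oracle[[cl]]))
    expect_identical(sum(s2$counts), 40L)
})
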