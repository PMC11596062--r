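test_that("full enumeration counts combinations", {
    set.seed(10)
    m23 <- randomRmsdMatrix(2, 3)
    expect_length(enumerateConstellations(NULL, m23), 9L)
    gen <- generatePoseSet(L = 5, M = 9, seed = 2)
    mat <- pairwiseMatrix(poseSetCores(gen$poseSet))
    expect_length(enumerateConstellations(gen$poseSet, mat), 59049L)
    expect_error(enumerateConstellations(gen$poseSet, mat, cap = 100),
                 "cap exceeded")
})

test_that("mean pairwise RMSD follows its arithmetic definition", {
    pts <- matrix(rnorm(75), 25, 3)
    cores <- lapply(1:3, function(i) makeCore(paste0("l", i), 1, pts))
    mat <- pairwiseMatrix(cores)
    mem <- setNames(rep(1L, 3), paste0("l", 1:3))
    expect_identical(meanPairRmsd(mem, mat), 0)
    # three members with pairwise RMSDs 1, 2, 3 -> mean 2
    v <- matrix(0, 3, 3)
    v[1, 2] <- v[2, 1] <- 1; v[1, 3] <- v[3, 1] <- 2
    v[2, 3] <- v[3, 2] <- 3
    m3 <- new("RmsdMatrix",
              labels = data.frame(ligandId = paste0("l", 1:3),
                                  modelIndex = 1L),
              values = v)
    expect_equal(meanPairRmsd(mem, m3), 2)
    expect_error(meanPairRmsd(mem[1], m3), "at least 2")
    # five members: mean of the 10 pair values, hand summation oracle
    set.seed(8)
    m5 <- randomRmsdMatrix(5, 2)
    mem5 <- setNames(c(1L, 2L, 1L, 2L, 1L), paste0("lig", 1:5))
    rows <- match(paste0(names(mem5), "/", mem5),
                  paste0(m5@labels$ligandId, "/", m5@labels$modelIndex))
    acc <- 0
    for (i in 1:4) for (j in (i + 1):5)
        acc <- acc + m5@values[rows[i], rows[j]]
    expect_equal(meanPairRmsd(mem5, m5), acc / 10)
})

test_that("enumeration matches the brute-force oracle and is canonical", {
    set.seed(31)
    for (rep in 1:5) {
        m <- randomRmsdMatrix(3, 3)
        got <- constellationTable(enumerateConstellations(NULL, m))
        want <- oracleConstellations(m)
        expect_equal(got$meanRmsd, want$meanRmsd, tolerance = 1e-12)
        expect_equal(got[, 1:3], want[, 1:3], ignore_attr = TRUE)
        expect_identical(got$index, seq_len(nrow(got)))
    }
})

test_that("ties are broken by the lexicographic member tuple", {
    # all-equal matrix: every constellation ties on meanRmsd
    v <- matrix(1, 4, 4); diag(v) <- 0
    m <- new("RmsdMatrix",
             labels = data.frame(ligandId = rep(c("a", "b"), each = 2),
                                 modelIndex = rep(1:2, 2)),
             values = v)
    tab <- constellationTable(enumerateConstellations(NULL, m))
    expect_equal(tab$a, c(1L, 1L, 2L, 2L))
    expect_equal(tab$b, c(1L, 2L, 1L, 2L))
})

test_that("constellation mean lies between min and max member pair", {
    set.seed(17)
    m <- randomRmsdMatrix(4, 3)
    cs <- enumerateConstellations(NULL, m)
    tab <- constellationTable(cs)
    for (r in sample(nrow(tab), 25)) {
        mem <- setNames(as.integer(tab[r, 1:4]), names(tab)[1:4])
        rows <- match(paste0(names(mem), "/", mem),
                      paste0(m@labels$ligandId, "/", m@labels$modelIndex))
        sub <- m@values[rows, rows]
        pairs <- sub[upper.tri(sub)]
        expect_gte(tab$meanRmsd[r], min(pairs) - 1e-12)
        expect_lte(tab$meanRmsd[r], max(pairs) + 1e-12)
    }
})

test_that("beam search reproduces full enumeration where feasible", {
    set.seed(23)
    for (rep in 1:20) {
        L <- sample(3:4, 1); M <- sample(3:5, 1)
        m <- randomRmsdMatrix(L, M)
        full <- topK(enumerateConstellations(NULL, m), 15)
        beam <- topK(enumerateConstellations(NULL, m, mode = "beam",
                                             beamWidth = 50), 15)
        expect_equal(constellationTable(full)[, seq_len(L)],
                     constellationTable(beam)[, seq_len(L)],
                     ignore_attr = TRUE)
        expect_equal(constellationTable(full)$meanRmsd,
                     constellationTable(beam)$meanRmsd, tolerance = 1e-9)
    }
})

test_that("beam matches full top-15 on planted 5x9 sets at width 50", {
    for (seed in c(101, 202)) {
        gen <- generatePoseSet(L = 5, M = 9, seed = seed)
        mat <- pairwiseMatrix(poseSetCores(gen$poseSet))
        full <- topK(enumerateConstellations(gen$poseSet, mat), 15)
        beam <- topK(enumerateConstellations(gen$poseSet, mat,
                                             mode = "beam",
                                             beamWidth = 50), 15)
        expect_equal(constellationTable(full)[, 1:5],
                     constellationTable(beam)[, 1:5], ignore_attr = TRUE)
    }
})

test_that("topK truncates and preserves non-decreasing order", {
    set.seed(4)
    m <- randomRmsdMatrix(3, 3)
    cs <- enumerateConstellations(NULL, m)
    t15 <- topK(cs, 15)
    expect_length(t15, 15L)
    expect_false(is.unsorted(constellationTable(t15)$meanRmsd))
    expect_length(topK(cs, 10000), 27L)
})

test_that("enumeration is deterministic across repeated runs", {
    gen <- generatePoseSet(L = 4, M = 3, seed = 77)
    mat <- pairwiseMatrix(poseSetCores(gen$poseSet))
    a <- constellationTable(enumerateConstellations(gen$poseSet, mat))
    b <- constellationTable(enumerateConstellations(gen$poseSet, mat))
    expect_identical(a, b)
})
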