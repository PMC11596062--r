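test_that("vanadate differencing is exact pairwise subtraction", {
    d <- new("DoseResponse", substrate = "dig",
             data = data.frame(concentration = c(0, 10, 10),
                               replicate = c(1L, 1L, 2L),
                               activityNoVanadate = c(4, 10, 3.5),
                               activityVanadate = c(4, 3.5, 4)))
    act <- suppressMessages(vanadateSensitiveActivity(d))
    expect_equal(act$activity, c(0, 6.5, -0.5))
    expect_message(vanadateSensitiveActivity(d), "negative")
    # independent elementwise loop oracle on generated data
    dr <- generateMmData(15, 20, seed = 9)
    got <- suppressMessages(vanadateSensitiveActivity(dr))
    for (i in sample(nrow(dr@data), 10))
        expect_equal(got$activity[i],
                     dr@data$activityNoVanadate[i] -
                     dr@data$activityVanadate[i])
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
    S <- c(1, 5, 10, 50, 100, 400, 800)
    v <- 20 * S / (10 + S)
    fit <- fitMichaelisMenten(S, v)
    expect_equal(fit@vmax, 20, tolerance = 1e-6)
    expect_equal(fit@km, 10, tolerance = 1e-6)
    expect_lt(fit@rss, 1e-12)
    # half-maximal velocity at S = Km on the fitted curve
    expect_equal(fit@vmax * fit@km / (fit@km + fit@km), fit@vmax / 2)
})

test_that("fit input validation", {
    expect_error(fitMichaelisMenten(c(0, 1, 1), c(0, 2, 2)),
                 "3 distinct positive")
    expect_error(fitMichaelisMenten(c(1, 5, 10), c(0, 0, 0)), "zero")
})

test_that("fit is scale-equivariant in activity", {
    set.seed(14)
    S <- rep(c(1, 5, 10, 25, 100, 400, 800), each = 3)
    v <- 12 * S / (30 + S) + rnorm(length(S), 0, 0.4)
    f1 <- fitMichaelisMenten(S, v)
    f2 <- fitMichaelisMenten(S, 3 * v)
    expect_equal(f2@vmax, 3 * f1@vmax, tolerance = 1e-6)
    expect_equal(f2@km, f1@km, tolerance = 1e-6)
})

test_that("a minimal design still converges", {
    S <- rep(c(2, 20, 200), 1)
    v <- 8 * S / (15 + S)
    fit <- fitMichaelisMenten(S, v)
    expect_equal(fit@km, 15, tolerance = 1e-4)
    expect_identical(fit@n, 3L)
})

test_that("curve comparison F test has the stated structure", {
    S <- c(1, 2, 5, 10, 50, 100, 400, 800)
    v <- 10 * S / (20 + S)
    fitA <- fitMichaelisMenten(S, v)
    pooled <- fitMichaelisMenten(c(S, S), c(v, v))
    same <- compareCurves(fitA, fitA, pooled)
    expect_equal(same$F, 0)
    expect_equal(same$p, 1)
    expect_equal(same$df, c(2L, 2L * length(S) - 4L))
    # two-fold Km difference, n = 8 points per curve, mild noise
    set.seed(77)
    vA <- 10 * S / (20 + S) + rnorm(8, 0, 0.25)
    vB <- 10 * S / (40 + S) + rnorm(8, 0, 0.25)
    cmp <- compareMichaelisMenten(S, vA, S, vB)
    expect_identical(cmp$test$df, c(2L, 12L))
    expect_lt(cmp$test$p, 0.05)
    expect_gte(cmp$test$F, 0)
})

test_that("delta table reproduces the transporter differences", {
    scores <- data.frame(
        substrate = rep(c("ouabain", "digoxin"), each = 2),
        transporter = rep(c("T1", "T2"), 2),
        score = c(-7.8, -8.6, -9.7, -10.4))
    km <- data.frame(substrate = rep(c("ouabain", "digoxin"), each = 2),
                     transporter = rep(c("T1", "T2"), 2),
                     km = c(48.56, 7.05, 33.73, 9.33))
    dt <- deltaTable(scores, km, transporters = c("T1", "T2"))
    expect_equal(dt$deltaScore[dt$substrate == "ouabain"], -0.8)
    expect_equal(dt$deltaScore[dt$substrate == "digoxin"], -0.7)
    expect_equal(dt$deltaKm[dt$substrate == "digoxin"], -24.40)
    # antisymmetry under label swap
    rev <- deltaTable(scores, km, transporters = c("T2", "T1"))
    expect_equal(rev$deltaScore, -dt$deltaScore)
    expect_equal(rev$deltaKm, -dt$deltaKm)
    # equal inputs give zero deltas
    eq <- scores; eq$score <- -8
    expect_equal(deltaTable(eq, transporters = c("T1", "T2"))$deltaScore,
                 c(0, 0))
    # docking-only substrates keep NA Km
    extra <- rbind(scores, data.frame(substrate = "cymarin",
                                      transporter = c("T1", "T2"),
                                      score = c(-8.3, -8.0)))
    dt2 <- deltaTable(extra, km, transporters = c("T1", "T2"))
    expect_true(is.na(dt2$deltaKm[dt2$substrate == "cymarin"]))
    expect_equal(dt2$deltaScore[dt2$substrate == "cymarin"], 0.3)
    # missing transporter errors
    expect_error(deltaTable(scores[-1, ], transporters = c("T1", "T2")),
                 "missing transporter")
})

test_that("delta table accepts kinetic fits keyed substrate.transporter", {
    S <- c(1, 5, 10, 25, 50, 100, 400, 800)
    fits <- list(
        "digoxin.T1" = fitMichaelisMenten(S, 21 * S / (33.73 + S)),
        "digoxin.T2" = fitMichaelisMenten(S, 12.5 * S / (9.33 + S)))
    scores <- data.frame(substrate = "digoxin",
                         transporter = c("T1", "T2"),
                         score = c(-9.7, -10.4))
    dt <- deltaTable(scores, fits, transporters = c("T1", "T2"))
    expect_equal(dt$deltaKm, 9.33 - 33.73, tolerance = 1e-4)
})
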