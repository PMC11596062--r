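#' @include AllClasses.R utils.R
NULL

#' Vanadate-sensitive ATPase activity
#'
#' Isolates the transporter-attributable phosphate release from a paired
#' assay: activity = (without vanadate) - (with 500 uM orthovanadate), per
#' concentration and replicate. Negative differences are measurement
#' noise; they are retained (truncating them would bias downstream fits)
#' and flagged via a message.
#'
#' @param d a [DoseResponse-class].
#' @return data.frame with columns concentration (uM), replicate and
#'   activity (nmol Pi/mg protein/min)
#' @export
vanadateSensitiveActivity <- function(d) {
    stopifnot(is(d, "DoseResponse"))
    out <- data.frame(concentration = d@data$concentration,
                      replicate = d@data$replicate,
                      activity = d@data$activityNoVanadate -
                                 d@data$activityVanadate)
    nneg <- sum(out$activity < 0)
    if (nneg > 0)
        message(nneg, " negative vanadate-sensitive activit",
                ifelse(nneg == 1, "y", "ies"), " retained (noise)")
    out
}

#' Fit a Michaelis--Menten curve
#'
#' Nonlinear least-squares fit of v = Vmax * S / (Km + S) with positivity
#' constraints (Levenberg--Marquardt via minpack.lm). Start values are
#' Vmax0 = max(v) and Km0 = the substrate concentration at the first
#' activity reaching Vmax0/2; standard errors come from the curvature of
#' the squared-error surface at the optimum (the usual asymptotic
#' nonlinear-regression SEs).
#'
#' @param S substrate concentrations, uM (at least 3 distinct positive
#'   values).
#' @param v activities (same length), nmol Pi/mg protein/min.
#' @return a [KineticFit-class]
#' @export
#' @examples
#' S <- c(1, 5, 10, 50, 100, 400, 800)
#' fitMichaelisMenten(S, 20 * S / (10 + S))  # recovers Vmax 20, Km 10
fitMichaelisMenten <- function(S, v) {
    stopifnot(length(S) == length(v))
    if (length(unique(S[S > 0])) < 3L)
        stop("need at least 3 distinct positive concentrations",
             call. = FALSE)
    if (all(v == 0)) stop("all activities are zero", call. = FALSE)
    vmax0 <- max(v)
    ordS <- order(S)
    halfIdx <- which(v[ordS] >= vmax0 / 2)[1]
    km0 <- max(S[ordS][halfIdx], min(S[S > 0]))
    df <- data.frame(S = S, v = v)
    fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                             start = list(Vmax = vmax0, Km = km0),
                             lower = c(Vmax = 1e-12, Km = 1e-12),
                             control = minpack.lm::nls.lm.control(
                                 maxiter = 1000, ftol = 1e-10,
                                 ptol = 1e-10))
    est <- summary(fit)$coefficients
    new("KineticFit",
        vmax = est["Vmax", "Estimate"], vmaxSE = est["Vmax", "Std. Error"],
        km = est["Km", "Estimate"], kmSE = est["Km", "Std. Error"],
        rss = sum(stats::residuals(fit)^2), n = length(v))
}

#' Extra-sum-of-squares F test between two Michaelis--Menten fits
#'
#' Tests whether two dose--response data sets are better described by
#' separate Michaelis--Menten curves than by one shared curve:
#' F = ((RSS_pooled - RSS_separate) / d) / (RSS_separate / df_separate),
#' where RSS_separate = RSS_A + RSS_B, d = 2 (the shared parameters Vmax
#' and Km freed when splitting) and df_separate = n_A + n_B - 4. With
#' noiseless identical data RSS_separate is 0 and F is defined as 0.
#'
#' @param fitA,fitB separate-curve [KineticFit-class] objects.
#' @param fitPooled [KineticFit-class] of the concatenated data.
#' @return list with `F`, `df` (numerator, denominator) and `p`
#' @export
compareCurves <- function(fitA, fitB, fitPooled) {
    rssSep <- fitA@rss + fitB@rss
    rssPool <- fitPooled@rss
    dfNum <- 2L
    dfDen <- fitA@n + fitB@n - 4L
    if (rssSep <= .Machine$double.eps * max(1, rssPool))
        return(list(F = 0, df = c(dfNum, dfDen), p = 1))
    Fstat <- max(0, (rssPool - rssSep) / dfNum / (rssSep / dfDen))
    list(F = Fstat, df = c(dfNum, dfDen),
         p = stats::pf(Fstat, dfNum, dfDen, lower.tail = FALSE))
}

#' Fit and compare two dose--response data sets
#'
#' Convenience wrapper around [fitMichaelisMenten()] and [compareCurves()]:
#' fits each data set separately and pooled, and runs the
#' extra-sum-of-squares F test.
#'
#' @param SA,vA,SB,vB concentration/activity vectors of the two data sets.
#' @return list with `fitA`, `fitB`, `fitPooled` and `test`
#' @export
compareMichaelisMenten <- function(SA, vA, SB, vB) {
    fitA <- fitMichaelisMenten(SA, vA)
    fitB <- fitMichaelisMenten(SB, vB)
    fitPooled <- fitMichaelisMenten(c(SA, SB), c(vA, vB))
    list(fitA = fitA, fitB = fitB, fitPooled = fitPooled,
         test = compareCurves(fitA, fitB, fitPooled))
}

#' Docking-score and Km differences between two transporters
#'
#' Builds the substrate-specificity comparison table: per substrate, the
#' docking score of each transporter, the Michaelis constant where
#' measured, and the differences Delta = value(other) - value(reference).
#' Substrates with docking scores but no kinetics (not experimentally
#' testable) keep `NA` Km columns. Swapping the two transporter labels
#' flips the sign of every Delta.
#'
#' @param scores data.frame with columns substrate, transporter, score
#'   (kcal/mol); both transporters present per substrate.
#' @param km optional data.frame with columns substrate, transporter, km
#'   (uM), or a list of [KineticFit-class] keyed "substrate.transporter".
#' @param transporters character(2): reference transporter first; Delta is
#'   second minus first.
#' @return data.frame: substrate, score_<ref>, score_<other>, km_<ref>,
#'   km_<other>, deltaScore, deltaKm
#' @export
#' @examples
#' sc <- data.frame(substrate = "ouabain",
#'                  transporter = c("T1", "T2"), score = c(-7.8, -8.6))
#' deltaTable(sc, transporters = c("T1", "T2"))$deltaScore  # -0.8
deltaTable <- function(scores, km = NULL, transporters = NULL) {
    stopifnot(all(c("substrate", "transporter", "score") %in% names(scores)))
    if (is.null(transporters)) transporters <- unique(scores$transporter)
    if (length(transporters) != 2L)
        stop("exactly two transporters required", call. = FALSE)
    ref <- transporters[1]; oth <- transporters[2]
    if (is.list(km) && !is.data.frame(km) && length(km))
        km <- do.call(rbind, lapply(names(km), function(nm) {
            parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
            data.frame(substrate = parts[1], transporter = parts[2],
                       km = km[[nm]]@km)
        }))
    subs <- unique(scores$substrate)
    getVal <- function(df, col, s, t) {
        hit <- df[df$substrate == s & df$transporter == t, col]
        if (length(hit) == 0L) NA_real_ else hit[1]
    }
    out <- do.call(rbind, lapply(subs, function(s) {
        s1 <- getVal(scores, "score", s, ref)
        s2 <- getVal(scores, "score", s, oth)
        if (is.na(s1) || is.na(s2))
            stop("missing transporter score for substrate ", s,
                 call. = FALSE)
        k1 <- if (is.null(km)) NA_real_ else getVal(km, "km", s, ref)
        k2 <- if (is.null(km)) NA_real_ else getVal(km, "km", s, oth)
        data.frame(substrate = s, score_ref = s1, score_other = s2,
                   km_ref = k1, km_other = k2,
                   deltaScore = s2 - s1, deltaKm = k2 - k1)
    }))
    names(out)[2:5] <- c(paste0("score_", ref), paste0("score_", oth),
                         paste0("km_", ref), paste0("km_", oth))
    rownames(out) <- NULL
    out
}
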