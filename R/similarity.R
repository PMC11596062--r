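#' @include AllClasses.R utils.R
NULL

#' Similarity factor from interaction counts
#'
#' The similarity factor of a constellation is the fraction of its
#' protein--ligand interactions whose key recurs across multiple ligands:
#' `Sf = B_similar / B_total`. This is the bare ratio; see
#' [constellationSimilarity()] for how the counts are derived from
#' interaction records.
#'
#' @param bSimilar number of interactions recurring in multiple ligands.
#' @param bTotal total number of interactions across the member poses;
#'   must be positive.
#' @return a [SimilarityResult-class]
#' @export
#' @examples
#' similarityFactor(sfFromCounts(13, 19))           # 0.6842...
#' roundHalfUp2 <- function(x) floor(x * 100 + 0.5) / 100
#' roundHalfUp2(similarityFactor(sfFromCounts(7, 13)))  # 0.54
sfFromCounts <- function(bSimilar, bTotal) {
    bSimilar <- as.integer(bSimilar); bTotal <- as.integer(bTotal)
    if (bTotal == 0L)
        stop("similarity factor undefined for zero total interactions",
             call. = FALSE)
    if (bSimilar < 0L || bSimilar > bTotal)
        stop("need 0 <= bSimilar <= bTotal, got ", bSimilar, "/", bTotal,
             call. = FALSE)
    new("SimilarityResult", bTotal = bTotal, bSimilar = bSimilar,
        sf = bSimilar / bTotal)
}

.interactionKeys <- function(records, keyMode) {
    key <- paste(records$chain, records$resnum, records$resname, sep = ":")
    if (keyMode == "residue_and_class")
        key <- paste(key, records$interaction_class, sep = ":")
    key
}

#' Interaction similarity of a constellation
#'
#' Restricts the interaction table to the constellation's member poses and
#' counts, for each record, whether its key -- the residue identity, plus
#' the interaction class under the default `residue_and_class` mode --
#' occurs in the member poses of at least two distinct ligands. `bTotal`
#' is the number of member-pose records, `bSimilar` the number whose key
#' so recurs; each record counts once in both tallies. A member pose with
#' no records contributes zero and is reported via a message.
#'
#' @param constellation a [Constellation-class] (or named member vector).
#' @param records interaction data.frame (see [readInteractionTable()]).
#' @param keyMode `"residue_and_class"` (occurrence and type must match;
#'   default) or `"residue_only"` (coarser: residue identity alone).
#' @return a [SimilarityResult-class]
#' @export
constellationSimilarity <- function(constellation, records,
                                    keyMode = c("residue_and_class",
                                                "residue_only")) {
    keyMode <- match.arg(keyMode)
    mem <- if (is(constellation, "Constellation"))
        constellation@members else constellation
    wanted <- paste0(names(mem), "/", mem)
    poseKey <- paste0(records$ligand_id, "/", records$model_index)
    sub <- records[poseKey %in% wanted, , drop = FALSE]
    empty <- setdiff(wanted, paste0(sub$ligand_id, "/", sub$model_index))
    if (length(empty))
        message("member pose(s) without interaction records: ",
                paste(empty, collapse = ", "))
    bTotal <- nrow(sub)
    if (bTotal == 0L)
        return(new("SimilarityResult", bTotal = 0L, bSimilar = 0L, sf = 0))
    keys <- .interactionKeys(sub, keyMode)
    nLigandsPerKey <- vapply(split(sub$ligand_id, keys), function(x)
        length(unique(x)), integer(1))
    similar <- nLigandsPerKey[keys] >= 2L
    new("SimilarityResult", bTotal = bTotal,
        bSimilar = as.integer(sum(similar)),
        sf = sum(similar) / bTotal)
}

#' Per-class interaction counts and the H-bond/alkyl ratio
#'
#' Tallies interaction records by bond class and reports the ratio of
#' hydrogen bonds (conventional + carbon) to alkyl-type contacts (alkyl +
#' pi-alkyl), a coarse polarity signature of a binding region. The ratio
#' is `NA` when no alkyl-type contacts exist.
#'
#' @param records non-empty interaction data.frame.
#' @return list with `counts` (named integer over the class vocabulary)
#'   and `hbAlkylRatio`
#' @export
bondClassSummary <- function(records) {
    if (nrow(records) == 0L)
        stop("no interaction records to summarize", call. = FALSE)
    counts <- table(factor(records$interaction_class,
                           levels = interactionClasses()))
    counts <- stats::setNames(as.integer(counts), names(counts))
    hb <- counts[["conventional_hbond"]] + counts[["carbon_hbond"]]
    alk <- counts[["alkyl"]] + counts[["pi_alkyl"]]
    list(counts = counts,
         hbAlkylRatio = if (alk == 0L) NA_real_ else hb / alk)
}
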