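#' Closed vocabulary of protein--ligand interaction classes
#'
#' The interaction classes accepted in interaction tables, following the
#' bond categories reported by common interaction-diagram software:
#' conventional and carbon hydrogen bonds, salt bridges / attractive
#' charges, pi-stacking (pi-pi and amide-pi), pi-alkyl and alkyl
#' hydrophobic contacts, van der Waals contacts, and unfavourable contacts.
#'
#' @return character vector of valid class tokens
#' @export
#' @examples
#' interactionClasses()
interactionClasses <- function() {
    c("conventional_hbond", "carbon_hbond", "salt_bridge", "pi_pi",
      "pi_alkyl", "alkyl", "van_der_waals", "unfavorable")
}

# "ligand/model" labels used in matrix dimnames and score vectors
poseLabels <- function(labels) {
    paste0(labels$ligandId, "/", labels$modelIndex)
}

# Round half away from zero at `digits` decimals; report tables print 0.625
# as 0.63, which base round() (half-to-even) would not give.
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer RNG seed stream derived from one master seed; keeps derived seeds
# below 2^31.
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 48271 + 11 * k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
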