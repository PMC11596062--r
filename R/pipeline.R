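#' @include AllClasses.R pose-io.R congruence.R selection.R kinetics.R synthetic.R
NULL

.inputError <- function(...) {
    stop(structure(class = c("dcInputError", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

#' Validated pipeline configuration
#'
#' Builds the run configuration: every parameter that alters numbers lives
#' here (not in command-line flags), so a run is auditable from its config
#' alone. Unknown fields are rejected.
#'
#' @param workdir directory holding (or receiving) the pipeline inputs.
#' @param k congruence-step candidate pool size.
#' @param keyMode interaction key mode (see [constellationSimilarity()]).
#' @param mode constellation search mode (see
#'   [enumerateConstellations()]).
#' @param beamWidth beam width for `mode = "beam"`.
#' @param congruenceThreshold redocking congruence call threshold,
#'   Angstrom.
#' @param mappingMode scaffold correspondence mode.
#' @param dialect pose file dialect.
#' @param seed master seed for the simulate stage.
#' @return a validated config list of class `dcConfig`
#' @export
pipelineConfig <- function(workdir, k = 15L,
                           keyMode = c("residue_and_class", "residue_only"),
                           mode = c("full", "beam"), beamWidth = 200L,
                           congruenceThreshold = 4,
                           mappingMode = c("by_name", "by_graph"),
                           dialect = c("pdb", "pdbqt"), seed = 1L) {
    cfg <- list(workdir = workdir, k = as.integer(k),
                keyMode = match.arg(keyMode), mode = match.arg(mode),
                beamWidth = as.integer(beamWidth),
                congruenceThreshold = congruenceThreshold,
                mappingMode = match.arg(mappingMode),
                dialect = match.arg(dialect), seed = as.integer(seed))
    if (cfg$k < 1L) .inputError("k must be >= 1")
    if (cfg$congruenceThreshold <= 0)
        .inputError("congruenceThreshold must be positive")
    structure(cfg, class = "dcConfig")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()]
#'   arguments.
#' @return a validated config list
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) .inputError("no such config file: ", path)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(pipelineConfig)))
    if (length(unknown))
        .inputError("unknown config field(s): ",
                    paste(unknown, collapse = ", "))
    do.call(pipelineConfig, vals)
}

.logStage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

.configHeader <- function(cfg) {
    sprintf("# config: %s",
            paste(sprintf("%s=%s", names(cfg),
                          vapply(cfg, function(x) paste(format(x), collapse = ","),
                                 character(1))),
                  collapse = " "))
}

#' Run pipeline stages
#'
#' Orchestrates the analysis as subcommands over a demo-or-real workspace:
#'
#' * `simulate`: materialize a synthetic workspace ([makeFixtures()]).
#' * `congruence`: read pose files, resolve scaffold correspondences,
#'   write the all-vs-all RMSD matrix (`rmsd_matrix.tsv`).
#' * `select`: congruence plus interaction similarity; writes the
#'   consensus selection report (`selection.tsv`, `selection.tsv.txt`).
#' * `kinetics`: fit Michaelis--Menten curves per substrate/transporter
#'   from `dose_response.csv`, and when `docking_scores.csv` is present,
#'   write the docking-score vs Km difference table (`delta_table.tsv`).
#' * `all`: simulate (if the workspace is empty) then select and
#'   kinetics.
#'
#' Every artifact carries a header line echoing the config. Re-running a
#' subcommand on identical inputs rewrites identical artifacts.
#'
#' @param subcommand one of `"simulate"`, `"congruence"`, `"select"`,
#'   `"kinetics"`, `"all"`.
#' @param config a `dcConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return named list of artifact paths (and key objects), invisibly
#' @export
runPipeline <- function(subcommand = c("simulate", "congruence", "select",
                                       "kinetics", "all"),
                        config) {
    subcommand <- match.arg(subcommand)
    if (!inherits(config, "dcConfig")) .inputError("invalid config object")
    wd <- config$workdir
    out <- list()
    if (subcommand %in% c("simulate", "all")) {
        if (subcommand == "simulate" ||
            length(list.files(wd, pattern = "\\.pdb$")) == 0L) {
            .logStage("simulate", "workspace -> ", wd,
                      " (seed ", config$seed, ")")
            fx <- makeFixtures(wd, seed = config$seed)
            out$fixtures <- fx[c("poseFiles", "interactions",
                                 "doseResponse")]
        }
        if (subcommand == "simulate") return(invisible(out))
    }
    if (subcommand %in% c("congruence", "select", "all")) {
        paths <- list.files(wd, pattern = "\\.(pdb|pdbqt)$",
                            full.names = TRUE)
        if (length(paths) == 0L)
            .inputError("no pose files in workspace: ", wd)
        poseSet <- readPoseSet(paths, dialect = config$dialect)
        .logStage("congruence", length(poseSet@poses), " poses, ",
                  length(ligandIds(poseSet)), " ligands")
        cores <- poseSetCores(poseSet, mode = config$mappingMode)
        mat <- pairwiseMatrix(cores)
        mp <- file.path(wd, "rmsd_matrix.tsv")
        writeRmsdMatrix(mat, mp)
        out$matrix <- mp
        if (subcommand != "congruence") {
            ip <- file.path(wd, "interactions.tsv")
            records <- if (file.exists(ip)) readInteractionTable(ip) else
                .inputError("no interaction table in workspace: ", ip)
            report <- selectConstellation(poseSet, mat, records,
                                          k = config$k,
                                          keyMode = config$keyMode,
                                          mode = config$mode,
                                          beamWidth = config$beamWidth)
            .logStage("select", "chose constellation #",
                      report@chosen@index, ", Sf = ",
                      sprintf("%.2f", report@similarity@sf))
            sp <- file.path(wd, "selection.tsv")
            writeSelectionReport(report, sp, poseSet)
            out$selection <- sp
            out$report <- report
        }
        if (subcommand != "all") return(invisible(out))
    }
    # kinetics stage
    dp <- file.path(wd, "dose_response.csv")
    if (!file.exists(dp)) .inputError("no dose-response table: ", dp)
    drs <- readDoseResponse(dp)
    fits <- lapply(drs, function(d) {
        act <- suppressMessages(vanadateSensitiveActivity(d))
        fitMichaelisMenten(act$concentration, act$activity)
    })
    .logStage("kinetics", length(fits), " Michaelis-Menten fits")
    fitTab <- data.frame(
        series = names(fits),
        vmax = vapply(fits, function(f) f@vmax, numeric(1)),
        vmax_se = vapply(fits, function(f) f@vmaxSE, numeric(1)),
        km = vapply(fits, function(f) f@km, numeric(1)),
        km_se = vapply(fits, function(f) f@kmSE, numeric(1)),
        rss = vapply(fits, function(f) f@rss, numeric(1)),
        n = vapply(fits, function(f) f@n, integer(1)))
    fp <- file.path(wd, "kinetic_fits.tsv")
    utils::write.table(fitTab, fp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$fits <- fp
    scoresPath <- file.path(wd, "docking_scores.csv")
    if (file.exists(scoresPath)) {
        scores <- utils::read.csv(scoresPath, stringsAsFactors = FALSE)
        transporters <- unique(scores$transporter)
        dt <- deltaTable(scores, km = fits, transporters = transporters)
        dtp <- file.path(wd, "delta_table.tsv")
        utils::write.table(dt, dtp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .logStage("kinetics", "delta table over ",
                  nrow(dt), " substrates -> ", dtp)
        out$deltaTable <- dtp
    }
    invisible(out)
}
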