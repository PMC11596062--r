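#' @include AllClasses.R utils.R
NULL

# Regular n-gon attached to an existing edge (p1 -> p2), placed on the side
# opposite `away`; returns the n-2 new vertices in cyclic order from p1.
.attachRing <- function(p1, p2, n, away) {
    s <- sqrt(sum((p2 - p1)^2))
    mid <- (p1 + p2) / 2
    e <- (p2 - p1) / s
    nrm <- c(-e[2], e[1], 0)
    apothem <- s / (2 * tan(pi / n))
    ctr <- mid + nrm * apothem
    if (sum((ctr - away)^2) < sum((mid - nrm * apothem - away)^2))
        ctr <- mid - nrm * apothem
    rot <- function(p, theta) {
        d <- p - ctr
        ctr + c(cos(theta) * d[1] - sin(theta) * d[2],
                sin(theta) * d[1] + cos(theta) * d[2], 0)
    }
    delta <- 2 * pi / n
    for (sgn in c(1, -1)) {
        last <- rot(p1, sgn * delta * (n - 1))
        if (sum((last - p2)^2) < 1e-12) {
            return(do.call(rbind, lapply(seq_len(n - 2),
                                         function(k) rot(p1, sgn * delta * k))))
        }
    }
    stop("internal: ring closure failed")
}

#' The 25-atom cardenolide core template
#'
#' Builds the common cardenolide aglycone scaffold used for congruence
#' comparison: the 17 carbons of the tetracyclic steroid nucleus (rings
#' A--D, C1--C17), the two angular methyl carbons C18/C19, the four
#' butenolide carbons C20--C23 and the two lactone oxygens (ring oxygen
#' O21, carbonyl oxygen O23) -- 25 heavy atoms, 23 C and 2 O. Glycone
#' (sugar) atoms and aglycone substituents are deliberately absent: they
#' differ between cardenolides and are excluded from the congruence
#' comparison.
#'
#' The exact atom membership of the core is a reconstruction from the
#' scaffold's chemistry (steroid nucleus plus lactone ring); it is a
#' replaceable template object, not hard-coded into the RMSD machinery. The
#' attached reference geometry is an idealized planar fused-ring layout
#' (bond lengths 1.54/1.45/1.22 Angstrom) used by the synthetic-pose
#' generator; correspondence resolution never uses it.
#'
#' @return a [ScaffoldTemplate-class] with 25 atoms
#' @export
#' @examples
#' tpl <- cardenolideTemplate()
#' nrow(tpl@atoms)   # 25
#' table(tpl@atoms$element)
cardenolideTemplate <- function() {
    s <- 1.54
    coords <- list()
    # ring A hexagon: C1 C2 C3 C4 C5 C10
    ringA <- c("C1", "C2", "C3", "C4", "C5", "C10")
    for (k in seq_along(ringA))
        coords[[ringA[k]]] <- c(s * cos(pi / 2 - (k - 1) * pi / 3),
                                s * sin(pi / 2 - (k - 1) * pi / 3), 0)
    ctrA <- c(0, 0, 0)
    # ring B: C5 C6 C7 C8 C9 C10 (fused on C5-C10)
    vb <- .attachRing(coords$C5, coords$C10, 6, ctrA)
    coords$C6 <- vb[1, ]; coords$C7 <- vb[2, ]
    coords$C8 <- vb[3, ]; coords$C9 <- vb[4, ]
    ctrB <- Reduce(`+`, coords[c("C5", "C6", "C7", "C8", "C9", "C10")]) / 6
    # ring C: C8 C9 C11 C12 C13 C14 (fused on C8-C9)
    vc <- .attachRing(coords$C9, coords$C8, 6, ctrB)
    coords$C11 <- vc[1, ]; coords$C12 <- vc[2, ]
    coords$C13 <- vc[3, ]; coords$C14 <- vc[4, ]
    ctrC <- Reduce(`+`, coords[c("C8", "C9", "C11", "C12", "C13", "C14")]) / 6
    # ring D pentagon: C13 C14 C15 C16 C17 (fused on C13-C14)
    vd <- .attachRing(coords$C14, coords$C13, 5, ctrC)
    coords$C15 <- vd[1, ]; coords$C16 <- vd[2, ]; coords$C17 <- vd[3, ]
    ctrD <- Reduce(`+`, coords[c("C13", "C14", "C15", "C16", "C17")]) / 5
    unitv <- function(v) v / sqrt(sum(v^2))
    # angular methyls sit axially (perpendicular to the mean ring plane)
    coords$C18 <- coords$C13 + c(0, 0, 1.54)
    coords$C19 <- coords$C10 + c(0, 0, 1.54)
    # butenolide: C20 bonded to C17; ring cycle C20-C21-O21-C23-C22
    u <- unitv(coords$C17 - ctrD)
    coords$C20 <- coords$C17 + 1.50 * u
    rp <- 1.45 / (2 * sin(pi / 5))
    ctrE <- coords$C20 + rp * u
    theta0 <- atan2(coords$C20[2] - ctrE[2], coords$C20[1] - ctrE[1])
    ringE <- c("C21", "O21", "C23", "C22")
    for (k in seq_along(ringE))
        coords[[ringE[k]]] <- ctrE + rp * c(cos(theta0 + k * 2 * pi / 5),
                                            sin(theta0 + k * 2 * pi / 5), 0)
    coords$O23 <- coords$C23 + 1.22 * unitv(coords$C23 - ctrE)
    labels <- c(paste0("C", 1:17), "C18", "C19", "C20", "C21", "C22", "C23",
                "O21", "O23")
    atoms <- data.frame(label = labels,
                        element = ifelse(startsWith(labels, "O"), "O", "C"),
                        stringsAsFactors = FALSE)
    bonds <- rbind(
        data.frame(from = c("C1", "C2", "C3", "C4", "C5", "C10"),
                   to   = c("C2", "C3", "C4", "C5", "C10", "C1")),
        data.frame(from = c("C5", "C6", "C7", "C8", "C9"),
                   to   = c("C6", "C7", "C8", "C9", "C10")),
        data.frame(from = c("C9", "C11", "C12", "C13", "C14"),
                   to   = c("C11", "C12", "C13", "C14", "C8")),
        data.frame(from = c("C14", "C15", "C16", "C17"),
                   to   = c("C15", "C16", "C17", "C13")),
        data.frame(from = c("C13", "C10", "C17"),
                   to   = c("C18", "C19", "C20")),
        data.frame(from = c("C20", "C21", "O21", "C23", "C20"),
                   to   = c("C21", "O21", "C23", "C22", "C22")),
        data.frame(from = "C23", to = "O23"))
    xyz <- do.call(rbind, coords[labels])
    dimnames(xyz) <- list(labels, c("x", "y", "z"))
    new("ScaffoldTemplate", name = "cardenolide-core-25", atoms = atoms,
        bonds = bonds, coords = xyz)
}

# single-bond covalent radii (Angstrom) for distance-based bond perception
.covalentRadii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

# Bond list of a heavy-atom coordinate set: pair (i, j) bonded when their
# distance is below r_i + r_j + tol.
.perceiveBonds <- function(atoms, tol = 0.45) {
    n <- nrow(atoms)
    r <- .covalentRadii[atoms$element]
    r[is.na(r)] <- 0.77
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    cutoff <- outer(r, r, `+`) + tol
    hits <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    data.frame(from = hits[, 1], to = hits[, 2])
}

#' Map a pose onto the scaffold template
#'
#' Establishes the bijection between the template's atoms and a subset of
#' the pose's heavy atoms, and returns the pose coordinates of the scaffold
#' atoms in template order, so that poses of different ligands can be
#' compared atom-by-atom. Two modes:
#'
#' * `by_name`: template labels are translated through `nameMap`
#'   (defaulting to the identity) and matched against pose atom names.
#'   Deterministic and auditable; the default for curated inputs.
#' * `by_graph`: the pose's heavy-atom connectivity is perceived from
#'   interatomic distances (covalent radii + 0.45 Angstrom tolerance) and
#'   the template graph is located by element-aware subgraph isomorphism.
#'   Fallback for arbitrary atom naming.
#'
#' Glycone and substituent atoms are never part of the template and are
#' therefore excluded automatically. If several graph embeddings exist with
#' coordinates disagreeing beyond 1e-6 Angstrom, an ambiguity error is
#' raised; coordinate-equivalent embeddings are resolved to the one with
#' the lexicographically smallest pose atom serial sequence (with a
#' warning).
#'
#' @param pose a [LigandPose-class].
#' @param template a [ScaffoldTemplate-class].
#' @param mode `"by_name"` or `"by_graph"`.
#' @param nameMap named character vector (template label -> pose atom
#'   name), `by_name` only; `NULL` means identity.
#' @return a [CoreCoordinates-class] with one row per template atom
#' @export
resolveCorrespondence <- function(pose, template,
                                  mode = c("by_name", "by_graph"),
                                  nameMap = NULL) {
    mode <- match.arg(mode)
    heavy <- pose@atoms[!pose@atoms$hydrogen, , drop = FALSE]
    labels <- template@atoms$label
    if (mode == "by_name") {
        if (is.null(nameMap)) nameMap <- stats::setNames(labels, labels)
        missing <- setdiff(labels, names(nameMap))
        if (length(missing))
            stop("name map does not cover template atom(s): ",
                 paste(missing, collapse = ", "), call. = FALSE)
        rows <- match(unname(nameMap[labels]), heavy$name)
        if (anyNA(rows))
            stop("unmapped template atom(s): ",
                 paste(labels[is.na(rows)], collapse = ", "), call. = FALSE)
    } else {
        rows <- .graphEmbedding(heavy, template)
    }
    pts <- as.matrix(heavy[rows, c("x", "y", "z")])
    dimnames(pts) <- list(labels, c("x", "y", "z"))
    new("CoreCoordinates", ligandId = pose@ligandId,
        modelIndex = pose@modelIndex, points = pts)
}

.graphEmbedding <- function(heavy, template) {
    elemLevels <- sort(unique(c(heavy$element, template@atoms$element)))
    poseBonds <- .perceiveBonds(heavy)
    pg <- igraph::make_empty_graph(nrow(heavy), directed = FALSE)
    pg <- igraph::add_edges(pg, t(as.matrix(poseBonds)))
    igraph::V(pg)$color <- match(heavy$element, elemLevels)
    tg <- igraph::graph_from_data_frame(template@bonds, directed = FALSE,
                                        vertices = template@atoms$label)
    igraph::V(tg)$color <- match(template@atoms$element, elemLevels)
    maps <- igraph::subgraph_isomorphisms(pattern = tg, target = pg,
                                          method = "vf2")
    if (length(maps) == 0L)
        stop("no scaffold embedding found in pose ", heavy$name[1],
             "...: unmapped template atoms: ",
             paste(template@atoms$label, collapse = ", "), call. = FALSE)
    # vf2 returns pattern-vertex -> target-vertex maps in template order
    embeddings <- unique(lapply(maps, as.integer))
    coordsOf <- function(rows) as.matrix(heavy[rows, c("x", "y", "z")])
    if (length(embeddings) > 1L) {
        ref <- coordsOf(embeddings[[1]])
        dev <- vapply(embeddings[-1], function(e)
            max(abs(coordsOf(e) - ref)), numeric(1))
        if (any(dev > 1e-6))
            stop("ambiguous scaffold embedding: ",
                 length(embeddings), " embeddings disagree on coordinates: ",
                 paste(vapply(embeddings, function(e)
                     paste(heavy$serial[e], collapse = ","), character(1)),
                     collapse = " | "), call. = FALSE)
        serialSeq <- vapply(embeddings, function(e)
            paste(sprintf("%09d", heavy$serial[e]), collapse = ""),
            character(1))
        warning("multiple coordinate-equivalent embeddings; choosing ",
                "lexicographically smallest serial sequence")
        embeddings <- embeddings[order(serialSeq)[1]]
    }
    embeddings[[1]]
}

#' Shipped atom-name maps for the five cardenolides
#'
#' Reads the packaged name-map config (template label -> pose atom name,
#' one map per ligand). The shipped maps follow the steroid numbering
#' convention (C1..C23, O21, O23) that the synthetic generator also emits;
#' for pose files from other preparation pipelines, edit a copy of the
#' config (see `system.file("extdata", "cardenolide_name_maps.yaml",
#' package = "DockConsensus")`).
#'
#' @param path optional path to an alternative YAML config.
#' @return named list of named character vectors
#' @export
cardenolideNameMaps <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "cardenolide_name_maps.yaml",
                            package = "DockConsensus")
    cfg <- yaml::read_yaml(path)
    cfg <- cfg[!startsWith(names(cfg), ".")]
    lapply(cfg, function(m) unlist(m))
}
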