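# Single-alanine atom template used to tile toy receptors: the middle
# residue of an extended tri-alanine, centred on its CA.
.ala_template <- function() {
    if (!is.null(.pkg_cache$ala_template)) return(.pkg_cache$ala_template)
    pep <- buildPeptide("AAA", dihedralTemplate("extended"))
    a <- pep@structure@atoms
    mid <- a[a$resno == 2, , drop = FALSE]
    xyz <- as.matrix(mid[, c("x", "y", "z")])
    ca <- as.numeric(mid[mid$elety == "CA", c("x", "y", "z")])
    tmpl <- list(elety = mid$elety, element = mid$element,
                 xyz = sweep(xyz, 2, ca))
    .pkg_cache$ala_template <- tmpl
    tmpl
}

# Orient a peptide with its CA principal axis along +x, centred at the
# origin (CA centroid), and its smallest-variance axis along z.
.orient_along_x <- function(structure) {
    xyz <- coords(structure)
    ca <- xyz[structure@atoms$elety == "CA", , drop = FALSE]
    cen <- colMeans(ca)
    pc <- prcomp(sweep(ca, 2, cen))
    R <- t(pc$rotation)
    if (det(R) < 0) R[3, ] <- -R[3, ]
    # make the axis point from first to last CA
    if ((R %*% (ca[nrow(ca), ] - ca[1, ]))[1] < 0)
        R <- diag(c(-1, -1, 1)) %*% R
    replaceCoords(structure, sweep(xyz, 2, cen) %*% t(R))
}

# Rotation taking the template's CA->CB direction onto +z (so a placed
# residue presents its side chain upward).
.cb_up_rotation <- function() {
    tmpl <- .ala_template()
    v <- tmpl$xyz[tmpl$elety == "CB", ]
    v <- v / sqrt(sum(v^2))
    ax <- .cross3(v, c(0, 0, 1))
    s <- sqrt(sum(ax^2))
    d <- v[3]
    if (s < 1e-9) return(if (d > 0) diag(3) else .rotation_about(c(1, 0, 0), 180))
    .rotation_about(ax, atan2(s, d) * 180 / pi)
}

# `resid`: per-residue 3-letter codes; orientation is random except for
# residues flagged in `cb_up`, which present their CB towards +z.
.place_residues <- function(centers, chain = "A", resid = "ALA",
                            cb_up = logical(nrow(centers))) {
    tmpl <- .ala_template()
    resid <- rep_len(resid, nrow(centers))
    rows <- list()
    for (i in seq_len(nrow(centers))) {
        R <- if (cb_up[i]) .cb_up_rotation() else .random_rotation()
        xyz <- sweep(tmpl$xyz %*% t(R), 2, -as.numeric(centers[i, ]))
        rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                                resid = resid[i], elety = tmpl$elety,
                                element = tmpl$element, x = xyz[, 1],
                                y = xyz[, 2], z = xyz[, 3], o = 1, alt = "",
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Deterministic toy receptor-peptide complexes
#'
#' Generates a poly-alanine receptor as a lattice slab, either with a
#' groove sized to hold the chosen peptide conformer
#' (\code{"slab_with_groove"}) or as a convex patch the peptide lies on top
#' of (\code{"convex_patch"}), and places the built peptide in contact. The
#' output is deterministic for a given seed and is the reference ("bound")
#' complex used throughout testing: receptor chain "A", peptide chain "B".
#'
#' @param shape receptor shape.
#' @param sequence peptide one-letter sequence; charged residues (K/R/D/E)
#'   in the groove fixture get a complementary charged receptor residue
#'   placed beneath their native side-chain position, giving the groove
#'   chemical specificity for the bound conformation.
#' @param template conformer template name or \linkS4class{DihedralTemplate}
#'   (default extended, which the groove is sized for).
#' @param grooveWidth wall-to-wall groove width in Angstrom.
#' @param grooveDepth floor depth below the peptide plane in Angstrom.
#' @param seed integer seed controlling residue orientations.
#' @return list with \code{complex}, \code{receptor} (both
#'   \linkS4class{PdbStructure}), \code{peptide} (the placed peptide
#'   structure) and \code{sequence}.
#' @examples
#' fx <- makeComplex(seed = 1)
#' fx$complex
#' @export
makeComplex <- function(shape = c("slab_with_groove", "convex_patch"),
                        sequence = "AAAAAAAA", template = "extended",
                        grooveWidth = 11, grooveDepth = 3.5, seed = 1) {
    shape <- match.arg(shape)
    set.seed(seed)
    if (is.character(template)) template <- dihedralTemplate(template)
    pep <- .orient_along_x(buildPeptide(sequence, template)@structure)
    # present charged side chains towards the groove floor
    pa0 <- pep@atoms
    chg <- !is.na(.CHARGED_RES[pa0$resid]) & pa0$elety == "CB"
    if (any(chg) && mean(pa0$z[chg]) > 0)
        pep <- replaceCoords(pep, coords(pep) %*% t(.rotation_about(c(1, 0, 0), 180)))
    pxyz <- coords(pep)
    xr <- range(pxyz[, 1])
    resid_extra <- character(0)
    cb_up_extra <- logical(0)
    extra <- NULL
    if (shape == "slab_with_groove") {
        if (grooveWidth < 7)
            stop("groove narrower than the peptide diameter")
        s <- 5.5                      # lattice spacing (A)
        half <- grooveWidth / 2
        xs <- seq(xr[1] - s, xr[2] + s, by = s)
        ys <- seq(-2 * s - half, 2 * s + half, by = s)
        centers <- list()
        # floor under everything, two layers thick so the binding funnel is
        # only approachable from the groove side
        for (zf in c(-grooveDepth - 2, -grooveDepth - 7)) for (x in xs) for (y in ys)
            centers[[length(centers) + 1]] <- c(x, y, zf)
        # walls either side of the groove (|y| >= half), plus end caps
        # closing the groove so the native register is unique
        for (x in xs) for (y in ys)
            if (abs(y) >= half || x <= xr[1] - s / 2 || x >= xr[2] + s / 2)
                centers[[length(centers) + 1]] <- c(x, y, -0.5)
        centers <- do.call(rbind, centers)
        # complementary charged residues under each charged peptide side
        # chain, CB pointing up at the native side-chain position: the
        # groove is chemically specific for the bound conformation
        pa <- pep@atoms
        charged <- !is.na(.CHARGED_RES[pa$resid]) & pa$elety == "CB"
        if (any(charged)) {
            partner <- c(LYS = "ASP", ARG = "ASP", ASP = "LYS", GLU = "LYS")
            cb <- pa[charged, , drop = FALSE]
            extra <- cbind(cb$x, cb$y, cb$z - 3.3 - 1.55)
            resid_extra <- unname(partner[cb$resid])
            cb_up_extra <- rep(TRUE, nrow(extra))
        }
    } else {
        # spherical cap below the peptide; peptide rests exposed on top
        Rc <- 16
        centers <- list()
        for (th in seq(0, 50, by = 14) * pi / 180)
            for (ph in seq(0, 330, by = 30) * pi / 180) {
                p <- Rc * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
                centers[[length(centers) + 1]] <- c(p[1], p[2], p[3] - Rc - 5.0)
                if (th == 0) break
            }
        centers <- unique(do.call(rbind, centers))
    }
    resid <- c(rep("ALA", nrow(centers)), resid_extra)
    cb_up <- c(logical(nrow(centers)), cb_up_extra)
    if (!is.null(extra)) centers <- rbind(centers, extra)
    ratoms <- .place_residues(centers, chain = "A", resid = resid,
                              cb_up = cb_up)
    receptor <- newStructure(ratoms, source = sprintf("fixture:%s", shape))
    cx <- mergeStructures(receptor, pep)
    near <- residuesWithin(cx, makeSelection(cx, chain = "A"),
                           makeSelection(cx, chain = "B"), 5)
    if (nrow(near@residues) < 1)
        stop("fixture generation failed: no receptor residue within 5 A")
    list(complex = cx, receptor = receptor, peptide = pep,
         sequence = sequence)
}

# Direct pooled-interface i-RMSD of a rigid peptide perturbation, used to
# calibrate decoys (receptor part fixed, peptide part moved).
.direct_irmsd <- function(recBB, pepBB, pepBB_moved) {
    kabschSuperpose(rbind(recBB, pepBB_moved), rbind(recBB, pepBB))$rmsd
}

#' Decoy models with known quality strata
#'
#' Applies calibrated rigid perturbations (rotation about the peptide
#' centroid plus translation) to the reference peptide so that the pooled
#' interface backbone RMSD lands in planned strata: high (<= 1 A),
#' near_native (1-2 A) and not_acceptable (> 2 A). The perturbation
#' magnitude is found by bisection against a direct pooled-fit RMSD
#' computation; the planned label is recorded for each decoy.
#'
#' @param reference reference complex \linkS4class{PdbStructure} (chains
#'   "A"/"B" as from \code{\link{makeComplex}}).
#' @param counts named integer vector: decoys per stratum, names among
#'   high, near_native, not_acceptable.
#' @param seed integer seed.
#' @param receptorChain,peptideChain chain ids.
#' @return list with \code{models} (list of complexes), \code{truth}
#'   (data.frame: model, stratum, target_irmsd).
#' @export
makeDecoySet <- function(reference,
                         counts = c(high = 2, near_native = 3,
                                    not_acceptable = 3),
                         seed = 1, receptorChain = "A", peptideChain = "B") {
    stopifnot(sum(counts) >= 1)
    set.seed(seed)
    iface <- interfaceSelection(reference, receptorChain, peptideChain)
    recBB <- coords(reference)[
        selectionRows(reference, .with_backbone(iface$receptor)), , drop = FALSE]
    pepSelBB <- .with_backbone(iface$peptide)
    a <- reference@atoms
    pepRows <- which(a$chain == peptideChain)
    pxyz <- coords(reference)[pepRows, , drop = FALSE]
    # positions of the peptide interface backbone within the peptide block
    pepBBrows <- match(selectionRows(reference, pepSelBB), pepRows)
    stopifnot(!anyNA(pepBBrows))
    pepBB <- pxyz[pepBBrows, , drop = FALSE]
    targets <- list(high = c(0.3, 0.8), near_native = c(1.2, 1.8),
                    not_acceptable = c(3.0, 7.0))
    models <- list(); truth <- list(); k <- 0
    for (stratum in names(counts)) for (j in seq_len(counts[[stratum]])) {
        k <- k + 1
        target <- stats::runif(1, targets[[stratum]][1], targets[[stratum]][2])
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
        cen <- colMeans(pxyz)
        move <- function(delta) {
            R <- .rotation_about(axis, delta * 4)   # degrees per A of shift
            sweep(sweep(pxyz, 2, cen) %*% t(R), 2, -(cen + dir * delta))
        }
        ir_of <- function(delta)
            .direct_irmsd(recBB, pepBB, move(delta)[pepBBrows, , drop = FALSE])
        lo <- 0; hi <- 1
        while (ir_of(hi) < target && hi < 64) hi <- hi * 2
        for (it in 1:40) {
            mid <- (lo + hi) / 2
            if (ir_of(mid) < target) lo <- mid else hi <- mid
        }
        newPep <- move((lo + hi) / 2)
        full <- coords(reference)
        full[pepRows, ] <- newPep
        models[[k]] <- replaceCoords(reference, full)
        truth[[k]] <- data.frame(model = k, stratum = stratum,
                                 target_irmsd = target,
                                 stringsAsFactors = FALSE)
    }
    list(models = models, truth = do.call(rbind, truth))
}
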