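#' Van der Waals radii used for SASA and contacts (Angstrom)
#'
#' Element-based radii: C 1.70, N 1.55, O 1.52, S 1.80. Unknown elements
#' raise an error rather than silently defaulting.
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

.pkg_cache <- new.env(parent = emptyenv())

.atom_radii <- function(structure) {
    el <- structure@atoms$element
    unknown <- setdiff(unique(el), names(VDW_RADII))
    if (length(unknown) > 0)
        stop("no van der Waals radius for element(s): ",
             paste(unknown, collapse = ", "))
    unname(VDW_RADII[el])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA by the dot-sphere method: each atom is covered with a
#' deterministic quasi-uniform set of test points on its solvent-expanded
#' sphere; the accessible area is proportional to the fraction of points not
#' buried inside any neighbouring sphere. Hydrogens are never present in a
#' \linkS4class{PdbStructure} and so never contribute.
#'
#' @param structure a \linkS4class{PdbStructure}.
#' @param probe solvent probe radius in Angstrom (default 1.4).
#' @param nPoints test points per atom (default 960); accuracy improves
#'   roughly with sqrt(nPoints).
#' @return numeric vector of per-atom areas (A^2), parallel to
#'   \code{atomTable(structure)}.
#' @export
shrakeRupleySASA <- function(structure, probe = 1.4, nPoints = 960) {
    .sasa_cpp(coords(structure), .atom_radii(structure), probe, as.integer(nPoints))
}

#' Total SASA of a structure
#' @inheritParams shrakeRupleySASA
#' @return total solvent-accessible surface area in A^2.
#' @export
totalSASA <- function(structure, probe = 1.4, nPoints = 960)
    sum(shrakeRupleySASA(structure, probe, nPoints))

# Reference maximal areas per residue type, from the central residue of an
# extended Gly-X-Gly tripeptide built by the conformer module; cached after
# first use so they are self-consistent with this SASA implementation.
.reference_areas <- function(resid3) {
    key <- paste0("ref_", resid3)
    if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
    aa1 <- .AA1[resid3]
    if (is.na(aa1)) stop("no reference areas for nonstandard residue ", resid3)
    pep <- buildPeptide(paste0("G", aa1, "G"), dihedralTemplate("extended"))
    a <- pep@structure@atoms
    sasa <- shrakeRupleySASA(pep@structure)
    mid <- a$resno == 2
    side <- sum(sasa[mid & !(a$elety %in% BACKBONE_ATOMS)])
    back <- sum(sasa[mid & a$elety %in% BACKBONE_ATOMS])
    ref <- c(side = side, backbone = back)
    .pkg_cache[[key]] <- ref
    ref
}

#' Relative solvent accessibility of one residue
#'
#' Side-chain and backbone SASA of the residue in its context structure,
#' divided by reference maximal areas from an extended Gly-X-Gly tripeptide.
#' A residue counts as solvent accessible when either relative value exceeds
#' 0.40. Glycine has no side chain in this representation; its side-chain
#' relative accessibility is reported as 0.
#'
#' @param context the \linkS4class{PdbStructure} the residue sits in.
#' @param chain,resno,insert residue identity within \code{context}.
#' @param threshold accessibility threshold on the relative values
#'   (default 0.40).
#' @return list with \code{side_chain_rel}, \code{backbone_rel},
#'   \code{accessible}.
#' @export
relativeAccessibility <- function(context, chain, resno, insert = "",
                                  threshold = 0.40) {
    a <- context@atoms
    rows <- a$chain == chain & a$resno == resno & a$insert == insert
    if (!any(rows)) stop("residue not found: ", chain, resno, insert)
    resid3 <- a$resid[rows][1]
    ref <- .reference_areas(resid3)
    sasa <- shrakeRupleySASA(context)
    side <- sum(sasa[rows & !(a$elety %in% BACKBONE_ATOMS)])
    back <- sum(sasa[rows & a$elety %in% BACKBONE_ATOMS])
    side_rel <- if (ref["side"] > 0) side / ref["side"] else 0
    back_rel <- if (ref["backbone"] > 0) back / ref["backbone"] else 0
    list(side_chain_rel = unname(side_rel), backbone_rel = unname(back_rel),
         accessible = unname(side_rel > threshold || back_rel > threshold))
}

#' Residues of one selection within a distance cutoff of another
#'
#' Returns the residues of selection A having any heavy atom within
#' \code{cutoff} of any heavy atom of selection B. Used with 5 A to define
#' the docking-active surface and with 10 A for interface definitions.
#'
#' @param structure the \linkS4class{PdbStructure} containing both sides
#'   (e.g. a complex).
#' @param selA,selB \linkS4class{ResidueSelection} objects on
#'   \code{structure}.
#' @param cutoff distance cutoff in Angstrom.
#' @return a \linkS4class{ResidueSelection} (subset of \code{selA}), with
#'   \code{selA}'s atom-name filter preserved.
#' @export
residuesWithin <- function(structure, selA, selB, cutoff) {
    rowsA <- selectionRows(structure, selA)
    rowsB <- selectionRows(structure, selB)
    if (length(rowsA) == 0 || length(rowsB) == 0)
        stop("empty selection in residuesWithin")
    a <- structure@atoms
    xyz <- coords(structure)
    keys <- paste(a$chain, a$resno, a$insert)
    # level i of the factor corresponds to row i of labA (order of appearance)
    grpA <- as.integer(factor(keys[rowsA], levels = unique(keys[rowsA])))
    labA <- unique(a[rowsA, c("chain", "resno", "insert")])
    pairs <- .contact_pairs_cpp(xyz[rowsA, , drop = FALSE], grpA,
                                xyz[rowsB, , drop = FALSE],
                                rep(1L, length(rowsB)), cutoff)
    hit <- sort(unique(pairs[, 1]))
    res <- labA[hit, , drop = FALSE]
    new("ResidueSelection", residues = res, atomNames = selA@atomNames)
}
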