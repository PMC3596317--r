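#' @import methods
#' @importFrom stats optim setNames dist
#' @importFrom utils write.table read.table head
#' @useDynLib PepDock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "o", "alt")

#' Hierarchical protein coordinate set
#'
#' Flat atom-table representation of a (possibly multi-chain) protein
#' structure as read from a PDB file. Author residue numbering is preserved;
#' one row per atom with chain id, residue number, insertion code, residue
#' and atom names, element, coordinates (Angstrom), occupancy and altloc.
#'
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z, o, alt.
#' @slot source character label recording where the coordinates came from.
#' @export
setClass("PdbStructure",
         representation(atoms = "data.frame", source = "character"),
         prototype(source = ""))

setValidity("PdbStructure", function(object) {
    a <- object@atoms
    if (!all(.ATOM_COLS %in% names(a)))
        return(paste("atoms must have columns:", paste(.ATOM_COLS, collapse = ", ")))
    if (nrow(a) == 0) return("structure has zero atoms")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        return("non-finite coordinates")
    if (any(!nzchar(a$element))) return("empty element symbols")
    key <- paste(a$chain, a$resno, a$insert, a$elety, a$alt)
    if (anyDuplicated(key))
        return("duplicate (chain, residue, atom, altloc) records")
    TRUE
})

#' Residue selection with an atom-name filter
#'
#' A set of residues identified by (chain, resno, insertion code) triples,
#' optionally restricted to named atoms (e.g. the backbone set N, CA, C, O).
#' An empty \code{atomNames} means all heavy atoms.
#'
#' @slot residues data.frame with columns chain, resno, insert.
#' @slot atomNames character vector of PDB atom names, or character(0).
#' @export
setClass("ResidueSelection",
         representation(residues = "data.frame", atomNames = "character"),
         prototype(atomNames = character(0)))

setValidity("ResidueSelection", function(object) {
    r <- object@residues
    if (!all(c("chain", "resno", "insert") %in% names(r)))
        return("residues needs columns chain, resno, insert")
    if (anyDuplicated(paste(r$chain, r$resno, r$insert)))
        return("duplicate residues in selection")
    TRUE
})

#' Backbone dihedral template for canonical peptide conformations
#'
#' Holds the ideal (phi, psi, omega) angles, in degrees, defining one of the
#' three canonical peptide conformations: extended (-139, -135), alpha-helix
#' (-57, -47) and polyproline II (-78, 149), all with omega = 180.
#'
#' @slot name one of "extended", "helix", "ppii".
#' @slot phi,psi,omega backbone dihedral angles in degrees, in (-180, 180].
#' @export
setClass("DihedralTemplate",
         representation(name = "character", phi = "numeric",
                        psi = "numeric", omega = "numeric"))

setValidity("DihedralTemplate", function(object) {
    ang <- c(object@phi, object@psi, object@omega)
    if (any(ang <= -180 | ang > 180)) return("angles must lie in (-180, 180]")
    if (!object@name %in% c("extended", "helix", "ppii"))
        return("name must be extended, helix or ppii")
    TRUE
})

#' A peptide conformer built from sequence
#'
#' Single-chain peptide coordinates generated by internal-coordinate chain
#' extension from a one-letter sequence and a \linkS4class{DihedralTemplate}.
#' Backbone (N, CA, C, O) plus CB (except glycine) are built; interior
#' phi/psi equal the template values exactly.
#'
#' @slot structure a \linkS4class{PdbStructure} with a single chain.
#' @slot template the \linkS4class{DihedralTemplate} used.
#' @slot sequence one-letter amino-acid string.
#' @slot termini named character vector c(n = ..., c = ...), each "charged"
#'   or "neutral"; consumed only by the electrostatic term.
#' @export
setClass("PeptideConformer",
         representation(structure = "PdbStructure",
                        template = "DihedralTemplate",
                        sequence = "character",
                        termini = "character"))

setValidity("PeptideConformer", function(object) {
    n <- nchar(object@sequence)
    nres <- length(unique(object@structure@atoms$resno))
    if (n != nres) return("residue count differs from sequence length")
    if (!all(object@termini %in% c("charged", "neutral")))
        return("termini flags must be 'charged' or 'neutral'")
    TRUE
})

#' Ambiguous interaction restraint set
#'
#' Active residues on the receptor (enforced to be at the interface) and
#' passive residues on the peptide (allowed to be), plus the effective
#' distance parameters of the flat-bottom restraint.
#'
#' @slot active receptor-side \linkS4class{ResidueSelection} (non-empty).
#' @slot passive peptide-side \linkS4class{ResidueSelection}.
#' @slot upperBound effective-distance upper bound in Angstrom.
#' @slot forceConstant restraint force constant (kcal/mol/A^2).
#' @export
setClass("AirRestraintSet",
         representation(active = "ResidueSelection",
                        passive = "ResidueSelection",
                        upperBound = "numeric",
                        forceConstant = "numeric"),
         prototype(upperBound = 2.0, forceConstant = 50))

setValidity("AirRestraintSet", function(object) {
    if (nrow(object@active@residues) == 0) return("active selection is empty")
    if (object@upperBound <= 0 || object@forceConstant <= 0)
        return("upperBound and forceConstant must be positive")
    TRUE
})

#' Result of ensemble rigid-body docking
#'
#' Container for the pose pool produced by \code{\link{samplePoses}}: the
#' receptor, the input conformer ensemble, a score table (one row per pose:
#' model_id, conformer, seed, score components, total) and the final peptide
#' coordinates of every pose.
#'
#' @slot receptor the fixed \linkS4class{PdbStructure}.
#' @slot conformers named list of \linkS4class{PeptideConformer} objects.
#' @slot poses data.frame of per-pose provenance and score components.
#' @slot coords list of n_atoms x 3 matrices, one per pose, parallel to
#'   \code{poses}.
#' @export
setClass("DockingResult",
         representation(receptor = "PdbStructure",
                        conformers = "list",
                        poses = "data.frame",
                        coords = "list"))

setValidity("DockingResult", function(object) {
    if (nrow(object@poses) != length(object@coords))
        return("poses table and coords list lengths differ")
    if (nrow(object@poses) > 0) {
        if (!all(object@poses$conformer %in% names(object@conformers)))
            return("pose conformer ids not all in the ensemble")
        if (!all(is.finite(object@poses$total)))
            return("non-finite pose scores")
    }
    TRUE
})

setMethod("show", "PdbStructure", function(object) {
    a <- object@atoms
    ch <- unique(a$chain)
    nres <- length(unique(paste(a$chain, a$resno, a$insert)))
    cat(sprintf("PdbStructure: %d atoms, %d residues, %d chain(s) [%s]\n",
                nrow(a), nres, length(ch), paste(ch, collapse = ",")))
    if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "PeptideConformer", function(object) {
    cat(sprintf("PeptideConformer: %s, %d residues, template %s (phi %g, psi %g)\n",
                object@sequence, nchar(object@sequence),
                object@template@name, object@template@phi, object@template@psi))
})

setMethod("show", "AirRestraintSet", function(object) {
    cat(sprintf(
        "AirRestraintSet: %d active / %d passive residues, upper bound %.1f A, k = %g\n",
        nrow(object@active@residues), nrow(object@passive@residues),
        object@upperBound, object@forceConstant))
})

setMethod("show", "DockingResult", function(object) {
    cat(sprintf("DockingResult: %d poses from %d conformer(s)\n",
                nrow(object@poses), length(object@conformers)))
    if (nrow(object@poses) > 0)
        cat(sprintf("  score range: [%.2f, %.2f]\n",
                    min(object@poses$total), max(object@poses$total)))
})

#' Accessors
#'
#' \code{atomTable} returns the flat atom data.frame of a structure;
#' \code{coords} its n x 3 coordinate matrix; \code{nAtoms} the atom count;
#' \code{chainIds} the chain identifiers; \code{posesTable} the per-pose
#' score table of a \linkS4class{DockingResult}.
#'
#' @param x a \linkS4class{PdbStructure}, \linkS4class{PeptideConformer} or
#'   \linkS4class{DockingResult}.
#' @return See the per-function description.
#' @aliases atomTable coords nAtoms chainIds posesTable
#' @name accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("posesTable", function(x) standardGeneric("posesTable"))

#' @rdname accessors
setMethod("atomTable", "PdbStructure", function(x) x@atoms)
#' @rdname accessors
setMethod("atomTable", "PeptideConformer", function(x) x@structure@atoms)
#' @rdname accessors
setMethod("coords", "PdbStructure", function(x)
    as.matrix(x@atoms[, c("x", "y", "z")]))
#' @rdname accessors
setMethod("coords", "PeptideConformer", function(x) coords(x@structure))
#' @rdname accessors
setMethod("nAtoms", "PdbStructure", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "PeptideConformer", function(x) nrow(x@structure@atoms))
#' @rdname accessors
setMethod("chainIds", "PdbStructure", function(x) unique(x@atoms$chain))
#' @rdname accessors
setMethod("posesTable", "DockingResult", function(x) x@poses)
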