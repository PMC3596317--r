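#' Extendedness cutoff (Angstrom per residue)
#'
#' A peptide counts as extended when its per-residue CA extension reaches
#' 80\% of the ideal extended value of 3.46 A: 0.8 x 3.46 = 2.8 (to the
#' printed precision, the product is 2.768; the rounded 2.8 is used, as
#' printed).
#' @export
EXTENDED_CUTOFF <- round(3.46 * 0.8, 1)

# Helical Ramachandran window + minimum run length used in place of a
# secondary-structure program, which is unreliable on very short chains.
.HELIX_WINDOW <- list(phi = c(-100, -30), psi = c(-80, -5))
.HELIX_MIN_RUN <- 4

#' Flag helical residues of a peptide
#'
#' A residue is helical iff its (phi, psi) lies in the alpha-helical window
#' (phi in [-100, -30], psi in [-80, -5]) and it belongs to a run of at
#' least 4 consecutive such residues. Terminal residues lacking phi or psi
#' are never helical. An externally computed secondary-structure string
#' (e.g. from DSSP/STRIDE) can be supplied instead; characters in "HGI"
#' count as helical.
#'
#' @param structure single-chain peptide \linkS4class{PdbStructure}.
#' @param ss optional external per-residue secondary-structure string.
#' @return logical vector, one flag per residue.
#' @export
assignHelicalResidues <- function(structure, ss = NULL) {
    tors <- measurePhiPsi(structure)
    n <- nrow(tors)
    if (!is.null(ss)) {
        ssv <- strsplit(ss, "")[[1]]
        if (length(ssv) != n) stop("secondary-structure string length mismatch")
        return(ssv %in% c("H", "G", "I"))
    }
    w <- .HELIX_WINDOW
    in_win <- !is.na(tors$phi) & !is.na(tors$psi) &
        tors$phi >= w$phi[1] & tors$phi <= w$phi[2] &
        tors$psi >= w$psi[1] & tors$psi <= w$psi[2]
    flags <- rep(FALSE, n)
    r <- rle(in_win)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values))
        if (r$values[k] && r$lengths[k] >= .HELIX_MIN_RUN)
            flags[starts[k]:ends[k]] <- TRUE
    flags
}

#' Conformational class of a peptide
#'
#' Helix if more than half of the residues are helical; otherwise extended
#' if the per-residue CA extension is at least \code{EXTENDED_CUTOFF}
#' (2.8 A); otherwise disordered. The helix test is evaluated first.
#'
#' @inheritParams assignHelicalResidues
#' @return list with \code{label} ("helix", "extended" or "disordered"),
#'   \code{helical_fraction} and \code{extension} (A/residue).
#' @examples
#' classifyPeptide(buildPeptide("AAAAAAAA", "helix")@structure)$label
#' @export
classifyPeptide <- function(structure, ss = NULL) {
    flags <- assignHelicalResidues(structure, ss)
    frac <- mean(flags)
    ext <- perResidueExtension(structure)
    label <- if (frac > 0.5) "helix"
             else if (ext >= EXTENDED_CUTOFF) "extended"
             else "disordered"
    list(label = label, helical_fraction = frac, extension = ext)
}

#' Docking difficulty from bound-peptide deviation
#'
#' Builds the ideal extended conformer of the sequence, superposes it on the
#' bound peptide over backbone atoms (Kabsch) and classifies by the post-fit
#' backbone RMSD: easy (<= 4 A), medium (4-8 A, upper bound inclusive) or
#' difficult (> 8 A).
#'
#' @param boundPeptide the peptide \linkS4class{PdbStructure} from the
#'   complex.
#' @param sequence its one-letter sequence (must match the residue count).
#' @return list with \code{label} and \code{rmsd_to_extended} (A).
#' @export
classifyDifficulty <- function(boundPeptide, sequence) {
    a <- boundPeptide@atoms
    nres <- length(unique(paste(a$resno, a$insert)))
    if (nchar(sequence) != nres)
        stop("sequence length ", nchar(sequence),
             " does not match bound peptide residue count ", nres)
    ext <- buildPeptide(sequence, dihedralTemplate("extended"))
    bb_bound <- .backbone_matrix(boundPeptide)
    bb_ext <- .backbone_matrix(ext@structure)
    if (nrow(bb_bound) != nrow(bb_ext))
        stop("backbone pairing mismatch between bound peptide and extended build")
    rmsd <- kabschSuperpose(bb_ext, bb_bound)$rmsd
    list(label = difficultyClass(rmsd), rmsd_to_extended = rmsd)
}

#' Difficulty class from the bound/extended RMSD
#'
#' easy for RMSD <= 4 A, medium for 4 < RMSD <= 8 A, difficult above 8 A
#' (upper bounds inclusive).
#'
#' @param rmsd backbone RMSD value(s) between the bound peptide and its
#'   ideal extended build, in Angstrom.
#' @return character vector of class labels.
#' @export
difficultyClass <- function(rmsd) {
    ifelse(rmsd <= 4, "easy", ifelse(rmsd <= 8, "medium", "difficult"))
}

# Backbone coordinates in residue order (N, CA, C, O per residue, present
# atoms only; a missing carbonyl O is dropped from the pairing).
.backbone_matrix <- function(structure) {
    a <- structure@atoms
    rows <- unlist(lapply(.residue_split(a), function(r) {
        r[match(BACKBONE_ATOMS, a$elety[r], nomatch = 0)]
    }), use.names = FALSE)
    coords(structure)[rows, , drop = FALSE]
}

#' Receptor interface conformational change between bound and unbound forms
#'
#' The receptor interface is defined as residues within 10 A of the peptide
#' in the complex; the returned value is the post-fit backbone RMSD of those
#' residues between the bound and unbound receptor (mapped by residue
#' number). Values above 2 A flag a large conformational change.
#'
#' @param complexStructure reference complex \linkS4class{PdbStructure}.
#' @param unbound unbound receptor \linkS4class{PdbStructure}.
#' @param receptorChain,peptideChain chain ids within the complex.
#' @param cutoff interface cutoff in Angstrom (default 10).
#' @return list with \code{rmsd} (A), \code{large_change} (> 2 A flag) and
#'   \code{interface} (the \linkS4class{ResidueSelection} used).
#' @export
receptorConformationalChange <- function(complexStructure, unbound,
                                         receptorChain, peptideChain,
                                         cutoff = 10) {
    iface <- residuesWithin(complexStructure,
                            makeSelection(complexStructure, chain = receptorChain),
                            makeSelection(complexStructure, chain = peptideChain),
                            cutoff)
    ifaceBB <- new("ResidueSelection", residues = iface@residues,
                   atomNames = BACKBONE_ATOMS)
    ub <- unbound@atoms
    mappable <- paste(iface@residues$resno, iface@residues$insert) %in%
        paste(ub$resno, ub$insert)
    if (!all(mappable)) {
        warning("interface residues not mappable to the unbound form, excluded: ",
                paste(iface@residues$resno[!mappable], collapse = ", "))
        ifaceBB@residues <- ifaceBB@residues[mappable, , drop = FALSE]
    }
    boundRows <- selectionRows(complexStructure, ifaceBB)
    ubSel <- new("ResidueSelection",
                 residues = data.frame(chain = ub$chain[1],
                                       resno = ifaceBB@residues$resno,
                                       insert = ifaceBB@residues$insert),
                 atomNames = BACKBONE_ATOMS)
    ubRows <- selectionRows(unbound, ubSel)
    ba <- complexStructure@atoms[boundRows, ]
    ua <- unbound@atoms[ubRows, ]
    key_b <- paste(ba$resno, ba$insert, ba$elety)
    key_u <- paste(ua$resno, ua$insert, ua$elety)
    common <- intersect(key_b, key_u)
    bxyz <- as.matrix(ba[match(common, key_b), c("x", "y", "z")])
    uxyz <- as.matrix(ua[match(common, key_u), c("x", "y", "z")])
    rmsd <- kabschSuperpose(uxyz, bxyz)$rmsd
    list(rmsd = rmsd, large_change = rmsd > 2.0, interface = iface)
}
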