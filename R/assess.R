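.with_backbone <- function(sel)
    new("ResidueSelection", residues = sel@residues, atomNames = BACKBONE_ATOMS)

# Paired coordinates (reference, model) for one selection, matched by
# (chain, resno, insert, atom name). Errors list missing correspondences.
.paired_coords <- function(model, reference, sel) {
    refRows <- selectionRows(reference, sel)
    ra <- reference@atoms[refRows, , drop = FALSE]
    ma <- model@atoms
    keyR <- paste(ra$chain, ra$resno, ra$insert, ra$elety)
    keyM <- paste(ma$chain, ma$resno, ma$insert, ma$elety)
    hit <- match(keyR, keyM)
    if (anyNA(hit))
        stop("model lacks atoms matching the reference: ",
             paste(head(keyR[is.na(hit)], 5), collapse = "; "),
             if (sum(is.na(hit)) > 5) " ...")
    list(ref = as.matrix(ra[, c("x", "y", "z")]),
         mod = as.matrix(ma[hit, c("x", "y", "z")]))
}

#' Reference interface selections for assessment
#'
#' Both-sided interface at \code{cutoff} (default 10 A), always defined on
#' the reference complex (never on a model): receptor residues within the
#' cutoff of the peptide and vice versa. Compute once per case and reuse
#' for all models.
#'
#' @param reference reference complex \linkS4class{PdbStructure}.
#' @param receptorChain,peptideChain chain ids in the reference.
#' @param cutoff heavy-atom distance cutoff (A).
#' @return list with \code{receptor} and \code{peptide}
#'   \linkS4class{ResidueSelection} objects.
#' @export
interfaceSelection <- function(reference, receptorChain, peptideChain,
                               cutoff = 10) {
    recSel <- makeSelection(reference, chain = receptorChain)
    pepSel <- makeSelection(reference, chain = peptideChain)
    rec <- residuesWithin(reference, recSel, pepSel, cutoff)
    pep <- residuesWithin(reference, pepSel, recSel, cutoff)
    if (nrow(rec@residues) == 0 || nrow(pep@residues) == 0)
        stop("empty interface at cutoff ", cutoff, " A")
    list(receptor = rec, peptide = pep)
}

#' Interface RMSD (i-RMSD)
#'
#' Backbone RMSD over the pooled interface residues of both molecules
#' (reference-defined, 10 A) after Kabsch superposition on those same
#' atoms.
#'
#' @param model model complex \linkS4class{PdbStructure} (chains named as
#'   in the reference).
#' @param reference reference complex.
#' @param interfaces list from \code{\link{interfaceSelection}}.
#' @return i-RMSD in Angstrom.
#' @export
iRMSD <- function(model, reference, interfaces) {
    pr <- .paired_coords(model, reference, .with_backbone(interfaces$receptor))
    pp <- .paired_coords(model, reference, .with_backbone(interfaces$peptide))
    kabschSuperpose(rbind(pr$mod, pp$mod), rbind(pr$ref, pp$ref))$rmsd
}

#' Ligand RMSD (l-RMSD)
#'
#' Peptide backbone RMSD after fitting the model on the reference over all
#' receptor backbone atoms (no second fit on the peptide).
#'
#' @inheritParams iRMSD
#' @param receptorChain,peptideChain chain ids.
#' @return l-RMSD in Angstrom.
#' @export
lRMSD <- function(model, reference, receptorChain, peptideChain) {
    rec <- .paired_coords(model, reference,
                          makeSelection(reference, chain = receptorChain,
                                        atomNames = BACKBONE_ATOMS))
    pep <- .paired_coords(model, reference,
                          makeSelection(reference, chain = peptideChain,
                                        atomNames = BACKBONE_ATOMS))
    fit <- kabschSuperpose(rec$mod, rec$ref)
    rmsdNoFit(applyTransform(pep$mod, fit$rotation, fit$translation), pep$ref)
}

#' Ligand-interface RMSD (l-i-RMSD)
#'
#' Peptide interface backbone RMSD after fitting on the receptor interface
#' backbone; 2.0 A is the usual near-native threshold on this metric.
#'
#' @inheritParams iRMSD
#' @return l-i-RMSD in Angstrom.
#' @export
liRMSD <- function(model, reference, interfaces) {
    rec <- .paired_coords(model, reference, .with_backbone(interfaces$receptor))
    pep <- .paired_coords(model, reference, .with_backbone(interfaces$peptide))
    fit <- kabschSuperpose(rec$mod, rec$ref)
    rmsdNoFit(applyTransform(pep$mod, fit$rotation, fit$translation), pep$ref)
}

.residue_contacts <- function(structure, receptorChain, peptideChain, cutoff) {
    a <- structure@atoms
    recRows <- which(a$chain == receptorChain)
    pepRows <- which(a$chain == peptideChain)
    keyR <- paste(a$resno, a$insert)[recRows]
    keyP <- paste(a$resno, a$insert)[pepRows]
    gR <- as.integer(factor(keyR, levels = unique(keyR)))
    gP <- as.integer(factor(keyP, levels = unique(keyP)))
    xyz <- coords(structure)
    pairs <- .contact_pairs_cpp(xyz[recRows, , drop = FALSE], gR,
                                xyz[pepRows, , drop = FALSE], gP, cutoff)
    paste(unique(keyR)[pairs[, 1]], unique(keyP)[pairs[, 2]], sep = "|")
}

#' Fraction of native contacts (Fnat)
#'
#' Native contacts are receptor-residue/peptide-residue pairs with any
#' heavy-atom pair closer than \code{cutoff} (default 5 A) in the
#' reference; Fnat is the fraction of them present in the model.
#'
#' @inheritParams lRMSD
#' @param cutoff contact distance cutoff (A).
#' @return fraction in [0, 1].
#' @export
fnat <- function(model, reference, receptorChain, peptideChain, cutoff = 5) {
    native <- .residue_contacts(reference, receptorChain, peptideChain, cutoff)
    if (length(native) == 0)
        stop("reference has no native contacts at ", cutoff,
             " A: malformed reference")
    modelc <- .residue_contacts(model, receptorChain, peptideChain, cutoff)
    length(intersect(native, modelc)) / length(native)
}

#' CAPRI-style quality class from i-RMSD
#'
#' high for i-RMSD <= 1 A, near_native for 1 < i-RMSD <= 2 A,
#' not_acceptable above 2 A (boundaries inclusive). "Acceptable" means
#' near-native or better.
#'
#' @param i_rmsd i-RMSD value(s) in Angstrom.
#' @return character vector of class labels.
#' @export
qualityClass <- function(i_rmsd) {
    ifelse(i_rmsd <= 1, "high",
           ifelse(i_rmsd <= 2, "near_native", "not_acceptable"))
}

#' Assess a set of models against a reference complex
#'
#' Computes i-RMSD, l-RMSD, l-i-RMSD, Fnat and the quality class for every
#' model, reusing one reference interface definition.
#'
#' @param models a \linkS4class{DockingResult} or a list of model complex
#'   \linkS4class{PdbStructure} objects.
#' @param reference reference complex.
#' @param receptorChain,peptideChain chain ids.
#' @return data.frame with one row per model: model, i_rmsd, l_rmsd,
#'   l_i_rmsd, fnat, quality.
#' @export
assessModels <- function(models, reference, receptorChain, peptideChain) {
    interfaces <- interfaceSelection(reference, receptorChain, peptideChain)
    if (is(models, "DockingResult")) {
        idx <- seq_len(nrow(models@poses))
        get <- function(i) poseComplex(models, i)
        ids <- models@poses$model_id
    } else {
        idx <- seq_along(models)
        get <- function(i) models[[i]]
        ids <- idx
    }
    rows <- lapply(idx, function(i) {
        m <- get(i)
        ir <- iRMSD(m, reference, interfaces)
        data.frame(model = ids[i], i_rmsd = ir,
                   l_rmsd = lRMSD(m, reference, receptorChain, peptideChain),
                   l_i_rmsd = liRMSD(m, reference, interfaces),
                   fnat = fnat(m, reference, receptorChain, peptideChain),
                   quality = qualityClass(ir), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Success as a function of the number of top models considered
#'
#' Given quality classes in rank order (best-scored first), reports for
#' each N whether at least one of the top N models is acceptable
#' (near-native or better). The curve is monotone non-decreasing.
#'
#' @param quality character vector of quality classes in score rank order.
#' @param N vector of top-N values (default 1..length(quality)).
#' @return named numeric vector of 0/1 success flags per N.
#' @export
successCurve <- function(quality, N = seq_along(quality)) {
    acceptable <- quality %in% c("high", "near_native")
    hit <- cumsum(acceptable) > 0
    out <- as.numeric(hit[pmin(N, length(hit))])
    names(out) <- N
    out
}
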