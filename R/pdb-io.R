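#' Backbone atom set used throughout
#'
#' The backbone atom names used for RMSD metrics, superposition and helix
#' assignment: N, CA, C and the carbonyl O.
#' @export
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- setNames(names(.AA3), .AA3)

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

newStructure <- function(atoms, source = "") {
    rownames(atoms) <- NULL
    new("PdbStructure", atoms = atoms[, .ATOM_COLS], source = source)
}

.guess_element <- function(elety) {
    e <- sub("^[0-9]+", "", trimws(elety))
    two <- toupper(substr(e, 1, 2))
    ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA"),
           two, toupper(substr(e, 1, 1)))
}

.resolve_altloc <- function(atoms) {
    if (all(atoms$alt == "")) return(atoms)
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
        if (length(i) == 1) return(i)
        i[order(-atoms$o[i], seq_along(i))][1]
    }), use.names = FALSE)
    out <- atoms[sort(keep), , drop = FALSE]
    out$alt <- ""
    out
}

.atoms_from_bio3d <- function(at, xyz = NULL) {
    insert <- at$insert
    insert[is.na(insert)] <- ""
    alt <- at$alt
    alt[is.na(alt)] <- ""
    chain <- at$chain
    chain[is.na(chain) | chain == ""] <- "A"
    elem <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
        toupper(trimws(at$elesy)) else .guess_element(at$elety)
    elem[!nzchar(elem)] <- .guess_element(at$elety[!nzchar(elem)])
    occ <- at$o
    occ[is.na(occ)] <- 1
    df <- data.frame(chain = chain, resno = as.integer(at$resno),
                     insert = insert, resid = toupper(at$resid),
                     elety = trimws(at$elety), element = elem,
                     x = at$x, y = at$y, z = at$z, o = occ, alt = alt,
                     stringsAsFactors = FALSE)
    if (!is.null(xyz)) {
        m <- matrix(xyz, ncol = 3, byrow = TRUE)
        df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
    }
    df
}

.clean_atoms <- function(df) {
    df <- df[!(df$resid %in% .WATER_RESID), , drop = FALSE]
    df <- df[df$element != "H" & df$element != "D", , drop = FALSE]
    .resolve_altloc(df)
}

#' Read a PDB file into a PdbStructure
#'
#' Parses ATOM/HETATM records (via bio3d), keeping only the first MODEL of
#' multi-model files, dropping waters and hydrogens, and resolving alternate
#' locations by highest occupancy (ties go to the first record).
#'
#' @param path path to a PDB file.
#' @return a \linkS4class{PdbStructure}.
#' @examples
#' pdb <- writePDB(buildPeptide("AAA", dihedralTemplate("extended"))@structure,
#'                 tempfile(fileext = ".pdb"))
#' readPDB(pdb)
#' @export
readPDB <- function(path) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
    df <- .clean_atoms(.atoms_from_bio3d(pdb$atom))
    if (nrow(df) == 0) stop("no protein atoms in ", path)
    newStructure(df, source = path)
}

#' Read a multi-model PDB ensemble
#'
#' @param path path to a PDB file with MODEL/ENDMDL records.
#' @return a list of \linkS4class{PdbStructure}, one per model.
#' @export
readPDBEnsemble <- function(path) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    nm <- if (is.matrix(xyz)) nrow(xyz) else 1
    lapply(seq_len(nm), function(i) {
        row <- if (is.matrix(xyz)) xyz[i, ] else xyz
        df <- .clean_atoms(.atoms_from_bio3d(pdb$atom, xyz = row))
        if (nrow(df) == 0) stop("model ", i, " has no protein atoms")
        newStructure(df, source = sprintf("%s#%d", path, i))
    })
}

.format_atom_name <- function(elety, element) {
    ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
           ifelse(nchar(element) == 1,
                  formatC(paste0(" ", elety), width = -4),
                  formatC(elety, width = -4)))
}

.atom_records <- function(atoms, serial_start = 1L) {
    sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial_start + seq_len(nrow(atoms)) - 1L,
            .format_atom_name(atoms$elety, atoms$element), atoms$alt,
            atoms$resid, atoms$chain, atoms$resno, atoms$insert,
            atoms$x, atoms$y, atoms$z, atoms$o, 0, atoms$element)
}

#' Write one structure, or an ensemble, in PDB format
#'
#' A list input is written as a multi-model file (MODEL/ENDMDL records);
#' a single \linkS4class{PdbStructure} as a plain single-model file. TER
#' records separate chains.
#'
#' @param x a \linkS4class{PdbStructure} or a list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(x, path) {
    if (is(x, "PdbStructure")) x <- list(x)
    multi <- length(x) > 1
    lines <- character(0)
    for (i in seq_along(x)) {
        stopifnot(is(x[[i]], "PdbStructure"))
        if (multi) lines <- c(lines, sprintf("MODEL     %4d", i))
        atoms <- x[[i]]@atoms
        for (ch in unique(atoms$chain)) {
            sub <- atoms[atoms$chain == ch, , drop = FALSE]
            lines <- c(lines, .atom_records(sub), "TER")
        }
        if (multi) lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Build a residue selection
#'
#' Constructs a \linkS4class{ResidueSelection} against a structure, checking
#' that every requested residue exists.
#'
#' @param structure target \linkS4class{PdbStructure}.
#' @param chain chain id(s) to include; NULL = all chains.
#' @param resno residue numbers to include; NULL = all residues of the
#'   chosen chains.
#' @param atomNames atom-name filter (e.g. \code{BACKBONE_ATOMS});
#'   character(0) means all heavy atoms.
#' @return a \linkS4class{ResidueSelection}.
#' @export
makeSelection <- function(structure, chain = NULL, resno = NULL,
                          atomNames = character(0)) {
    a <- structure@atoms
    keep <- rep(TRUE, nrow(a))
    if (!is.null(chain)) keep <- keep & a$chain %in% chain
    if (!is.null(resno)) keep <- keep & a$resno %in% resno
    res <- unique(a[keep, c("chain", "resno", "insert")])
    if (nrow(res) == 0) stop("selection resolves to no residues")
    new("ResidueSelection", residues = res, atomNames = as.character(atomNames))
}

#' Atom rows matched by a selection
#'
#' @param structure a \linkS4class{PdbStructure}.
#' @param selection a \linkS4class{ResidueSelection}.
#' @param strict error if a selected residue is absent from the structure
#'   (default TRUE).
#' @return integer vector of row indices into \code{atomTable(structure)}.
#' @export
selectionRows <- function(structure, selection, strict = TRUE) {
    a <- structure@atoms
    r <- selection@residues
    want <- paste(r$chain, r$resno, r$insert)
    have <- paste(a$chain, a$resno, a$insert)
    if (strict && !all(want %in% have))
        stop("selection refers to residues absent from the structure: ",
             paste(setdiff(want, have), collapse = "; "))
    rows <- which(have %in% want)
    if (length(selection@atomNames) > 0)
        rows <- rows[a$elety[rows] %in% selection@atomNames]
    rows
}

#' Extract one chain as a new structure
#' @param structure a \linkS4class{PdbStructure}.
#' @param chain a chain identifier present in the structure.
#' @return a \linkS4class{PdbStructure} holding only that chain.
#' @export
chainStructure <- function(structure, chain) {
    a <- structure@atoms[structure@atoms$chain == chain, , drop = FALSE]
    if (nrow(a) == 0) stop("no such chain: ", chain)
    newStructure(a, source = structure@source)
}

#' Concatenate structures into one (e.g. receptor + peptide complex)
#' @param ... \linkS4class{PdbStructure} objects with disjoint chain ids.
#' @return the combined \linkS4class{PdbStructure}.
#' @export
mergeStructures <- function(...) {
    parts <- list(...)
    atoms <- do.call(rbind, lapply(parts, atomTable))
    newStructure(atoms, source = paste(vapply(parts, function(p) p@source,
                                              character(1)), collapse = "+"))
}

#' Replace the coordinates of a structure
#' @param structure a \linkS4class{PdbStructure}.
#' @param xyz an nAtoms x 3 matrix.
#' @return the structure with new coordinates.
#' @export
replaceCoords <- function(structure, xyz) {
    stopifnot(nrow(xyz) == nrow(structure@atoms), ncol(xyz) == 3)
    structure@atoms$x <- xyz[, 1]
    structure@atoms$y <- xyz[, 2]
    structure@atoms$z <- xyz[, 3]
    structure
}

#' One-letter sequence of a chain
#' @param structure a \linkS4class{PdbStructure}.
#' @param chain chain id; NULL for the first chain.
#' @return one-letter amino-acid string ("X" for nonstandard residues).
#' @export
chainSequence <- function(structure, chain = NULL) {
    if (is.null(chain)) chain <- structure@atoms$chain[1]
    a <- structure@atoms[structure@atoms$chain == chain, , drop = FALSE]
    res <- unique(a[, c("resno", "insert", "resid")])
    aa <- .AA1[res$resid]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

.residue_split <- function(atoms) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert)
    split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}
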