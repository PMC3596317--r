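# Backbone bond geometry (Engh-Huber-style standards), Angstrom / degrees.
.GEO <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.521,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_c_ca_cb = 110.1,
    # improper N-C-CA-CB fixing L chirality at CA
    d_n_c_ca_cb = -122.6)

.TEMPLATES <- list(
    extended = c(phi = -139, psi = -135),
    helix    = c(phi = -57,  psi = -47),
    ppii     = c(phi = -78,  psi = 149))

#' Canonical dihedral templates
#'
#' The three canonical peptide conformations used for ensemble docking:
#' extended (phi -139, psi -135), alpha-helix (-57, -47) and polyproline II
#' (-78, 149), all with omega 180.
#'
#' @param name "extended", "helix" or "ppii".
#' @return a \linkS4class{DihedralTemplate}.
#' @export
dihedralTemplate <- function(name = c("extended", "helix", "ppii")) {
    name <- match.arg(name)
    t <- .TEMPLATES[[name]]
    new("DihedralTemplate", name = name, phi = unname(t["phi"]),
        psi = unname(t["psi"]), omega = 180)
}

# Natural extension reference frame: position of atom D given A, B, C,
# bond length C-D, angle B-C-D and dihedral A-B-C-D (degrees).
.nerf <- function(A, B, C, r, theta, chi) {
    t <- theta * pi / 180
    p <- -chi * pi / 180    # sign matches the IUPAC convention of measureDihedral
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    n <- .cross3(B - A, bc); n <- n / sqrt(sum(n^2))
    m <- .cross3(n, bc)
    C + r * (-cos(t) * bc + sin(t) * cos(p) * m + sin(t) * sin(p) * n)
}

#' Build a peptide conformer from sequence
#'
#' Sequential internal-coordinate (NeRF) chain extension with standard bond
#' lengths and angles. Backbone N, CA, C, O plus CB (except glycine) are
#' placed; all interior phi/psi equal the template values exactly and all
#' omega are 180 (trans). Side chains beyond CB are not built: the
#' rigid-body stage operates on this reduced representation.
#'
#' @param sequence one-letter amino-acid string, standard residues only,
#'   length >= 3.
#' @param template a \linkS4class{DihedralTemplate} (or name accepted by
#'   \code{\link{dihedralTemplate}}).
#' @param termini named character vector c(n = , c = ), "charged" or
#'   "neutral"; affects only the electrostatic term downstream.
#' @param chain chain id given to the built peptide (default "B").
#' @return a \linkS4class{PeptideConformer}.
#' @examples
#' helix <- buildPeptide("AAAAA", dihedralTemplate("helix"))
#' measurePhiPsi(helix@structure)
#' @export
buildPeptide <- function(sequence, template,
                         termini = c(n = "neutral", c = "neutral"),
                         chain = "B") {
    if (is.character(template)) template <- dihedralTemplate(template)
    sequence <- toupper(sequence)
    aa <- strsplit(sequence, "")[[1]]
    if (length(aa) < 3) stop("peptide too short: need length >= 3")
    bad <- setdiff(aa, names(.AA3))
    if (length(bad) > 0)
        stop("nonstandard residue letter(s): ", paste(unique(bad), collapse = ""))
    n <- length(aa)
    phi <- template@phi; psi <- template@psi; omega <- template@omega
    g <- .GEO
    N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$b_n_ca, 0, 0)
    th <- g$a_n_ca_c * pi / 180
    C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
    for (i in seq_len(n)) {
        if (i > 1) {
            N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$b_c_n, g$a_ca_c_n, psi)
            CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ],
                             g$b_n_ca, g$a_c_n_ca, omega)
            C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, phi)
        }
        # carbonyl O anti to the next amide N; terminal residue uses the
        # template psi so the build is fully determined
        O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                        psi + 180)
        if (aa[i] != "G")
            CB[i, ] <- .nerf(N[i, ], C[i, ], CA[i, ], g$b_ca_cb,
                             g$a_c_ca_cb, g$d_n_c_ca_cb)
    }
    rows <- list()
    for (i in seq_len(n)) {
        nm <- c("N", "CA", "C", "O", if (aa[i] != "G") "CB")
        xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ],
                     if (aa[i] != "G") CB[i, ])
        rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                                resid = unname(.AA3[aa[i]]), elety = nm,
                                element = substr(nm, 1, 1), x = xyz[, 1],
                                y = xyz[, 2], z = xyz[, 3], o = 1, alt = "",
                                stringsAsFactors = FALSE)
    }
    struct <- newStructure(do.call(rbind, rows),
                           source = sprintf("built:%s:%s", template@name, sequence))
    new("PeptideConformer", structure = struct, template = template,
        sequence = sequence, termini = termini)
}

#' Measure backbone dihedrals of a single-chain peptide
#'
#' @param structure a single-chain \linkS4class{PdbStructure} with complete
#'   backbone.
#' @return data.frame with resno, phi, psi, omega (degrees; NA where the
#'   flanking residue is missing).
#' @export
measurePhiPsi <- function(structure) {
    a <- structure@atoms
    res <- .residue_split(a)
    getAt <- function(i, name) {
        r <- res[[i]]
        j <- r[a$elety[r] == name]
        if (length(j) == 0) return(NULL)
        as.numeric(c(a$x[j[1]], a$y[j[1]], a$z[j[1]]))
    }
    n <- length(res)
    out <- data.frame(resno = vapply(res, function(r) a$resno[r[1]], numeric(1)),
                      phi = NA_real_, psi = NA_real_, omega = NA_real_)
    for (i in seq_len(n)) {
        Ni <- getAt(i, "N"); CAi <- getAt(i, "CA"); Ci <- getAt(i, "C")
        if (i > 1) {
            Cp <- getAt(i - 1, "C"); CAp <- getAt(i - 1, "CA")
            if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
                out$phi[i] <- measureDihedral(Cp, Ni, CAi, Ci)
            if (!is.null(CAp) && !is.null(Cp) && !is.null(Ni) && !is.null(CAi))
                out$omega[i] <- measureDihedral(CAp, Cp, Ni, CAi)
        }
        if (i < n) {
            Nn <- getAt(i + 1, "N")
            if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
                out$psi[i] <- measureDihedral(Ni, CAi, Ci, Nn)
        }
    }
    rownames(out) <- NULL
    out
}

#' Per-residue extension of a peptide
#'
#' End-to-end CA distance divided by (n - 1): the average per-residue
#' extension used to decide whether a peptide is in an (ideally) extended
#' conformation. An ideal extended chain gives about 3.46 A/residue.
#'
#' @param structure a single-chain peptide \linkS4class{PdbStructure} with
#'   >= 2 CA atoms.
#' @return extension in Angstrom per residue.
#' @export
perResidueExtension <- function(structure) {
    a <- structure@atoms
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(ca) < 2) stop("incomplete backbone: need at least 2 CA atoms")
    n <- nrow(ca)
    d <- sqrt(sum((as.numeric(ca[1, c("x", "y", "z")]) -
                   as.numeric(ca[n, c("x", "y", "z")]))^2))
    d / (n - 1)
}

#' Build the canonical three-conformer ensemble
#'
#' Builds the extended, alpha-helical and polyproline-II conformers of a
#' sequence (in that fixed order) with identical termini flags.
#'
#' @inheritParams buildPeptide
#' @return named list of three \linkS4class{PeptideConformer} objects
#'   (extended, helix, ppii).
#' @export
canonicalEnsemble <- function(sequence, termini = c(n = "neutral", c = "neutral"),
                              chain = "B") {
    setNames(lapply(c("extended", "helix", "ppii"), function(t)
        buildPeptide(sequence, dihedralTemplate(t), termini, chain)),
        c("extended", "helix", "ppii"))
}

#' Write an ensemble as a multi-model PDB file
#' @param ensemble list of \linkS4class{PeptideConformer} (or structures).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
    writePDB(lapply(ensemble, function(e)
        if (is(e, "PeptideConformer")) e@structure else e), path)
}

#' Backbone dihedral restraints for helical regions
#'
#' One phi and one psi restraint per helical residue where the four defining
#' atoms exist, centred on the measured value with a flat bottom of
#' +/- \code{halfWidth} degrees (default 10).
#'
#' @param conformer a \linkS4class{PeptideConformer}.
#' @param helixAssignment logical vector, one flag per residue (e.g. from
#'   \code{\link{assignHelicalResidues}}).
#' @param halfWidth allowed variation around the target, degrees.
#' @param forceConstant quadratic penalty constant (energy/deg^2).
#' @return data.frame with columns resno, angle, a1..a4 ("resno:atom"
#'   references), target, half_width, force_constant.
#' @export
helicalDihedralRestraints <- function(conformer, helixAssignment,
                                      halfWidth = 10, forceConstant = 1) {
    stopifnot(halfWidth > 0)
    tors <- measurePhiPsi(conformer@structure)
    n <- nrow(tors)
    stopifnot(length(helixAssignment) == n)
    out <- list()
    ref <- function(i, at) sprintf("%d:%s", tors$resno[i], at)
    for (i in which(helixAssignment)) {
        if (!is.na(tors$phi[i]))
            out[[length(out) + 1]] <- data.frame(
                resno = tors$resno[i], angle = "phi",
                a1 = ref(i - 1, "C"), a2 = ref(i, "N"), a3 = ref(i, "CA"),
                a4 = ref(i, "C"), target = tors$phi[i],
                half_width = halfWidth, force_constant = forceConstant,
                stringsAsFactors = FALSE)
        if (!is.na(tors$psi[i]))
            out[[length(out) + 1]] <- data.frame(
                resno = tors$resno[i], angle = "psi",
                a1 = ref(i, "N"), a2 = ref(i, "CA"), a3 = ref(i, "C"),
                a4 = ref(i + 1, "N"), target = tors$psi[i],
                half_width = halfWidth, force_constant = forceConstant,
                stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
        return(data.frame(resno = integer(0), angle = character(0),
                          a1 = character(0), a2 = character(0),
                          a3 = character(0), a4 = character(0),
                          target = numeric(0), half_width = numeric(0),
                          force_constant = numeric(0)))
    do.call(rbind, out)
}

#' Flat-bottom energy of dihedral restraints on a structure
#'
#' E = sum k * max(0, |delta| - half_width)^2 with delta the periodic
#' difference between the measured and target dihedral.
#'
#' @param structure a single-chain \linkS4class{PdbStructure}.
#' @param restraints data.frame from \code{\link{helicalDihedralRestraints}}.
#' @return total restraint energy.
#' @export
dihedralRestraintEnergy <- function(structure, restraints) {
    if (nrow(restraints) == 0) return(0)
    a <- structure@atoms
    getxyz <- function(ref) {
        p <- strsplit(ref, ":")[[1]]
        j <- which(a$resno == as.integer(p[1]) & a$elety == p[2])
        if (length(j) == 0) stop("restraint atom not found: ", ref)
        as.numeric(c(a$x[j[1]], a$y[j[1]], a$z[j[1]]))
    }
    e <- 0
    for (r in seq_len(nrow(restraints))) {
        val <- measureDihedral(getxyz(restraints$a1[r]), getxyz(restraints$a2[r]),
                               getxyz(restraints$a3[r]), getxyz(restraints$a4[r]))
        d <- (val - restraints$target[r] + 180) %% 360 - 180
        viol <- abs(d) - restraints$half_width[r]
        if (viol > 0) e <- e + restraints$force_constant[r] * viol^2
    }
    e
}

#' Serialize dihedral restraints
#'
#' \code{writeRestraintsTSV} writes the plain-text table;
#' \code{formatCNSDihedrals} renders CNS-style \code{assign} statements.
#'
#' @param restraints data.frame from \code{\link{helicalDihedralRestraints}}.
#' @param path output path for the TSV writer.
#' @param segid segment id used in the CNS statements.
#' @return the path (TSV) or a character vector of statements (CNS).
#' @export
writeRestraintsTSV <- function(restraints, path) {
    write.table(restraints, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRestraintsTSV
#' @export
formatCNSDihedrals <- function(restraints, segid = "B") {
    if (nrow(restraints) == 0) return(character(0))
    sel <- function(ref) {
        p <- strsplit(ref, ":")[[1]]
        sprintf("(segid %s and resid %s and name %s)", segid, p[1], p[2])
    }
    vapply(seq_len(nrow(restraints)), function(r) sprintf(
        "assign %s %s %s %s 1.0 %.2f %.2f 2",
        sel(restraints$a1[r]), sel(restraints$a2[r]), sel(restraints$a3[r]),
        sel(restraints$a4[r]), restraints$target[r], restraints$half_width[r]),
        character(1))
}
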