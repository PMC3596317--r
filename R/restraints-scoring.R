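#' Composite rigid-body score weights
#'
#' total = 0.01 E_rest + 0.01 E_vdw + 1.0 E_elec + 1.0 E_desol - 0.01 BSA.
#' These weights are fixed; the underlying energy parameters are editable
#' through \code{\link{dockingParams}}.
#' @export
SCORE_WEIGHTS <- c(e_rest = 0.01, e_vdw = 0.01, e_elec = 1.0,
                   e_desol = 1.0, bsa = -0.01)

#' Energy-function parameters for the rigid-body stage
#'
#' One editable table for all simplified nonbonded forms used under the
#' composite score: the flat-bottom ambiguous-restraint parameters, the
#' per-element 12-6 Lennard-Jones table, Coulomb settings (relative
#' dielectric, shared truncation cutoff), per-element atomic solvation
#' parameters and the SASA discretization used during docking.
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of parameters.
#' @export
dockingParams <- function(...) {
    p <- list(
        air_upper = 2.0,          # AIR effective-distance bound (A)
        air_k = 50,               # AIR force constant (kcal/mol/A^2)
        lj_cutoff = 8.5,          # nonbonded truncation (A)
        eps_r = 10,               # relative dielectric
        sigma = c(C = 3.40, N = 3.25, O = 3.00, S = 3.60),
        eps = c(C = 0.086, N = 0.170, O = 0.210, S = 0.250),
        solv = c(C = 0.0126, N = -0.006, O = -0.006, S = 0.0126),
        probe = 1.4,
        sasa_points = 960,        # reporting-quality SASA
        sasa_points_dock = 92,    # SASA during pose minimization
        minimizer_maxit = 150,    # Nelder-Mead budget per start
        minimizer_restarts = 1,   # fresh-simplex restarts at the optimum
        restart_maxit = 100)      # budget per restart
    over <- list(...)
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
    p
}

#' Write/read the parameter table as a flat key = value file
#' @param params list from \code{\link{dockingParams}}.
#' @param path file path.
#' @return \code{path} (write) or a parameter list (read).
#' @export
writeParams <- function(params, path) {
    fmt <- function(v) if (is.null(names(v))) paste(v, collapse = ",")
        else paste(sprintf("%s:%g", names(v), v), collapse = ",")
    writeLines(sprintf("%s = %s", names(params),
                       vapply(params, fmt, character(1))), path)
    invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
    lines <- readLines(path)
    p <- dockingParams()
    for (ln in lines[nzchar(trimws(lines))]) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        key <- trimws(kv[1]); val <- trimws(kv[2])
        parts <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (grepl(":", parts[1])) {
            sp <- strsplit(parts, ":", fixed = TRUE)
            v <- setNames(as.numeric(vapply(sp, `[`, "", 2)),
                          vapply(sp, `[`, "", 1))
        } else v <- as.numeric(parts)
        p[[key]] <- v
    }
    p
}

#' Define ambiguous interaction restraints from a reference complex
#'
#' Active residues are the receptor residues with any heavy atom within
#' \code{cutoff} (default 5 A) of the peptide chain; all peptide residues
#' are passive. This deliberately broad binding-site definition drives the
#' docking towards the approximate location of the site without specifying
#' the exact pocket.
#'
#' @param complexStructure reference complex \linkS4class{PdbStructure}.
#' @param receptorChain,peptideChain chain ids in the complex.
#' @param cutoff active-residue distance cutoff (A).
#' @param params list from \code{\link{dockingParams}} (supplies the
#'   restraint upper bound and force constant).
#' @return an \linkS4class{AirRestraintSet}.
#' @export
defineAIRs <- function(complexStructure, receptorChain, peptideChain,
                       cutoff = 5.0, params = dockingParams()) {
    active <- residuesWithin(complexStructure,
                             makeSelection(complexStructure, chain = receptorChain),
                             makeSelection(complexStructure, chain = peptideChain),
                             cutoff)
    if (nrow(active@residues) == 0)
        stop("no receptor residues within ", cutoff,
             " A of the peptide: no interface")
    passive <- makeSelection(complexStructure, chain = peptideChain)
    new("AirRestraintSet", active = active, passive = passive,
        upperBound = params$air_upper, forceConstant = params$air_k)
}

# Per-atom partial charges: unit charges on charged side chains (on CB in
# the reduced representation) and +/-1 on terminal N/C when the termini are
# flagged charged. Histidine and everything else: 0.
.CHARGED_RES <- c(ASP = -1, GLU = -1, LYS = +1, ARG = +1)

.charge_vector <- function(atoms, termini = c(n = "neutral", c = "neutral")) {
    q <- numeric(nrow(atoms))
    sc <- .CHARGED_RES[atoms$resid]
    on_cb <- !is.na(sc) & atoms$elety == "CB"
    q[on_cb] <- sc[on_cb]
    if (identical(unname(termini["n"]), "charged")) {
        first <- atoms$resno == min(atoms$resno)
        q[first & atoms$elety == "N"] <- q[first & atoms$elety == "N"] + 1
    }
    if (identical(unname(termini["c"]), "charged")) {
        last <- atoms$resno == max(atoms$resno)
        q[last & atoms$elety == "C"] <- q[last & atoms$elety == "C"] - 1
    }
    q
}

.element_param <- function(atoms, table, what) {
    v <- table[atoms$element]
    if (any(is.na(v)))
        stop("no ", what, " parameter for element(s): ",
             paste(unique(atoms$element[is.na(v)]), collapse = ", "))
    unname(v)
}

# Precomputed arrays for repeated scoring of one receptor/peptide pair.
.score_context <- function(receptor, peptide, airs, params = dockingParams(),
                           nPoints = params$sasa_points) {
    ra <- receptor@atoms
    pa <- if (is(peptide, "PeptideConformer")) peptide@structure@atoms
          else peptide@atoms
    termini <- if (is(peptide, "PeptideConformer")) peptide@termini
               else c(n = "neutral", c = "neutral")
    rkey <- paste(ra$chain, ra$resno, ra$insert)
    act <- airs@active@residues
    groups <- lapply(paste(act$chain, act$resno, act$insert), function(k)
        as.integer(which(rkey == k) - 1L))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    rec_xyz <- as.matrix(ra[, c("x", "y", "z")])
    pep_xyz <- as.matrix(pa[, c("x", "y", "z")])
    rec_radii <- .element_param(ra, VDW_RADII, "radius")
    pep_radii <- .element_param(pa, VDW_RADII, "radius")
    ctx <- list(
        rec_xyz = rec_xyz, pep_xyz0 = pep_xyz,
        rec_sig = .element_param(ra, params$sigma, "LJ sigma"),
        pep_sig = .element_param(pa, params$sigma, "LJ sigma"),
        rec_eps = .element_param(ra, params$eps, "LJ epsilon"),
        pep_eps = .element_param(pa, params$eps, "LJ epsilon"),
        rec_q = .charge_vector(ra), pep_q = .charge_vector(pa, termini),
        rec_solv = .element_param(ra, params$solv, "solvation"),
        pep_solv = .element_param(pa, params$solv, "solvation"),
        rec_radii = rec_radii, pep_radii = pep_radii,
        groups = groups, params = params, nPoints = nPoints)
    ctx$rec_sasa_free <- .sasa_cpp(rec_xyz, rec_radii, params$probe, nPoints)
    ctx$pep_sasa_free <- .sasa_cpp(pep_xyz, pep_radii, params$probe, nPoints)
    ctx
}

# Score components for peptide coordinates `pep_xyz` against the context.
.score_eval <- function(ctx, pep_xyz) {
    p <- ctx$params
    e_rest <- .air_energy_cpp(ctx$rec_xyz, ctx$groups, pep_xyz,
                              p$air_upper, p$air_k)
    pe <- .pair_energies_cpp(ctx$rec_xyz, ctx$rec_sig, ctx$rec_eps, ctx$rec_q,
                             pep_xyz, ctx$pep_sig, ctx$pep_eps, ctx$pep_q,
                             p$lj_cutoff, p$eps_r)
    sasa_cx <- .sasa_complex_cpp(ctx$rec_xyz, ctx$rec_radii, ctx$rec_sasa_free,
                                 pep_xyz, ctx$pep_radii, p$probe, ctx$nPoints)
    free <- c(ctx$rec_sasa_free, ctx$pep_sasa_free)
    e_desol <- sum(c(ctx$rec_solv, ctx$pep_solv) * (sasa_cx - free))
    bsa <- sum(free) - sum(sasa_cx)
    comp <- c(e_rest = e_rest, e_vdw = pe[1], e_elec = pe[2],
              e_desol = e_desol, bsa = bsa)
    c(comp, total = scoreTotal(comp))
}

#' Weighted total of score components
#' @param components named vector/list with e_rest, e_vdw, e_elec, e_desol,
#'   bsa.
#' @return the weighted composite score.
#' @export
scoreTotal <- function(components) {
    sum(SCORE_WEIGHTS * unlist(components)[names(SCORE_WEIGHTS)])
}

#' Ambiguous-restraint energy of a pose
#'
#' For each active residue i, the effective distance to the passive partner
#' pools all heavy-atom pairs: d_eff(i) = (sum d^-6)^(-1/6); the energy is
#' k sum max(0, d_eff(i) - upper_bound)^2 and is zero iff every active
#' residue is satisfied.
#'
#' @param receptor receptor \linkS4class{PdbStructure}.
#' @param peptide peptide \linkS4class{PdbStructure} (pose coordinates).
#' @param airs an \linkS4class{AirRestraintSet}.
#' @return restraint energy (kcal/mol-like units).
#' @export
airEnergy <- function(receptor, peptide, airs) {
    ra <- receptor@atoms
    rkey <- paste(ra$chain, ra$resno, ra$insert)
    act <- airs@active@residues
    groups <- lapply(paste(act$chain, act$resno, act$insert), function(k)
        as.integer(which(rkey == k) - 1L))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    .air_energy_cpp(coords(receptor), groups, coords(peptide),
                    airs@upperBound, airs@forceConstant)
}

#' Intermolecular nonbonded and desolvation energies
#'
#' \code{vdwEnergy}: truncated-shifted 12-6 Lennard-Jones over heavy-atom
#' pairs. \code{elecEnergy}: truncated-shifted Coulomb with relative
#' dielectric from the parameter table. \code{desolvationEnergy}: per-atom
#' atomic-solvation parameter times the SASA change upon complexation;
#' \code{buriedSurfaceArea}: SASA(A) + SASA(B) - SASA(AB).
#'
#' @param receptor,peptide the two \linkS4class{PdbStructure} molecules
#'   (the peptide may be a \linkS4class{PeptideConformer}, whose termini
#'   flags then feed the charge assignment).
#' @param params list from \code{\link{dockingParams}}.
#' @return energy in kcal/mol-like units (area in A^2 for
#'   \code{buriedSurfaceArea}).
#' @export
vdwEnergy <- function(receptor, peptide, params = dockingParams()) {
    .pair_component(receptor, peptide, params)[1]
}

#' @rdname vdwEnergy
#' @export
elecEnergy <- function(receptor, peptide, params = dockingParams()) {
    .pair_component(receptor, peptide, params)[2]
}

.pair_component <- function(receptor, peptide, params) {
    pa <- if (is(peptide, "PeptideConformer")) peptide@structure@atoms
          else peptide@atoms
    termini <- if (is(peptide, "PeptideConformer")) peptide@termini
               else c(n = "neutral", c = "neutral")
    ra <- receptor@atoms
    .pair_energies_cpp(
        as.matrix(ra[, c("x", "y", "z")]),
        .element_param(ra, params$sigma, "LJ sigma"),
        .element_param(ra, params$eps, "LJ epsilon"),
        .charge_vector(ra),
        as.matrix(pa[, c("x", "y", "z")]),
        .element_param(pa, params$sigma, "LJ sigma"),
        .element_param(pa, params$eps, "LJ epsilon"),
        .charge_vector(pa, termini),
        params$lj_cutoff, params$eps_r)
}

#' @rdname vdwEnergy
#' @export
desolvationEnergy <- function(receptor, peptide, params = dockingParams()) {
    pep <- if (is(peptide, "PeptideConformer")) peptide@structure else peptide
    ra <- receptor@atoms; pa <- pep@atoms
    rr <- .element_param(ra, VDW_RADII, "radius")
    pr <- .element_param(pa, VDW_RADII, "radius")
    np <- params$sasa_points
    free <- c(.sasa_cpp(as.matrix(ra[, c("x", "y", "z")]), rr, params$probe, np),
              .sasa_cpp(as.matrix(pa[, c("x", "y", "z")]), pr, params$probe, np))
    cx <- .sasa_cpp(rbind(as.matrix(ra[, c("x", "y", "z")]),
                          as.matrix(pa[, c("x", "y", "z")])),
                    c(rr, pr), params$probe, np)
    solv <- c(.element_param(ra, params$solv, "solvation"),
              .element_param(pa, params$solv, "solvation"))
    sum(solv * (cx - free))
}

#' @rdname vdwEnergy
#' @export
buriedSurfaceArea <- function(receptor, peptide, params = dockingParams()) {
    pep <- if (is(peptide, "PeptideConformer")) peptide@structure else peptide
    ra <- receptor@atoms; pa <- pep@atoms
    rr <- .element_param(ra, VDW_RADII, "radius")
    pr <- .element_param(pa, VDW_RADII, "radius")
    np <- params$sasa_points
    free <- sum(.sasa_cpp(as.matrix(ra[, c("x", "y", "z")]), rr, params$probe, np)) +
        sum(.sasa_cpp(as.matrix(pa[, c("x", "y", "z")]), pr, params$probe, np))
    cx <- sum(.sasa_cpp(rbind(as.matrix(ra[, c("x", "y", "z")]),
                              as.matrix(pa[, c("x", "y", "z")])),
                        c(rr, pr), params$probe, np))
    free - cx
}

#' Composite rigid-body score of a pose
#'
#' Computes all components (restraint, van der Waals, electrostatic,
#' desolvation, buried surface area) and the weighted total
#' 0.01 E_rest + 0.01 E_vdw + 1.0 E_elec + 1.0 E_desol - 0.01 BSA.
#'
#' @inheritParams vdwEnergy
#' @param airs an \linkS4class{AirRestraintSet}.
#' @return named numeric vector: e_rest, e_vdw, e_elec, e_desol, bsa, total.
#' @export
rigidScore <- function(receptor, peptide, airs, params = dockingParams()) {
    ctx <- .score_context(receptor, peptide, airs, params,
                          nPoints = params$sasa_points)
    .score_eval(ctx, ctx$pep_xyz0)
}

#' Serialize an AIR restraint set
#'
#' \code{writeAIRsTSV} writes active/passive residues as a TSV table;
#' \code{formatCNSAIRs} renders one CNS-style ambiguous \code{assign}
#' statement per active residue.
#'
#' @param airs an \linkS4class{AirRestraintSet}.
#' @param path output path.
#' @return the path, or a character vector of statements.
#' @export
writeAIRsTSV <- function(airs, path) {
    act <- airs@active@residues; pas <- airs@passive@residues
    df <- rbind(data.frame(role = "active", act),
                data.frame(role = "passive", pas))
    df$upper_bound <- airs@upperBound
    df$force_constant <- airs@forceConstant
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAIRsTSV
#' @export
formatCNSAIRs <- function(airs) {
    act <- airs@active@residues; pas <- airs@passive@residues
    pass_sel <- paste(sprintf("(segid %s and resid %d)", pas$chain, pas$resno),
                      collapse = " or ")
    vapply(seq_len(nrow(act)), function(i) sprintf(
        "assign (segid %s and resid %d) (%s) %.1f %.1f 0.0",
        act$chain[i], act$resno[i], pass_sel, airs@upperBound, airs@upperBound),
        character(1))
}
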