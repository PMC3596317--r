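# Deterministic per-pose RNG substream: every pose gets its own stream
# derived from (seed, global pose counter), so pose i is reproducible
# independent of how many poses are requested.
.pose_seed <- function(seed, index) {
    as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

# Translate the placed peptide towards the receptor centre along -u until
# the intermolecular vdW energy signals contact, stepping back to the last
# clash-free position. Keeps minimization local to the surface.
.slide_in <- function(ctx, placed, u, dist0, params) {
    p <- ctx$params
    zeros_r <- numeric(nrow(ctx$rec_xyz)); zeros_p <- numeric(nrow(ctx$pep_xyz0))
    last_ok <- 0
    for (t in seq(0, dist0 - 2, by = 0.75)) {
        xyz <- sweep(placed, 2, u * t)
        ev <- .pair_energies_cpp(ctx$rec_xyz, ctx$rec_sig, ctx$rec_eps, zeros_r,
                                 xyz, ctx$pep_sig, ctx$pep_eps, zeros_p,
                                 p$lj_cutoff, p$eps_r)[1]
        if (ev > 10) break
        last_ok <- t
    }
    sweep(placed, 2, u * last_ok)
}

#' Ensemble rigid-body sampling
#'
#' For each conformer of the ensemble, generates \code{nPerConformer} poses:
#' the peptide is randomly oriented and placed on a sphere around the
#' receptor (at receptor radius + peptide radius + 3 A), then the composite
#' score is minimized rigidly over the 6 translation/rotation degrees of
#' freedom with a derivative-free local search. Each start is paired with
#' its 180-degree rotated counterpart and the better minimized solution is
#' kept. Every conformer is represented equally in the returned pool;
#' selection is left to the score.
#'
#' @param receptor receptor \linkS4class{PdbStructure}.
#' @param ensemble named list of \linkS4class{PeptideConformer} objects
#'   (e.g. from \code{\link{canonicalEnsemble}}).
#' @param airs an \linkS4class{AirRestraintSet} (active residues defined on
#'   the receptor).
#' @param nPerConformer poses per conformer (>= 1).
#' @param seed integer seed; the same seed reproduces the pose list exactly.
#' @param params list from \code{\link{dockingParams}}; the SASA dot density
#'   and minimizer budget used here come from it.
#' @return a \linkS4class{DockingResult}.
#' @export
samplePoses <- function(receptor, ensemble, airs, nPerConformer, seed,
                        params = dockingParams()) {
    stopifnot(nPerConformer >= 1, length(ensemble) >= 1)
    if (is.null(names(ensemble)))
        names(ensemble) <- vapply(ensemble, function(e) e@template@name,
                                  character(1))
    rec_xyz <- coords(receptor)
    rec_cen <- colMeans(rec_xyz)
    rec_rad <- sqrt(max(rowSums(sweep(rec_xyz, 2, rec_cen)^2)))
    poses <- list(); xyz_out <- list()
    counter <- 0L
    for (cid in names(ensemble)) {
        conf <- ensemble[[cid]]
        ctx <- .score_context(receptor, conf, airs, params,
                              nPoints = params$sasa_points_dock)
        pep0 <- ctx$pep_xyz0
        pep_cen0 <- colMeans(pep0)
        pep_rad <- sqrt(max(rowSums(sweep(pep0, 2, pep_cen0)^2)))
        pep_c <- sweep(pep0, 2, pep_cen0)   # conformer centred at origin
        dist0 <- rec_rad + pep_rad + 3
        for (i in seq_len(nPerConformer)) {
            counter <- counter + 1L
            sseed <- .pose_seed(seed, counter)
            set.seed(sseed)
            R0 <- .random_rotation()
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            start_cen <- rec_cen + u * dist0
            placed <- sweep(pep_c %*% t(R0), 2, -start_cen)
            flipped <- sweep(sweep(placed, 2, start_cen) %*%
                             t(.rotation_about(u, 180)), 2, -start_cen)
            start_total <- unname(.score_eval(ctx, placed)["total"])
            # approach phase: slide towards the receptor centre along the
            # placement axis until van der Waals contact (cheap, no SASA);
            # the 180-degree rotated start is evaluated too and the better
            # of the two is minimized
            starts <- lapply(list(placed, flipped), .slide_in,
                             ctx = ctx, u = u, dist0 = dist0, params = params)
            svals <- vapply(starts, function(x)
                unname(.score_eval(ctx, x)["total"]), numeric(1))
            start_xyz <- starts[[which.min(svals)]]
            cen <- colMeans(start_xyz)
            base <- sweep(start_xyz, 2, cen)
            obj <- function(par) {
                R <- .rotation_from_vector(par[4:6])
                xyz <- sweep(base %*% t(R), 2, -(cen + par[1:3]))
                unname(.score_eval(ctx, xyz)["total"])
            }
            fit <- tryCatch({
                f <- optim(rep(0, 6), obj, method = "Nelder-Mead",
                           control = list(maxit = params$minimizer_maxit,
                                          parscale = c(rep(4, 3), rep(0.4, 3))))
                # Nelder-Mead collapses its simplex early in 6D; fresh
                # restarts at the optimum recover most of the funnel
                for (k in seq_len(params$minimizer_restarts))
                    f <- optim(f$par, obj, method = "Nelder-Mead",
                               control = list(maxit = params$restart_maxit,
                                              parscale = c(rep(2, 3), rep(0.2, 3))))
                f
            }, error = function(e) NULL)
            if (is.null(fit)) {
                best <- list(xyz = start_xyz,
                             score = .score_eval(ctx, start_xyz),
                             minimized = FALSE)
            } else {
                R <- .rotation_from_vector(fit$par[4:6])
                xyz <- sweep(base %*% t(R), 2, -(cen + fit$par[1:3]))
                best <- list(xyz = xyz, score = .score_eval(ctx, xyz),
                             minimized = TRUE)
            }
            s <- best$score
            poses[[counter]] <- data.frame(
                model_id = counter, conformer = cid, seed = sseed,
                e_rest = s[["e_rest"]], e_vdw = s[["e_vdw"]],
                e_elec = s[["e_elec"]], e_desol = s[["e_desol"]],
                bsa = s[["bsa"]], total = s[["total"]],
                start_total = start_total,
                minimized = best$minimized, stringsAsFactors = FALSE)
            xyz_out[[counter]] <- best$xyz
        }
    }
    new("DockingResult", receptor = receptor, conformers = ensemble,
        poses = do.call(rbind, poses), coords = xyz_out)
}

#' Select the best-scored poses
#'
#' Sorts poses ascending by total score (lower is better) with a stable
#' tie-break on model_id, and keeps the first \code{n}.
#'
#' @param result a \linkS4class{DockingResult}.
#' @param n number of poses to keep (<= pool size).
#' @return a \linkS4class{DockingResult} restricted to the selection, in
#'   score order.
#' @export
selectTop <- function(result, n) {
    p <- result@poses
    if (n > nrow(p)) stop("requested top ", n, " from a pool of ", nrow(p))
    ord <- order(p$total, p$model_id)[seq_len(n)]
    new("DockingResult", receptor = result@receptor,
        conformers = result@conformers,
        poses = p[ord, , drop = FALSE], coords = result@coords[ord])
}

#' Conformational-selection statistics
#'
#' Counts, fractions and enrichment factors of the starting conformers
#' represented in a selected pose set. With k conformers sampled equally,
#' EF(c) = fraction(c) x k; a uniform selection gives EF = 1 everywhere and
#' the EFs always sum to k.
#'
#' @param x a \linkS4class{DockingResult} (typically from
#'   \code{\link{selectTop}}) or a character vector of conformer ids.
#' @param conformerIds the conformer universe; defaults to the ensemble
#'   names (or the distinct ids seen).
#' @return data.frame with conformer, count, fraction, ef.
#' @examples
#' selectionStats(rep(c("helix", "extended"), c(60, 40)),
#'                conformerIds = c("extended", "helix", "ppii"))
#' @export
selectionStats <- function(x, conformerIds = NULL) {
    ids <- if (is(x, "DockingResult")) x@poses$conformer else x
    if (is.null(conformerIds))
        conformerIds <- if (is(x, "DockingResult")) names(x@conformers)
                        else sort(unique(ids))
    k <- length(conformerIds)
    counts <- vapply(conformerIds, function(c) sum(ids == c), numeric(1))
    frac <- counts / length(ids)
    data.frame(conformer = conformerIds, count = as.integer(counts),
               fraction = frac, ef = frac * k, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Materialize one pose as structures
#'
#' \code{posePeptide} returns the peptide of pose \code{i} as a
#' \linkS4class{PdbStructure}; \code{poseComplex} the receptor + peptide
#' complex.
#'
#' @param result a \linkS4class{DockingResult}.
#' @param i pose index into \code{posesTable(result)} (row position).
#' @return a \linkS4class{PdbStructure}.
#' @export
posePeptide <- function(result, i) {
    cid <- result@poses$conformer[i]
    replaceCoords(result@conformers[[cid]]@structure, result@coords[[i]])
}

#' @rdname posePeptide
#' @export
poseComplex <- function(result, i) {
    mergeStructures(result@receptor, posePeptide(result, i))
}

#' Write a docking result to disk
#'
#' Writes the poses as a multi-model PDB of complexes plus a TSV sidecar
#' with provenance and score components.
#'
#' @param result a \linkS4class{DockingResult}.
#' @param pdbPath,tsvPath output paths.
#' @return invisibly, a list of the two paths.
#' @export
writeDockingResult <- function(result, pdbPath, tsvPath) {
    models <- lapply(seq_len(nrow(result@poses)),
                     function(i) poseComplex(result, i))
    writePDB(models, pdbPath)
    write.table(result@poses, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(pdb = pdbPath, tsv = tsvPath))
}
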