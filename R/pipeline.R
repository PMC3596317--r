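#' Scaled-down end-to-end docking pipeline
#'
#' Runs the full workflow on one case: define ambiguous restraints from the
#' reference complex (5 A active surface), build the canonical
#' three-conformer ensemble from the peptide sequence, sample and minimize
#' rigid-body poses, select the top-scored pool, assess every selected
#' model against the reference (i-RMSD, l-RMSD, l-i-RMSD, Fnat), cluster
#' the selection and rank clusters by their top-4 mean score.
#'
#' @param reference reference complex \linkS4class{PdbStructure} (receptor
#'   chain + peptide chain).
#' @param receptor receptor-only \linkS4class{PdbStructure} to dock against
#'   (defaults to the receptor chain extracted from the reference).
#' @param sequence peptide sequence; defaults to the sequence of the
#'   peptide chain in the reference.
#' @param receptorChain,peptideChain chain ids in the reference.
#' @param nPerConformer rigid-body poses per conformer.
#' @param top number of top-scored models selected for assessment and
#'   clustering.
#' @param seed integer seed for the sampling stage.
#' @param clusterCutoff RMSD clustering cutoff (A).
#' @param params list from \code{\link{dockingParams}}.
#' @return list with \code{airs}, \code{ensemble}, \code{poses} (full
#'   \linkS4class{DockingResult}), \code{top} (selected subset),
#'   \code{stats} (conformer selection stats on the top pool),
#'   \code{quality} (per-model assessment table), \code{clusters} (ranked
#'   cluster table) and \code{cluster_success} (0/1 per top-K cluster).
#' @export
runDockingPipeline <- function(reference, receptor = NULL, sequence = NULL,
                               receptorChain = "A", peptideChain = "B",
                               nPerConformer = 50, top = 30, seed = 1,
                               clusterCutoff = 5.0,
                               params = dockingParams()) {
    if (is.null(receptor)) receptor <- chainStructure(reference, receptorChain)
    if (is.null(sequence)) sequence <- chainSequence(reference, peptideChain)
    airs <- defineAIRs(reference, receptorChain, peptideChain,
                       params = params)
    ensemble <- canonicalEnsemble(sequence, chain = peptideChain)
    poses <- samplePoses(receptor, ensemble, airs, nPerConformer, seed,
                         params = params)
    sel <- selectTop(poses, top)
    stats <- selectionStats(sel)
    quality <- assessModels(sel, reference, receptorChain, peptideChain)
    scores <- setNames(sel@poses$total, sel@poses$model_id)
    qual <- setNames(quality$quality, quality$model)
    clusters <- NULL; csucc <- numeric(0)
    if (top >= 2) {
        D <- pairwiseMatrix(sel, reference, receptorChain, peptideChain)
        clustering <- clusterModels(D, cutoff = clusterCutoff)
        clusters <- rankClusters(clustering, scores)
        if (nrow(clusters) > 0)
            csucc <- clusterSuccess(clusters, qual)
    }
    list(airs = airs, ensemble = ensemble, poses = poses, top = sel,
         stats = stats, quality = quality, clusters = clusters,
         cluster_success = csucc)
}
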