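#' Pairwise model-model RMSD matrix
#'
#' Default clustering metric: peptide backbone RMSD after fitting each pair
#' of models on the receptor interface backbone (interface taken from the
#' reference complex). Symmetric with a zero diagonal.
#'
#' @param models a \linkS4class{DockingResult} or list of model complexes.
#' @param reference reference complex defining the receptor interface.
#' @param receptorChain,peptideChain chain ids.
#' @param interfaces optional precomputed \code{\link{interfaceSelection}}.
#' @return symmetric n x n matrix of distances (A), dimnames = model ids.
#' @export
pairwiseMatrix <- function(models, reference, receptorChain, peptideChain,
                           interfaces = NULL) {
    if (is.null(interfaces))
        interfaces <- interfaceSelection(reference, receptorChain, peptideChain)
    recSel <- .with_backbone(interfaces$receptor)
    pepSel <- makeSelection(reference, chain = peptideChain,
                            atomNames = BACKBONE_ATOMS)
    if (is(models, "DockingResult")) {
        n <- nrow(models@poses)
        get <- function(i) poseComplex(models, i)
        ids <- models@poses$model_id
    } else {
        n <- length(models)
        get <- function(i) models[[i]]
        ids <- seq_len(n)
    }
    if (n < 2) stop("need at least 2 models for a pairwise matrix")
    recI <- vector("list", n); pepB <- vector("list", n)
    for (i in seq_len(n)) {
        m <- get(i)
        pr <- .paired_coords(m, reference, recSel)
        pp <- .paired_coords(m, reference, pepSel)
        recI[[i]] <- pr$mod
        pepB[[i]] <- pp$mod
    }
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        fit <- kabschSuperpose(recI[[j]], recI[[i]])
        d <- rmsdNoFit(applyTransform(pepB[[j]], fit$rotation, fit$translation),
                       pepB[[i]])
        D[i, j] <- D[j, i] <- d
    }
    D
}

#' Neighbour-counting RMSD clustering
#'
#' Iterative greedy clustering: the model with most neighbours within
#' \code{cutoff} seeds a cluster together with those neighbours; members
#' are removed and the procedure repeats. Ties are broken by lower model
#' id, making the result deterministic and independent of input order.
#' Clusters smaller than \code{minSize} are dissolved to unclustered.
#'
#' @param D symmetric distance matrix from \code{\link{pairwiseMatrix}}
#'   (dimnames used as model ids).
#' @param cutoff neighbour cutoff in Angstrom (default 5.0, suited to the
#'   small interfaces of protein-peptide complexes).
#' @param minSize minimum cluster size (default 4, forced by the top-4
#'   cluster scoring rule).
#' @return list with \code{clusters} (list of integer id vectors) and
#'   \code{unclustered} (integer ids).
#' @export
clusterModels <- function(D, cutoff = 5.0, minSize = 4) {
    stopifnot(nrow(D) == ncol(D), isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    ids <- if (!is.null(rownames(D))) as.integer(rownames(D)) else seq_len(nrow(D))
    pool <- seq_len(nrow(D))
    clusters <- list()
    while (length(pool) > 0) {
        sub <- D[pool, pool, drop = FALSE]
        nb <- rowSums(sub <= cutoff) - 1L
        seedPos <- pool[order(-nb, ids[pool])][1]
        memberPos <- pool[D[seedPos, pool] <= cutoff]
        clusters[[length(clusters) + 1]] <- ids[memberPos]
        pool <- setdiff(pool, memberPos)
    }
    keep <- vapply(clusters, length, integer(1)) >= minSize
    unclustered <- sort(unlist(clusters[!keep], use.names = FALSE))
    list(clusters = clusters[keep], unclustered = as.integer(unclustered))
}

#' Rank clusters by the mean score of their four best members
#'
#' Cluster score = mean total score of the 4 best-scored members; clusters
#' are returned ascending by that score with a stable tie-break on the
#' representative (best-scored member) model id.
#'
#' @param clustering result of \code{\link{clusterModels}}.
#' @param modelScores named numeric vector: total score per model id.
#' @return data.frame with rank, cluster_score, representative and a list
#'   column \code{members} (ids ordered by score).
#' @export
rankClusters <- function(clustering, modelScores) {
    cl <- clustering$clusters
    if (length(cl) == 0)
        return(data.frame(rank = integer(0), cluster_score = numeric(0),
                          representative = integer(0)))
    info <- lapply(cl, function(members) {
        sc <- modelScores[as.character(members)]
        if (anyNA(sc)) stop("missing scores for cluster members")
        ord <- members[order(sc, members)]
        list(members = ord,
             cluster_score = mean(sort(unname(sc))[seq_len(4)]),
             representative = ord[1])
    })
    sc <- vapply(info, `[[`, numeric(1), "cluster_score")
    rep_ <- vapply(info, `[[`, numeric(1), "representative")
    ord <- order(sc, rep_)
    out <- data.frame(rank = seq_along(ord), cluster_score = sc[ord],
                      representative = as.integer(rep_[ord]))
    out$members <- lapply(info[ord], `[[`, "members")
    out
}

#' Cluster-based docking success
#'
#' A cluster counts as near-native if one of its four best-scored members
#' is of near-native quality or better; success at K means such a cluster
#' appears among the top K ranked clusters. Monotone non-decreasing in K.
#'
#' @param ranked data.frame from \code{\link{rankClusters}}.
#' @param quality named character vector: quality class per model id.
#' @param topK vector of K values.
#' @return named numeric vector of 0/1 flags per K.
#' @export
clusterSuccess <- function(ranked, quality, topK = seq_len(nrow(ranked))) {
    ok <- vapply(seq_len(nrow(ranked)), function(i) {
        top4 <- head(ranked$members[[i]], 4)
        any(quality[as.character(top4)] %in% c("high", "near_native"))
    }, logical(1))
    hit <- cumsum(ok) > 0
    out <- if (length(hit) == 0) rep(0, length(topK))
           else as.numeric(hit[pmin(topK, length(hit))])
    out[topK > length(hit) & length(hit) == 0] <- 0
    names(out) <- topK
    out
}
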