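# Decoys around the groove reference give models with known structure.
decoySet <- function(counts = c(high = 2, near_native = 3, not_acceptable = 3),
                     seed = 2) {
    makeDecoySet(grooveFixture()$complex, counts = counts, seed = seed)
}

test_that("pairwise matrices are symmetric, zero-diagonal and recomputable", {
    fx <- grooveFixture()
    dec <- decoySet()
    models <- c(dec$models[1:4], dec$models[1])   # include a duplicate
    D <- pairwiseMatrix(models, fx$complex, "A", "B")
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_equal(D[1, 5], 0)                      # duplicate pair
    # one-by-one recomputation with the assessment primitives
    ifc <- interfaceSelection(fx$complex, "A", "B")
    recSel <- PepDock:::.with_backbone(ifc$receptor)
    rows_rec <- selectionRows(fx$complex, recSel)
    a <- atomTable(fx$complex)
    rows_pep <- which(a$chain == "B" & a$elety %in% BACKBONE_ATOMS)
    for (i in 1:2) for (j in 3:4) {
        fit <- kabschSuperpose(coords(models[[j]])[rows_rec, ],
                               coords(models[[i]])[rows_rec, ])
        d <- rmsdNoFit(applyTransform(coords(models[[j]])[rows_pep, ],
                                      fit$rotation, fit$translation),
                       coords(models[[i]])[rows_pep, ])
        expect_equal(D[i, j], d, tolerance = 1e-9)
    }
})

test_that("neighbour-counting clustering handles canonical cases", {
    # all pairs beyond the cutoff: no clusters
    D <- matrix(10, 6, 6); diag(D) <- 0
    dimnames(D) <- list(1:6, 1:6)
    cl <- clusterModels(D, cutoff = 5, minSize = 4)
    expect_length(cl$clusters, 0)
    expect_equal(cl$unclustered, 1:6)
    # six identical models: one cluster of six
    D0 <- matrix(0, 6, 6); dimnames(D0) <- list(1:6, 1:6)
    cl0 <- clusterModels(D0, cutoff = 5, minSize = 4)
    expect_length(cl0$clusters, 1)
    expect_setequal(cl0$clusters[[1]], 1:6)
    # two tight blobs of five at inter-blob distance 20: two clusters
    D2 <- matrix(20, 10, 10)
    D2[1:5, 1:5] <- 1; D2[6:10, 6:10] <- 1
    diag(D2) <- 0; dimnames(D2) <- list(1:10, 1:10)
    cl2 <- clusterModels(D2, cutoff = 5, minSize = 4)
    expect_length(cl2$clusters, 2)
    expect_setequal(cl2$clusters[[1]], 1:5)
    expect_setequal(cl2$clusters[[2]], 6:10)
})

test_that("clustering partitions the models and is permutation-invariant", {
    fx <- grooveFixture()
    dec <- decoySet(counts = c(high = 3, near_native = 4, not_acceptable = 5))
    D <- pairwiseMatrix(dec$models, fx$complex, "A", "B")
    cl <- clusterModels(D)
    all_ids <- c(unlist(cl$clusters), cl$unclustered)
    expect_setequal(all_ids, as.integer(rownames(D)))
    expect_equal(length(all_ids), length(unique(all_ids)))   # disjoint
    # permuting the matrix (ids fixed) leaves the partition unchanged
    set.seed(10)
    p <- sample(nrow(D))
    Dp <- D[p, p]
    clp <- clusterModels(Dp)
    expect_setequal(lapply(cl$clusters, sort), lapply(clp$clusters, sort))
    expect_setequal(cl$unclustered, clp$unclustered)
})

test_that("cluster ranking averages the four best member scores", {
    clustering <- list(clusters = list(c(1L, 2L, 3L, 4L, 5L),
                                       c(6L, 7L, 8L, 9L)),
                       unclustered = integer(0))
    scores <- setNames(c(1, 2, 3, 4, 100, -10, -5, 0, 5), 1:9)
    ranked <- rankClusters(clustering, scores)
    expect_equal(ranked$cluster_score, c(mean(c(-10, -5, 0, 5)), 2.5))
    expect_equal(ranked$representative, c(6L, 1L))
    expect_equal(ranked$members[[2]], c(1L, 2L, 3L, 4L, 5L))
    # ranking equals a sort oracle
    expect_equal(order(ranked$cluster_score), seq_len(nrow(ranked)))
})

test_that("cluster success requires an acceptable model among the top four", {
    clustering <- list(clusters = list(c(1L, 2L, 3L, 4L, 5L)),
                       unclustered = integer(0))
    scores <- setNames(c(-5, -4, -3, -2, -1), 1:5)
    ranked <- rankClusters(clustering, scores)
    q_in_top4 <- setNames(c("not_acceptable", "near_native", "not_acceptable",
                            "not_acceptable", "not_acceptable"), 1:5)
    expect_equal(unname(clusterSuccess(ranked, q_in_top4, topK = 1)), 1)
    # the near-native model ranked fifth in its cluster does not count
    q_fifth <- setNames(c(rep("not_acceptable", 4), "near_native"), 1:5)
    expect_equal(unname(clusterSuccess(ranked, q_fifth, topK = 1)), 0)
    # monotone non-decreasing in K and equal to a brute-force scan
    clustering2 <- list(clusters = list(1:4, 5:8, 9:12), unclustered = integer(0))
    scores2 <- setNames(seq(-12, -1), 1:12)
    ranked2 <- rankClusters(clustering2, scores2)
    qual2 <- setNames(rep("not_acceptable", 12), 1:12)
    qual2["10"] <- "high"
    got <- clusterSuccess(ranked2, qual2, topK = 1:3)
    brute <- sapply(1:3, function(K) {
        hit <- FALSE
        for (k in seq_len(K)) {
            top4 <- head(ranked2$members[[k]], 4)
            if (any(qual2[as.character(top4)] %in% c("high", "near_native")))
                hit <- TRUE
        }
        as.numeric(hit)
    })
    expect_equal(unname(got), brute)
    expect_true(all(diff(got) >= 0))
})

test_that("cluster ranking is at least as successful as single-structure ranking", {
    fx <- grooveFixture()
    a <- atomTable(fx$complex)
    pep <- a$chain == "B"
    # models pooled into basins, the way minimization funnels real pose sets:
    # one near-native basin and two spurious ones per case
    basinModels <- function(centre_shift, n, jitter = 0.5) {
        lapply(seq_len(n), function(i) {
            xyz <- coords(fx$complex)
            xyz[pep, ] <- sweep(xyz[pep, ], 2,
                                -(centre_shift + rnorm(3, sd = jitter)))
            replaceCoords(fx$complex, xyz)
        })
    }
    singles <- numeric(0); clustered <- numeric(0)
    for (case in 1:10) {
        set.seed(200 + case)
        dir1 <- rnorm(3); dir1 <- dir1 / sqrt(sum(dir1^2))
        dir2 <- rnorm(3); dir2 <- dir2 / sqrt(sum(dir2^2))
        models <- c(basinModels(c(0, 0, 0), 5),
                    basinModels(dir1 * 7, 4), basinModels(dir2 * 9, 4))
        qual <- assessModels(models, fx$complex, "A", "B")
        scores <- setNames(qual$i_rmsd + rnorm(nrow(qual), sd = 4), qual$model)
        singles[case] <- successCurve(qual$quality[order(scores)], N = 3)[[1]]
        D <- pairwiseMatrix(models, fx$complex, "A", "B")
        rk <- rankClusters(clusterModels(D), scores)
        qv <- setNames(qual$quality, qual$model)
        clustered[case] <- if (nrow(rk) > 0)
            clusterSuccess(rk, qv, topK = min(3, nrow(rk)))[[1]] else 0
    }
    expect_gte(mean(clustered), mean(singles))
})
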