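test_that("interface selections come from the reference and match brute force", {
    fx <- grooveFixture()
    ifc <- interfaceSelection(fx$complex, "A", "B")
    brute <- bruteContacts(fx$complex, "A", "B", 10)
    expect_setequal(ifc$receptor@residues$resno,
                    unique(as.integer(sub(" .*", "", brute))))
    expect_setequal(ifc$peptide@residues$resno,
                    unique(as.integer(sub(".* ", "", brute))))
    # boundary: a pair at exactly 10.00005 A is picked up only by the
    # slightly wider cutoff
    m <- microComplex(pep_y2 = 10.00005)
    i10 <- interfaceSelection(m, "A", "B", cutoff = 10)
    i10b <- interfaceSelection(m, "A", "B", cutoff = 10.0001)
    expect_equal(setdiff(i10b$receptor@residues$resno,
                         i10$receptor@residues$resno), 2)
})

test_that("all four metrics are zero for the reference and rigid copies", {
    fx <- grooveFixture()
    ifc <- interfaceSelection(fx$complex, "A", "B")
    expect_equal(iRMSD(fx$complex, fx$complex, ifc), 0, tolerance = 1e-9)
    expect_equal(lRMSD(fx$complex, fx$complex, "A", "B"), 0, tolerance = 1e-9)
    expect_equal(liRMSD(fx$complex, fx$complex, ifc), 0, tolerance = 1e-9)
    expect_equal(fnat(fx$complex, fx$complex, "A", "B"), 1)
    set.seed(6)
    for (i in 1:3) {
        moved <- rigidMove(fx$complex, randomRotation(), rnorm(3, sd = 25))
        expect_equal(iRMSD(moved, fx$complex, ifc), 0, tolerance = 1e-7)
        expect_equal(lRMSD(moved, fx$complex, "A", "B"), 0, tolerance = 1e-7)
        expect_equal(liRMSD(moved, fx$complex, ifc), 0, tolerance = 1e-7)
        expect_equal(fnat(moved, fx$complex, "A", "B"), 1)
    }
})

test_that("i-RMSD equals an independent 6-DOF minimization oracle", {
    fx <- grooveFixture()
    ifc <- interfaceSelection(fx$complex, "A", "B")
    a <- atomTable(fx$complex)
    xyz <- coords(fx$complex)
    xyz[a$chain == "B", 2] <- xyz[a$chain == "B", 2] + 2
    model <- replaceCoords(fx$complex, xyz)
    got <- iRMSD(model, fx$complex, ifc)
    # oracle: numerically minimize pooled-interface RMSD over rotation
    # (Euler angles) + translation, independent of the Kabsch path
    sel <- c(selectionRows(fx$complex, PepDock:::.with_backbone(ifc$receptor)),
             selectionRows(fx$complex, PepDock:::.with_backbone(ifc$peptide)))
    P <- coords(model)[sel, ]; Q <- coords(fx$complex)[sel, ]
    obj <- function(p) {
        cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
        cz <- cos(p[3]); sz <- sin(p[3])
        Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
        Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
        Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
        sqrt(mean(rowSums((sweep(P %*% t(Rz %*% Ry %*% Rx), 2, -p[4:6]) - Q)^2)))
    }
    best <- Inf
    for (s in 1:15) {
        set.seed(s)
        f <- optim(c(runif(3, -0.5, 0.5), rnorm(3)), obj,
                   control = list(maxit = 3000, reltol = 1e-14))
        best <- min(best, f$value)
    }
    expect_equal(got, best, tolerance = 1e-3)
})

test_that("l-RMSD is a pure peptide displacement after receptor fit", {
    fx <- grooveFixture()
    a <- atomTable(fx$complex)
    xyz <- coords(fx$complex)
    xyz[a$chain == "B", 1] <- xyz[a$chain == "B", 1] + 3
    model <- replaceCoords(fx$complex, xyz)
    expect_equal(lRMSD(model, fx$complex, "A", "B"), 3, tolerance = 1e-9)
    # the optimally fitted peptide backbone bounds l-RMSD from below
    set.seed(8)
    for (i in 1:5) {
        xyz2 <- coords(fx$complex)
        pep <- a$chain == "B"
        xyz2[pep, ] <- sweep(xyz2[pep, ] %*% t(randomRotation()), 2,
                             -rnorm(3, sd = 4))
        m2 <- replaceCoords(fx$complex, xyz2)
        l <- lRMSD(m2, fx$complex, "A", "B")
        bbsel <- pep & a$elety %in% BACKBONE_ATOMS
        lower <- kabschSuperpose(xyz2[bbsel, ], coords(fx$complex)[bbsel, ])$rmsd
        expect_gte(l + 1e-9, lower)
    }
})

test_that("l-i-RMSD reduces to l-RMSD for an all-interface selection", {
    fx <- grooveFixture()
    ifcAll <- interfaceSelection(fx$complex, "A", "B", cutoff = 1e3)
    a <- atomTable(fx$complex)
    xyz <- coords(fx$complex)
    xyz[a$chain == "B", 3] <- xyz[a$chain == "B", 3] + 2.5
    model <- replaceCoords(fx$complex, xyz)
    expect_equal(liRMSD(model, fx$complex, ifcAll),
                 lRMSD(model, fx$complex, "A", "B"), tolerance = 1e-9)
    # the 2 A near-native threshold on this metric is a plain comparison
    ifc <- interfaceSelection(fx$complex, "A", "B")
    expect_true(liRMSD(fx$complex, fx$complex, ifc) <= 2)
})

test_that("fnat counts preserved native residue contacts", {
    ref <- microComplex()                   # contacts: A1-B1 and A2-B2
    moved <- microComplex()
    moved@atoms$y[4] <- 40                  # break the A2-B2 contact
    expect_equal(fnat(moved, ref, "A", "B"), 0.5)
    gone <- microComplex()
    gone@atoms$y[3:4] <- 40
    expect_equal(fnat(gone, ref, "A", "B"), 0)
    noref <- microComplex()
    noref@atoms$y[3:4] <- 40
    expect_error(fnat(ref, noref, "A", "B"), "native")
    # monotone non-increasing under radial retreat of the peptide
    fx <- grooveFixture()
    prev <- 1
    for (h in seq(0, 8, by = 2)) {
        a <- atomTable(fx$complex)
        xyz <- coords(fx$complex)
        xyz[a$chain == "B", 3] <- xyz[a$chain == "B", 3] + h
        f <- fnat(replaceCoords(fx$complex, xyz), fx$complex, "A", "B")
        expect_lte(f, prev + 1e-12)
        prev <- f
    }
})

test_that("quality classes cut at 1 and 2 A inclusively", {
    expect_equal(qualityClass(c(0.4, 1, 1.0001, 2, 2.0001)),
                 c("high", "high", "near_native", "near_native",
                   "not_acceptable"))
})

test_that("success curves are monotone and match a direct scan", {
    q <- c("not_acceptable", "near_native", "not_acceptable", "high",
           "not_acceptable")
    sc <- successCurve(q)
    expect_equal(unname(sc), c(0, 1, 1, 1, 1))
    expect_true(all(diff(sc) >= 0))
    expect_equal(unname(successCurve(rep("not_acceptable", 4))), rep(0, 4))
    expect_equal(unname(successCurve(c("high", rep("not_acceptable", 3)))),
                 rep(1, 4))
    # random permutations against a brute-force top-N scan
    set.seed(9)
    for (i in 1:10) {
        qq <- sample(c("high", "near_native", "not_acceptable"), 12,
                     replace = TRUE)
        got <- successCurve(qq)
        brute <- sapply(seq_along(qq), function(N)
            as.numeric(any(qq[1:N] %in% c("high", "near_native"))))
        expect_equal(unname(got), brute)
        expect_equal(unname(got[length(qq)]),
                     as.numeric(any(qq %in% c("high", "near_native"))))
    }
})
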