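# Shared fixtures, built once per test run.
.fx_env <- new.env()

grooveFixture <- function() {
    if (is.null(.fx_env$groove)) .fx_env$groove <- makeComplex(seed = 1)
    .fx_env$groove
}

patchFixture <- function() {
    if (is.null(.fx_env$patch))
        .fx_env$patch <- makeComplex("convex_patch", seed = 1)
    .fx_env$patch
}

grooveAIRs <- function() {
    if (is.null(.fx_env$airs))
        .fx_env$airs <- defineAIRs(grooveFixture()$complex, "A", "B")
    .fx_env$airs
}

# A tiny synthetic complex with exactly known contacts: two single-atom
# receptor "residues" and two single-atom peptide "residues".
microComplex <- function(pep_y2 = 4) {
    mk <- function(chain, resno, x, y, z)
        data.frame(chain = chain, resno = resno, insert = "", resid = "ALA",
                   elety = "CB", element = "C", x = x, y = y, z = z,
                   o = 1, alt = "", stringsAsFactors = FALSE)
    PepDock:::newStructure(rbind(mk("A", 1, 0, 0, 0), mk("A", 2, 10, 0, 0),
                                 mk("B", 1, 0, 4, 0), mk("B", 2, 10, pep_y2, 0)),
                           source = "micro")
}

# Brute-force O(N^2) residue-contact scan, independent of the package path.
bruteContacts <- function(structure, chainA, chainB, cutoff) {
    a <- atomTable(structure)
    xa <- a[a$chain == chainA, ]
    xb <- a[a$chain == chainB, ]
    hits <- character(0)
    for (ra in unique(xa$resno)) {
        pa <- as.matrix(xa[xa$resno == ra, c("x", "y", "z")])
        for (rb in unique(xb$resno)) {
            pb <- as.matrix(xb[xb$resno == rb, c("x", "y", "z")])
            d <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                      2 * pa %*% t(pb))
            if (any(d < cutoff)) hits <- c(hits, paste(ra, rb))
        }
    }
    hits
}

randomRotation <- function() {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

rigidMove <- function(structure, R = diag(3), t = c(0, 0, 0)) {
    replaceCoords(structure, sweep(coords(structure) %*% t(R), 2, -t))
}
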