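# Shared fixtures: all data are built in code at test time.

# Small cohort with clinical fields overridden to exact values.
makeClinicalCohort <- function(n, sex = NULL, age = NULL, cgi = NULL,
                               diagnoses = NULL, seed = 1L) {
    co <- suppressMessages(generateCohort(
        cohortConfig(nPatients = n, missingRate = 0, seed = seed)))
    cd <- SummarizedExperiment::colData(co)
    if (!is.null(sex)) cd$sex <- sex
    if (!is.null(age)) cd$age <- age
    if (!is.null(cgi)) cd$cgi <- as.integer(cgi)
    if (!is.null(diagnoses))
        cd$diagnoses <- IRanges::CharacterList(diagnoses)
    SummarizedExperiment::colData(co) <- cd
    co
}

# Activation matrix whose rows encode the wanted profile labels
# (factor 1 = least significant bit), named by patient ids.
activationFromLabels <- function(labels, ids = NULL) {
    z <- cbind(bitwAnd(labels, 1L), as.integer(bitwAnd(labels, 2L) > 0L))
    if (!is.null(ids)) rownames(z) <- ids
    z
}

# Exact group-by-distinct-rows partition, the clustering oracle.
groupByRowsPartition <- function(z) {
    key <- apply(z, 1, paste, collapse = "")
    as.integer(factor(key))
}

# Two partitions are the same up to label names.
samePartition <- function(a, b) {
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Hamming agreement of a recovered activation matrix with the planted
# truth, maximized over the two column orders (K = 2 only).
matchedAccuracy <- function(zHat, zTrue) {
    a1 <- mean(c(zHat[, 1] == zTrue[, 1], zHat[, 2] == zTrue[, 2]))
    a2 <- mean(c(zHat[, 2] == zTrue[, 1], zHat[, 1] == zTrue[, 2]))
    max(a1, a2)
}

# Column permutation aligning recovered factors to the planted order.
matchedPerm <- function(zHat, zTrue) {
    a1 <- mean(c(zHat[, 1] == zTrue[, 1], zHat[, 2] == zTrue[, 2]))
    a2 <- mean(c(zHat[, 2] == zTrue[, 1], zHat[, 1] == zTrue[, 2]))
    if (a1 >= a2) 1:2 else 2:1
}

jaccard <- function(a, b)
    length(intersect(a, b)) / length(union(a, b))
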