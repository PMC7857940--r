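test_that("four activation patterns give the four canonical profiles", {
    z <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))[
        rep(1:4, c(5, 3, 4, 2)), ]
    pa <- kmeansProfiles(z, k = 4, seed = 1)
    expect_identical(unname(profileCounts(pa)$patients),
                     c(5L, 3L, 4L, 2L, 14L))
    expect_identical(profileComposition(pa),
                     list(`0` = integer(0), `1` = 1L, `2` = 2L,
                          `3` = c(1L, 2L)))
    # labels follow the activation pattern of each patient
    expect_identical(unname(profileLabels(pa)),
                     rep(0:3, c(5L, 3L, 4L, 2L)))
})

test_that("degenerate clustering inputs are handled", {
    z <- matrix(1L, 7, 2)
    pa <- kmeansProfiles(z, k = 1)
    expect_identical(unname(profileCounts(pa)$patients), c(7L, 7L))
    expect_error(kmeansProfiles(z, k = 3), "distinct activation")
})

test_that("k-means equals the group-by-distinct-rows oracle", {
    set.seed(50)
    for (rep in 1:10) {
        z <- matrix(rbinom(400, 1, 0.5), 200, 2)
        pa <- kmeansProfiles(z, k = 4, seed = rep)
        expect_true(samePartition(profileLabels(pa),
                                  groupByRowsPartition(z)))
    }
})

test_that("canonical relabeling is invariant to patient order", {
    set.seed(51)
    z <- matrix(rbinom(300, 1, 0.4), 150, 2)
    rownames(z) <- sprintf("P%03d", 1:150)
    pa <- kmeansProfiles(z, k = 4, seed = 1)
    shuf <- sample(150)
    pb <- kmeansProfiles(z[shuf, ], k = 4, seed = 2)
    expect_identical(profileComposition(pa), profileComposition(pb))
    expect_identical(pa@counts, pb@counts)
    expect_identical(profileLabels(pb)[rownames(z)], profileLabels(pa))
})

test_that("profile weights compose additively from factor weights", {
    set.seed(52)
    beta <- matrix(rexp(2 * 23), 2, 23)
    bias <- rexp(23, 4)
    w <- composeProfileWeights(beta, bias)
    expect_identical(dim(w), c(23L, 4L))
    expect_equal(w[, 1], bias)                      # profile 0 = bias
    expect_equal(w[, 4], w[, 2] + w[, 3])           # exact additivity
    expect_equal(unname(w[, 2]), beta[1, ])
    # empty composition passes the bias column through unchanged
    only0 <- composeProfileWeights(beta, bias,
                                   composition = list(`0` = integer(0)))
    expect_equal(only0[, 1], bias)
    expect_error(
        composeProfileWeights(beta, bias, composition = list(a = 3L)),
        "unknown factor")
})

test_that("empirical profile means average observed scores per cluster", {
    set.seed(54)
    sc <- matrix(runif(40 * 3, 0, 100), 40, 3)
    sc[1, 1] <- NA
    lab <- rep(0:1, each = 20)
    pa <- kmeansProfiles(activationFromLabels(lab), k = 2)
    m <- profileItemMeans(sc, pa)
    expect_equal(unname(m[, "profile0"]),
                 unname(colMeans(sc[1:20, ], na.rm = TRUE)))
    expect_equal(unname(m[, "profile1"]), unname(colMeans(sc[21:40, ])))
    expect_error(profileItemMeans(sc[1:10, ], pa), "does not match")
})

test_that("profile counts conserve the number of patients", {
    set.seed(53)
    for (rep in 1:5) {
        n <- sample(20:200, 1)
        z <- matrix(rbinom(2 * n, 1, 0.5), n, 2)
        k <- nrow(unique(z))
        pa <- kmeansProfiles(z, k = k, seed = rep)
        tab <- profileCounts(pa)
        expect_identical(tab$patients[nrow(tab)], n)
        expect_identical(sum(tab$patients[-nrow(tab)]), n)
    }
    one <- kmeansProfiles(matrix(c(1L, 0L), 1, 2), k = 1)
    expect_identical(unname(profileCounts(one)$patients), c(1L, 1L))
})
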