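# Independent per-cell probability oracle for the Bernoulli-Poisson
# observation model, computed cell by cell with explicit loops.
cellProductOracle <- function(X, Z, beta, bias) {
    total <- 0
    for (n in seq_len(nrow(X))) for (d in seq_len(ncol(X))) {
        x <- X[n, d]
        if (is.na(x)) next
        lam <- bias[d]
        for (k in seq_len(ncol(Z))) lam <- lam + Z[n, k] * beta[k, d]
        p1 <- 1 - exp(-lam)
        total <- total + log(if (x == 1) p1 else 1 - p1)
    }
    total
}

test_that("likelihood agrees with closed forms on degenerate states", {
    X0 <- matrix(0L, 2, 3)
    expect_identical(spfmLogLikelihood(X0, matrix(0L, 2, 0),
                                       matrix(0, 0, 3), rep(0, 3)), 0)
    # single observed cell with rate ln 2: P(x = 1) = 1/2
    X1 <- matrix(1L, 1, 1)
    expect_equal(spfmLogLikelihood(X1, matrix(1L, 1, 1),
                                   matrix(log(2), 1, 1), 0),
                 log(0.5), tolerance = 1e-12)
})

test_that("likelihood equals the cell-by-cell product oracle", {
    set.seed(11)
    for (rep in 1:10) {
        X <- matrix(rbinom(6, 1, 0.5), 3, 2)
        X[sample(6, 1)] <- NA
        Z <- matrix(rbinom(6, 1, 0.5), 3, 2)
        beta <- matrix(rexp(4), 2, 2)
        bias <- rexp(2, 5)
        expect_equal(spfmLogLikelihood(X, Z, beta, bias),
                     cellProductOracle(X, Z, beta, bias),
                     tolerance = 1e-12)
    }
})

test_that("observation model normalizes over all binary outcomes", {
    set.seed(12)
    Z <- matrix(rbinom(4, 1, 0.5), 2, 2)
    beta <- matrix(rexp(4), 2, 2)
    bias <- rexp(2, 2)
    total <- 0
    for (code in 0:15) {
        X <- matrix(as.integer(intToBits(code)[1:4]), 2, 2)
        total <- total + exp(spfmLogLikelihood(X, Z, beta, bias))
    }
    expect_equal(total, 1, tolerance = 1e-12)
})

test_that("masked cells are excluded, not imputed", {
    set.seed(13)
    X <- matrix(rbinom(12, 1, 0.4), 4, 3)
    Z <- matrix(rbinom(8, 1, 0.5), 4, 2)
    beta <- matrix(rexp(6), 2, 3)
    bias <- rexp(3, 2)
    Xm <- X; Xm[2, ] <- NA
    expect_equal(spfmLogLikelihood(Xm, Z, beta, bias),
                 spfmLogLikelihood(X[-2, , drop = FALSE],
                                   Z[-2, , drop = FALSE], beta, bias),
                 tolerance = 1e-12)
})

test_that("contract violations are rejected", {
    X <- matrix(0L, 2, 2); Z <- matrix(0L, 2, 1)
    expect_error(spfmLogLikelihood(X, Z, matrix(-1, 1, 2), c(0, 0)),
                 "nonnegative")
    expect_error(spfmLogLikelihood(matrix(2, 2, 2), Z,
                                   matrix(1, 1, 2), c(0, 0)), "binary")
    expect_error(spfmLogLikelihood(X, Z, matrix(1, 1, 2), c(0, 0, 0)),
                 "dimension|entry per item")
})

# ---- IBP prior ----

# Exhaustive enumeration of the two-customer sequential buffet process:
# customer 1 takes Poisson(alpha) new dishes; customer 2 takes each with
# probability 1/2 and Poisson(alpha/2) new ones. A configuration class
# is (a, b, c) = (# dishes only 1 took, only 2 took, both took).
enumerateTwoCustomerClasses <- function(alpha, maxK = 8) {
    mass <- new.env()
    for (k1 in 0:maxK) for (cc in 0:k1) for (k2 in 0:maxK) {
        p <- dpois(k1, alpha) * choose(k1, cc) * 0.5^k1 *
            dpois(k2, alpha / 2)
        key <- paste(k1 - cc, k2, cc, sep = ",")
        mass[[key]] <- (if (is.null(mass[[key]])) 0 else mass[[key]]) + p
    }
    mass
}

classMatrix <- function(a, b, c) {
    cols <- c(rep(list(c(1L, 0L)), a), rep(list(c(0L, 1L)), b),
              rep(list(c(1L, 1L)), c))
    if (length(cols) == 0) matrix(0L, 2, 0) else do.call(cbind, cols)
}

test_that("IBP prior matches the sequential-process enumeration oracle", {
    alpha <- 1.3
    mass <- enumerateTwoCustomerClasses(alpha)
    for (a in 0:3) for (b in 0:3) for (c in 0:3) {
        if (a + b + c > 3) next
        expected <- mass[[paste(a, b, c, sep = ",")]]
        expect_equal(exp(ibpLogPrior(classMatrix(a, b, c), alpha)),
                     expected, tolerance = 1e-12,
                     label = sprintf("class (%d,%d,%d)", a, b, c))
    }
})

test_that("IBP prior closed forms and invariances hold", {
    expect_equal(ibpLogPrior(matrix(0L, 1, 0), alpha = 1), -1,
                 tolerance = 1e-12)     # Poisson(alpha) zero count
    set.seed(14)
    Z <- matrix(rbinom(24, 1, 0.5), 6, 4)
    Z <- Z[, colSums(Z) > 0, drop = FALSE]
    lp <- ibpLogPrior(Z, 0.8)
    expect_equal(ibpLogPrior(Z[sample(6), , drop = FALSE], 0.8), lp,
                 tolerance = 1e-12)     # row exchangeability
    expect_equal(ibpLogPrior(Z[, sample(ncol(Z)), drop = FALSE], 0.8),
                 lp, tolerance = 1e-12) # column order irrelevant
    expect_error(ibpLogPrior(Z, 0), "alpha")
    expect_error(ibpLogPrior(cbind(Z, 0L), 1), "all-zero")
})
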