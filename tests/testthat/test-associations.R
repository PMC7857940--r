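test_that("diagnosis crosstab matches a per-patient enumeration oracle", {
    co <- suppressMessages(completenessFilter(
        generateCohort(cohortConfig(nPatients = 600, seed = 30)),
        "diagnosis"))
    set.seed(30)
    lab <- sample(0:3, ncol(co), replace = TRUE)
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 4)
    ct <- crosstabDiagnosisByProfile(co, pa)
    # oracle: loop over patients, one count per carried chapter
    dx <- clinicalData(co)$diagnoses
    oracle <- matrix(0L, nrow(ct$counts), ncol(ct$counts),
                     dimnames = dimnames(ct$counts))
    for (i in seq_along(dx))
        for (ch in dx[[i]])
            oracle[ch, as.character(lab[i])] <-
                oracle[ch, as.character(lab[i])] + 1L
    expect_identical(ct$counts, oracle)
    # with comorbidity, total counts = sum of per-patient multiplicities
    expect_identical(sum(ct$counts), sum(lengths(dx)))
    expect_true(all(abs(rowSums(ct$rowPercentages) - 100) <= 0.2))
    expect_true(ct$multiCounting)
})

test_that("single-patient crosstab and empty cohorts behave", {
    co <- makeClinicalCohort(1, diagnoses = list("F4"))
    pa <- kmeansProfiles(activationFromLabels(0L, colnames(co)), k = 1)
    ct <- crosstabDiagnosisByProfile(co, pa)
    expect_identical(unname(ct$counts["F4", "0"]), 1L)
    expect_equal(unname(ct$rowPercentages["F4", "0"]), 100)
    expect_error(crosstabDiagnosisByProfile(co[, 0], pa), "empty cohort")
})

test_that("CGI summaries match a direct two-pass oracle", {
    set.seed(31)
    n <- 400
    cgi <- sample(0:7, n, replace = TRUE)
    lab <- sample(0:3, n, replace = TRUE)
    co <- makeClinicalCohort(n, cgi = cgi)
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 4)
    s <- cgiByProfile(co, pa)
    for (p in names(s)) {
        v <- cgi[lab == as.integer(p)]
        expect_identical(s[[p]]$n, length(v))
        expect_equal(s[[p]]$mean, round(sum(v) / length(v), 2))
        expect_equal(s[[p]]$sd,
                     round(sqrt(sum((v - mean(v))^2) / (length(v) - 1)), 2))
        expect_identical(sum(s[[p]]$distribution$n), length(v))
        expect_lte(abs(sum(s[[p]]$distribution$percent) - 100), 0.2)
    }
})

test_that("constant CGI gives mean 3, sd 0; empty profiles are omitted", {
    co <- makeClinicalCohort(30, cgi = rep(3L, 30))
    lab <- rep(c(0L, 1L), 15)
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 2)
    s <- cgiByProfile(co, pa)
    expect_equal(s[["0"]]$mean, 3)
    expect_equal(s[["0"]]$sd, 0)
    # a profile present in the assignment but absent from the filtered
    # cohort is dropped with a note
    keep <- lab == 0L
    expect_message(s2 <- cgiByProfile(co[, keep], pa), "omitted")
    expect_identical(names(s2), "0")
})

test_that("homogeneity tests reproduce zero-signal closed forms", {
    # same age multiset in every profile: between-group variance is 0
    ages <- rep(c(30, 40, 50, 60), times = 4)
    lab <- rep(0:3, each = 4)
    co <- makeClinicalCohort(16, age = ages,
                             sex = rep(c("female", "male"), 8))
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 4)
    ft <- testProfileHomogeneity(co, pa, "age")
    expect_identical(ft$test, "one-way-F")
    expect_equal(ft$statistic, 0, tolerance = 1e-12)
    expect_identical(ft$df[1], 3L)
    # balanced 2x2 sex table: chi-square 0
    co2 <- makeClinicalCohort(40, sex = rep(c("female", "male"), 20))
    lab2 <- rep(c(0L, 1L), each = 20)
    pa2 <- kmeansProfiles(activationFromLabels(lab2, colnames(co2)), k = 2)
    ct <- testProfileHomogeneity(co2, pa2, "sex")
    expect_identical(ct$test, "chi-square")
    expect_equal(ct$statistic, 0, tolerance = 1e-12)
    expect_identical(unname(ct$df), 1L)
})

test_that("F and chi-square match hand-computed statistics and a
           permutation null", {
    set.seed(33)
    n <- 80
    age <- rnorm(n, 50, 12)
    lab <- sample(0:3, n, replace = TRUE)
    sex <- sample(c("female", "male", NA), n, replace = TRUE,
                  prob = c(0.5, 0.38, 0.12))
    co <- makeClinicalCohort(n, age = age, sex = sex)
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 4)
    ft <- testProfileHomogeneity(co, pa, "age")
    # one-way F from explicit sums of squares
    g <- factor(lab)
    gm <- tapply(age, g, mean)
    ssb <- sum(table(g) * (gm - mean(age))^2)
    ssw <- sum((age - gm[g])^2)
    fOracle <- (ssb / 3) / (ssw / (n - 4))
    expect_equal(ft$statistic, fOracle, tolerance = 1e-9)
    # permutation check of the p-value (Monte Carlo CI)
    perms <- replicate(999, {
        gp <- sample(g)
        gmp <- tapply(age, gp, mean)
        (sum(table(gp) * (gmp - mean(age))^2) / 3) /
            (sum((age - gmp[gp])^2) / (n - 4))
    })
    pPerm <- mean(perms >= ft$statistic)
    expect_lt(abs(pPerm - ft$pValue),
              3 * sqrt(ft$pValue * (1 - ft$pValue) / 999) + 0.01)
    # chi-square from the classic observed/expected formula,
    # missing sex excluded
    ct <- testProfileHomogeneity(co, pa, "sex")
    keep <- !is.na(sex)
    tab <- table(sex[keep], lab[keep])
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(ct$statistic, sum((tab - exp_)^2 / exp_),
                 tolerance = 1e-9)
    # statistic invariant under relabeling rows/columns of the table
    tab2 <- tab[2:1, c(3, 1, 4, 2)]
    exp2 <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
    expect_equal(sum((tab2 - exp2)^2 / exp2), ct$statistic,
                 tolerance = 1e-9)
})

test_that("insufficient groups or observations raise errors", {
    co <- makeClinicalCohort(12, age = c(rnorm(11, 50, 5), 60))
    lab <- c(rep(0L, 11), 1L)
    pa <- kmeansProfiles(activationFromLabels(lab, colnames(co)), k = 2)
    expect_error(testProfileHomogeneity(co, pa, "age"), ">= 2 age")
    one <- kmeansProfiles(
        activationFromLabels(rep(0L, 12), colnames(co)), k = 1)
    expect_error(testProfileHomogeneity(co, one, "age"), "2 profiles")
})
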