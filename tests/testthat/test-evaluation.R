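test_that("splits partition the collection and are seed-deterministic", {
    pop <- randomPopulation(nCases = 1000, nItems = 8, seed = 2)
    sp <- splitCases(pop, testFraction = 0.1, seed = 99)
    expect_equal(nCases(sp$train), 900L)
    expect_equal(nCases(sp$test), 100L)
    expect_length(intersect(caseIds(sp$train), caseIds(sp$test)), 0L)
    expect_setequal(c(caseIds(sp$train), caseIds(sp$test)), caseIds(pop))

    again <- splitCases(pop, testFraction = 0.1, seed = 99)
    expect_identical(caseIds(again$test), caseIds(sp$test))

    ## different seeds give different partitions (overwhelmingly)
    differs <- vapply(1:5, function(s) {
        !identical(caseIds(splitCases(pop, 0.1, seed = s)$test),
                   caseIds(sp$test))
    }, logical(1))
    expect_true(all(differs))
})

test_that("degenerate inputs are rejected by the ROC", {
    expect_error(rocCurve(c(1, 2), c(TRUE, TRUE)), "each outcome class")
    expect_error(splitCases(tinyCases(), testFraction = 0), "between 0 and 1")
})

test_that("AUC handles perfect separation and pure ties", {
    expect_equal(auc(rocCurve(c(10, 9, 1, 2),
                              c(TRUE, TRUE, FALSE, FALSE))), 1)
    expect_equal(auc(rocCurve(c(3, 3, 3, 3),
                              c(TRUE, FALSE, TRUE, FALSE))), 0.5)
    ## explicit 4-pair enumeration: (1 + 1 + 0.5 + 1)/4
    expect_equal(auc(rocCurve(c(3, 1, 2, 2),
                              c(TRUE, FALSE, TRUE, FALSE))), 0.875)
})

test_that("rank AUC matches the all-pairs oracle on random inputs", {
    set.seed(42)
    for (k in 1:100) {
        n <- sample(10:60, 1)
        ## draw from few distinct values so ties actually occur
        scores <- sample(seq(0.5, 5, by = 0.5), n, replace = TRUE)
        died <- runif(n) < 0.4
        if (!any(died) || all(died)) next
        roc <- rocCurve(scores, died)
        expect_equal(auc(roc), bruteForceAuc(scores, died),
                     tolerance = 1e-10)
        ## the rank statistic equals the trapezoidal area under the curve
        ## curve points run from the highest threshold down, so FPR and
        ## TPR are already ascending; prepend the (0, 0) corner
        fpr <- c(0, 1 - roc@specificity)
        tpr <- c(0, roc@sensitivity)
        trap <- sum(diff(fpr) * (utils::head(tpr, -1) +
                                     utils::tail(tpr, -1)) / 2)
        expect_equal(auc(roc), trap, tolerance = 1e-10)
    }
})

test_that("AUC is invariant under increasing transforms and flips sign", {
    set.seed(7)
    scores <- rexp(80)
    died <- runif(80) < 0.3
    a0 <- auc(rocCurve(scores, died))
    expect_equal(auc(rocCurve(log(scores + 1), died)), a0)
    expect_equal(auc(rocCurve(scores^3, died)), a0)
    ## tie-free scores: complement under score negation
    expect_equal(auc(rocCurve(-scores, died)), 1 - a0, tolerance = 1e-12)
})

test_that("AUC agrees with an independent reference implementation", {
    skip_if_not_installed("pROC")
    set.seed(13)
    for (k in 1:20) {
        n <- sample(20:80, 1)
        scores <- sample(seq(1, 10, by = 0.5), n, replace = TRUE)
        died <- runif(n) < 0.35
        if (!any(died) || all(died)) next
        ref <- as.numeric(pROC::auc(pROC::roc(
            response = died, predictor = scores, quiet = TRUE,
            direction = "<")))
        expect_equal(auc(rocCurve(scores, died)), ref, tolerance = 1e-10)
    }
})

test_that("Youden boundary matches the exhaustive threshold sweep", {
    set.seed(31)
    for (k in 1:30) {
        n <- sample(10:40, 1)
        scores <- sample(seq(0.5, 4, by = 0.5), n, replace = TRUE)
        died <- runif(n) < 0.4
        if (!any(died) || all(died)) next
        roc <- rocCurve(scores, died)
        oracle <- bruteForceYouden(scores, died)
        expect_equal(roc@youdenJ, oracle$J, tolerance = 1e-12)
        expect_equal(youdenBoundary(roc), oracle$threshold)
    }
    ## perfect separation: J = 1 at the smallest separating threshold
    roc <- rocCurve(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(roc@youdenJ, 1)
    expect_equal(youdenBoundary(roc), 9)
    ## all ties: no discrimination, J = 0
    roc <- rocCurve(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(roc@youdenJ, 0)
})

test_that("confusion metrics agree with a hand-counted table", {
    scores <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 3.5, 2.2,
                4.5, 0.8, 1.2, 2.8, 3.2, 0.3, 1.8, 2.1, 0.9, 4.2)
    died <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
              TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
              FALSE, TRUE, FALSE, FALSE)
    delta <- 2.5
    ## hand count at score >= 2.5: deaths flagged are 5, 4, 2.5, 3.5,
    ## 4.5, 3.2 (6 of 7); survivors cleared are all but 3, 2.8, 4.2
    ## (10 of 13)
    cm <- confusionMetrics(scores, died, delta)
    expect_equal(cm[["sensitivity"]], 6 / 7)
    expect_equal(cm[["specificity"]], 10 / 13)
    expect_equal(cm[["accuracy"]], 16 / 20)

    ## degenerate boundaries
    perfect <- confusionMetrics(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE), 5)
    expect_equal(unname(perfect), c(1, 1, 1))
    low <- confusionMetrics(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE), 0.1)
    expect_equal(low[["sensitivity"]], 1)
    expect_equal(low[["specificity"]], 0)
})

test_that("the default threshold grid has the canonical 13 values", {
    g <- defaultPMaxGrid()
    expect_length(g, 13L)
    expect_equal(min(g), 0)
    expect_equal(max(g), 1)
    expect_true(0.05 %in% g)
    expect_true(all(10^-(0:10) %in% g))
})

test_that("a reduced grid runs end to end and respects anti-monotonicity", {
    cfg <- mimicLikeConfig("small")
    pop <- generatePopulation(cfg, seed = 8)
    cells <- runGrid(pop, pMaxValues = c(1e-6, 1e-3, 0.05, 1),
                     bonferroniOptions = c(FALSE, TRUE),
                     repetitions = 2, seed = 5)
    expect_equal(nrow(cells), 4 * 2 * 2)
    expect_true(all(cells$valid))
    expect_true(all(cells$aucTrain >= 0 & cells$aucTrain <= 1))
    ## rule count is non-decreasing in pMax within a repetition/setting
    for (g in split(cells, list(cells$bonferroni, cells$repetition))) {
        g <- g[order(g$pMax), ]
        expect_true(all(diff(g$nRules) >= 0))
    }
    ## single-cell grid
    one <- runGrid(pop, pMaxValues = 0.05, bonferroniOptions = FALSE,
                   repetitions = 1, seed = 5)
    expect_equal(nrow(one), 1L)
    ## aggregation gives one row per configuration
    agg <- aggregateGrid(cells)
    expect_equal(nrow(agg), 8L)
    expect_true(all(agg$nValid == 2L))
})

test_that("invalid splits are flagged, not dropped", {
    ## 10 cases, 1 death: some splits leave the test set without deaths
    cs <- makeCaseSet(data.frame(
        case_id = sprintf("c%02d", 1:10),
        variable_type = "ward", code = rep(c("ICU", "ER"), 5),
        outcome = c("died", rep("survived", 9))
    ))
    cells <- runGrid(cs, pMaxValues = 0.5, bonferroniOptions = FALSE,
                     repetitions = 6, testFraction = 0.2, seed = 1)
    expect_equal(nrow(cells), 6L)
    expect_true(any(!cells$valid))  # with 1 death most splits degenerate
    expect_true(all(is.na(cells$aucTest[!cells$valid])))
})

test_that("rule summaries count signs, types and extremes", {
    cand <- data.frame(
        variableType = c("diagnosis", "diagnosis", "ward", "prescription"),
        code = c("sepsis A", "sepsis B", "ICU", "heparin"),
        oddsRatio = c(0.5, 2, 3, 1),
        pValue = c(0, 0, 0, 0),
        a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
        stringsAsFactors = FALSE
    )
    model <- applyFilter(cand, pMax = 1)
    s <- summarizeRules(model, k = 2)
    expect_equal(s$nRules, 4L)
    expect_equal(s$countsByType[["diagnosis"]], 2L)
    expect_equal(s$countsByType[["ward"]], 1L)
    expect_equal(s$countsByType[["gender"]], 0L)
    expect_equal(s$nNegative, 1L)
    expect_equal(s$nPositive, 2L)  # OR exactly 1 is neither
    expect_equal(s$topRules$code[1], "ICU")
    expect_equal(s$bottomRules$code[1], "sepsis A")

    grp <- ruleGroupRange(model, "sepsis")
    expect_equal(grp$n, 2L)
    expect_equal(grp$minOR, 0.5)
    expect_equal(grp$maxOR, 2)

    empty <- applyFilter(cand[0, ], pMax = 0.5)
    s0 <- summarizeRules(empty)
    expect_equal(s0$nRules, 0L)
    expect_true(all(s0$countsByType == 0L))
})
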