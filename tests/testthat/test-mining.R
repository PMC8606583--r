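test_that("contingency tables count item presence against mortality", {
    cs <- tinyCases()
    ## A419 present in the one death and in 1 of 3 survivors
    expect_equal(tabulateItem(cs, "diagnosis", "A419"),
                 c(a = 1, b = 1, c = 0, d = 2))
    ## absent item: a = b = 0, margins preserved
    expect_equal(tabulateItem(cs, "diagnosis", "nope"),
                 c(a = 0, b = 0, c = 1, d = 3))
})

test_that("contingency cells match a per-case double loop on random data", {
    pop <- randomPopulation(nCases = 300, nItems = 10, seed = 7)
    info <- itemInfo(pop)
    died <- outcomes(pop) == "died"
    for (r in seq_len(nrow(info))) {
        inCase <- vapply(seq_len(nCases(pop)), function(k) {
            items <- caseItems(pop, k)
            any(items$variableType == info$variableType[r] &
                    items$code == info$code[r])
        }, logical(1))
        expected <- c(a = sum(inCase & died), b = sum(inCase & !died),
                      c = sum(!inCase & died), d = sum(!inCase & !died))
        got <- tabulateItem(pop, info$variableType[r], info$code[r])
        expect_equal(got, expected)
        expect_equal(sum(got), nCases(pop))
    }
})

test_that("odds ratio is the cross-product ratio; zero cells are flagged", {
    expect_identical(oddsRatio(c(100, 200, 300, 400)), 2 / 3)
    expect_identical(oddsRatio(c(10, 10, 10, 10)), 1)
    expect_identical(oddsRatio(c(50, 100, 25, 200)), 4)
    expect_true(is.na(oddsRatio(c(0, 10, 10, 10))))
    expect_true(is.na(oddsRatio(c(10, 10, 10, 0))))
})

test_that("log-odds-ratio test matches an independent normal tail", {
    ## OR = 1 gives z = 0 and p = 1
    expect_equal(logOrTest(c(100, 100, 100, 100)), 1)

    ## recompute the worked table with an independent CDF route:
    ## numeric integration of the standard normal density
    tab <- c(100, 200, 300, 400)
    z <- log(2 / 3) / sqrt(1 / 100 + 1 / 200 + 1 / 300 + 1 / 400)
    tail <- stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                             abs(z), Inf, rel.tol = 1e-12)$value
    expect_equal(logOrTest(tab), 2 * tail, tolerance = 1e-9)
    expect_equal(logOrTest(tab), 0.004967, tolerance = 1e-4)

    ## overwhelming association with huge counts underflows to exactly 0
    expect_identical(logOrTest(c(1e5, 1e5, 1e5, 1e6)), 0)

    ## zero cells are a contract violation here, not a silent result
    expect_error(logOrTest(c(0, 1, 1, 1)), "positive")
})

test_that("mining yields one candidate per distinct item minus zero cells", {
    pop <- randomPopulation(nCases = 1000, nItems = 20, seed = 11)
    cand <- mineCandidates(pop)
    info <- itemInfo(pop)
    ## brute-force expectation: items whose four cells are all positive
    expectKeep <- vapply(seq_len(nrow(info)), function(r) {
        all(tabulateItem(pop, info$variableType[r], info$code[r]) > 0)
    }, logical(1))
    expect_equal(nrow(cand), sum(expectKeep))
    ## every candidate's stored cells reproduce its OR and p-value
    for (r in seq_len(nrow(cand))) {
        tab <- c(cand$a[r], cand$b[r], cand$c[r], cand$d[r])
        expect_equal(cand$oddsRatio[r], oddsRatio(tab))
        expect_equal(cand$pValue[r], logOrTest(tab))
    }
})

test_that("an item seen only in deaths yields no candidate", {
    cs <- makeCaseSet(data.frame(
        case_id = c("d1", "d2", "s1", "s2"),
        variable_type = "diagnosis",
        code = c("fatal", "other", "other", "other"),
        outcome = c("died", "died", "survived", "survived")
    ))
    cand <- mineCandidates(cs)
    expect_false("fatal" %in% cand$code)  # zero cell: OR would be infinite
})

test_that("minimal-class mining over clinical-only data finds nothing", {
    cs <- makeCaseSet(data.frame(
        case_id = c("a", "b"),
        variable_type = "diagnosis", code = c("x", "x"),
        outcome = c("died", "survived")
    ))
    expect_equal(nrow(mineCandidates(cs, "minimal")), 0L)
})

test_that("single-class collections are rejected", {
    allDied <- makeCaseSet(data.frame(
        case_id = c("a", "b"), variable_type = "ward", code = "ICU",
        outcome = "died"))
    expect_error(mineCandidates(allDied), "at least one death and one")
})

test_that("filter keeps rules strictly below the effective threshold", {
    cand <- data.frame(
        variableType = "ward", code = sprintf("w%d", 1:3),
        oddsRatio = c(4, 2, 1.1), pValue = c(0, 0.01, 0.2),
        a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
        stringsAsFactors = FALSE
    )
    expect_equal(nRules(applyFilter(cand, pMax = 0.05)), 2L)
    expect_equal(nRules(applyFilter(cand, pMax = 1)), 3L)
    ## pMax = 0 keeps only exactly-zero p-values
    m0 <- applyFilter(cand, pMax = 0)
    expect_equal(rules(m0)$code, "w1")
    ## Bonferroni divides by the number of executed tests
    mb <- applyFilter(cand, pMax = 0.05, bonferroni = TRUE)
    expect_equal(nTests(mb), 3L)
    expect_equal(nRules(mb), 2L)  # threshold 0.0167: keeps 0 and 0.01
    ## ties at the threshold are excluded (strict <)
    tie <- cand
    tie$pValue <- c(0.05, 0.01, 0.2)
    expect_equal(nRules(applyFilter(tie, pMax = 0.05)), 1L)
    expect_error(applyFilter(cand, pMax = 1.5), "pMax")
})

test_that("filtering is anti-monotone in pMax and under Bonferroni", {
    pop <- randomPopulation(nCases = 800, nItems = 25, seed = 3)
    cand <- mineCandidates(pop)
    ruleSet <- function(m) itemKey(rules(m)$variableType, rules(m)$code)
    grid <- sort(c(0, 10^seq(-6, 0, by = 1), 0.05, 0.3))
    for (bf in c(FALSE, TRUE)) {
        prev <- character(0)
        for (pm in grid) {
            cur <- ruleSet(applyFilter(cand, pMax = pm, bonferroni = bf))
            expect_true(all(prev %in% cur))
            prev <- cur
        }
    }
    for (pm in grid[grid > 0]) {
        withB <- ruleSet(applyFilter(cand, pMax = pm, bonferroni = TRUE))
        without <- ruleSet(applyFilter(cand, pMax = pm, bonferroni = FALSE))
        expect_true(all(withB %in% without))
    }
})

test_that("swapping outcome labels inverts every mined odds ratio", {
    pop <- randomPopulation(nCases = 500, nItems = 15, seed = 5)
    swapped <- pop
    swapped@outcome <- factor(
        ifelse(pop@outcome == "died", "survived", "died"),
        levels = c("survived", "died"))
    a <- mineCandidates(pop)
    b <- mineCandidates(swapped)
    expect_equal(nrow(a), nrow(b))
    key <- function(d) itemKey(d$variableType, d$code)
    b <- b[match(key(a), key(b)), ]
    expect_equal(b$oddsRatio, 1 / a$oddsRatio, tolerance = 1e-12)
    expect_equal(b$pValue, a$pValue, tolerance = 1e-12)
})

test_that("mining is deterministic", {
    pop <- randomPopulation(nCases = 400, nItems = 10, seed = 9)
    expect_identical(mineCandidates(pop), mineCandidates(pop))
    expect_equal(mineRules(pop, 0.05, TRUE), mineRules(pop, 0.05, TRUE))
})
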