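#' Contingency table of one item against in-hospital mortality
#'
#' Cross-classifies the labeled cases by presence of the item and by
#' outcome: `a` = cases with the item that died, `b` = with the item,
#' survived, `c` = without the item, died, `d` = without the item,
#' survived. `a+b+c+d` equals the number of labeled cases.
#'
#' @param x a [CaseSet]; unlabeled cases are not allowed here.
#' @param variableType,code identify the item; an item absent from the
#'   collection yields `a = b = 0`.
#' @return named integer vector `c(a, b, c, d)`.
#' @examples
#' cs <- makeCaseSet(data.frame(
#'     case_id = c("p1", "p2", "p3", "p4"),
#'     variable_type = "ward",
#'     code = c("ICU", "ICU", "ER", "ER"),
#'     outcome = c("died", "survived", "survived", "survived")
#' ))
#' tabulateItem(cs, "ward", "ICU")  # a=1 b=1 c=0 d=2
#' @export
tabulateItem <- function(x, variableType, code) {
    stopifnot(is(x, "CaseSet"))
    if (nCases(x) == 0L) stop("case collection is empty", call. = FALSE)
    if (anyNA(x@outcome))
        stop("cannot tabulate over unlabeled cases", call. = FALSE)
    died <- x@outcome == "died"
    idx <- match(itemKey(variableType, code),
                 itemKey(x@itemInfo$variableType, x@itemInfo$code))
    if (is.na(idx)) {
        present <- rep(FALSE, nCases(x))
    } else {
        present <- x@itemMatrix[idx, ] > 0
    }
    c(a = sum(present & died), b = sum(present & !died),
      c = sum(!present & died), d = sum(!present & !died))
}

#' Odds ratio of a 2x2 contingency table
#'
#' The cross-product ratio `a*d / (b*c)`: 1 means no association between
#' the item and in-hospital mortality, above 1 a positive and below 1 a
#' negative association. When any cell is zero the odds ratio would be 0
#' or infinite; such tables are signalled with `NA`, the marker telling
#' the mining step to discard the rule (no continuity correction is
#' applied).
#'
#' @param table named or positional numeric vector `(a, b, c, d)`.
#' @return a positive finite number, or `NA` for a zero cell.
#' @examples
#' oddsRatio(c(100, 200, 300, 400))  # 2/3
#' oddsRatio(c(10, 10, 10, 10))      # 1
#' oddsRatio(c(5, 0, 3, 7))          # NA: discard
#' @export
oddsRatio <- function(table) {
    table <- as.numeric(table)
    stopifnot(length(table) == 4L, all(table >= 0))
    if (any(table == 0)) return(NA_real_)
    (table[1] * table[4]) / (table[2] * table[3])
}

#' Two-sided test of "odds ratio = 1" by the normal approximation
#'
#' Tests the null hypothesis of no association using the large-sample
#' normal approximation of the log odds ratio with the Woolf standard
#' error `SE = sqrt(1/a + 1/b + 1/c + 1/d)`:
#' `z = log(OR)/SE`, `p = 2 * (1 - Phi(|z|))`. With very large counts and
#' an odds ratio far from 1 the p-value underflows to exactly 0 in double
#' precision; that underflow is meaningful (the strictest filter setting
#' keeps only such rules).
#'
#' @param table numeric vector `(a, b, c, d)`; all cells must be positive
#'   (zero-cell tables must have been discarded upstream).
#' @return two-sided p-value in \\[0, 1\\].
#' @examples
#' logOrTest(c(100, 100, 100, 100))  # 1: OR = 1 exactly
#' logOrTest(c(100, 200, 300, 400))  # ~0.005
#' @export
logOrTest <- function(table) {
    table <- as.numeric(table)
    stopifnot(length(table) == 4L)
    if (any(table <= 0)) {
        stop("all four cells must be positive; zero-cell tables are ",
             "discarded before testing", call. = FALSE)
    }
    z <- log(oddsRatio(table)) / sqrt(sum(1 / table))
    2 * stats::pnorm(-abs(z))
}

#' Mine candidate single-item mortality rules
#'
#' For every distinct item in the collection (restricted to the five
#' admission-time demographic types when `modelClass = "minimal"`), builds
#' the 2x2 contingency table against the outcome, computes the odds ratio,
#' and tests it against 1. Items with a zero cell -- odds ratio 0 or
#' infinite -- are discarded. The survivors are the candidates that the
#' significance filter ([applyFilter()]) then prunes into a model.
#'
#' @param x a [CaseSet] containing at least one death and one survivor,
#'   with no unlabeled cases.
#' @param modelClass `"full"` (all ten variable types) or `"minimal"`.
#' @return data.frame of candidates, one row per rule, sorted by
#'   (variableType, code): columns `variableType`, `code`, `oddsRatio`,
#'   `pValue`, `a`, `b`, `c`, `d`.
#' @seealso [applyFilter()], [mineRules()]
#' @export
mineCandidates <- function(x, modelClass = c("full", "minimal")) {
    stopifnot(is(x, "CaseSet"))
    modelClass <- match.arg(modelClass)
    if (nCases(x) == 0L) stop("case collection is empty", call. = FALSE)
    if (anyNA(x@outcome))
        stop("cannot mine rules from unlabeled cases", call. = FALSE)
    if (modelClass == "minimal") x <- restrictToMinimal(x)
    died <- x@outcome == "died"
    nDied <- sum(died)
    nSurv <- sum(!died)
    if (nDied == 0L || nSurv == 0L) {
        stop("rule mining needs at least one death and one survivor; ",
             "got ", nDied, " death(s) and ", nSurv, " survivor(s)",
             call. = FALSE)
    }
    if (nItems(x) == 0L) {
        return(emptyRuleFrame())
    }
    a <- as.numeric(Matrix::rowSums(x@itemMatrix[, died, drop = FALSE]))
    total <- as.numeric(Matrix::rowSums(x@itemMatrix))
    b <- total - a
    cc <- nDied - a
    d <- nSurv - b
    keep <- a > 0 & b > 0 & cc > 0 & d > 0
    or <- (a * d) / (b * cc)
    z <- log(or) / sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    p <- 2 * stats::pnorm(-abs(z))
    out <- data.frame(
        variableType = x@itemInfo$variableType[keep],
        code = x@itemInfo$code[keep],
        oddsRatio = or[keep],
        pValue = p[keep],
        a = as.integer(a[keep]), b = as.integer(b[keep]),
        c = as.integer(cc[keep]), d = as.integer(d[keep]),
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
}

emptyRuleFrame <- function() {
    data.frame(
        variableType = character(), code = character(),
        oddsRatio = numeric(), pValue = numeric(),
        a = integer(), b = integer(), c = integer(), d = integer(),
        stringsAsFactors = FALSE
    )
}

#' Significance-filter candidate rules into a model
#'
#' Keeps candidates whose p-value lies strictly below the effective
#' threshold: `pMax` itself, or `pMax / nTests` under Bonferroni
#' correction, where `nTests` is the number of tests actually executed
#' (the candidate count after zero-cell discard). The special setting
#' `pMax = 0` keeps exactly the rules whose p-value underflowed to 0 --
#' the strictest filter, available only because double-precision
#' p-values of overwhelming associations round to zero.
#'
#' @param candidates data.frame from [mineCandidates()].
#' @param pMax significance threshold in \\[0, 1\\].
#' @param bonferroni divide `pMax` by the number of executed tests?
#' @param modelClass recorded in the model (`"full"` or `"minimal"`).
#' @return a [RuleModel]; its decision boundary is unset until
#'   calibrated (see [youdenBoundary()]).
#' @examples
#' cand <- data.frame(
#'     variableType = "ward", code = c("ICU", "ER", "OR"),
#'     oddsRatio = c(4, 2, 1.1), pValue = c(0, 0.01, 0.2),
#'     a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_
#' )
#' nRules(applyFilter(cand, pMax = 0.05))  # 2
#' @export
applyFilter <- function(candidates, pMax = 0.05, bonferroni = FALSE,
                        modelClass = c("full", "minimal")) {
    modelClass <- match.arg(modelClass)
    if (length(pMax) != 1L || is.na(pMax) || pMax < 0 || pMax > 1)
        stop("pMax must be a single value in [0, 1]", call. = FALSE)
    nTests <- nrow(candidates)
    if (pMax == 0) {
        keep <- candidates$pValue == 0
    } else {
        threshold <- if (bonferroni && nTests > 0L) pMax / nTests else pMax
        keep <- candidates$pValue < threshold
    }
    kept <- candidates[keep, , drop = FALSE]
    rownames(kept) <- NULL
    new("RuleModel",
        rules = kept, pMax = pMax, bonferroni = isTRUE(bonferroni),
        nTests = as.integer(nTests), modelClass = modelClass,
        decisionBoundary = NA_real_, transcribed = FALSE)
}

#' Mine and filter a rule model in one step
#'
#' @param x a labeled [CaseSet].
#' @param pMax,bonferroni filter settings, see [applyFilter()].
#' @param modelClass `"full"` or `"minimal"`.
#' @return a [RuleModel].
#' @examples
#' cfg <- mimicLikeConfig("small")
#' cases <- generatePopulation(cfg, seed = 1)
#' model <- mineRules(cases, pMax = 1e-4)
#' model
#' @export
mineRules <- function(x, pMax = 0.05, bonferroni = FALSE,
                      modelClass = c("full", "minimal")) {
    modelClass <- match.arg(modelClass)
    applyFilter(mineCandidates(x, modelClass), pMax = pMax,
                bonferroni = bonferroni, modelClass = modelClass)
}

#' RuleModel accessors
#'
#' @param x a [RuleModel].
#' @param value replacement decision boundary (positive number).
#' @return `rules` returns the rule data.frame; `nRules` its row count;
#'   the remaining accessors return the corresponding configuration
#'   fields.
#' @name RuleModel-accessors
#' @rdname RuleModel-accessors
#' @export
setMethod("rules", "RuleModel", function(x) x@rules)

#' @rdname RuleModel-accessors
#' @export
setMethod("nRules", "RuleModel", function(x) nrow(x@rules))

#' @rdname RuleModel-accessors
#' @export
setMethod("pMax", "RuleModel", function(x) x@pMax)

#' @rdname RuleModel-accessors
#' @export
setMethod("bonferroni", "RuleModel", function(x) x@bonferroni)

#' @rdname RuleModel-accessors
#' @export
setMethod("nTests", "RuleModel", function(x) x@nTests)

#' @rdname RuleModel-accessors
#' @export
setMethod("modelClass", "RuleModel", function(x) x@modelClass)

#' @rdname RuleModel-accessors
#' @export
setMethod("decisionBoundary", "RuleModel", function(x) x@decisionBoundary)

#' @rdname RuleModel-accessors
#' @export
setMethod("decisionBoundary<-", "RuleModel", function(x, value) {
    stopifnot(length(value) == 1L, is.na(value) || value > 0)
    x@decisionBoundary <- as.numeric(value)
    validObject(x)
    x
})

#' @export
#' @describeIn applyFilter compact display of a rule model.
#' @param object a `RuleModel`.
setMethod("show", "RuleModel", function(object) {
    cat("RuleModel (", object@modelClass, " class) with ", nRules(object),
        " rule(s)\n", sep = "")
    cat("  filter: pMax = ", format(object@pMax),
        if (object@bonferroni) " with Bonferroni correction" else "",
        " over ", object@nTests, " test(s)\n", sep = "")
    cat("  decision boundary: ",
        if (is.na(object@decisionBoundary)) "unset (calibrate first)"
        else format(object@decisionBoundary), "\n", sep = "")
    if (object@transcribed)
        cat("  transcribed from a published rule table (p-values are",
            "placeholders)\n")
    invisible(NULL)
})
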