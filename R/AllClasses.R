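#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' CaseSet: a collection of clinical cases as itemsets
#'
#' A `CaseSet` holds a collection of clinical cases, each reduced to the
#' *set* of categorical items (variable type + code) recorded during the
#' case, together with a binary in-hospital mortality outcome. Internally
#' the cases are a sparse item-by-case incidence matrix, which makes rule
#' mining a handful of sparse matrix operations.
#'
#' Slots:
#' \describe{
#'   \item{itemMatrix}{`dgCMatrix`, items in rows, cases in columns, entries
#'     0/1 (an item is either in a case's set or not).}
#'   \item{itemInfo}{data.frame with one row per item: `variableType`,
#'     `code`. Row order matches `itemMatrix` rows.}
#'   \item{outcome}{factor with levels `survived`, `died`; `NA` marks an
#'     unlabeled case (allowed for prediction input, rejected by mining).}
#'   \item{caseIds}{character vector of case identifiers.}
#' }
#'
#' @seealso [makeCaseSet()], [buildItemset()], [restrictToMinimal()]
#' @aliases CaseSet
#' @exportClass CaseSet
setClass("CaseSet",
    representation(
        itemMatrix = "dgCMatrix",
        itemInfo = "data.frame",
        outcome = "factor",
        caseIds = "character"
    )
)

setValidity("CaseSet", function(object) {
    msg <- character()
    m <- object@itemMatrix
    info <- object@itemInfo
    if (!all(c("variableType", "code") %in% colnames(info)))
        msg <- c(msg, "itemInfo must have columns variableType, code")
    if (nrow(info) != nrow(m))
        msg <- c(msg, "itemInfo rows must match itemMatrix rows")
    if (length(object@outcome) != ncol(m))
        msg <- c(msg, "outcome length must match the number of cases")
    if (length(object@caseIds) != ncol(m))
        msg <- c(msg, "caseIds length must match the number of cases")
    if (!identical(levels(object@outcome), c("survived", "died")))
        msg <- c(msg, "outcome levels must be exactly (survived, died)")
    if (length(m@x) > 0L && !all(m@x == 1))
        msg <- c(msg, "itemMatrix entries must be 0/1")
    if (length(msg) == 0L && nrow(info) > 0L) {
        bad <- setdiff(unique(info$variableType), variableTypes()$variableType)
        if (length(bad) > 0L)
            msg <- c(msg, paste0(
                "unknown variable type(s) in itemInfo: ",
                paste(bad, collapse = ", ")
            ))
        if (anyDuplicated(itemKey(info$variableType, info$code)))
            msg <- c(msg, "duplicate (variableType, code) items in itemInfo")
    }
    if (length(msg) == 0L) TRUE else msg
})

#' RuleModel: a filtered set of mortality association rules
#'
#' The result of mining and significance-filtering single-item rules
#' "item => in-hospital mortality". Each rule carries its odds ratio, the
#' two-sided p-value of the log-odds-ratio test, and the 2x2 contingency
#' counts it was computed from.
#'
#' Slots:
#' \describe{
#'   \item{rules}{data.frame with columns `variableType`, `code`,
#'     `oddsRatio`, `pValue`, `a`, `b`, `c`, `d` (counts may be `NA` for
#'     transcribed models whose source published only the odds ratios).}
#'   \item{pMax}{the configured significance threshold in \\[0, 1\\].}
#'   \item{bonferroni}{whether the threshold was Bonferroni-divided by the
#'     number of executed tests.}
#'   \item{nTests}{number of hypothesis tests executed (candidates that
#'     survived the zero-cell discard).}
#'   \item{modelClass}{`"minimal"` (admission-time demographics only) or
#'     `"full"` (all ten variable types).}
#'   \item{decisionBoundary}{the decision boundary delta on the mean-OR
#'     score; `NA` until calibrated.}
#'   \item{transcribed}{`TRUE` for models transcribed from published rule
#'     tables rather than mined from data (their p-values are placeholders).}
#' }
#'
#' @seealso [mineRules()], [applyFilter()], [classifyCases()]
#' @aliases RuleModel
#' @exportClass RuleModel
setClass("RuleModel",
    representation(
        rules = "data.frame",
        pMax = "numeric",
        bonferroni = "logical",
        nTests = "integer",
        modelClass = "character",
        decisionBoundary = "numeric",
        transcribed = "logical"
    ),
    prototype(
        pMax = 1, bonferroni = FALSE, nTests = 0L,
        modelClass = "full", decisionBoundary = NA_real_,
        transcribed = FALSE
    )
)

setValidity("RuleModel", function(object) {
    msg <- character()
    r <- object@rules
    needed <- c("variableType", "code", "oddsRatio", "pValue",
                "a", "b", "c", "d")
    if (!all(needed %in% colnames(r)))
        msg <- c(msg, paste0(
            "rules must have columns ", paste(needed, collapse = ", ")
        ))
    if (length(object@pMax) != 1L || is.na(object@pMax) ||
        object@pMax < 0 || object@pMax > 1)
        msg <- c(msg, "pMax must be a single value in [0, 1]")
    if (!object@modelClass %in% c("minimal", "full"))
        msg <- c(msg, "modelClass must be 'minimal' or 'full'")
    if (length(object@decisionBoundary) != 1L)
        msg <- c(msg, "decisionBoundary must be a single value (or NA)")
    if (length(msg) == 0L && nrow(r) > 0L) {
        if (any(!is.finite(r$oddsRatio)) || any(r$oddsRatio <= 0))
            msg <- c(msg, "rule odds ratios must be finite and > 0")
        if (any(r$pValue < 0 | r$pValue > 1))
            msg <- c(msg, "rule p-values must lie in [0, 1]")
        hasTab <- stats::complete.cases(r[, c("a", "b", "c", "d")])
        if (any(hasTab)) {
            orTab <- with(r[hasTab, , drop = FALSE], (a * d) / (b * c))
            if (any(abs(orTab - r$oddsRatio[hasTab]) >
                    1e-8 * pmax(1, r$oddsRatio[hasTab])))
                msg <- c(msg, "stored odds ratios must equal a*d/(b*c)")
        }
        if (object@modelClass == "minimal" &&
            !all(r$variableType %in% minimalVariableTypes()))
            msg <- c(msg, "minimal-class model contains non-minimal rules")
    }
    if (length(msg) == 0L) TRUE else msg
})

#' RocCurve: an empirical receiver operating characteristic
#'
#' Sensitivity and specificity at every distinct score threshold (the
#' classifier predicts the positive class when score >= threshold), the
#' area under the curve by the rank (Mann-Whitney) statistic with ties
#' counted half, and the Youden-optimal threshold.
#'
#' @seealso [rocCurve()], [youdenBoundary()]
#' @aliases RocCurve
#' @exportClass RocCurve
setClass("RocCurve",
    representation(
        thresholds = "numeric",
        sensitivity = "numeric",
        specificity = "numeric",
        auc = "numeric",
        youdenJ = "numeric",
        youdenThreshold = "numeric"
    )
)

setValidity("RocCurve", function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (length(object@sensitivity) != n || length(object@specificity) != n)
        msg <- c(msg, "sensitivity/specificity must match thresholds")
    if (any(object@sensitivity < -1e-12 | object@sensitivity > 1 + 1e-12))
        msg <- c(msg, "sensitivity out of [0, 1]")
    if (any(object@specificity < -1e-12 | object@specificity > 1 + 1e-12))
        msg <- c(msg, "specificity out of [0, 1]")
    if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must be a single value in [0, 1]")
    if (length(msg) == 0L) TRUE else msg
})

#' SyntheticConfig: specification of a synthetic EHR population
#'
#' Describes a population of clinical cases with a Bernoulli mortality
#' outcome and per-item planted odds ratios. Each variable has a prevalence
#' `q` among survivors and a planted odds ratio `rho`; the implied
#' prevalence among deaths is `p = rho*q / (1 - q + rho*q)`, so the
#' population odds ratio of every item equals its planted value exactly.
#' Variables with a non-`NA` `family` are mutually exclusive categories of
#' one demographic family (at most one category per case); clinical items
#' are sampled independently given the outcome.
#'
#' @seealso [syntheticConfig()], [generatePopulation()], [mimicLikeConfig()]
#' @aliases SyntheticConfig
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        nCases = "integer",
        baseMortality = "numeric",
        variables = "data.frame"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nCases < 1L)
        msg <- c(msg, "nCases must be >= 1")
    if (object@baseMortality <= 0 || object@baseMortality >= 1)
        msg <- c(msg, "baseMortality must lie in (0, 1)")
    v <- object@variables
    needed <- c("variableType", "code", "family", "prevalence", "oddsRatio")
    if (!all(needed %in% colnames(v))) {
        msg <- c(msg, paste0(
            "variables must have columns ", paste(needed, collapse = ", ")
        ))
        return(msg)
    }
    if (nrow(v) > 0L) {
        bad <- setdiff(unique(v$variableType), variableTypes()$variableType)
        if (length(bad) > 0L)
            msg <- c(msg, paste0("unknown variable type(s): ",
                                 paste(bad, collapse = ", ")))
        if (any(v$prevalence <= 0 | v$prevalence >= 1))
            msg <- c(msg, "survivor prevalences must lie in (0, 1)")
        if (any(!is.finite(v$oddsRatio) | v$oddsRatio <= 0))
            msg <- c(msg, "planted odds ratios must be finite and > 0")
        if (anyDuplicated(itemKey(v$variableType, v$code)))
            msg <- c(msg, "duplicate (variableType, code) items")
        if (length(msg) == 0L) {
            p <- deathPrevalence(v$prevalence, v$oddsRatio)
            if (any(p <= 0 | p >= 1))
                msg <- c(msg, "implied death-class prevalence outside (0, 1)")
            fam <- v$family[!is.na(v$family)]
            for (f in unique(fam)) {
                sel <- !is.na(v$family) & v$family == f
                if (sum(v$prevalence[sel]) > 1 + 1e-9)
                    msg <- c(msg, paste0(
                        "family '", f, "': survivor prevalences sum above 1"
                    ))
                if (sum(p[sel]) > 1 + 1e-9)
                    msg <- c(msg, paste0(
                        "family '", f,
                        "': implied death prevalences sum above 1"
                    ))
            }
        }
    }
    if (length(msg) == 0L) TRUE else msg
})
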