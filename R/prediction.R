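#' Rules of a model that apply to one case
#'
#' A rule applies to a case when its antecedent item is a member of the
#' case's itemset. The result is the per-case explanation a provider
#' would read: each applying rule, its odds ratio, and hence how the
#' case's risk score comes about.
#'
#' @param model a [RuleModel].
#' @param x a [CaseSet].
#' @param case case index or id within `x` (default: the first case).
#' @return the subset of `rules(model)` applying to the case, sorted by
#'   (variableType, code); zero rows when nothing applies.
#' @examples
#' model <- exampleRuleModel("minimal")
#' patient <- exampleCase()
#' applyingRules(model, patient)
#' @export
applyingRules <- function(model, x, case = 1L) {
    stopifnot(is(model, "RuleModel"), is(x, "CaseSet"))
    items <- caseItems(x, case)
    r <- rules(model)
    hit <- itemKey(r$variableType, r$code) %in%
        itemKey(items$variableType, items$code)
    out <- r[hit, , drop = FALSE]
    out <- out[order(out$variableType, out$code, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Mean-odds-ratio risk scores for a case collection
#'
#' Each case is scored by the arithmetic mean of the odds ratios of the
#' rules that apply to it. A case to which no rule applies receives the
#' neutral score 1 -- the no-association odds ratio -- which falls below
#' any decision boundary above 1 and therefore classifies as low risk.
#'
#' @param model a [RuleModel].
#' @param x a [CaseSet] (outcomes may be missing; only items are used).
#' @return named numeric vector of scores, one per case, with the number
#'   of applying rules per case in attribute `nApplying`.
#' @examples
#' model <- exampleRuleModel("full")
#' patient <- exampleCase()
#' scoreCases(model, patient)  # mean of the nine applying rule ORs
#' @export
scoreCases <- function(model, x) {
    stopifnot(is(model, "RuleModel"), is(x, "CaseSet"))
    r <- rules(model)
    idx <- match(itemKey(x@itemInfo$variableType, x@itemInfo$code),
                 itemKey(r$variableType, r$code))
    rows <- which(!is.na(idx))
    if (length(rows) == 0L || nCases(x) == 0L) {
        scores <- rep(1, nCases(x))
        nApply <- rep(0L, nCases(x))
    } else {
        m <- x@itemMatrix[rows, , drop = FALSE]
        or <- r$oddsRatio[idx[rows]]
        nApply <- as.integer(Matrix::colSums(m))
        total <- as.numeric(Matrix::crossprod(m, or))
        scores <- ifelse(nApply > 0L, total / pmax(nApply, 1L), 1)
    }
    names(scores) <- x@caseIds
    attr(scores, "nApplying") <- nApply
    scores
}

#' Classify cases against a decision boundary
#'
#' Labels a case high-risk when its mean-odds-ratio score is greater than
#' or equal to the decision boundary delta, low-risk otherwise (a score
#' exactly at the boundary is high-risk).
#'
#' @param model a [RuleModel].
#' @param x a [CaseSet].
#' @param boundary decision boundary delta (> 0); defaults to the model's
#'   calibrated boundary. With neither set, classification is refused:
#'   calibrate first (e.g. [youdenBoundary()] on a training ROC) or pass
#'   a boundary explicitly.
#' @return data.frame with one row per case: `caseId`, `score`,
#'   `nApplyingRules`, `label` (factor `low-risk`/`high-risk`).
#' @examples
#' model <- exampleRuleModel("minimal")  # boundary 1.015
#' classifyCases(model, exampleCase())   # score 0.636 -> low-risk
#' @export
classifyCases <- function(model, x, boundary = NULL) {
    stopifnot(is(model, "RuleModel"), is(x, "CaseSet"))
    if (is.null(boundary)) boundary <- decisionBoundary(model)
    if (length(boundary) != 1L || is.na(boundary)) {
        stop("no decision boundary: calibrate the model (see ",
             "youdenBoundary()) or pass `boundary` explicitly",
             call. = FALSE)
    }
    if (boundary <= 0) stop("boundary must be > 0", call. = FALSE)
    scores <- scoreCases(model, x)
    out <- data.frame(
        caseId = x@caseIds,
        score = as.numeric(scores),
        nApplyingRules = attr(scores, "nApplying"),
        label = factor(ifelse(scores >= boundary, "high-risk", "low-risk"),
                       levels = c("low-risk", "high-risk")),
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
}
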