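#' Random train/test split of a case collection
#'
#' Simple random (unstratified) partition into a training and a test set,
#' deterministic under a fixed seed. With a rare outcome and small
#' collections a split can leave one side without both outcome classes;
#' callers (e.g. [runGrid()]) flag such splits invalid rather than
#' silently dropping them.
#'
#' @param x a [CaseSet].
#' @param testFraction fraction of cases assigned to the test set,
#'   in (0, 1); default 0.1 (a 90/10 split).
#' @param seed integer seed for the split.
#' @return list with elements `train` and `test`, two disjoint
#'   [CaseSet]s that together exhaust `x`.
#' @export
splitCases <- function(x, testFraction = 0.1, seed = 1L) {
    stopifnot(is(x, "CaseSet"))
    if (testFraction <= 0 || testFraction >= 1)
        stop("testFraction must lie strictly between 0 and 1", call. = FALSE)
    n <- nCases(x)
    nTest <- round(n * testFraction)
    nTest <- max(1L, min(n - 1L, as.integer(nTest)))
    ## local RNG state: do not disturb the caller's stream
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    testIdx <- sample.int(n, nTest)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    list(train = x[setdiff(seq_len(n), testIdx)], test = x[sort(testIdx)])
}

#' Empirical ROC curve, AUC and Youden index
#'
#' Builds the receiver operating characteristic of a score vector against
#' binary outcomes, where a case is called positive (death-predicted) when
#' its score is at or above a threshold. The curve is evaluated at every
#' distinct score; the area under it is computed by the rank
#' (Mann-Whitney) statistic, counting ties as one half -- ties are common
#' here because scores are means over a small shared rule pool. The
#' Youden-optimal threshold (maximizing sensitivity + specificity - 1,
#' smallest threshold on ties) is recorded on the curve.
#'
#' @param scores numeric risk scores.
#' @param labels outcomes: a factor with levels survived/died, a logical
#'   (TRUE = died), or 0/1.
#' @return a [RocCurve].
#' @examples
#' roc <- rocCurve(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
#' auc(roc)             # 1: perfect separation
#' youdenBoundary(roc)  # 9: smallest separating threshold
#' @rdname rocCurve
#' @export
rocCurve <- function(scores, labels) {
    pos <- asDiedLogical(labels)
    if (length(scores) != length(pos))
        stop("scores and labels differ in length", call. = FALSE)
    if (anyNA(scores) || anyNA(pos))
        stop("scores and labels must not contain NA", call. = FALSE)
    P <- sum(pos)
    N <- sum(!pos)
    if (P == 0L || N == 0L)
        stop("ROC needs at least one case of each outcome class",
             call. = FALSE)
    ## curve at every distinct score threshold, descending
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- pos[o]
    last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each run
    tp <- cumsum(y)[last]
    fp <- cumsum(!y)[last]
    thresholds <- s[last]
    sens <- tp / P
    spec <- 1 - fp / N
    ## rank AUC, ties half
    r <- rank(scores)
    aucVal <- (sum(r[pos]) - P * (P + 1) / 2) / (as.numeric(P) * N)
    j <- sens + spec - 1
    best <- max(j)
    ## thresholds are descending; the last maximal one is the smallest
    bestIdx <- max(which(j >= best - 1e-12))
    new("RocCurve",
        thresholds = thresholds, sensitivity = sens, specificity = spec,
        auc = aucVal, youdenJ = j[bestIdx], youdenThreshold =
            thresholds[bestIdx])
}

## internal: normalize outcome encodings to TRUE = died
asDiedLogical <- function(labels) {
    if (is.factor(labels)) return(labels == "died")
    if (is.logical(labels)) return(labels)
    if (is.numeric(labels)) return(labels != 0)
    if (is.character(labels)) return(parseOutcome(labels) == "died")
    stop("cannot interpret outcome labels", call. = FALSE)
}

#' @rdname rocCurve
#' @param x a `RocCurve`.
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' Youden-optimal decision boundary
#'
#' Returns the score threshold maximizing the Youden index
#' J = sensitivity + specificity - 1; among ties the smallest such
#' threshold is returned. Computed on a training-split ROC, this is the
#' calibration step that sets a model's decision boundary.
#'
#' @param x a [RocCurve].
#' @return the optimal threshold (a score value).
#' @rdname youdenBoundary
#' @export
setMethod("youdenBoundary", "RocCurve", function(x) x@youdenThreshold)

#' @export
#' @describeIn rocCurve compact display.
#' @param object a `RocCurve`.
setMethod("show", "RocCurve", function(object) {
    cat("RocCurve over ", length(object@thresholds),
        " threshold(s)\n", sep = "")
    cat("  AUC = ", format(object@auc, digits = 4),
        ", Youden J = ", format(object@youdenJ, digits = 4),
        " at threshold ", format(object@youdenThreshold, digits = 4),
        "\n", sep = "")
    invisible(NULL)
})

#' Accuracy, sensitivity and specificity at a decision boundary
#'
#' High-risk (score >= boundary) counts as the positive, death-predicting
#' class: sensitivity is the fraction of deaths flagged high-risk,
#' specificity the fraction of survivors cleared as low-risk, accuracy
#' the overall fraction classified correctly.
#'
#' @param scores numeric risk scores.
#' @param labels outcomes (factor survived/died, logical, or 0/1).
#' @param boundary decision boundary delta (> 0).
#' @return named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
confusionMetrics <- function(scores, labels, boundary) {
    stopifnot(length(boundary) == 1L, boundary > 0)
    pos <- asDiedLogical(labels)
    pred <- scores >= boundary
    c(accuracy = mean(pred == pos),
      sensitivity = mean(pred[pos]),
      specificity = mean(!pred[!pos]))
}

#' The default significance-threshold grid
#'
#' Thresholds `10^-n` for n = 0..10, the conventional 0.05, and the
#' strict 0 (keep only underflowed p-values): 13 values, each crossed
#' with Bonferroni on/off for 26 configurations.
#'
#' @return increasing numeric vector of 13 thresholds.
#' @export
defaultPMaxGrid <- function() {
    sort(unique(c(0, 10^-(10:0), 0.05)))
}

#' Run the repeated-split evaluation grid
#'
#' The full experimental protocol: for each repetition the collection is
#' randomly split into training and test sets; for each (pMax,
#' Bonferroni) configuration a model is mined and filtered on the
#' training split, both splits are scored, AUCs are recorded, the
#' decision boundary is calibrated by the Youden index on the training
#' ROC, and confusion metrics are taken on the test split. Splits whose
#' training or test side lacks one outcome class are reported as invalid
#' cells, not dropped.
#'
#' @param x a labeled [CaseSet].
#' @param pMaxValues significance thresholds; default [defaultPMaxGrid()].
#' @param bonferroniOptions logical vector of correction settings.
#' @param repetitions number of independent splits per configuration.
#' @param modelClass `"full"` or `"minimal"`.
#' @param testFraction test-set fraction per split.
#' @param seed base seed; repetition k splits with seed `seed + k - 1`.
#' @return data.frame with one row per cell: `pMax`, `bonferroni`,
#'   `repetition`, `splitSeed`, `valid`, `nRules`, `aucTrain`, `aucTest`,
#'   `meanApplyingTest`, `boundary`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @seealso [aggregateGrid()]
#' @export
runGrid <- function(x, pMaxValues = defaultPMaxGrid(),
                    bonferroniOptions = c(FALSE, TRUE),
                    repetitions = 10L,
                    modelClass = c("full", "minimal"),
                    testFraction = 0.1, seed = 1L) {
    stopifnot(is(x, "CaseSet"), repetitions >= 1L)
    modelClass <- match.arg(modelClass)
    cells <- vector("list", length(pMaxValues) * length(bonferroniOptions) *
                        repetitions)
    k <- 0L
    for (rep in seq_len(repetitions)) {
        splitSeed <- as.integer(seed) + rep - 1L
        sp <- splitCases(x, testFraction = testFraction, seed = splitSeed)
        trainOut <- sp$train@outcome
        testOut <- sp$test@outcome
        valid <- !anyNA(trainOut) && !anyNA(testOut) &&
            all(c("survived", "died") %in% trainOut) &&
            all(c("survived", "died") %in% testOut)
        cand <- if (valid) mineCandidates(sp$train, modelClass) else NULL
        for (bf in bonferroniOptions) {
            for (pm in pMaxValues) {
                k <- k + 1L
                row <- data.frame(
                    pMax = pm, bonferroni = bf, repetition = rep,
                    splitSeed = splitSeed, valid = valid,
                    nRules = NA_integer_, aucTrain = NA_real_,
                    aucTest = NA_real_, meanApplyingTest = NA_real_,
                    boundary = NA_real_, accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_
                )
                if (valid) {
                    model <- applyFilter(cand, pMax = pm, bonferroni = bf,
                                         modelClass = modelClass)
                    sTrain <- scoreCases(model, sp$train)
                    sTest <- scoreCases(model, sp$test)
                    rocTrain <- rocCurve(sTrain, trainOut)
                    rocTest <- rocCurve(sTest, testOut)
                    delta <- youdenBoundary(rocTrain)
                    cm <- confusionMetrics(sTest, testOut, delta)
                    row$nRules <- nRules(model)
                    row$aucTrain <- auc(rocTrain)
                    row$aucTest <- auc(rocTest)
                    row$meanApplyingTest <- mean(attr(sTest, "nApplying"))
                    row$boundary <- delta
                    row$accuracy <- cm[["accuracy"]]
                    row$sensitivity <- cm[["sensitivity"]]
                    row$specificity <- cm[["specificity"]]
                }
                cells[[k]] <- row
            }
        }
    }
    out <- do.call(rbind, cells)
    rownames(out) <- NULL
    out
}

#' Aggregate grid cells across repetitions
#'
#' Mean and standard deviation of the per-cell metrics for each
#' (pMax, Bonferroni) configuration, over its valid repetitions.
#'
#' @param cells data.frame from [runGrid()].
#' @return data.frame with one row per configuration.
#' @export
aggregateGrid <- function(cells) {
    key <- interaction(cells$pMax, cells$bonferroni, drop = TRUE)
    rows <- lapply(split(cells, key), function(g) {
        v <- g[g$valid, , drop = FALSE]
        data.frame(
            pMax = g$pMax[1], bonferroni = g$bonferroni[1],
            nRepetitions = nrow(g), nValid = nrow(v),
            meanAucTrain = mean(v$aucTrain), sdAucTrain = stats::sd(v$aucTrain),
            meanAucTest = mean(v$aucTest), sdAucTest = stats::sd(v$aucTest),
            meanNRules = mean(v$nRules), sdNRules = stats::sd(v$nRules),
            meanApplyingTest = mean(v$meanApplyingTest)
        )
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$bonferroni, out$pMax), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize a rule model
#'
#' Per-variable-type rule counts, the split into negative (OR < 1) and
#' positive (OR > 1) associations, and the extreme rules at both ends of
#' the odds-ratio range -- the ingredients of a rule-set review.
#'
#' @param x a [RuleModel].
#' @param k how many top/bottom rules to list.
#' @return list with elements `nRules`, `countsByType` (named integer
#'   vector over all ten variable types), `nNegative`, `nPositive`,
#'   `topRules`, `bottomRules`.
#' @rdname summarizeRules
#' @export
setMethod("summarizeRules", "RuleModel", function(x, k = 5L) {
    r <- rules(x)
    types <- variableTypes()$variableType
    counts <- stats::setNames(integer(length(types)), types)
    if (nrow(r) > 0L) {
        tt <- table(factor(r$variableType, levels = types))
        counts[names(tt)] <- as.integer(tt)
    }
    ord <- order(r$oddsRatio, decreasing = TRUE)
    list(
        nRules = nrow(r),
        countsByType = counts,
        nNegative = sum(r$oddsRatio < 1),
        nPositive = sum(r$oddsRatio > 1),
        topRules = utils::head(r[ord, , drop = FALSE], k),
        bottomRules = utils::head(r[rev(ord), , drop = FALSE], k)
    )
})

#' Odds-ratio range of rules matching a code pattern
#'
#' Groups rules by a substring (fixed, case-insensitive) match on their
#' codes -- e.g. all sepsis diagnoses, or all heparin prescriptions --
#' and reports how many match and the span of their odds ratios.
#'
#' @param model a [RuleModel].
#' @param pattern substring to match against rule codes.
#' @return list with `n`, `minOR`, `maxOR`, and the matching `rules`.
#' @export
ruleGroupRange <- function(model, pattern) {
    r <- rules(model)
    hit <- grepl(pattern, r$code, fixed = TRUE, ignore.case = FALSE) |
        grepl(tolower(pattern), tolower(r$code), fixed = TRUE)
    sub <- r[hit, , drop = FALSE]
    rownames(sub) <- NULL
    list(
        n = nrow(sub),
        minOR = if (nrow(sub) > 0L) min(sub$oddsRatio) else NA_real_,
        maxOR = if (nrow(sub) > 0L) max(sub$oddsRatio) else NA_real_,
        rules = sub
    )
}
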