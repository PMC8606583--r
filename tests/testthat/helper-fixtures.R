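## Shared builders for tiny in-code fixtures.

## A small labeled case collection, built from explicit long-format events.
tinyCases <- function() {
    makeCaseSet(data.frame(
        case_id = c("c1", "c1", "c1", "c2", "c2", "c3", "c4", "c4"),
        variable_type = c("diagnosis", "ward", "gender",
                          "diagnosis", "gender",
                          "gender",
                          "ward", "gender"),
        code = c("A419", "ICU", "Male",
                 "A419", "Male",
                 "Female",
                 "ICU", "Female"),
        outcome = c("died", "died", "died",
                    "survived", "survived",
                    "survived",
                    "survived", "survived"),
        stringsAsFactors = FALSE
    ))
}

## A random labeled population with independent items; used for
## brute-force recount oracles. Returns the CaseSet.
randomPopulation <- function(nCases = 200, nItems = 12, seed = 1,
                             mortality = 0.3) {
    set.seed(seed)
    types <- variableTypes()$variableType
    itemType <- sample(types, nItems, replace = TRUE)
    itemCode <- sprintf("code_%02d", seq_len(nItems))
    rows <- list()
    for (k in seq_len(nCases)) {
        present <- which(runif(nItems) < 0.25)
        outcome <- if (runif(1) < mortality) "died" else "survived"
        if (length(present) == 0L) {
            rows[[k]] <- data.frame(
                case_id = sprintf("r%03d", k), variable_type = "",
                code = "", outcome = outcome, stringsAsFactors = FALSE)
        } else {
            rows[[k]] <- data.frame(
                case_id = sprintf("r%03d", k),
                variable_type = itemType[present],
                code = itemCode[present],
                outcome = outcome, stringsAsFactors = FALSE)
        }
    }
    makeCaseSet(do.call(rbind, rows))
}

## Independent all-pairs AUC oracle: P(score_pos > score_neg) + ties/2.
bruteForceAuc <- function(scores, died) {
    ps <- scores[died]
    ns <- scores[!died]
    total <- 0
    for (p in ps) {
        total <- total + sum(p > ns) + 0.5 * sum(p == ns)
    }
    total / (length(ps) * length(ns))
}

## Exhaustive Youden sweep oracle over all candidate thresholds
## (prediction rule: positive iff score >= threshold).
bruteForceYouden <- function(scores, died) {
    cand <- sort(unique(scores))
    best <- -Inf
    bestT <- NA_real_
    for (t in cand) {
        pred <- scores >= t
        j <- mean(pred[died]) + mean(!pred[!died]) - 1
        if (j > best + 1e-12) {
            best <- j
            bestT <- t
        }
    }
    list(J = best, threshold = bestT)
}
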