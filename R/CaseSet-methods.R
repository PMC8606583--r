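#' Build a CaseSet from long-format case events
#'
#' Transforms a long-format event table (one row per recorded variable
#' occurrence) into a [CaseSet]: repeated occurrences of the same
#' (variable type, code) pair within one case collapse to a single item,
#' so each case becomes a deduplicated itemset. Row order is irrelevant.
#' Codes are matched as exact strings -- no trimming or normalization --
#' because near-duplicate codes (differing, say, by a stray space) are a
#' real feature of clinical data that the mined rules should surface,
#' not hide.
#'
#' Rows whose `code` (or `variable_type`) is empty or `NA` contribute no
#' item but still register the case and its outcome; this is how a case
#' with an empty itemset is represented in long format (no case is ever
#' excluded for having few or no items).
#'
#' @param events data.frame with columns `case_id`, `variable_type`,
#'   `code` and `outcome` (accepted codings: died/survived or 1/0; empty or
#'   `NA` leaves a case unlabeled, which is valid for prediction input only).
#' @return a [CaseSet].
#' @examples
#' ev <- data.frame(
#'     case_id = c("p1", "p1", "p1", "p2"),
#'     variable_type = c("diagnosis", "diagnosis", "ward", "gender"),
#'     code = c("A419", "A419", "ICU", "Female"),
#'     outcome = c("died", "died", "died", "survived")
#' )
#' cs <- makeCaseSet(ev)
#' nCases(cs)   # 2
#' nItems(cs)   # 3 (the duplicated diagnosis collapses)
#' @export
makeCaseSet <- function(events) {
    needed <- c("case_id", "variable_type", "code", "outcome")
    missing <- setdiff(needed, colnames(events))
    if (length(missing) > 0L) {
        stop("events is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    caseId <- as.character(events$case_id)
    vtype <- as.character(events$variable_type)
    code <- as.character(events$code)
    hasItem <- !is.na(vtype) & vtype != "" & !is.na(code) & code != ""
    checkVariableTypes(vtype[hasItem])

    ids <- unique(caseId)
    outMap <- parseOutcome(events$outcome)
    outcome <- factor(rep(NA_character_, length(ids)),
                      levels = c("survived", "died"))
    labeled <- !is.na(outMap)
    if (any(labeled)) {
        byCase <- split(as.character(outMap[labeled]), caseId[labeled])
        conflict <- vapply(byCase, function(v) length(unique(v)) > 1L,
                           logical(1))
        if (any(conflict)) {
            stop("conflicting outcomes for case(s): ",
                 paste(names(byCase)[conflict], collapse = ", "),
                 call. = FALSE)
        }
        lab <- vapply(byCase, `[`, character(1), 1L)
        outcome[match(names(byCase), ids)] <- lab
    }

    key <- itemKey(vtype[hasItem], code[hasItem])
    ukeys <- sort(unique(key))
    info <- data.frame(
        variableType = vtype[hasItem][match(ukeys, key)],
        code = code[hasItem][match(ukeys, key)],
        stringsAsFactors = FALSE
    )
    ## sort items by (type, code) for deterministic reporting
    ord <- order(info$variableType, info$code, method = "radix")
    info <- info[ord, , drop = FALSE]
    rownames(info) <- NULL
    ukeys <- itemKey(info$variableType, info$code)

    i <- match(key, ukeys)
    j <- match(caseId[hasItem], ids)
    dup <- duplicated(cbind(i, j))
    m <- Matrix::sparseMatrix(
        i = i[!dup], j = j[!dup], x = 1,
        dims = c(nrow(info), length(ids))
    )
    new("CaseSet", itemMatrix = methods::as(m, "CsparseMatrix"),
        itemInfo = info, outcome = outcome, caseIds = ids)
}

#' Build the itemset of a single case
#'
#' Convenience constructor for one clinical case: deduplicates the event
#' sequence into an itemset and attaches the outcome. The result is a
#' one-case [CaseSet], so everything that operates on case collections
#' (scoring, rule lookup) applies directly.
#'
#' @param events data.frame (or two-column matrix) of
#'   `variable_type`, `code` pairs; duplicates and arbitrary order allowed.
#' @param outcome `"died"`, `"survived"` (or 1/0); `NA` for an unlabeled
#'   case awaiting prediction.
#' @param caseId identifier for the case.
#' @return a [CaseSet] with one case.
#' @examples
#' p <- buildItemset(
#'     data.frame(variable_type = c("diagnosis", "diagnosis", "ward"),
#'                code = c("A419", "A419", "ICU")),
#'     outcome = "died", caseId = "p1"
#' )
#' nItems(p)  # 2
#' @export
buildItemset <- function(events, outcome = NA, caseId = "case") {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    if (ncol(events) >= 2L &&
        !all(c("variable_type", "code") %in% colnames(events))) {
        colnames(events)[1:2] <- c("variable_type", "code")
    }
    if (nrow(events) == 0L) {
        events <- data.frame(variable_type = "", code = "",
                             stringsAsFactors = FALSE)
    }
    events$case_id <- caseId
    events$outcome <- if (is.na(outcome)) NA_character_ else
        as.character(outcome)
    makeCaseSet(events)
}

#' @describeIn makeCaseSet number of cases in the set.
#' @param x a `CaseSet`.
#' @name CaseSet-accessors
#' @aliases nCases nItems caseIds outcomes itemInfo caseItems
NULL

#' CaseSet accessors
#'
#' @param x a [CaseSet].
#' @param case a case index or case id (for `caseItems`).
#' @return `nCases`/`nItems` return counts; `caseIds` the id vector;
#'   `outcomes` the outcome factor (levels survived/died, `NA` =
#'   unlabeled); `itemInfo` the item table; `caseItems` the items present
#'   in one case, ordered by (variableType, code).
#' @rdname CaseSet-accessors
#' @export
setMethod("nCases", "CaseSet", function(x) ncol(x@itemMatrix))

#' @rdname CaseSet-accessors
#' @export
setMethod("nItems", "CaseSet", function(x) nrow(x@itemMatrix))

#' @rdname CaseSet-accessors
#' @export
setMethod("caseIds", "CaseSet", function(x) x@caseIds)

#' @rdname CaseSet-accessors
#' @export
setMethod("outcomes", "CaseSet", function(x) {
    stats::setNames(x@outcome, x@caseIds)
})

#' @rdname CaseSet-accessors
#' @export
setMethod("itemInfo", "CaseSet", function(x) x@itemInfo)

#' @rdname CaseSet-accessors
#' @export
setMethod("caseItems", "CaseSet", function(x, case) {
    j <- resolveCase(x, case)
    present <- x@itemMatrix[, j] > 0
    out <- x@itemInfo[present, , drop = FALSE]
    rownames(out) <- NULL
    out
})

## internal: case index from id or position
resolveCase <- function(x, case) {
    if (is.character(case)) {
        j <- match(case, x@caseIds)
        if (is.na(j)) stop("unknown case id: ", case, call. = FALSE)
        return(j)
    }
    j <- as.integer(case)
    if (j < 1L || j > nCases(x)) stop("case index out of range", call. = FALSE)
    j
}

#' Restrict cases to admission-time demographic items
#'
#' Returns a copy of the case set keeping only items whose variable type
#' belongs to the minimal class (ethnicity, gender, insurance type,
#' language, marital status) -- the information a patient can report at
#' admission, before any clinical workup. Outcomes and case membership
#' are unchanged; cases whose items were all clinical end up with empty
#' itemsets but are retained.
#'
#' @param x a [CaseSet].
#' @return a [CaseSet] over the minimal item universe.
#' @examples
#' cs <- makeCaseSet(data.frame(
#'     case_id = "p1",
#'     variable_type = c("gender", "diagnosis"),
#'     code = c("Female", "A419"),
#'     outcome = "survived"
#' ))
#' nItems(restrictToMinimal(cs))  # 1
#' @rdname restrictToMinimal
#' @export
setMethod("restrictToMinimal", "CaseSet", function(x) {
    keep <- x@itemInfo$variableType %in% minimalVariableTypes()
    info <- x@itemInfo[keep, , drop = FALSE]
    rownames(info) <- NULL
    new("CaseSet",
        itemMatrix = x@itemMatrix[keep, , drop = FALSE],
        itemInfo = info, outcome = x@outcome, caseIds = x@caseIds)
})

#' Subset a CaseSet by cases
#'
#' `x[i]` keeps the selected cases; the item universe is left intact so
#' models mined on one subset can score another.
#'
#' @param x a [CaseSet].
#' @param i case indices, ids, or a logical mask.
#' @param j,...,drop ignored.
#' @return a [CaseSet].
#' @export
setMethod("[", "CaseSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@caseIds)
    new("CaseSet",
        itemMatrix = x@itemMatrix[, i, drop = FALSE],
        itemInfo = x@itemInfo,
        outcome = x@outcome[i],
        caseIds = x@caseIds[i])
})

#' @export
#' @describeIn makeCaseSet compact display of a case collection.
#' @param object a `CaseSet`.
setMethod("show", "CaseSet", function(object) {
    n <- nCases(object)
    died <- sum(object@outcome == "died", na.rm = TRUE)
    unlabeled <- sum(is.na(object@outcome))
    cat("CaseSet with ", n, " case(s), ", nItems(object),
        " distinct item(s)\n", sep = "")
    cat("  outcomes: ", died, " died, ",
        sum(object@outcome == "survived", na.rm = TRUE), " survived",
        if (unlabeled > 0L) paste0(", ", unlabeled, " unlabeled") else "",
        "\n", sep = "")
    tt <- table(object@itemInfo$variableType)
    if (length(tt) > 0L) {
        cat("  item types: ",
            paste(names(tt), tt, sep = ":", collapse = " "), "\n", sep = "")
    }
    invisible(NULL)
})
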