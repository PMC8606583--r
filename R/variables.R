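#' The categorical variable universe
#'
#' Ten categorical variable types describe a clinical case. Five of them --
#' ethnicity, gender, insurance type, language, and marital status -- are
#' patient-reportable demographics available at admission and form the
#' "minimal" class; the other five (diagnoses, prescriptions, procedures,
#' services, wards) accumulate during the stay and complete the "full" class.
#'
#' @return `variableTypes()` returns a data.frame with columns
#'   `variableType` and `minimalClass`; `minimalVariableTypes()` the character
#'   vector of the five admission-time types.
#' @examples
#' variableTypes()
#' minimalVariableTypes()
#' @export
variableTypes <- function() {
    data.frame(
        variableType = c(
            "diagnosis", "ethnicity", "gender", "insurance_type",
            "language", "marital_status", "prescription", "procedure",
            "service", "ward"
        ),
        minimalClass = c(
            FALSE, TRUE, TRUE, TRUE,
            TRUE, TRUE, FALSE, FALSE,
            FALSE, FALSE
        ),
        stringsAsFactors = FALSE
    )
}

#' @rdname variableTypes
#' @export
minimalVariableTypes <- function() {
    vt <- variableTypes()
    vt$variableType[vt$minimalClass]
}

## internal: validate a vector of variable type names
checkVariableTypes <- function(x) {
    bad <- setdiff(unique(as.character(x)), variableTypes()$variableType)
    if (length(bad) > 0L) {
        stop(
            "unknown variable type(s): ", paste(sQuote(bad), collapse = ", "),
            "; known types are: ",
            paste(variableTypes()$variableType, collapse = ", "),
            call. = FALSE
        )
    }
    invisible(TRUE)
}

## internal: identity key of an item. Items are exact (type, code) string
## pairs -- no trimming, no case folding: near-duplicate codes that differ
## only in whitespace are deliberately distinct items.
itemKey <- function(variableType, code) {
    paste(variableType, code, sep = "\x1f")
}

## internal: map outcome codings (died/survived, 1/0) to a factor with
## levels survived/died; NA marks an unlabeled (prediction-only) case.
parseOutcome <- function(x) {
    x <- as.character(x)
    out <- rep(NA_character_, length(x))
    x_low <- tolower(trimws(x))
    out[x_low %in% c("died", "1", "true", "dead")] <- "died"
    out[x_low %in% c("survived", "0", "false")] <- "survived"
    unknown <- !is.na(x) & !(x_low %in% c(
        "died", "1", "true", "dead",
        "survived", "0", "false", "", "na", "unknown"
    ))
    if (any(unknown)) {
        stop(
            "unrecognized outcome value(s): ",
            paste(sQuote(unique(x[unknown])), collapse = ", "),
            "; expected died/survived (or 1/0)",
            call. = FALSE
        )
    }
    factor(out, levels = c("survived", "died"))
}
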