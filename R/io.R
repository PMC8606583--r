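## Delimited and JSON input/output. TSV is the default delimiter because
## clinical codes and drug names frequently contain commas. Lines whose
## first character is '#' are provenance/comment lines and are skipped on
## input (only leading '#' counts: codes may legitimately contain '#').

readDelimited <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- !startsWith(lines, "#")
    lines <- lines[keep]
    if (length(lines) == 0L)
        stop("no data lines in ", path, call. = FALSE)
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
    df <- tryCatch(
        utils::read.table(
            text = lines, sep = sep, header = TRUE, quote = "\"",
            colClasses = "character", check.names = FALSE,
            comment.char = "", na.strings = character()
        ),
        error = function(e) {
            stop("failed to parse ", path, ": ", conditionMessage(e),
                 call. = FALSE)
        }
    )
    df
}

#' Read cases from a long-format delimited file
#'
#' Expects a tab- or comma-separated file with a header and columns
#' `case_id`, `variable_type`, `code`, `outcome` (died/survived, 1/0, or
#' empty for an unlabeled case). Lines starting with `#` are provenance
#' comments and are skipped. Rows with an empty `code` register the case
#' without contributing an item (how an empty itemset travels in long
#' format).
#'
#' @param path file path.
#' @return a [CaseSet].
#' @seealso [writeCases()], [makeCaseSet()]
#' @export
readCases <- function(path) {
    df <- readDelimited(path)
    needed <- c("case_id", "variable_type", "code", "outcome")
    missing <- setdiff(needed, colnames(df))
    if (length(missing) > 0L) {
        stop(path, " is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    makeCaseSet(df)
}

#' Write cases to a long-format delimited file
#'
#' One row per (case, item); cases with empty itemsets get a single row
#' with empty `variable_type`/`code` so no case is lost in the round
#' trip. Output is UTF-8 TSV. Optional provenance lines (prefixed `#`)
#' are written before the header.
#'
#' @param x a [CaseSet].
#' @param path output path.
#' @param provenance optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
writeCases <- function(x, path, provenance = NULL) {
    stopifnot(is(x, "CaseSet"))
    m <- x@itemMatrix
    sm <- methods::as(m, "TsparseMatrix")
    i <- sm@i + 1L
    j <- sm@j + 1L
    out <- rep(NA_character_, nCases(x))
    out[!is.na(x@outcome)] <- as.character(x@outcome[!is.na(x@outcome)])
    df <- data.frame(
        case_id = x@caseIds[j],
        variable_type = x@itemInfo$variableType[i],
        code = x@itemInfo$code[i],
        outcome = out[j],
        stringsAsFactors = FALSE
    )
    emptyCases <- setdiff(seq_len(nCases(x)), unique(j))
    if (length(emptyCases) > 0L) {
        df <- rbind(df, data.frame(
            case_id = x@caseIds[emptyCases], variable_type = "",
            code = "", outcome = out[emptyCases],
            stringsAsFactors = FALSE
        ))
    }
    df <- df[order(match(df$case_id, x@caseIds)), , drop = FALSE]
    df$outcome[is.na(df$outcome)] <- ""
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read and write cases as itemset JSON
#'
#' The JSON itemset form is an array of objects
#' `{case_id, outcome, items: [{variable_type, code}, ...]}`; `outcome`
#' is `"died"`, `"survived"` or `null` (unlabeled). Empty itemsets are
#' empty arrays, so the form round-trips every case.
#'
#' @param path file path.
#' @param x a [CaseSet].
#' @return `readCasesJson` returns a [CaseSet]; `writeCasesJson` returns
#'   `path` invisibly.
#' @export
readCasesJson <- function(path) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(raw$case_id))
        stop(path, ": expected an array of {case_id, outcome, items}",
             call. = FALSE)
    rows <- lapply(seq_along(raw$case_id), function(k) {
        items <- raw$items[[k]]
        if (is.null(items) || length(items) == 0L || nrow(items) == 0L) {
            data.frame(case_id = raw$case_id[k], variable_type = "",
                       code = "", outcome = naToEmpty(raw$outcome[k]),
                       stringsAsFactors = FALSE)
        } else {
            data.frame(case_id = raw$case_id[k],
                       variable_type = items$variable_type,
                       code = items$code,
                       outcome = naToEmpty(raw$outcome[k]),
                       stringsAsFactors = FALSE)
        }
    })
    makeCaseSet(do.call(rbind, rows))
}

naToEmpty <- function(x) if (is.null(x) || is.na(x)) "" else as.character(x)

#' @rdname readCasesJson
#' @export
writeCasesJson <- function(x, path) {
    stopifnot(is(x, "CaseSet"))
    out <- rep(NA_character_, nCases(x))
    out[!is.na(x@outcome)] <- as.character(x@outcome[!is.na(x@outcome)])
    objs <- lapply(seq_len(nCases(x)), function(k) {
        items <- caseItems(x, k)
        list(
            case_id = x@caseIds[k],
            outcome = out[k],
            items = if (nrow(items) == 0L) list() else
                data.frame(variable_type = items$variableType,
                           code = items$code, stringsAsFactors = FALSE)
        )
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' Serialize a rule model to JSON
#'
#' Canonical JSON form: configuration fields (`model_class`, `p_max`,
#' `bonferroni`, `n_tests`, `decision_boundary`, `transcribed`) plus the
#' rule array `{variable_type, code, or, p_value, a, b, c, d}` (counts
#' are `null` for transcribed models). The representation is canonical --
#' fixed key order, full-precision numbers -- so write/read/write is
#' byte-identical.
#'
#' @param model a [RuleModel].
#' @param path output path.
#' @param x for `readRuleModel`: input path.
#' @return `writeRuleModel` returns `path` invisibly; `readRuleModel` a
#'   [RuleModel].
#' @export
writeRuleModel <- function(model, path) {
    stopifnot(is(model, "RuleModel"))
    r <- rules(model)
    ruleArr <- if (nrow(r) == 0L) list() else data.frame(
        variable_type = r$variableType,
        code = r$code,
        or = r$oddsRatio,
        p_value = r$pValue,
        a = r$a, b = r$b, c = r$c, d = r$d,
        stringsAsFactors = FALSE
    )
    obj <- list(
        tool = "oddsrules",
        format = "rule-model/1",
        model_class = modelClass(model),
        p_max = pMax(model),
        bonferroni = bonferroni(model),
        n_tests = nTests(model),
        decision_boundary = decisionBoundary(model),
        transcribed = model@transcribed,
        rules = ruleArr
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeRuleModel
#' @export
readRuleModel <- function(x) {
    obj <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
    needed <- c("model_class", "p_max", "bonferroni", "n_tests", "rules")
    missing <- setdiff(needed, names(obj))
    if (length(missing) > 0L) {
        stop(x, " is not a rule-model file; missing field(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    r <- obj$rules
    if (is.null(r) || length(r) == 0L || NROW(r) == 0L) {
        r <- emptyRuleFrame()
    } else {
        r <- data.frame(
            variableType = r$variable_type, code = r$code,
            oddsRatio = r$or, pValue = r$p_value,
            a = asIntNA(r$a), b = asIntNA(r$b),
            c = asIntNA(r$c), d = asIntNA(r$d),
            stringsAsFactors = FALSE
        )
    }
    boundary <- obj$decision_boundary
    if (is.null(boundary)) boundary <- NA_real_
    new("RuleModel",
        rules = r,
        pMax = as.numeric(obj$p_max),
        bonferroni = isTRUE(obj$bonferroni),
        nTests = as.integer(obj$n_tests),
        modelClass = obj$model_class,
        decisionBoundary = as.numeric(boundary),
        transcribed = isTRUE(obj$transcribed))
}

asIntNA <- function(x) {
    if (is.null(x)) return(NA_integer_)
    suppressWarnings(as.integer(x))
}

#' Export a rule table as CSV
#'
#' Flat, human-reviewable rule table: variable type, code, odds ratio,
#' p-value and contingency counts, one rule per row.
#'
#' @param model a [RuleModel].
#' @param path output path.
#' @param provenance optional character vector of `#`-prefixed header
#'   lines.
#' @return `path`, invisibly.
#' @export
exportRulesCsv <- function(model, path, provenance = NULL) {
    stopifnot(is(model, "RuleModel"))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", provenance), con)
    utils::write.csv(rules(model), con, row.names = FALSE)
    invisible(path)
}

#' Read and write a synthetic configuration as JSON
#'
#' Schema (`synthetic-config/1`): `n_cases`, `base_mortality`, and a
#' `variables` array of `{variable_type, code, family, prevalence,
#' odds_ratio}` with `family` `null` for independent clinical items.
#'
#' @param path file path.
#' @param config a [SyntheticConfig].
#' @return `readSyntheticConfig` returns a [SyntheticConfig];
#'   `writeSyntheticConfig` returns `path` invisibly.
#' @export
readSyntheticConfig <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    needed <- c("n_cases", "base_mortality", "variables")
    missing <- setdiff(needed, names(obj))
    if (length(missing) > 0L) {
        stop(path, " is not a synthetic-config file; missing field(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    v <- obj$variables
    syntheticConfig(
        nCases = obj$n_cases,
        baseMortality = obj$base_mortality,
        variables = data.frame(
            variableType = v$variable_type, code = v$code,
            family = if (is.null(v$family)) NA_character_ else v$family,
            prevalence = v$prevalence, oddsRatio = v$odds_ratio,
            stringsAsFactors = FALSE
        )
    )
}

#' @rdname readSyntheticConfig
#' @export
writeSyntheticConfig <- function(config, path) {
    stopifnot(is(config, "SyntheticConfig"))
    v <- config@variables
    obj <- list(
        tool = "oddsrules",
        format = "synthetic-config/1",
        n_cases = config@nCases,
        base_mortality = config@baseMortality,
        variables = data.frame(
            variable_type = v$variableType, code = v$code,
            family = v$family, prevalence = v$prevalence,
            odds_ratio = v$oddsRatio, stringsAsFactors = FALSE
        )
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' Bundled worked-example rule models and patient
#'
#' `exampleRuleModel()` loads one of the two bundled illustrative rule
#' models: the 13-rule minimal model over the admission-time demographic
#' types (decision boundary 1.015) or the full-model excerpt that adds
#' four clinical rules (decision boundary 5.306). Both are transcribed
#' from a published rule table -- their odds ratios are real, their
#' p-values placeholders -- and exist to demonstrate scoring and
#' explanation, not as mined output.
#'
#' `exampleCase()` loads the matching fictional emergency-department
#' patient: a female, Black/African American, single, Medicaid-insured,
#' English-speaking patient who was diagnosed with acidosis and
#' anuria/oliguria and received sodium bicarbonate and furosemide (nine
#' items, outcome unknown).
#'
#' @param name `"minimal"` or `"full"`.
#' @return a [RuleModel] or a one-case [CaseSet].
#' @examples
#' model <- exampleRuleModel("minimal")
#' patient <- exampleCase()
#' scoreCases(model, restrictToMinimal(patient))  # 0.636
#' @export
exampleRuleModel <- function(name = c("minimal", "full")) {
    name <- match.arg(name)
    path <- system.file("extdata",
                        paste0("example_rules_", name, ".json"),
                        package = "oddsrules", mustWork = TRUE)
    readRuleModel(path)
}

#' @rdname exampleRuleModel
#' @export
exampleCase <- function() {
    path <- system.file("extdata", "fictional_patient.tsv",
                        package = "oddsrules", mustWork = TRUE)
    readCases(path)
}
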