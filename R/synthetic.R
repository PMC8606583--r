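#' Death-class prevalence implied by a planted odds ratio
#'
#' Given an item's prevalence `q` among survivors and a target odds ratio
#' `rho`, returns the prevalence `p` among deaths that makes the
#' population odds ratio equal `rho` exactly:
#' `p / (1 - p) = rho * q / (1 - q)`, i.e.
#' `p = rho * q / (1 - q + rho * q)`.
#'
#' @param q prevalence among survivors, in (0, 1); vectorized.
#' @param rho planted odds ratio, > 0; vectorized.
#' @return prevalence among deaths, in (0, 1).
#' @examples
#' deathPrevalence(0.5, 1)    # 0.5: no association
#' deathPrevalence(0.2, 4)    # 0.5
#' deathPrevalence(0.5, 1/3)  # 0.25
#' @export
deathPrevalence <- function(q, rho) {
    stopifnot(all(q > 0 & q < 1), all(rho > 0))
    rho * q / (1 - q + rho * q)
}

#' Construct a synthetic population configuration
#'
#' @param nCases number of cases to generate.
#' @param variables data.frame with columns `variableType`, `code`,
#'   `family` (`NA` for independently sampled clinical items; a family
#'   name groups mutually exclusive demographic categories), `prevalence`
#'   (among survivors, in (0, 1)) and `oddsRatio` (planted, > 0). Within
#'   a family, survivor prevalences and the implied death-class
#'   prevalences must each sum to at most 1; any remainder means the
#'   family's category went unrecorded for that case.
#' @param baseMortality marginal probability that a case dies in
#'   hospital; the default 0.0179 mirrors large emergency/critical-care
#'   populations where roughly 1.79\% of cases end in death.
#' @return a [SyntheticConfig].
#' @seealso [generatePopulation()], [mimicLikeConfig()]
#' @export
syntheticConfig <- function(nCases, variables, baseMortality = 0.0179) {
    variables <- as.data.frame(variables, stringsAsFactors = FALSE)
    if (!"family" %in% colnames(variables)) variables$family <- NA_character_
    variables$family <- as.character(variables$family)
    variables <- variables[, c("variableType", "code", "family",
                               "prevalence", "oddsRatio")]
    rownames(variables) <- NULL
    new("SyntheticConfig", nCases = as.integer(nCases),
        baseMortality = baseMortality, variables = variables)
}

#' Ground truth of a synthetic configuration
#'
#' The per-item survivor prevalence `q`, the implied death-class
#' prevalence `p`, and the planted odds ratio -- the reference values
#' that parameter-recovery checks compare mined rules against.
#'
#' @param config a [SyntheticConfig].
#' @return data.frame with columns `variableType`, `code`, `family`,
#'   `q`, `p`, `oddsRatio`.
#' @export
syntheticTruth <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    v <- config@variables
    data.frame(
        variableType = v$variableType, code = v$code, family = v$family,
        q = v$prevalence,
        p = deathPrevalence(v$prevalence, v$oddsRatio),
        oddsRatio = v$oddsRatio,
        stringsAsFactors = FALSE
    )
}

#' Generate a synthetic case population
#'
#' Draws each case's outcome as Bernoulli(`baseMortality`), then samples
#' items conditionally on the outcome: an independent (clinical) item is
#' included with probability `q` for survivors and `p` for deaths, so its
#' population odds ratio equals the planted value; a demographic family
#' assigns at most one of its mutually exclusive categories per case,
#' with the per-category probabilities again `q`/`p` by outcome class.
#' Items are conditionally independent given the outcome -- exactly the
#' regime in which single-item odds-ratio rules carry the full signal.
#'
#' All randomness flows from the single `seed` in a fixed draw order
#' (outcome, then families in sorted order, then independent items in
#' table order), so populations are fully reproducible.
#'
#' @param config a [SyntheticConfig].
#' @param seed integer seed.
#' @return a [CaseSet] whose item universe is all configured items
#'   (including any that happen not to occur).
#' @examples
#' cfg <- syntheticConfig(
#'     nCases = 500,
#'     variables = data.frame(variableType = "diagnosis", code = "D1",
#'                            prevalence = 0.3, oddsRatio = 3),
#'     baseMortality = 0.2
#' )
#' cases <- generatePopulation(cfg, seed = 1)
#' tabulateItem(cases, "diagnosis", "D1")
#' @export
generatePopulation <- function(config, seed = 1L) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    n <- config@nCases
    v <- config@variables
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))

    died <- stats::runif(n) < config@baseMortality
    p <- if (nrow(v) > 0L) deathPrevalence(v$prevalence, v$oddsRatio)
         else numeric()

    triplets_i <- list()
    triplets_j <- list()
    tIdx <- 0L

    ## demographic families: one draw per case, cut into category bands
    fams <- sort(unique(v$family[!is.na(v$family)]))
    for (f in fams) {
        rows <- which(!is.na(v$family) & v$family == f)
        cumQ <- cumsum(v$prevalence[rows])
        cumP <- cumsum(p[rows])
        u <- stats::runif(n)
        band <- ifelse(died,
                       findInterval(u, c(0, cumP)),
                       findInterval(u, c(0, cumQ)))
        ## band k in 1..length(rows) selects category k; beyond = none
        hit <- band >= 1L & band <= length(rows) &
            u < ifelse(died, cumP[pmin(band, length(rows))],
                       cumQ[pmin(band, length(rows))])
        sel <- which(hit)
        tIdx <- tIdx + 1L
        triplets_i[[tIdx]] <- rows[band[sel]]
        triplets_j[[tIdx]] <- sel
    }

    ## independent clinical items
    indep <- which(is.na(v$family))
    for (r in indep) {
        prob <- ifelse(died, p[r], v$prevalence[r])
        sel <- which(stats::runif(n) < prob)
        if (length(sel) > 0L) {
            tIdx <- tIdx + 1L
            triplets_i[[tIdx]] <- rep.int(r, length(sel))
            triplets_j[[tIdx]] <- sel
        }
    }

    info <- data.frame(variableType = v$variableType, code = v$code,
                       stringsAsFactors = FALSE)
    ord <- order(info$variableType, info$code, method = "radix")
    rowMap <- integer(nrow(info))
    rowMap[ord] <- seq_along(ord)
    info <- info[ord, , drop = FALSE]
    rownames(info) <- NULL

    i <- rowMap[unlist(triplets_i, use.names = FALSE)]
    j <- unlist(triplets_j, use.names = FALSE)
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(nrow(info), n))
    new("CaseSet",
        itemMatrix = methods::as(m, "CsparseMatrix"),
        itemInfo = info,
        outcome = factor(ifelse(died, "died", "survived"),
                         levels = c("survived", "died")),
        caseIds = sprintf("case_%06d", seq_len(n)))
}

#' @export
#' @rdname SyntheticConfig-class
#' @param object a `SyntheticConfig`.
setMethod("show", "SyntheticConfig", function(object) {
    v <- object@variables
    cat("SyntheticConfig: ", object@nCases, " case(s), base mortality ",
        format(object@baseMortality), "\n", sep = "")
    cat("  ", nrow(v), " item(s); ",
        length(unique(v$family[!is.na(v$family)])),
        " exclusive demographic family(ies), ",
        sum(is.na(v$family)), " independent clinical item(s)\n", sep = "")
    if (nrow(v) > 0L)
        cat("  planted odds ratios span [",
            format(min(v$oddsRatio), digits = 3), ", ",
            format(max(v$oddsRatio), digits = 3), "]\n", sep = "")
    invisible(NULL)
})

#' Ready-made configuration emulating a critical-care EHR population
#'
#' A deterministic configuration whose statistical shape follows a large
#' emergency/critical-care database: five demographic families of
#' mutually exclusive categories (20 admission-time items in total,
#' matching the size of the minimal variable universe) with mild planted
#' odds ratios anchored at published demographic mortality associations,
#' plus five clinical variable types (diagnosis, prescription, procedure,
#' service, ward) holding many mostly-rare items whose planted odds
#' ratios span roughly 0.05 to 50. Base mortality is 0.0179.
#'
#' Two scales are provided: `"small"` (5,000 cases, 110 items) for fast
#' protocol checks, `"medium"` (50,000 cases, 1,000 items) for
#' discrimination experiments. The configuration itself contains no
#' randomness; only [generatePopulation()] draws.
#'
#' @param scale `"small"` or `"medium"`.
#' @return a [SyntheticConfig].
#' @examples
#' cfg <- mimicLikeConfig("small")
#' cfg
#' @export
mimicLikeConfig <- function(scale = c("small", "medium")) {
    scale <- match.arg(scale)
    demo <- demographicFamilies()
    sizes <- switch(scale,
        small = c(diagnosis = 40L, prescription = 25L, procedure = 12L,
                  service = 5L, ward = 8L),
        medium = c(diagnosis = 600L, prescription = 250L, procedure = 100L,
                   service = 10L, ward = 20L)
    )
    ranges <- list(
        diagnosis = list(or = c(0.05, 50), q = c(5e-4, 0.05)),
        prescription = list(or = c(0.1, 30), q = c(1e-3, 0.10)),
        procedure = list(or = c(0.5, 26), q = c(1e-3, 0.05)),
        service = list(or = c(0.2, 3), q = c(0.01, 0.30)),
        ward = list(or = c(0.05, 13), q = c(5e-3, 0.20))
    )
    clin <- do.call(rbind, lapply(names(sizes), function(ty) {
        clinicalFamily(ty, sizes[[ty]], ranges[[ty]]$or, ranges[[ty]]$q)
    }))
    nCases <- switch(scale, small = 5000L, medium = 50000L)
    syntheticConfig(nCases = nCases, variables = rbind(demo, clin),
                    baseMortality = 0.0179)
}

## Deterministic demographic families. Survivor prevalences sum to 1 per
## family; planted odds ratios are mild (roughly 0.5-2.5, plus the rarer
## "unknown" ethnicities), anchored at published demographic mortality
## associations. Per-family death-class prevalences sum to <= 1; the
## small remainder means the category went unrecorded.
demographicFamilies <- function() {
    fam <- function(type, codes, q, or) {
        data.frame(variableType = type, code = codes, family = type,
                   prevalence = q, oddsRatio = or,
                   stringsAsFactors = FALSE)
    }
    rbind(
        fam("gender", c("Male", "Female"), c(0.50, 0.50), c(1.25, 0.80)),
        fam("language", c("English", "Other"), c(0.80, 0.20), c(0.73, 1.36)),
        fam("insurance_type", c("Medicare", "Medicaid", "Other"),
            c(0.35, 0.25, 0.40), c(2.40, 0.57, 0.50)),
        fam("ethnicity",
            c("White", "Black/African American", "Hispanic/Latino",
              "Asian", "Other", "Unknown", "Unable to obtain",
              "American Indian/Alaska Native"),
            c(0.60, 0.18, 0.08, 0.05, 0.04, 0.02, 0.02, 0.01),
            c(1.10, 0.58, 0.47, 0.90, 1.00, 4.59, 2.25, 1.00)),
        fam("marital_status",
            c("Married", "Single", "Widowed", "Divorced", "Missing"),
            c(0.40, 0.30, 0.10, 0.10, 0.10),
            c(1.00, 0.50, 2.05, 1.10, 1.30))
    )
}

## Deterministic clinical family: prevalences fall geometrically from
## qMax to qMin; planted odds ratios sweep the log range but are assigned
## through a golden-ratio permutation so effect size is not confounded
## with item frequency.
clinicalFamily <- function(type, n, orRange, qRange) {
    q <- exp(seq(log(qRange[2]), log(qRange[1]), length.out = n))
    or <- exp(seq(log(orRange[1]), log(orRange[2]), length.out = n))
    phi <- (sqrt(5) - 1) / 2
    perm <- order((seq_len(n) * phi) %% 1)
    data.frame(
        variableType = type,
        code = sprintf("%s_%04d", toupper(substr(type, 1, 4)), seq_len(n)),
        family = NA_character_,
        prevalence = q,
        oddsRatio = or[perm],
        stringsAsFactors = FALSE
    )
}
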