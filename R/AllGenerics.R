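#' @rdname CaseSet-accessors
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname CaseSet-accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname CaseSet-accessors
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))

#' @rdname CaseSet-accessors
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @rdname CaseSet-accessors
#' @export
setGeneric("itemInfo", function(x) standardGeneric("itemInfo"))

#' @rdname CaseSet-accessors
#' @export
setGeneric("caseItems", function(x, case) standardGeneric("caseItems"))

#' @rdname restrictToMinimal
#' @export
setGeneric("restrictToMinimal", function(x) standardGeneric("restrictToMinimal"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("nRules", function(x) standardGeneric("nRules"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("pMax", function(x) standardGeneric("pMax"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("bonferroni", function(x) standardGeneric("bonferroni"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("nTests", function(x) standardGeneric("nTests"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("modelClass", function(x) standardGeneric("modelClass"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("decisionBoundary", function(x) standardGeneric("decisionBoundary"))

#' @rdname RuleModel-accessors
#' @export
setGeneric("decisionBoundary<-",
    function(x, value) standardGeneric("decisionBoundary<-"))

#' @rdname summarizeRules
#' @export
setGeneric("summarizeRules", function(x, k = 5L) standardGeneric("summarizeRules"))

#' @rdname rocCurve
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname youdenBoundary
#' @export
setGeneric("youdenBoundary", function(x) standardGeneric("youdenBoundary"))
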