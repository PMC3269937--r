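#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes. Accessors
#' are preferred over direct slot access, which is not part of the API.
#'
#' @param x An object of one of the package's S4 classes.
#' @return The slot value named by the generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("deltaMatrix", function(x) standardGeneric("deltaMatrix"))

#' @rdname accessors
#' @export
setGeneric("labelObjects", function(x) standardGeneric("labelObjects"))

#' @rdname accessors
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setGeneric("sourceProfiles", function(x) standardGeneric("sourceProfiles"))

#' @rdname accessors
#' @export
setGeneric("tapScore", function(x) standardGeneric("tapScore"))

#' @rdname accessors
#' @export
setGeneric("perQueryEvals", function(x) standardGeneric("perQueryEvals"))

#' @rdname accessors
#' @export
setGeneric("thresholdX", function(x) standardGeneric("thresholdX"))

#' @rdname accessors
#' @export
setGeneric("chosenDocuments", function(x) standardGeneric("chosenDocuments"))

#' @rdname accessors
#' @export
setGeneric("documentScores", function(x) standardGeneric("documentScores"))
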