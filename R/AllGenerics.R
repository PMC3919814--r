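#' @rdname trajectory-metrics
#' @export
setGeneric("netXDisplacement", function(x, ...) standardGeneric("netXDisplacement"))

#' @rdname trajectory-metrics
#' @export
setGeneric("pathLength", function(x, ...) standardGeneric("pathLength"))

#' @rdname trajectory-metrics
#' @export
setGeneric("netDistance", function(x, ...) standardGeneric("netDistance"))

#' @rdname trajectory-metrics
#' @export
setGeneric("migrationSpeed", function(x, ...) standardGeneric("migrationSpeed"))

#' @rdname trajectory-metrics
#' @export
setGeneric("persistence", function(x, ...) standardGeneric("persistence"))

#' @rdname shearStress
#' @export
setGeneric("shearStress", function(chamber, ...) standardGeneric("shearStress"))

#' @rdname accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
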