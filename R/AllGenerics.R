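#' @include AllClasses.R
NULL

#' Accessors for alignment, profile and pangenome objects
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x a [PairAlignment], [ProfileHMM] or [PangenomeMatrix] object.
#' @return `rawScore()`, `bitScore()`, `evalue()`, `identityFraction()` return
#'   scalars from a [PairAlignment]; `nMatchStates()` the number of match
#'   states of a [ProfileHMM]; `presenceMatrix()` the logical matrix,
#'   `genomeIds()` and `clusterIds()` the dimnames of a [PangenomeMatrix].
#' @name accessors
#' @aliases rawScore bitScore evalue identityFraction nMatchStates
#'   presenceMatrix genomeIds clusterIds
NULL

#' @rdname accessors
#' @export
setGeneric("rawScore", function(x) standardGeneric("rawScore"))
#' @rdname accessors
#' @export
setGeneric("bitScore", function(x) standardGeneric("bitScore"))
#' @rdname accessors
#' @export
setGeneric("evalue", function(x) standardGeneric("evalue"))
#' @rdname accessors
#' @export
setGeneric("identityFraction", function(x) standardGeneric("identityFraction"))
#' @rdname accessors
#' @export
setGeneric("nMatchStates", function(x) standardGeneric("nMatchStates"))
#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
setMethod("rawScore", "PairAlignment", function(x) x@rawScore)
#' @rdname accessors
setMethod("bitScore", "PairAlignment", function(x) x@bitScore)
#' @rdname accessors
setMethod("evalue", "PairAlignment", function(x) x@evalue)
#' @rdname accessors
setMethod("identityFraction", "PairAlignment", function(x) x@identity)
#' @rdname accessors
setMethod("nMatchStates", "ProfileHMM", function(x) x@M)
#' @rdname accessors
setMethod("presenceMatrix", "PangenomeMatrix", function(x) x@presence)
#' @rdname accessors
setMethod("genomeIds", "PangenomeMatrix", function(x) rownames(x@presence))
#' @rdname accessors
setMethod("clusterIds", "PangenomeMatrix", function(x) colnames(x@presence))
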