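# Accessor generics: the supported way to get at slot content.

#' @rdname accessors
#' @param object an sseFold object
#' @export
setGeneric("ssType", function(object) standardGeneric("ssType"))
#' @rdname accessors
#' @export
setGeneric("sseRange", function(object) standardGeneric("sseRange"))
#' @rdname accessors
#' @export
setGeneric("sseLength", function(object) standardGeneric("sseLength"))
#' @rdname accessors
#' @param atom atom name among N, CA, C, O, CB (CB is the pseudo-CB for
#'   glycine)
#' @export
setGeneric("atomCoords", function(object, atom = "CA") standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("bodyFrame", function(object) standardGeneric("bodyFrame"))
#' @rdname accessors
#' @export
setGeneric("modelSequence", function(object) standardGeneric("modelSequence"))
#' @rdname accessors
#' @export
setGeneric("modelSses", function(object) standardGeneric("modelSses"))
#' @rdname accessors
#' @export
setGeneric("poolEntries", function(object) standardGeneric("poolEntries"))
#' @rdname accessors
#' @export
setGeneric("predProb", function(object) standardGeneric("predProb"))

#' Accessors for sseFold classes
#'
#' @name accessors
#' @return the requested component; `atomCoords` returns an n x 3 matrix
#'   of the chosen atom per residue (rows named by residue index).
NULL

#' @rdname accessors
setMethod("ssType", "SSE", function(object) object@ssType)

#' @rdname accessors
setMethod("sseRange", "SSE", function(object) c(object@first, object@last))

#' @rdname accessors
setMethod("sseLength", "SSE", function(object) object@last - object@first + 1L)

#' @rdname accessors
setMethod("atomCoords", "SSE", function(object, atom = "CA") {
  k <- match(atom, ATOM_NAMES)
  if (is.na(k)) stop("unknown atom name: ", atom)
  n <- sseLength(object)
  out <- object@coords[seq.int(k, by = N_ATOMS, length.out = n), , drop = FALSE]
  rownames(out) <- as.character(seq.int(object@first, object@last))
  out
})

#' @rdname accessors
setMethod("atomCoords", "ProteinModel", function(object, atom = "CA") {
  parts <- lapply(object@sses, atomCoords, atom = atom)
  k <- match(atom, ATOM_NAMES)
  if (length(object@coil)) {
    coil <- t(vapply(object@coil, function(m) m[k, ], numeric(3)))
    rownames(coil) <- names(object@coil)
    parts <- c(parts, list(coil))
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) return(matrix(numeric(0), 0, 3))
  out[order(as.integer(rownames(out))), , drop = FALSE]
})

#' @rdname accessors
setMethod("bodyFrame", "SSE", function(object) object@frame)

#' @rdname accessors
setMethod("modelSequence", "ProteinModel", function(object) object@sequence)

#' @rdname accessors
setMethod("modelSses", "ProteinModel", function(object) object@sses)

#' @rdname accessors
setMethod("poolEntries", "SSEPool", function(object) object@entries)

#' @rdname accessors
setMethod("predProb", "SSPrediction", function(object) object@prob)

#' Minimum SSE length for a secondary structure type
#'
#' Helices must span at least five residues and strands at least three;
#' shorter elements are excluded everywhere (pool construction, resize
#' moves, model validity).
#'
#' @param ssType "helix" or "strand"
#' @return integer minimum length
#' @export
minSseLength <- function(ssType) {
  ifelse(ssType == "helix", 5L, 3L)
}

#' Residue indices covered by the model's SSEs
#'
#' @param model a [ProteinModel-class]
#' @return sorted integer vector of covered residue indices
#' @export
modeledResidues <- function(model) {
  if (!length(model@sses)) return(integer(0))
  sort(unlist(lapply(model@sses, function(s) seq.int(s@first, s@last))))
}

#' Fraction of pool regions represented in a model
#'
#' Completeness is the fraction of distinct pool residue coverage that is
#' represented by the model's SSEs, in [0, 1].
#'
#' @param model a [ProteinModel-class]
#' @param pool an [SSEPool-class]
#' @return numeric scalar in [0, 1]
#' @export
modelCompleteness <- function(model, pool) {
  e <- pool@entries
  if (!nrow(e)) return(1)
  covered <- unique(unlist(mapply(seq.int, e$first, e$last, SIMPLIFY = FALSE)))
  length(intersect(covered, modeledResidues(model))) / length(covered)
}
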