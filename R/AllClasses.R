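# S4 classes for the core containers: rigid transforms, placed secondary
# structure elements, the protein model the search mutates, the SSE pool,
# three-state secondary structure predictions, and per-term energy
# breakdowns.

ATOM_NAMES <- c("N", "CA", "C", "O", "CB")
N_ATOMS <- length(ATOM_NAMES)

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy, normalized to [-1, 1] by the scale maximum 4.5.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2) / 4.5

SS_STATES <- c("H", "E", "C")

#' Rigid-body transform
#'
#' A proper rotation plus translation acting on 3D coordinates
#' (Angstrom).  Used to place idealized secondary structure elements in
#' space and to express rigid-body moves.
#'
#' @slot rotation 3x3 proper orthonormal matrix (det = +1).
#' @slot translation numeric length-3 translation vector.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (!all(is.finite(R)) || !all(is.finite(object@translation)))
    return("non-finite transform")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = 1)")
  TRUE
})

#' Secondary structure element
#'
#' A contiguous sequence segment with idealized backbone geometry placed
#' rigidly in space.  Coordinates hold the five tracked atoms per residue
#' (N, CA, C, O, CB; glycine carries a pseudo-CB at the HA2 position) in
#' residue-major order.  The body frame maps the canonical template
#' (principal axis along +z, CA centroid at the origin, N-terminus at
#' negative z) onto the placed coordinates.
#'
#' @slot ssType "helix" or "strand".
#' @slot first,last 1-based inclusive sequence bounds.
#' @slot aaSeq one-letter amino acid string of the segment.
#' @slot coords (5 * length) x 3 coordinate matrix, atoms N, CA, C, O, CB
#'   per residue.
#' @slot frame [RigidTransform-class] placing the canonical template.
#' @export
setClass("SSE",
  representation(ssType = "character", first = "integer", last = "integer",
                 aaSeq = "character", coords = "matrix",
                 frame = "RigidTransform"))

setValidity("SSE", function(object) {
  if (!length(object@first)) return(TRUE)  # prototype
  if (!object@ssType %in% c("helix", "strand")) return("ssType must be helix/strand")
  n <- object@last - object@first + 1L
  if (n < 1L || object@first < 1L) return("invalid bounds")
  if (n < minSseLength(object@ssType))
    return(sprintf("%s must have >= %d residues", object@ssType,
                   minSseLength(object@ssType)))
  if (nchar(object@aaSeq) != n) return("aaSeq length must match bounds")
  if (!all(strsplit(object@aaSeq, "")[[1]] %in% AA1))
    return("unknown residue code in aaSeq")
  if (!all(dim(object@coords) == c(N_ATOMS * n, 3L)))
    return("coords must be (5*length) x 3")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' Protein model
#'
#' An ordered collection of placed secondary structure elements over one
#' sequence; the object the Monte Carlo search mutates.  Loop (coil)
#' residues built by the loop builder are stored separately so that the
#' SSE-only representation used during folding stays untouched.
#'
#' @slot sequence full one-letter amino acid string.
#' @slot sses list of [SSE-class], kept sorted by first residue,
#'   non-overlapping in sequence.
#' @slot coil named list mapping residue index (as character) to a 5x3
#'   coordinate matrix for loop residues built outside SSEs.
#' @slot provenance free-text pool/run identifier.
#' @export
setClass("ProteinModel",
  representation(sequence = "character", sses = "list", coil = "list",
                 provenance = "character"),
  prototype(coil = list(), provenance = ""))

setValidity("ProteinModel", function(object) {
  if (!length(object@sequence)) return(TRUE)  # prototype
  n <- nchar(object@sequence)
  if (n < 1L) return("empty sequence")
  if (length(object@sses)) {
    b <- t(vapply(object@sses, function(s) c(s@first, s@last), integer(2)))
    if (is.unsorted(b[, 1], strictly = TRUE) && nrow(b) > 1)
      return("sses must be sorted by first residue")
    if (any(b[, 2] > n)) return("SSE bounds exceed sequence length")
    if (nrow(b) > 1 && any(b[-1, 1] <= b[-nrow(b), 2]))
      return("SSEs overlap in sequence")
    for (s in object@sses) {
      if (substring(object@sequence, s@first, s@last) != s@aaSeq)
        return("SSE segment does not match the full sequence")
    }
  }
  if (length(object@coil)) {
    idx <- as.integer(names(object@coil))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n))
      return("coil residue indices out of range")
  }
  TRUE
})

#' Pool of candidate secondary structure elements
#'
#' Candidate SSEs (possibly overlapping, multiple lengths per region)
#' from which folding draws.  Entries are rows of a data.frame with
#' columns `type` ("helix"/"strand"), `first`, `last` and `source`.
#'
#' @slot entries data.frame of candidate elements.
#' @slot sequence the full amino acid sequence the pool refers to.
#' @slot source free-text pool provenance tag.
#' @export
setClass("SSEPool",
  representation(entries = "data.frame", sequence = "character",
                 source = "character"),
  prototype(source = ""))

setValidity("SSEPool", function(object) {
  e <- object@entries
  if (!ncol(e)) return(TRUE)  # prototype
  need <- c("type", "first", "last", "source")
  if (!all(need %in% names(e))) return("entries need type/first/last/source")
  if (nrow(e)) {
    if (!all(e$type %in% c("helix", "strand"))) return("bad entry type")
    if (any(e$first < 1L) || any(e$last > nchar(object@sequence)))
      return("entry bounds outside sequence")
    len <- e$last - e$first + 1L
    short <- len < ifelse(e$type == "helix", 5L, 3L)
    if (any(short)) return("entry below minimum SSE length")
  }
  TRUE
})

#' Three-state secondary structure prediction
#'
#' Per-residue helix/strand/coil probabilities for one or two prediction
#' methods (slots named "psipred" and "jufo"), each an n x 3 matrix with
#' columns H, E, C summing to 1 per row.
#'
#' @slot prob named list of n x 3 probability matrices.
#' @slot sequence the amino acid sequence (may be empty when unknown).
#' @export
setClass("SSPrediction",
  representation(prob = "list", sequence = "character"),
  prototype(sequence = ""))

setValidity("SSPrediction", function(object) {
  if (!length(object@prob)) return(TRUE)  # prototype; constructors enforce content

  if (is.null(names(object@prob)) || any(!nzchar(names(object@prob))))
    return("prediction methods must be named")
  n <- nrow(object@prob[[1]])
  for (m in names(object@prob)) {
    p <- object@prob[[m]]
    if (!is.matrix(p) || ncol(p) != 3L) return("each method needs an n x 3 matrix")
    if (nrow(p) != n) return("methods disagree on sequence length")
    if (any(p < -1e-9) || any(p > 1 + 1e-9)) return("probabilities outside [0,1]")
    if (any(abs(rowSums(p) - 1) > 1e-6)) return("probabilities must sum to 1")
  }
  TRUE
})

#' Per-term energy breakdown
#'
#' Raw and weighted scores for the twelve composite energy terms, in
#' arbitrary energy units.  The total equals the sum of the weighted
#' terms.
#'
#' @slot raw,weighted named numeric vectors over the twelve terms.
#' @slot total numeric total energy.
#' @export
setClass("EnergyBreakdown",
  representation(raw = "numeric", weighted = "numeric", total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  if (!length(object@raw)) return(TRUE)  # prototype
  if (!identical(sort(names(object@raw)), sort(energyTermNames())))
    return("raw must cover the twelve terms")
  if (!identical(names(object@raw), names(object@weighted)))
    return("raw/weighted name mismatch")
  if (!all(is.finite(object@raw)) || !all(is.finite(object@weighted)) ||
      !is.finite(object@total)) return("non-finite energies")
  if (abs(object@total - sum(object@weighted)) > 1e-9)
    return("total must equal the sum of weighted terms")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 4))
  cat("  translation:", paste(round(object@translation, 3), collapse = " "), "\n")
})

setMethod("show", "SSE", function(object) {
  cat(sprintf("SSE %s %d-%d (%d residues) %s\n", object@ssType,
              object@first, object@last, object@last - object@first + 1L,
              object@aaSeq))
})

setMethod("show", "ProteinModel", function(object) {
  cat(sprintf("ProteinModel: %d residues, %d SSEs, %d coil residues built\n",
              nchar(object@sequence), length(object@sses), length(object@coil)))
  for (s in object@sses)
    cat(sprintf("  %s %d-%d\n", s@ssType, s@first, s@last))
})

setMethod("show", "SSEPool", function(object) {
  cat(sprintf("SSEPool: %d entries over %d residues [%s]\n",
              nrow(object@entries), nchar(object@sequence), object@source))
})

setMethod("show", "SSPrediction", function(object) {
  cat(sprintf("SSPrediction: %d residues, methods: %s\n",
              nrow(object@prob[[1]]), paste(names(object@prob), collapse = ", ")))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown (arbitrary energy units)\n")
  df <- data.frame(raw = round(object@raw, 4), weighted = round(object@weighted, 4))
  print(df)
  cat(sprintf("total: %.4f\n", object@total))
})
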