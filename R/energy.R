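# Composite 12-term energy over SSE-only models.  The term inventory
# follows the composite knowledge-based score (clash, pair distance,
# solvation, SSE packing and pairing, loop length and closure, radius of
# gyration, secondary structure agreement per prediction method, contact
# order); the functional forms are documented package stand-ins with all
# constants exposed through the configuration.

#' Names of the twelve energy terms
#' @return character vector of term names
#' @export
energyTermNames <- function() {
  c("aa_clash", "aa_pair_distance", "aa_solvation", "sse_pair_clash",
    "sse_packing", "strand_pairing", "loop_length", "loop_closure",
    "radius_of_gyration", "ss_agreement_method1", "ss_agreement_method2",
    "contact_order")
}

#' Default weight set
#'
#' Non-negative weight per term; defaults to 1 for every term.
#'
#' @param ... named overrides, e.g. `weightSet(loop_closure = 2)`
#' @return named numeric vector over the twelve terms
#' @export
weightSet <- function(...) {
  w <- setNames(rep(1, 12L), energyTermNames())
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(w))
    if (length(bad)) stop("unknown energy term: ", paste(bad, collapse = ", "))
    w[names(over)] <- as.numeric(over)
  }
  if (any(w < 0)) stop("weights must be >= 0")
  w
}

# term constants (config-exposed; see defaultConfig())
energyConstants <- function() {
  list(
    clash_dist = 3.0, clash_kappa = 10,
    sse_clash_min = c(hh = 7.0, hs = 6.0, ss = 4.0),
    packing_ideal = c(hh = 9.5, hs = 10.0),
    packing_width = 2.0, packing_range = 12,
    strand_pair_ideal = 4.75, strand_pair_width = 1.0,
    pair_cutoff = 12, pair_min_sep = 5L,
    neighbor_cutoff = 10, neighbor_ref = 13, neighbor_scale = 4,
    rg_coef = 2.2, rg_exp = 0.38,
    rco_target = 0.3, rco_width = 0.15,
    loop_per_res = 2.5, closure_penalty = 1000,
    contact_cutoff = 8)
}

# CB coordinates + residue numbers + SSE membership of modeled residues
modelCbTable <- function(model) {
  ns <- length(model@sses)
  cb <- vector("list", ns); resno <- vector("list", ns); sid <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- model@sses[[i]]
    n <- s@last - s@first + 1L
    cb[[i]] <- s@coords[seq.int(5L, by = N_ATOMS, length.out = n), , drop = FALSE]
    resno[[i]] <- seq.int(s@first, s@last)
    sid[[i]] <- rep.int(i, n)
  }
  list(cb = do.call(rbind, cb), resno = unlist(resno), sse = unlist(sid))
}

modelCaMatrix <- function(model) {
  do.call(rbind, lapply(model@sses, function(s) {
    n <- s@last - s@first + 1L
    s@coords[seq.int(2L, by = N_ATOMS, length.out = n), , drop = FALSE]
  }))
}

# shortest distance between two 3D segments (p1,p2) and (q1,q2)
segmentDistance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * c - b * b
  if (den < 1e-12) { s <- 0 } else { s <- (b * e - c * d) / den }
  s <- min(1, max(0, s))
  t <- if (c < 1e-12) 0 else (b * s + e) / c
  t <- min(1, max(0, t))
  s <- if (a < 1e-12) 0 else min(1, max(0, (b * t - d) / a))
  norm3((p1 + s * u) - (q1 + t * v))
}

sseSegment <- function(sse) {
  ax <- sseAxis(sse)
  h <- ax$length / 2
  list(p1 = ax$center - h * ax$direction, p2 = ax$center + h * ax$direction,
       dir = ax$direction, center = ax$center)
}

pairKey <- function(t1, t2) {
  if (t1 == "helix" && t2 == "helix") "hh"
  else if (t1 == "strand" && t2 == "strand") "ss"
  else "hs"
}

# mean CA-CA pairing distance between two strands: for each residue of
# each strand, the distance to the nearest CA of the other strand,
# averaged over both directions.
strandPairingDistance <- function(s1, s2) {
  a <- atomCoords(s1, "CA"); b <- atomCoords(s2, "CA")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

# precomputed per-sequence scoring context (hydrophobicity, floored
# -log p matrices, flattened constants)
energyContext <- function(sequence, pred = NULL, const = energyConstants()) {
  aa <- strsplit(sequence, "")[[1]]
  nlp <- function(m) -log(pmax(m, PROB_FLOOR))
  list(
    n = length(aa),
    hyd = unname(KD_HYDROPATHY[aa]),
    nlp1 = if (!is.null(pred)) nlp(pred@prob[[1]]) else NULL,
    nlp2 = if (!is.null(pred) && length(pred@prob) >= 2)
      nlp(pred@prob[[2]]) else NULL,
    consts = c(clash_dist = const$clash_dist,
               clash_kappa = const$clash_kappa,
               pair_cutoff = const$pair_cutoff,
               pair_min_sep = const$pair_min_sep,
               neighbor_cutoff = const$neighbor_cutoff,
               neighbor_ref = const$neighbor_ref,
               neighbor_scale = const$neighbor_scale,
               contact_cutoff = const$contact_cutoff,
               packing_range = const$packing_range,
               packing_width = const$packing_width,
               packing_ideal_hh = unname(const$packing_ideal[["hh"]]),
               packing_ideal_hs = unname(const$packing_ideal[["hs"]]),
               sse_clash_hh = unname(const$sse_clash_min[["hh"]]),
               sse_clash_hs = unname(const$sse_clash_min[["hs"]]),
               sse_clash_ss = unname(const$sse_clash_min[["ss"]]),
               strand_pair_ideal = const$strand_pair_ideal,
               strand_pair_width = const$strand_pair_width,
               loop_per_res = const$loop_per_res,
               closure_penalty = const$closure_penalty,
               rg_coef = const$rg_coef, rg_exp = const$rg_exp,
               rco_target = const$rco_target, rco_width = const$rco_width,
               seq_len = length(aa)))
}

# all twelve raw terms in one pass through the C++ kernel
computeRawTerms <- function(model, pred = NULL, const = energyConstants(),
                            ctx = NULL) {
  if (is.null(ctx)) ctx <- energyContext(model@sequence, pred, const)
  sses <- model@sses
  k <- length(sses)
  coordsList <- vector("list", k)
  firsts <- integer(k); lasts <- integer(k); typeCode <- integer(k)
  axP1 <- matrix(0, k, 3); axP2 <- matrix(0, k, 3); axDir <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    s <- sses[[i]]
    coordsList[[i]] <- s@coords
    firsts[i] <- s@first
    lasts[i] <- s@last
    typeCode[i] <- if (s@ssType == "strand") 1L else 0L
    fr <- s@frame
    d <- fr@rotation[, 3]
    ctr <- fr@translation
    h <- attr(templateForSse(s@ssType, s@aaSeq), "axisLength") / 2
    axDir[i, ] <- d
    axP1[i, ] <- ctr - h * d
    axP2[i, ] <- ctr + h * d
  }
  raw <- .energyKernel(coordsList, firsts, lasts, ctx$hyd, typeCode,
                       axP1, axP2, axDir, ctx$consts)
  # secondary structure agreement incl. the unfolded part (coil)
  ss1 <- 0; ss2 <- 0
  if (!is.null(ctx$nlp1)) {
    col <- rep(3L, ctx$n)
    for (i in seq_len(k))
      col[seq.int(firsts[i], lasts[i])] <- if (typeCode[i] == 1L) 2L else 1L
    idx <- cbind(seq_len(ctx$n), col)
    ss1 <- sum(ctx$nlp1[idx])
    if (!is.null(ctx$nlp2)) ss2 <- sum(ctx$nlp2[idx])
  }
  out <- c(raw, ss_agreement_method1 = ss1, ss_agreement_method2 = ss2)
  out[energyTermNames()]
}

#' Clash terms
#'
#' `aa_clash` penalizes CB (pseudo-CB) pairs in different SSEs closer
#' than 3 A quadratically (10 energy units per square Angstrom);
#' `sse_pair_clash` penalizes SSE axis-segment distances below type-pair
#' minima (helix-helix 7.0 A, helix-strand 6.0 A, strand-strand 4.0 A).
#'
#' @param model a [ProteinModel-class]
#' @param const term constants (see `defaultConfig()$energy`)
#' @return list with `aa_clash` and `sse_pair_clash` (both >= 0)
#' @export
clashTerms <- function(model, const = energyConstants()) {
  raw <- computeRawTerms(model, NULL, const)
  list(aa_clash = unname(raw["aa_clash"]),
       sse_pair_clash = unname(raw["sse_pair_clash"]))
}

#' Loop terms
#'
#' For each sequence-adjacent SSE pair with chain-break distance `euclid`
#' and `nLoop` missing residues: `loop_length` adds
#' `max(0, euclid / sqrt(nLoop + 1) - 2.5)^2` (the per-residue loop span
#' above what a relaxed loop covers), and `loop_closure` adds a fixed
#' 1000-unit penalty when `euclid > 2.56 (nLoop + 1) + 2.0` A, i.e. when
#' not even a fully extended loop could close the gap.
#'
#' @inheritParams clashTerms
#' @return list with `loop_length` and `loop_closure`
#' @export
loopTerms <- function(model, const = energyConstants()) {
  raw <- computeRawTerms(model, NULL, const)
  list(loop_length = unname(raw["loop_length"]),
       loop_closure = unname(raw["loop_closure"]))
}

#' Geometry terms
#'
#' `sse_packing`: for each helix-helix or helix-strand pair with axis
#' distance within 12 A, a negative well centered at the ideal packing
#' distance (9.5 / 10.0 A, width 2 A) scaled by an axis-alignment bonus
#' `0.5 + 0.5 |cos(packing angle)|`; most favorable at the ideal
#' distance with aligned (parallel or antiparallel) axes.
#' `strand_pairing`: per strand pair, a negative well on the mean CA-CA
#' pairing distance centered at 4.75 A (width 1 A).
#' `radius_of_gyration`: squared relative deviation of the CA radius of
#' gyration from the expected `2.2 N^0.38`.  `contact_order`: squared
#' deviation of the model's relative contact order from 0.3 in units of
#' 0.15.
#'
#' @inheritParams clashTerms
#' @return list with `sse_packing`, `strand_pairing`,
#'   `radius_of_gyration`, `contact_order`
#' @export
geometryTerms <- function(model, const = energyConstants()) {
  raw <- computeRawTerms(model, NULL, const)
  list(sse_packing = unname(raw["sse_packing"]),
       strand_pairing = unname(raw["strand_pairing"]),
       radius_of_gyration = unname(raw["radius_of_gyration"]),
       contact_order = unname(raw["contact_order"]))
}

#' Profile terms
#'
#' `aa_pair_distance`: hydrophobicity-product attraction over CB pairs
#' with sequence separation >= 5 and distance < 12 A (Kyte-Doolittle
#' based).  `aa_solvation`: bounded neighbor-count potential (CB
#' neighbors within 10 A) penalizing exposed hydrophobics and buried
#' polars, with a flat zero reference for unmodeled residues.
#' `ss_agreement_*`: per prediction method, sum over all residues of
#' `-log p(assigned state)` where SSE residues take their element's
#' state and all other residues (the unfolded part) count as coil.
#'
#' @inheritParams clashTerms
#' @param pred an [SSPrediction-class] (NULL allowed; agreement terms 0)
#' @return list with `aa_pair_distance`, `aa_solvation`,
#'   `ss_agreement_method1`, `ss_agreement_method2`
#' @export
profileTerms <- function(model, pred = NULL, const = energyConstants()) {
  raw <- computeRawTerms(model, pred, const)
  list(aa_pair_distance = unname(raw["aa_pair_distance"]),
       aa_solvation = unname(raw["aa_solvation"]),
       ss_agreement_method1 = unname(raw["ss_agreement_method1"]),
       ss_agreement_method2 = unname(raw["ss_agreement_method2"]))
}

#' Score a protein model with the composite energy
#'
#' Evaluates all twelve terms and combines them with the supplied
#' weights.  Solvation and secondary-structure agreement also cover the
#' unfolded part of the protein: residues not represented in the model
#' are scored as coil for the agreement terms and contribute a flat zero
#' solvation reference.  Deterministic.
#'
#' @param model a [ProteinModel-class] with at least one SSE
#' @param pred an [SSPrediction-class]; required when either
#'   ss_agreement weight is positive
#' @param weights named weight vector from [weightSet]
#' @param const term constants (see `defaultConfig()$energy`)
#' @return an [EnergyBreakdown-class]
#' @export
scoreModel <- function(model, pred = NULL, weights = weightSet(),
                       const = energyConstants()) {
  if (!length(model@sses)) stop("model must contain at least one SSE")
  if (is.null(pred) &&
      (weights[["ss_agreement_method1"]] > 0 ||
       weights[["ss_agreement_method2"]] > 0))
    stop("prediction required when ss_agreement weights are positive")
  raw <- computeRawTerms(model, pred, const)[energyTermNames()]
  weighted <- raw * weights[energyTermNames()]
  b <- new("EnergyBreakdown")
  b@raw <- raw; b@weighted <- weighted; b@total <- sum(weighted)
  b
}

#' Write an energy breakdown as a TSV table
#'
#' @param breakdown an [EnergyBreakdown-class]
#' @param path output file
#' @export
writeEnergyTsv <- function(breakdown, path) {
  df <- data.frame(term = names(breakdown@raw), raw = breakdown@raw,
                   weighted = breakdown@weighted)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
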