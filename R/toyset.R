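# Synthetic toy proteins: designed SSE arrangements with closable loops,
# perfect secondary structure predictions and native pools.  These stand
# in for experimental benchmark structures at desk scale; everything
# they emit is labelled synthetic.

CORE_AAS <- c("L", "I", "V", "F", "M", "A")     # buried face
SURF_AAS <- c("E", "K", "Q", "R", "S", "T", "N", "D")  # exposed face
LOOP_AAS <- c("G", "S", "N", "D", "T", "P")

#' Specify a toy topology
#'
#' Describes a synthetic protein as a list of SSE types/lengths placed
#' on a circular bundle (helix bundles) or in a linear sheet
#' arrangement, with antiparallel neighbors and fixed loop lengths.
#'
#' @param types character vector of "helix"/"strand" per element
#' @param lengths integer vector of element lengths (residues)
#' @param loopLength residues between consecutive elements (default 4)
#' @param spacing center-to-center neighbor distance in Angstrom
#'   (default 10 for bundles, 4.75 for sheets)
#' @param arrangement "bundle" (circular) or "sheet" (linear)
#' @return a toy topology specification list
#' @export
toyTopologySpec <- function(types, lengths, loopLength = 4L, spacing = NULL,
                            arrangement = c("bundle", "sheet")) {
  arrangement <- match.arg(arrangement)
  if (length(types) != length(lengths)) stop("types/lengths length mismatch")
  if (!all(types %in% c("helix", "strand"))) stop("bad element type")
  if (any(lengths < minSseLength(types)))
    stop("element below minimum SSE length")
  if (is.null(spacing))
    spacing <- if (arrangement == "bundle") 10 else 4.75
  list(types = types, lengths = as.integer(lengths),
       loopLength = as.integer(loopLength), spacing = spacing,
       arrangement = arrangement)
}

#' The default three-helix bundle specification
#'
#' Three 14-residue helices at the vertices of an equilateral triangle
#' (10 Angstrom side), antiparallel neighbors, 4-residue loops: about 50
#' residues in total, the realistic geometry of natural three-helix
#' bundles.
#'
#' @return a toy topology specification
#' @export
threeHelixBundleSpec <- function() {
  toyTopologySpec(rep("helix", 3), rep(14L, 3), loopLength = 4L,
                  spacing = 10, arrangement = "bundle")
}

toyPlacements <- function(spec) {
  k <- length(spec$types)
  centers <- matrix(0, k, 3)
  if (spec$arrangement == "bundle" && k > 1) {
    radius <- spec$spacing / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1) / k
    centers[, 1] <- radius * cos(ang)
    centers[, 2] <- radius * sin(ang)
  } else if (spec$arrangement == "sheet") {
    centers[, 1] <- (seq_len(k) - 1) * spec$spacing
  }
  dirs <- ifelse(seq_len(k) %% 2 == 1, 1, -1)  # antiparallel neighbors
  list(centers = centers, dirs = dirs)
}

#' Generate a synthetic toy protein
#'
#' Builds a designed native structure from ideal SSEs at the specified
#' placements, grows and CCD-closes its loops, and emits a matching
#' "perfect" prediction (probability 0.95 on the true state), the native
#' pool (exact native bounds) and a DSSP-style per-residue assignment.
#' Deterministic for a fixed seed.
#'
#' @param spec toy topology specification from [toyTopologySpec]
#' @param seed integer seed
#' @param predQuality probability assigned to the true state
#'   (default 0.95)
#' @return list with `sseModel` (SSE-only native), `completeModel`
#'   (loops built and closed), `closure` (loop closure report),
#'   `prediction` ([SSPrediction-class] with psipred and jufo slots),
#'   `pool` ([SSEPool-class]), `labels` (native per-residue states) and
#'   `nativeSses` (data.frame)
#' @export
generateToyProtein <- function(spec, seed = 1L, predQuality = 0.95) {
  saved <- .Random.seed_save()
  on.exit(.Random.seed_restore(saved))
  set.seed(seed)
  k <- length(spec$types)
  starts <- integer(k); ends <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + spec$lengths[i] - 1L
    pos <- ends[i] + 1L + if (i < k) spec$loopLength else 0L
  }
  n <- ends[k]
  labels <- rep("C", n)
  for (i in seq_len(k))
    labels[seq.int(starts[i], ends[i])] <-
      if (spec$types[i] == "helix") "H" else "E"

  # place the elements first with a placeholder sequence, then design an
  # amphipathic sequence: residues whose CB points toward the core get
  # hydrophobic types, exposed positions get polar ones (the composition
  # of natural bundles and sheets)
  pl <- toyPlacements(spec)
  placeholder <- strrep("L", n)
  # spins are chosen deterministically so that consecutive chain ends
  # face each other (tight, closable loops, as in natural bundles); the
  # small per-element grid offset keeps same-direction elements from
  # being exact translates of each other
  spins <- numeric(k)
  placed <- vector("list", k)
  placeAt <- function(i, spin)
    applyTransform(buildIdealSse(placeholder, starts[i], ends[i],
                                 spec$types[i]),
                   frameFromAxis(c(0, 0, pl$dirs[i]), pl$centers[i, ], spin))
  placed[[1]] <- placeAt(1, 0)
  for (i in seq_len(k)[-1]) {
    bestGap <- Inf
    for (sp in (0:35) * 10 + (i - 1) * 1.7) {
      cand <- placeAt(i, sp)
      prev <- placed[[i - 1]]
      np <- sseLength(prev)
      gapD <- norm3(prev@coords[(np - 1L) * N_ATOMS + 3L, ] - cand@coords[1L, ])
      if (gapD < bestGap) {
        bestGap <- gapD
        spins[i] <- sp
        placed[[i]] <- cand
      }
    }
  }
  core <- colMeans(t(vapply(placed, function(s) sseAxis(s)$center, numeric(3))))
  aa <- character(n)
  for (i in seq_len(k)) {
    ca <- atomCoords(placed[[i]], "CA")
    cb <- atomCoords(placed[[i]], "CB")
    for (r in seq_len(nrow(ca))) {
      toCore <- core - ca[r, ]
      toCore[3] <- 0  # radial burial only; the axis direction is neutral
      inward <- sum((cb[r, ] - ca[r, ]) * toCore) > 0
      aa[starts[i] + r - 1L] <-
        if (inward) sample(CORE_AAS, 1) else sample(SURF_AAS, 1)
    }
  }
  aa[labels == "C"] <- sample(LOOP_AAS, sum(labels == "C"), replace = TRUE)
  sequence <- paste(aa, collapse = "")

  sses <- vector("list", k)
  for (i in seq_len(k)) {
    frame <- frameFromAxis(c(0, 0, pl$dirs[i]), pl$centers[i, ],
                           spin = spins[i])
    sses[[i]] <- applyTransform(
      buildIdealSse(sequence, starts[i], ends[i], spec$types[i]), frame)
  }
  sseModel <- newModel(sequence, sses, provenance = "synthetic-toy")
  validObject(sseModel)
  # the spec must be closable after the loop builder's one-residue trim
  trimmed <- trimSses(sseModel)
  for (i in seq_len(length(trimmed@sses) - 1L)) {
    g <- chainBreakGap(trimmed, i)
    if (g$euclid > loopClosureLimit(g$nLoop))
      stop(sprintf("unclosable toy spec: loop %d gap %.1f A > limit %.1f A",
                   i, g$euclid, loopClosureLimit(g$nLoop)))
  }
  # the native must be complete: give the closure stage a generous
  # budget (the folding experiment itself uses the standard defaults)
  cfg <- defaultConfig()
  cfg$loops$max_sweeps <- 600L
  cfg$loops$force_rounds <- 12L
  built <- buildLoops(sseModel, cfg)

  col <- match(labels, SS_STATES)
  mk <- function() {
    p <- matrix((1 - predQuality) / 2, n, 3,
                dimnames = list(NULL, SS_STATES))
    p[cbind(seq_len(n), col)] <- predQuality
    p
  }
  prediction <- ssPrediction(psipred = mk(), jufo = mk(), sequence = sequence)

  pool <- new("SSEPool")
  pool@entries <- data.frame(type = spec$types, first = starts, last = ends,
                             source = "native", stringsAsFactors = FALSE)
  pool@sequence <- sequence
  pool@source <- "synthetic-native"
  validObject(pool)

  list(sseModel = sseModel, completeModel = built$model,
       closure = built$closure, prediction = prediction, pool = pool,
       labels = labels,
       nativeSses = data.frame(type = spec$types, first = starts,
                               last = ends, stringsAsFactors = FALSE))
}

#' Write a toy fixture bundle to a directory
#'
#' Emits the native SSE-only and complete models (PDB), the perfect
#' predictions (.ss2 and generic TSV), the native pool file and the
#' DSSP-style assignment, plus a manifest.
#'
#' @param toy result of [generateToyProtein]
#' @param dir output directory (created if missing)
#' @param seed seed recorded in the manifest
#' @return invisibly, the directory
#' @export
writeToySet <- function(toy, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePdbModel(toy$sseModel, file.path(dir, "native_sse.pdb"))
  writePdbModel(toy$completeModel, file.path(dir, "native_complete.pdb"))
  writePoolFile(toy$pool, file.path(dir, "native.pool"))
  writeAssignment(toy$labels, file.path(dir, "native.assign"))
  p <- toy$prediction@prob$psipred
  aa <- strsplit(toy$sseModel@sequence, "")[[1]]
  writeLines(sprintf("%d %s %s %6.3f %6.3f %6.3f",
                     seq_along(aa), aa, c(H = "H", E = "E", C = "C")[
                       SS_STATES[max.col(p)]],
                     p[, "C"], p[, "H"], p[, "E"]),
             file.path(dir, "toy.ss2"))
  j <- toy$prediction@prob$jufo
  writeLines(sprintf("%d\t%s\t%6.3f\t%6.3f\t%6.3f", seq_along(aa), aa,
                     j[, "H"], j[, "E"], j[, "C"]),
             file.path(dir, "toy_jufo.tsv"))
  writeManifest(file.path(dir, "manifest.txt"), seed, defaultConfig())
  invisible(dir)
}
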