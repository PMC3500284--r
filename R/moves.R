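# Move registry: six categories (add, remove, swap, single-SSE, SSE-pair,
# domain) with helix/strand/sheet specializations, stage-specific move
# sets with pool-dependent weights, and the propose() dispatcher.  Every
# move either returns a complete new model or the skipped marker; a move
# never returns a partially mutated model.

MOVE_AMPLITUDES <- list(large = list(trans = 8, rot = 90),
                        small = list(trans = 1.5, rot = 15))

randomUnitVector <- function() unit3(rnorm(3))

# random spin + axis-alignment frame: canonical +z -> dir, centroid -> center
frameFromAxis <- function(dir, center, spin = runif(1, 0, 360)) {
  dir <- unit3(dir)
  z <- c(0, 0, 1)
  ax <- cross3(z, dir)
  if (norm3(ax) < 1e-9) {
    R <- if (sum(z * dir) > 0) diag(3) else rtRotation(c(1, 0, 0), 180)@rotation
  } else {
    R <- rtRotation(ax, acos(max(-1, min(1, sum(z * dir)))) * 180 / pi)@rotation
  }
  spinR <- rtRotation(dir, spin)@rotation
  newRT(spinR %*% R, as.numeric(center))
}

randomPerpendicular <- function(dir) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(dir, ref))
  rtApply(rtRotation(dir, runif(1, 0, 360)), matrix(u, 1))[1, ]
}

idealPackingDistance <- function(t1, t2, const = energyConstants()) {
  key <- pairKey(t1, t2)
  if (key == "ss") const$strand_pair_ideal else const$packing_ideal[[key]]
}

# pool entries whose sequence range does not overlap any model SSE
poolCandidates <- function(model, pool) {
  e <- pool@entries
  if (!nrow(e)) return(e)
  ok <- rep(TRUE, nrow(e))
  for (s in model@sses)
    ok <- ok & (e$last < s@first | e$first > s@last)
  e[ok, , drop = FALSE]
}

entryToSse <- function(entry, sequence, frame) {
  applyTransform(fastIdealSse(sequence, entry$first, entry$last, entry$type),
                 frame)
}

pickIndex <- function(n) if (n == 1L) 1L else sample.int(n, 1L)
pickOne <- function(x) x[pickIndex(length(x))]

modelStrands <- function(model)
  which(vapply(model@sses, function(s) s@ssType == "strand", logical(1)))
modelHelices <- function(model)
  which(vapply(model@sses, function(s) s@ssType == "helix", logical(1)))

# strands chained by pairing distance < 6 A; transitive closure forms the
# sheet.  Returns the largest component with >= minSize members.
detectSheet <- function(model, minSize = 2L, maxPair = 6) {
  st <- modelStrands(model)
  if (length(st) < minSize) return(integer(0))
  k <- length(st)
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    d <- strandPairingDistance(model@sses[[st[i]]], model@sses[[st[j]]])
    adj[i, j] <- adj[j, i] <- d < maxPair
  }
  comp <- rep(0L, k); cid <- 0L
  for (i in seq_len(k)) {
    if (comp[i]) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  sizes <- tabulate(comp)
  best <- which.max(sizes)
  if (sizes[best] < minSize) return(integer(0))
  st[comp == best]
}

replaceSse <- function(model, idx, sse) {
  sses <- model@sses
  sses[[idx]] <- sse
  m <- model
  attr(m, "sses") <- sses  # bounds unchanged or guarded: order preserved
  m
}

modelCentroid <- function(model) colMeans(modelCaMatrix(model))

## ---- add moves ----------------------------------------------------------

moveAddSseRandom <- function(model, pool, amp) {
  cand <- poolCandidates(model, pool)
  if (!nrow(cand)) return(NULL)
  e <- cand[pickIndex(nrow(cand)), ]
  ctr <- modelCentroid(model)
  nRes <- length(modeledResidues(model)) + (e$last - e$first + 1L)
  radius <- max(10, 1.2 * energyConstants()$rg_coef * nRes^energyConstants()$rg_exp)
  pos <- ctr + randomUnitVector() * runif(1, 0, radius)
  frame <- frameFromAxis(randomUnitVector(), pos)
  newModel(model@sequence, c(model@sses, entryToSse(e, model@sequence, frame)),
           model@coil, model@provenance)
}

# place next to an existing SSE at the ideal packing distance, axis
# parallel or antiparallel to the base
placeAdjacent <- function(model, entry, baseIdx, dist = NULL) {
  base <- model@sses[[baseIdx]]
  ax <- sseAxis(base)
  if (is.null(dist)) dist <- idealPackingDistance(base@ssType, entry$type)
  offset <- randomPerpendicular(ax$direction) * dist
  dir <- ax$direction * sample(c(-1, 1), 1)
  frame <- frameFromAxis(dir, ax$center + offset)
  entryToSse(entry, model@sequence, frame)
}

moveAddSseNextToSse <- function(model, pool, amp) {
  cand <- poolCandidates(model, pool)
  if (!nrow(cand) || !length(model@sses)) return(NULL)
  e <- cand[pickIndex(nrow(cand)), ]
  sse <- placeAdjacent(model, e, pickIndex(length(model@sses)))
  newModel(model@sequence, c(model@sses, sse), model@coil, model@provenance)
}

moveAddSseShortLoop <- function(model, pool, amp, maxLoop = 7L) {
  cand <- poolCandidates(model, pool)
  if (!nrow(cand) || !length(model@sses)) return(NULL)
  bounds <- t(vapply(model@sses, function(s) c(s@first, s@last), integer(2)))
  opts <- NULL
  for (k in seq_len(nrow(cand))) {
    e <- cand[k, ]
    for (i in seq_along(model@sses)) {
      s <- model@sses[[i]]
      if (e$first > s@last) {
        nl <- e$first - s@last - 1L
        between <- any(bounds[, 1] > s@last & bounds[, 1] < e$first)
        if (nl <= maxLoop && !between)
          opts <- rbind(opts, c(k, i, 1L, nl))
      } else if (e$last < s@first) {
        nl <- s@first - e$last - 1L
        between <- any(bounds[, 2] < s@first & bounds[, 2] > e$last)
        if (nl <= maxLoop && !between)
          opts <- rbind(opts, c(k, i, -1L, nl))
      }
    }
  }
  if (is.null(opts)) return(NULL)
  o <- opts[pickIndex(nrow(opts)), ]
  e <- cand[o[1], ]; baseIdx <- o[2]; side <- o[3]; nl <- o[4]
  sse <- placeAdjacent(model, e, baseIdx)
  # enforce closability: pull the new SSE toward the anchor when needed
  base <- model@sses[[baseIdx]]
  nb <- sseLength(base)
  if (side > 0) {  # new SSE is downstream: C(base last) .. N(new first)
    anchor <- base@coords[(nb - 1L) * N_ATOMS + 3L, ]
    endpoint <- sse@coords[1L, ]
  } else {
    anchor <- base@coords[1L, ]
    nNew <- sseLength(sse)
    endpoint <- sse@coords[(nNew - 1L) * N_ATOMS + 3L, ]
  }
  limit <- 0.9 * loopClosureLimit(nl)
  gap <- endpoint - anchor
  if (norm3(gap) > limit)
    sse <- applyTransform(sse, rtTranslation(-(1 - limit / norm3(gap)) * gap))
  newModel(model@sequence, c(model@sses, sse), model@coil, model@provenance)
}

moveAddStrandNextToSheet <- function(model, pool, amp) {
  cand <- poolCandidates(model, pool)
  cand <- cand[cand$type == "strand", , drop = FALSE]
  st <- modelStrands(model)
  if (!nrow(cand) || !length(st)) return(NULL)
  sheet <- detectSheet(model)
  base <- if (length(sheet)) sheet[pickIndex(length(sheet))] else st[pickIndex(length(st))]
  e <- cand[pickIndex(nrow(cand)), ]
  sse <- placeAdjacent(model, e, base,
                       dist = energyConstants()$strand_pair_ideal)
  newModel(model@sequence, c(model@sses, sse), model@coil, model@provenance)
}

## ---- remove moves -------------------------------------------------------

moveRemoveRandom <- function(model, pool, amp) {
  if (length(model@sses) < 2L) return(NULL)
  i <- pickIndex(length(model@sses))
  newModel(model@sequence, model@sses[-i], model@coil, model@provenance)
}

moveRemoveUnpairedStrand <- function(model, pool, amp, maxPair = 6) {
  st <- modelStrands(model)
  if (!length(st) || length(model@sses) < 2L) return(NULL)
  unpaired <- st[vapply(st, function(i) {
    others <- setdiff(st, i)
    !length(others) || all(vapply(others, function(j)
      strandPairingDistance(model@sses[[i]], model@sses[[j]]) >= maxPair,
      logical(1)))
  }, logical(1))]
  if (!length(unpaired)) return(NULL)
  i <- unpaired[pickIndex(length(unpaired))]
  newModel(model@sequence, model@sses[-i], model@coil, model@provenance)
}

## ---- swap moves ---------------------------------------------------------

moveSwapSses <- function(model, pool, amp) {
  types <- vapply(model@sses, function(s) s@ssType, character(1))
  pairs <- NULL
  for (t in unique(types)) {
    idx <- which(types == t)
    if (length(idx) >= 2) pairs <- rbind(pairs, t(combn(idx, 2)))
  }
  if (is.null(pairs)) return(NULL)
  p <- pairs[pickIndex(nrow(pairs)), ]
  a <- model@sses[[p[1]]]; b <- model@sses[[p[2]]]
  newA <- placeIdealSse(model@sequence, a@first, a@last, a@ssType, b@frame)
  newB <- placeIdealSse(model@sequence, b@first, b@last, b@ssType, a@frame)
  m <- replaceSse(model, p[1], newA)
  replaceSse(m, p[2], newB)
}

moveSwapSseWithPool <- function(model, pool, amp) {
  e <- pool@entries
  opts <- NULL
  for (i in seq_along(model@sses)) {
    s <- model@sses[[i]]
    others <- model@sses[-i]
    for (k in seq_len(nrow(e))) {
      if (e$type[k] != s@ssType) next
      if (e$first[k] > s@last || e$last[k] < s@first) next       # must overlap
      if (e$first[k] == s@first && e$last[k] == s@last) next     # identical
      clash <- any(vapply(others, function(o)
        e$first[k] <= o@last && e$last[k] >= o@first, logical(1)))
      if (!clash) opts <- rbind(opts, c(i, k))
    }
  }
  if (is.null(opts)) return(NULL)
  o <- opts[pickIndex(nrow(opts)), ]
  s <- model@sses[[o[1]]]
  sse <- entryToSse(pool@entries[o[2], ], model@sequence, s@frame)
  replaceSse(model, o[1], sse)
}

## ---- single-SSE moves ---------------------------------------------------

moveSseTranslate <- function(model, pool, amp) {
  i <- pickIndex(length(model@sses))
  t <- rtTranslation(randomUnitVector() * runif(1, 0, amp$trans))
  replaceSse(model, i, applyTransform(model@sses[[i]], t))
}

moveSseRotate <- function(model, pool, amp) {
  i <- pickIndex(length(model@sses))
  s <- model@sses[[i]]
  t <- rtRotation(randomUnitVector(), runif(1, 0, amp$rot), sseAxis(s)$center)
  replaceSse(model, i, applyTransform(s, t))
}

moveSseTransform <- function(model, pool, amp) {
  i <- pickIndex(length(model@sses))
  s <- model@sses[[i]]
  t1 <- rtRotation(randomUnitVector(), runif(1, 0, amp$rot), sseAxis(s)$center)
  t2 <- rtTranslation(randomUnitVector() * runif(1, 0, amp$trans))
  replaceSse(model, i, applyTransform(s, rtCompose(t2, t1)))
}

moveStrandTranslateZ <- function(model, pool, amp) {
  st <- modelStrands(model)
  if (!length(st)) return(NULL)
  i <- st[pickIndex(length(st))]
  s <- model@sses[[i]]
  shift <- sseAxis(s)$direction * runif(1, -amp$trans, amp$trans)
  replaceSse(model, i, applyTransform(s, rtTranslation(shift)))
}

# resize one terminus by +/- 1 residue, preserving placed geometry of the
# retained residues (Kabsch fit of the rebuilt ideal segment)
moveSseResize <- function(model, pool, amp, terminus) {
  order <- sample(seq_along(model@sses))
  for (i in order) {
    s <- model@sses[[i]]
    for (delta in sample(c(-1L, 1L))) {
      first <- s@first; last <- s@last
      if (terminus == "nterm") first <- first - delta else last <- last + delta
      if (first < 1L || last > nchar(model@sequence)) next
      if (last - first + 1L < minSseLength(s@ssType)) next
      others <- model@sses[-i]
      if (any(vapply(others, function(o)
        first <= o@last && last >= o@first, logical(1)))) next
      shared <- seq.int(max(first, s@first), min(last, s@last))
      cand <- buildIdealSse(model@sequence, first, last, s@ssType)
      fit <- kabsch(backboneAtoms(cand, shared), backboneAtoms(s, shared))
      t <- new("RigidTransform", rotation = fit$rotation,
               translation = fit$translation)
      return(replaceSse(model, i, applyTransform(cand, t)))
    }
  }
  NULL
}

# N/CA/C coordinates of the given residue indices
backboneAtoms <- function(sse, residues) {
  rows <- unlist(lapply(residues - sse@first + 1L, function(r)
    (r - 1L) * N_ATOMS + 1:3))
  sse@coords[rows, , drop = FALSE]
}

moveSseSplit <- function(model, pool, amp) {
  ok <- which(vapply(model@sses, function(s)
    sseLength(s) >= 2L * minSseLength(s@ssType), logical(1)))
  if (!length(ok)) return(NULL)
  i <- ok[pickIndex(length(ok))]
  s <- model@sses[[i]]
  mn <- minSseLength(s@ssType)
  cut <- pickOne(seq.int(s@first + mn - 1L, s@last - mn))
  part <- function(first, last) {
    rows <- unlist(lapply(seq.int(first, last) - s@first + 1L, function(r)
      (r - 1L) * N_ATOMS + seq_len(N_ATOMS)))
    p <- newSSE(s@ssType, first, last,
                substring(model@sequence, first, last),
                s@coords[rows, , drop = FALSE], s@frame)
    p@frame <- deriveFrame(p)
    p
  }
  sses <- c(model@sses[-i], part(s@first, cut), part(cut + 1L, s@last))
  newModel(model@sequence, sses, model@coil, model@provenance)
}

## ---- SSE-pair moves -----------------------------------------------------

pickPair <- function(model) {
  ns <- length(model@sses)
  if (ns < 2L) return(NULL)
  p <- sample.int(ns, 2L)
  sort(p)
}

moveSsePairTranslate <- function(model, pool, amp) {
  p <- pickPair(model)
  if (is.null(p)) return(NULL)
  t <- rtTranslation(randomUnitVector() * runif(1, 0, amp$trans))
  m <- replaceSse(model, p[1], applyTransform(model@sses[[p[1]]], t))
  replaceSse(m, p[2], applyTransform(m@sses[[p[2]]], t))
}

moveSsePairRotateHinge <- function(model, pool, amp) {
  p <- pickPair(model)
  if (is.null(p)) return(NULL)
  moved <- p[1]; hinge <- p[2]
  ax <- sseAxis(model@sses[[hinge]])
  t <- rtRotation(ax$direction, runif(1, -amp$rot, amp$rot), ax$center)
  replaceSse(model, moved, applyTransform(model@sses[[moved]], t))
}

moveSheetPairStrands <- function(model, pool, amp, maxPair = 6) {
  st <- modelStrands(model)
  if (length(st) < 2L) return(NULL)
  pairs <- t(combn(st, 2))
  far <- pairs[apply(pairs, 1, function(p)
    strandPairingDistance(model@sses[[p[1]]], model@sses[[p[2]]]) >= maxPair),
    , drop = FALSE]
  if (!nrow(far)) return(NULL)
  p <- far[pickIndex(nrow(far)), ]
  base <- model@sses[[p[2]]]
  ax <- sseAxis(base)
  offset <- randomPerpendicular(ax$direction) * energyConstants()$strand_pair_ideal
  dir <- ax$direction * sample(c(-1, 1), 1)
  s <- model@sses[[p[1]]]
  frame <- frameFromAxis(dir, ax$center + offset)
  replaceSse(model, p[1],
             placeIdealSse(model@sequence, s@first, s@last, s@ssType, frame))
}

## ---- domain moves -------------------------------------------------------

applyToSses <- function(model, idx, t) {
  sses <- model@sses
  for (i in idx) sses[[i]] <- applyTransform(sses[[i]], t)
  m <- model
  attr(m, "sses") <- sses
  m
}

sheetGeometry <- function(model, sheet) {
  dirs <- lapply(model@sses[sheet], function(s) sseAxis(s)$direction)
  ref <- dirs[[1]]
  axis <- Reduce(`+`, lapply(dirs, function(d) if (sum(d * ref) < 0) -d else d))
  centers <- t(vapply(model@sses[sheet], function(s) sseAxis(s)$center,
                      numeric(3)))
  list(axis = unit3(axis), centers = centers,
       centroid = colMeans(centers))
}

moveDomainFlipSheet <- function(model, pool, amp) {
  sheet <- detectSheet(model, minSize = 2L)
  if (length(sheet) < 2L) return(NULL)
  g <- sheetGeometry(model, sheet)
  applyToSses(model, sheet, rtRotation(g$axis, 180, g$centroid))
}

moveDomainShuffleSheet <- function(model, pool, amp) {
  sheet <- detectSheet(model, minSize = 2L)
  if (length(sheet) < 2L) return(NULL)
  p <- sample(sheet, 2L)
  a <- model@sses[[p[1]]]; b <- model@sses[[p[2]]]
  m <- replaceSse(model, p[1],
                  placeIdealSse(model@sequence, a@first, a@last, a@ssType, b@frame))
  replaceSse(m, p[2],
             placeIdealSse(model@sequence, b@first, b@last, b@ssType, a@frame))
}

moveDomainTranslate <- function(model, pool, amp) {
  sheet <- detectSheet(model, minSize = 2L)
  idx <- if (length(sheet) >= 2L) sheet else {
    if (length(model@sses) < 2L) return(NULL)
    sample.int(length(model@sses), 2L)
  }
  applyToSses(model, idx,
              rtTranslation(randomUnitVector() * runif(1, 0, amp$trans)))
}

moveHelixDomainTranslate <- function(model, pool, amp) {
  hx <- modelHelices(model)
  if (length(hx) < 2L) return(NULL)
  applyToSses(model, hx,
              rtTranslation(randomUnitVector() * runif(1, 0, amp$trans)))
}

moveSheetDivide <- function(model, pool, amp) {
  sheet <- detectSheet(model, minSize = 4L)
  if (length(sheet) < 4L) return(NULL)
  g <- sheetGeometry(model, sheet)
  rel <- sweep(g$centers, 2, g$centroid)
  across <- svd(rel)$v[, 1]
  proj <- rel %*% across
  half <- sheet[proj > stats::median(proj)]
  if (!length(half) || length(half) == length(sheet))
    half <- sheet[seq_len(length(sheet) %/% 2)]
  normal <- unit3(cross3(g$axis, across))
  applyToSses(model, half, rtTranslation(normal * 10))
}

## ---- registry and move sets ---------------------------------------------

#' The move registry
#'
#' All implemented move behaviors with their category, stage, amplitude
#' class and specialization flags.  Strand/sheet-specific moves receive
#' probability zero when the pool contains no strands, helix-domain moves
#' when it contains no helices.
#'
#' @return data.frame with columns name, category, stage, amplitude,
#'   strandSpecific, helixSpecific
#' @export
moveRegistry <- function() {
  reg <- function(name, category, stage, amplitude, strand = FALSE,
                  helix = FALSE)
    data.frame(name = name, category = category, stage = stage,
               amplitude = amplitude, strandSpecific = strand,
               helixSpecific = helix, stringsAsFactors = FALSE)
  rbind(
    reg("add_sse_random", "add", "assembly", "large"),
    reg("add_sse_next_to_sse", "add", "assembly", "large"),
    reg("add_sse_short_loop", "add", "assembly", "large"),
    reg("add_strand_next_to_sheet", "add", "assembly", "large", strand = TRUE),
    reg("remove_random", "remove", "assembly", "large"),
    reg("remove_unpaired_strand", "remove", "assembly", "large", strand = TRUE),
    reg("swap_sses", "swap", "assembly", "large"),
    reg("swap_sse_with_pool", "swap", "assembly", "large"),
    reg("sse_translate_large", "single_sse", "assembly", "large"),
    reg("sse_rotate_large", "single_sse", "assembly", "large"),
    reg("sse_transform_large", "single_sse", "assembly", "large"),
    reg("sse_split", "single_sse", "assembly", "large"),
    reg("sse_resize_nterm", "single_sse", "both", "both"),
    reg("sse_resize_cterm", "single_sse", "both", "both"),
    reg("sse_pair_translate_large", "sse_pair", "assembly", "large"),
    reg("sse_pair_rotate_hinge_large", "sse_pair", "assembly", "large"),
    reg("sheet_pair_strands", "sse_pair", "assembly", "large", strand = TRUE),
    reg("domain_translate_large", "domain", "assembly", "large"),
    reg("helix_domain_translate", "domain", "assembly", "large", helix = TRUE),
    reg("domain_shuffle_sheet", "domain", "assembly", "large", strand = TRUE),
    reg("domain_flip_sheet", "domain", "assembly", "large", strand = TRUE),
    reg("sheet_divide", "domain", "assembly", "large", strand = TRUE),
    reg("sse_translate_small", "single_sse", "refinement", "small"),
    reg("sse_rotate_small", "single_sse", "refinement", "small"),
    reg("sse_transform_small", "single_sse", "refinement", "small"),
    reg("strand_translate_z_small", "single_sse", "refinement", "small",
        strand = TRUE),
    reg("sse_pair_translate_small", "sse_pair", "refinement", "small"),
    reg("sse_pair_rotate_hinge_small", "sse_pair", "refinement", "small"),
    reg("domain_translate_small", "domain", "refinement", "small"))
}

moveBehaviors <- function() {
  list(
    add_sse_random = moveAddSseRandom,
    add_sse_next_to_sse = moveAddSseNextToSse,
    add_sse_short_loop = moveAddSseShortLoop,
    add_strand_next_to_sheet = moveAddStrandNextToSheet,
    remove_random = moveRemoveRandom,
    remove_unpaired_strand = moveRemoveUnpairedStrand,
    swap_sses = moveSwapSses,
    swap_sse_with_pool = moveSwapSseWithPool,
    sse_translate_large = moveSseTranslate,
    sse_rotate_large = moveSseRotate,
    sse_transform_large = moveSseTransform,
    sse_split = moveSseSplit,
    sse_resize_nterm = function(m, p, a) moveSseResize(m, p, a, "nterm"),
    sse_resize_cterm = function(m, p, a) moveSseResize(m, p, a, "cterm"),
    sse_pair_translate_large = moveSsePairTranslate,
    sse_pair_rotate_hinge_large = moveSsePairRotateHinge,
    sheet_pair_strands = moveSheetPairStrands,
    domain_translate_large = moveDomainTranslate,
    helix_domain_translate = moveHelixDomainTranslate,
    domain_shuffle_sheet = moveDomainShuffleSheet,
    domain_flip_sheet = moveDomainFlipSheet,
    sheet_divide = moveSheetDivide,
    sse_translate_small = moveSseTranslate,
    sse_rotate_small = moveSseRotate,
    sse_transform_small = moveSseTransform,
    strand_translate_z_small = moveStrandTranslateZ,
    sse_pair_translate_small = moveSsePairTranslate,
    sse_pair_rotate_hinge_small = moveSsePairRotateHinge,
    domain_translate_small = moveDomainTranslate)
}

#' Build a stage-specific move set
#'
#' Selects the registry moves for the stage (resize moves participate in
#' both stages), zeroes strand/sheet-specific moves when the pool
#' contains no strands and helix-domain moves when it contains no
#' helices, splits the configured category weights equally among the
#' remaining moves of each category, and renormalizes so the selection
#' probabilities sum to 1.
#'
#' @param pool a non-empty [SSEPool-class]
#' @param stage "assembly" or "refinement"
#' @param config run configuration (see [defaultConfig]); uses
#'   `config$moves`
#' @return data.frame of moves with a `prob` column summing to 1
#' @export
buildMoveSet <- function(pool, stage = c("assembly", "refinement"),
                         config = defaultConfig()) {
  stage <- match.arg(stage)
  if (!nrow(pool@entries)) stop("empty pool")
  reg <- moveRegistry()
  reg <- reg[reg$stage == stage | reg$stage == "both", , drop = FALSE]
  hasStrand <- any(pool@entries$type == "strand")
  hasHelix <- any(pool@entries$type == "helix")
  excluded <- (reg$strandSpecific & !hasStrand) |
              (reg$helixSpecific & !hasHelix)
  catW <- config$moves$category_weights[[stage]]
  # resize moves share the single-SSE category in assembly but carry
  # their own category weight in refinement
  effCat <- reg$category
  if (stage == "refinement") effCat[reg$stage == "both"] <- "resize"
  reg$prob <- 0
  for (cat in unique(effCat)) {
    inCat <- effCat == cat & !excluded
    w <- catW[[cat]]
    if (is.null(w)) w <- 0
    if (any(inCat)) reg$prob[inCat] <- w / sum(inCat)
  }
  if (sum(reg$prob) <= 0) stop("no applicable moves for stage ", stage)
  reg$prob <- reg$prob / sum(reg$prob)
  reg$stage <- stage
  rownames(reg) <- NULL
  reg
}

#' Propose a move
#'
#' Applies the named move behavior to a model.  Returns either a valid
#' new model (the input model is never modified) or the skipped marker
#' when the move's structural prerequisites are absent.
#'
#' @param move a move name from [moveRegistry] (or a one-row move-set
#'   data.frame)
#' @param model a [ProteinModel-class]
#' @param pool an [SSEPool-class]
#' @param config run configuration (amplitudes)
#' @return list with `model` (or NULL) and logical `skipped`
#' @export
propose <- function(move, model, pool, config = defaultConfig()) {
  if (is.data.frame(move)) {
    name <- move$name[1]; ampClass <- move$amplitude[1]
  } else {
    name <- move
    reg <- moveRegistry()
    ampClass <- reg$amplitude[match(name, reg$name)]
    if (is.na(ampClass)) stop("unknown move: ", name)
  }
  fn <- moveBehaviors()[[name]]
  if (is.null(fn)) stop("unknown move: ", name)
  if (ampClass == "both") ampClass <- "small"  # resize moves take no amplitude
  amp <- config$moves$amplitudes[[ampClass]]
  out <- fn(model, pool, amp)
  if (is.null(out)) list(model = NULL, skipped = TRUE)
  else list(model = out, skipped = FALSE)
}
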