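# Loop building: trim SSE termini, grow missing loop residues with
# Ramachandran-biased dihedrals, close chain breaks by cyclic coordinate
# descent (closed-form per-dihedral minimization of the downstream
# anchor RMSD), and force-close stubborn loops by re-growing.

#' Analytic Ramachandran tables
#'
#' Discretized (phi, psi) probability grids (10 degree bins) for coil
#' states, built from Gaussian mixtures around the canonical basins
#' (beta, right- and left-handed alpha).  Glycine gets broader, partly
#' mirrored basins and proline a restricted phi.  Each grid sums to 1.
#'
#' @return named list (general, glycine, proline) of 36 x 36 probability
#'   matrices; row/col names give bin centers
#' @export
ramachandranTable <- function() {
  centers <- seq(-175, 175, by = 10)
  wrap <- function(x) ((x + 180) %% 360) - 180
  mixture <- function(basins) {
    g <- matrix(0, 36, 36, dimnames = list(centers, centers))
    for (b in basins) {
      dphi <- outer(wrap(centers - b$phi), rep(1, 36))
      dpsi <- outer(rep(1, 36), wrap(centers - b$psi))
      g <- g + b$w * exp(-0.5 * ((dphi / b$sphi)^2 + (dpsi / b$spsi)^2))
    }
    g / sum(g)
  }
  list(
    general = mixture(list(
      list(phi = -120, psi = 130, sphi = 30, spsi = 30, w = 0.45),
      list(phi = -63, psi = -43, sphi = 15, spsi = 15, w = 0.40),
      list(phi = 60, psi = 45, sphi = 15, spsi = 15, w = 0.15))),
    glycine = mixture(list(
      list(phi = -120, psi = 130, sphi = 40, spsi = 40, w = 0.30),
      list(phi = 120, psi = -130, sphi = 40, spsi = 40, w = 0.20),
      list(phi = -63, psi = -43, sphi = 25, spsi = 25, w = 0.25),
      list(phi = 63, psi = 43, sphi = 25, spsi = 25, w = 0.25))),
    proline = mixture(list(
      list(phi = -63, psi = 150, sphi = 10, spsi = 20, w = 0.60),
      list(phi = -63, psi = -35, sphi = 10, spsi = 20, w = 0.40))))
}

ramaForAa <- function(aa, rama) {
  if (aa == "G") rama$glycine else if (aa == "P") rama$proline
  else rama$general
}

# one (phi, psi) draw from a grid: sample a bin, then uniform in the bin
sampleDihedralPair <- function(grid) {
  k <- sample.int(length(grid), 1L, prob = as.vector(grid))
  i <- (k - 1L) %% 36L + 1L
  j <- (k - 1L) %/% 36L + 1L
  centers <- as.numeric(rownames(grid))
  c(phi = centers[i] + runif(1, -5, 5), psi = centers[j] + runif(1, -5, 5))
}

dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Trim one residue from each SSE terminus
#'
#' Shortens every SSE by one residue at each end (coordinates of
#' retained residues unchanged) to increase the chance of closing the
#' connecting loops.  SSEs that would fall below their minimum length
#' are left untrimmed.  Not idempotent: each call trims again.
#'
#' @param model a [ProteinModel-class]
#' @return trimmed [ProteinModel-class]
#' @export
trimSses <- function(model) {
  sses <- lapply(model@sses, function(s) {
    n <- sseLength(s)
    if (n < minSseLength(s@ssType) + 2L) return(s)
    rows <- seq.int(N_ATOMS + 1L, (n - 1L) * N_ATOMS)
    out <- newSSE(s@ssType, s@first + 1L, s@last - 1L,
                  substring(s@aaSeq, 2L, n - 1L),
                  s@coords[rows, , drop = FALSE], s@frame)
    out@frame <- deriveFrame(out)
    out
  })
  newModel(model@sequence, sses, model@coil, model@provenance)
}

# residue gaps of a model: list of (residues, upstream sse idx or NA,
# downstream sse idx or NA)
modelGaps <- function(model) {
  if (!length(model@sses)) stop("model has no SSEs")
  b <- t(vapply(model@sses, function(s) c(s@first, s@last), integer(2)))
  n <- nchar(model@sequence)
  gaps <- list()
  if (b[1, 1] > 1)
    gaps <- c(gaps, list(list(residues = seq_len(b[1, 1] - 1L),
                              up = NA_integer_, down = 1L)))
  if (nrow(b) > 1) {
    for (i in seq_len(nrow(b) - 1L)) {
      if (b[i + 1, 1] - b[i, 2] > 1L)
        gaps <- c(gaps, list(list(residues = seq.int(b[i, 2] + 1L, b[i + 1, 1] - 1L),
                                  up = i, down = i + 1L)))
      else
        gaps <- c(gaps, list(list(residues = integer(0), up = i, down = i + 1L)))
    }
  }
  if (b[nrow(b), 2] < n)
    gaps <- c(gaps, list(list(residues = seq.int(b[nrow(b), 2] + 1L, n),
                              up = nrow(b), down = NA_integer_)))
  gaps
}

sseResidueAtoms <- function(sse, resIdx) {
  r <- resIdx - sse@first + 1L
  sse@coords[(r - 1L) * N_ATOMS + seq_len(N_ATOMS), , drop = FALSE]
}

# forward-build loop backbone (N, CA, C per residue) plus the mobile
# downstream anchor triple, from the upstream anchor residue's N/CA/C
# and a dihedral vector c(psiU, phi1, psi1, ..., phiK, psiK).
buildLoopForward <- function(anchor, dihedrals, k, phiDown) {
  atoms <- matrix(NA_real_, 3L * (k + 1L), 3L)
  aPrev <- anchor  # rows N, CA, C of the previous residue
  pos <- 0L
  psiPrev <- dihedrals[1]
  di <- 1L
  for (r in seq_len(k + 1L)) {
    nNew <- placeAtom(aPrev[1, ], aPrev[2, ], aPrev[3, ], BOND_C_N,
                      ANGLE_CA_C_N, psiPrev)
    caNew <- placeAtom(aPrev[2, ], aPrev[3, ], nNew, BOND_N_CA,
                       ANGLE_C_N_CA, 180)
    phi <- if (r <= k) dihedrals[di + 1L] else phiDown
    cNew <- placeAtom(aPrev[3, ], nNew, caNew, BOND_CA_C, ANGLE_N_CA_C, phi)
    atoms[pos + 1:3, ] <- rbind(nNew, caNew, cNew)
    pos <- pos + 3L
    aPrev <- rbind(nNew, caNew, cNew)
    if (r <= k) {
      psiPrev <- dihedrals[di + 2L]
      di <- di + 2L
    }
  }
  atoms
}

# backward growth for N-terminal tails: given the downstream residue's
# (N, CA, C), build preceding residues
buildLoopBackward <- function(anchor, dihedrals, k) {
  atoms <- matrix(NA_real_, 3L * k, 3L)
  aNext <- anchor
  phiNext <- dihedrals[1]
  di <- 1L
  for (r in seq_len(k)) {
    cNew <- placeAtom(aNext[3, ], aNext[2, ], aNext[1, ], BOND_C_N,
                      ANGLE_C_N_CA, phiNext)
    caNew <- placeAtom(aNext[2, ], aNext[1, ], cNew, BOND_CA_C,
                       ANGLE_CA_C_N, 180)
    psi <- dihedrals[di + 1L]
    nNew <- placeAtom(aNext[1, ], cNew, caNew, BOND_N_CA, ANGLE_N_CA_C, psi)
    row <- 3L * (k - r)
    atoms[row + 1:3, ] <- rbind(nNew, caNew, cNew)
    aNext <- rbind(nNew, caNew, cNew)
    phiNext <- dihedrals[di + 2L]
    di <- di + 2L
  }
  atoms
}

randomLoopDihedrals <- function(aaTypes, rama, leadPsi = TRUE) {
  d <- numeric(0)
  if (leadPsi) d <- runif(1, -180, 180)
  for (aa in aaTypes) {
    pair <- sampleDihedralPair(ramaForAa(aa, rama))
    d <- c(d, pair)
  }
  unname(d)
}

# stepwise closure-biased growth: per residue, a handful of Ramachandran
# draws are tried and the one keeping the downstream anchor within
# comfortable reach of the remaining residues is kept.  Returns the
# mobile atom matrix (loop residues + mobile anchor triple).
growLoopBiased <- function(anchor, target, aaTypes, rama, phiDown,
                           nTry = 12L) {
  k <- length(aaTypes)
  atoms <- matrix(NA_real_, 3L * (k + 1L), 3L)
  aPrev <- anchor
  psiPrev <- runif(1, -180, 180)
  for (r in seq_len(k + 1L)) {
    if (r <= k) {
      grid <- ramaForAa(aaTypes[r], rama)
      best <- NULL; bestPen <- Inf; bestPair <- NULL
      for (tr in seq_len(nTry)) {
        pair <- sampleDihedralPair(grid)
        psiCand <- if (r == 1L) runif(1, -180, 180) else psiPrev
        nNew <- placeAtom(aPrev[1, ], aPrev[2, ], aPrev[3, ], BOND_C_N,
                          ANGLE_CA_C_N, psiCand)
        caNew <- placeAtom(aPrev[2, ], aPrev[3, ], nNew, BOND_N_CA,
                           ANGLE_C_N_CA, 180)
        cNew <- placeAtom(aPrev[3, ], nNew, caNew, BOND_CA_C,
                          ANGLE_N_CA_C, pair["phi"])
        mRem <- k - r + 1L
        d <- norm3(cNew - target[1, ])
        pen <- max(0, d - 1.0 * mRem)^2 + 0.5 * d
        if (pen < bestPen) {
          bestPen <- pen
          best <- rbind(nNew, caNew, cNew)
          bestPair <- pair
        }
      }
      atoms[3L * (r - 1L) + 1:3, ] <- best
      aPrev <- best
      psiPrev <- bestPair["psi"]
    } else {
      nNew <- placeAtom(aPrev[1, ], aPrev[2, ], aPrev[3, ], BOND_C_N,
                        ANGLE_CA_C_N, psiPrev)
      caNew <- placeAtom(aPrev[2, ], aPrev[3, ], nNew, BOND_N_CA,
                         ANGLE_C_N_CA, 180)
      cNew <- placeAtom(aPrev[3, ], nNew, caNew, BOND_CA_C, ANGLE_N_CA_C,
                        phiDown)
      atoms[3L * (r - 1L) + 1:3, ] <- rbind(nNew, caNew, cNew)
    }
  }
  atoms
}

# place O and CB for loop residues from final backbone geometry
completeLoopResidues <- function(atoms, residues, aaTypes, nextN) {
  out <- list()
  k <- length(residues)
  for (r in seq_len(k)) {
    nA <- atoms[3 * (r - 1) + 1, ]; caA <- atoms[3 * (r - 1) + 2, ]
    cA <- atoms[3 * (r - 1) + 3, ]
    nNext <- if (r < k) atoms[3 * r + 1, ] else nextN
    psi <- if (!is.null(nNext)) dihedralAngle(nA, caA, cA, nNext) else -40
    o <- placeAtom(nA, caA, cA, BOND_C_O, ANGLE_CA_C_O, psi + 180)
    bb <- if (aaTypes[r] == "G") BOND_CA_HA else BOND_CA_CB
    cb <- placeAtom(cA, nA, caA, bb, ANGLE_N_CA_CB, DIHEDRAL_CB)
    m <- rbind(nA, caA, cA, o, cb)
    rownames(m) <- ATOM_NAMES
    out[[as.character(residues[r])]] <- m
  }
  out
}

# quick candidate score: CB clash against the model + compactness of the
# loop + closure bias (anchor gap distance)
candidateScore <- function(atoms, k, modelCb, target) {
  score <- 0
  if (k > 0) {
    ca <- atoms[3 * seq_len(k) - 1, , drop = FALSE]
    for (r in seq_len(nrow(ca))) {
      d <- sqrt(rowSums(sweep(modelCb, 2, ca[r, ])^2))
      score <- score + 10 * sum(pmax(0, 3 - d)^2)
    }
  }
  if (!is.null(target)) {
    mobileAnchor <- atoms[nrow(atoms) - 2:0, , drop = FALSE]
    score <- score + sqrt(mean(rowSums((mobileAnchor - target)^2)))
  }
  score
}

#' Grow missing loop residues
#'
#' Adds every unmodeled residue to the model with (phi, psi) angles
#' drawn from the Ramachandran table of the residue's amino acid type.
#' Per loop, `nCandidates` dihedral sets are sampled and the one with the
#' best combined clash + closure-bias score is kept.  Interior loops are
#' grown from the N-terminal anchor toward the C-terminal anchor;
#' terminal tails are grown outward without a closure target.  SSE atoms
#' are never moved.
#'
#' @param model a (typically trimmed) [ProteinModel-class]
#' @param rama Ramachandran tables from [ramachandranTable]
#' @param nCandidates candidate dihedral sets per loop (default 20)
#' @return [ProteinModel-class] with all residues present
#' @export
growLoops <- function(model, rama = ramachandranTable(), nCandidates = 20L) {
  aa <- strsplit(model@sequence, "")[[1]]
  tab <- modelCbTable(model)
  coil <- model@coil
  for (gap in modelGaps(model)) {
    k <- length(gap$residues)
    if (k == 0L) next
    aaTypes <- aa[gap$residues]
    if (is.na(gap$up)) {
      # N-terminal tail, grown backward from the first SSE
      anchor <- sseResidueAtoms(model@sses[[gap$down]],
                                model@sses[[gap$down]]@first)[1:3, ]
      best <- NULL; bestScore <- Inf
      for (cand in seq_len(nCandidates)) {
        d <- randomLoopDihedrals(rev(aaTypes), rama, leadPsi = TRUE)
        atoms <- buildLoopBackward(anchor, d, k)
        sc <- candidateScore(atoms, k, tab$cb, NULL)
        if (sc < bestScore) { best <- atoms; bestScore <- sc }
      }
      coil <- c(coil, completeLoopResidues(best, gap$residues, aaTypes,
                                           anchor[1, ]))
    } else {
      up <- model@sses[[gap$up]]
      anchor <- sseResidueAtoms(up, up@last)[1:3, ]
      target <- NULL; phiDown <- -57
      if (!is.na(gap$down)) {
        down <- model@sses[[gap$down]]
        target <- sseResidueAtoms(down, down@first)[1:3, ]
        phiDown <- IDEAL_DIHEDRALS[[down@ssType]]["phi"]
      }
      best <- NULL; bestScore <- Inf
      for (cand in seq_len(nCandidates)) {
        atoms <- if (is.null(target))
          buildLoopForward(anchor, randomLoopDihedrals(aaTypes, rama), k,
                           phiDown)
        else
          growLoopBiased(anchor, target, aaTypes, rama, phiDown)
        sc <- candidateScore(atoms, k, tab$cb, target)
        if (sc < bestScore) { best <- atoms; bestScore <- sc }
      }
      nextN <- if (!is.na(gap$down)) target[1, ] else NULL
      coil <- c(coil, completeLoopResidues(best[seq_len(3 * k), , drop = FALSE],
                                           gap$residues, aaTypes, nextN))
    }
  }
  out <- newModel(model@sequence, model@sses, coil, model@provenance)
  validObject(out)
  out
}

# ---- cyclic coordinate descent ------------------------------------------

# optimal rotation angle (degrees) about axis (point p, unit u) moving
# mobile points toward fixed targets
ccdOptimalAngle <- function(mobile, targets, p, u) {
  a <- 0; b <- 0
  for (i in seq_len(nrow(mobile))) {
    w <- mobile[i, ] - p
    o <- p + sum(w * u) * u
    r <- mobile[i, ] - o
    nr <- norm3(r)
    if (nr < 1e-9) next
    rhat <- r / nr
    shat <- cross3(u, rhat)
    f <- targets[i, ] - o
    a <- a + nr * sum(f * rhat)
    b <- b + nr * sum(f * shat)
  }
  atan2(b, a) * 180 / pi
}

rotatePoints <- function(x, p, u, angle) {
  rtApply(rtRotation(u, angle, p), x)
}

# close one loop: mobile = loop backbone + mobile anchor triple (already
# positioned); anchor = upstream N/CA/C; target = downstream N/CA/C.
# Dihedral axes: psiU (CA_u -> C_u), then phi/psi of each loop residue;
# each axis is taken from the CURRENT atom positions so every per-dihedral
# update is exactly the closed-form optimum.
ccdLoop <- function(atoms, anchor, target, k, tolerance, maxSweeps) {
  nr <- nrow(atoms)
  mobileRows <- nr - 2:0
  anchorRmsd <- function()
    sqrt(mean(rowSums((atoms[mobileRows, , drop = FALSE] - target)^2)))
  nDih <- 2L + 2L * k  # psiU, (phi, psi) per loop residue, phi of the anchor
  oneSweep <- function(first) {
    # randomized dihedral order: each update is still the per-dihedral
    # optimum, so the anchor RMSD stays non-increasing per sweep, but
    # cyclic stalls of a fixed order are escaped
    order <- if (first) seq_len(nDih) else sample.int(nDih)
    for (d in order) {
      if (d == 1L) {
        p <- anchor[2, ]; q <- anchor[3, ]; fromRow <- 1L
      } else if (d == nDih) {
        # phi of the downstream anchor residue: rotates its mobile C
        p <- atoms[nr - 2L, ]; q <- atoms[nr - 1L, ]; fromRow <- nr
      } else {
        r <- (d - 2L) %/% 2L          # 0-based loop residue index
        nRow <- 3L * r + 1L
        if (d %% 2L == 0L) {          # phi: N -> CA, moves C onward
          p <- atoms[nRow, ]; q <- atoms[nRow + 1L, ]; fromRow <- nRow + 2L
        } else {                      # psi: CA -> C, moves next N onward
          p <- atoms[nRow + 1L, ]; q <- atoms[nRow + 2L, ]; fromRow <- nRow + 3L
        }
      }
      u <- unit3(q - p)
      theta <- ccdOptimalAngle(atoms[mobileRows, , drop = FALSE],
                               target, p, u)
      if (abs(theta) < 1e-10) next
      rows <- seq.int(fromRow, nr)
      atoms[rows, ] <<- rotatePoints(atoms[rows, , drop = FALSE], p, u, theta)
    }
  }
  rmsd <- anchorRmsd()
  trace <- rmsd
  sweeps <- 0L
  while (rmsd > tolerance && sweeps < maxSweeps) {
    sweeps <- sweeps + 1L
    oneSweep(sweeps == 1L)
    rmsd <- anchorRmsd()
    trace <- c(trace, rmsd)
  }
  # post-convergence polish: a few extra (still monotone) sweeps push the
  # anchor safely below the threshold so a closed loop re-enters CCD
  # without re-triggering
  if (rmsd <= tolerance) {
    for (p in seq_len(15L)) {
      if (sweeps >= maxSweeps || rmsd <= 0.85 * tolerance) break
      prev <- rmsd
      sweeps <- sweeps + 1L
      oneSweep(FALSE)
      rmsd <- anchorRmsd()
      trace <- c(trace, rmsd)
      if (rmsd > 0.995 * prev) break
    }
  }
  list(atoms = atoms, rmsd = rmsd, sweeps = sweeps, trace = trace)
}

# rebuild the mobile atom matrix for an interior loop from current coil
loopMobileAtoms <- function(model, gap) {
  k <- length(gap$residues)
  rows <- matrix(NA_real_, 3L * (k + 1L), 3L)
  for (r in seq_len(k)) {
    m <- model@coil[[as.character(gap$residues[r])]]
    rows[3L * (r - 1L) + 1:3, ] <- m[1:3, ]
  }
  down <- model@sses[[gap$down]]
  up <- model@sses[[gap$up]]
  anchor <- sseResidueAtoms(up, up@last)[1:3, ]
  # mobile anchor triple continued from the loop end (or the upstream
  # anchor directly when the loop is empty)
  aPrev <- if (k > 0) rows[3L * (k - 1L) + 1:3, ] else anchor
  # seed the mobile anchor with ideal geometry, psi chosen to point the
  # new N toward its true position (CCD then refines all dihedrals)
  target <- sseResidueAtoms(down, down@first)[1:3, ]
  psi <- dihedralAngle(aPrev[1, ], aPrev[2, ], aPrev[3, ], target[1, ])
  nNew <- placeAtom(aPrev[1, ], aPrev[2, ], aPrev[3, ], BOND_C_N,
                    ANGLE_CA_C_N, psi)
  caNew <- placeAtom(aPrev[2, ], aPrev[3, ], nNew, BOND_N_CA, ANGLE_C_N_CA, 180)
  phiDown <- IDEAL_DIHEDRALS[[down@ssType]]["phi"]
  cNew <- placeAtom(aPrev[3, ], nNew, caNew, BOND_CA_C, ANGLE_N_CA_C, phiDown)
  triple <- rbind(nNew, caNew, cNew)
  # refine the seeding psi (whole triple) and the anchor phi (its C
  # atom) with the closed-form optima so that re-entering an
  # already-closed loop starts at or below its converged anchor RMSD
  u <- unit3(aPrev[3, ] - aPrev[2, ])
  theta <- ccdOptimalAngle(triple, target, aPrev[2, ], u)
  if (abs(theta) > 1e-12)
    triple <- rotatePoints(triple, aPrev[2, ], u, theta)
  u2 <- unit3(triple[2, ] - triple[1, ])
  theta2 <- ccdOptimalAngle(triple, target, triple[1, ], u2)
  if (abs(theta2) > 1e-12)
    triple[3, ] <- rotatePoints(triple[3, , drop = FALSE], triple[1, ],
                                u2, theta2)[1, ]
  rows[3L * k + 1:3, ] <- triple
  list(atoms = rows, anchor = anchor, target = target, k = k)
}

#' Close loops by cyclic coordinate descent
#'
#' For each interior loop, iterates over the adjustable dihedrals (the
#' upstream anchor's psi and each loop residue's phi and psi), setting
#' each in turn to the closed-form angle that minimizes the RMSD of the
#' mobile downstream anchor triple (N, CA, C of the first residue of the
#' downstream SSE) to its fixed position.  Stops per loop when the
#' anchor RMSD drops to `tolerance` or after `maxSweeps` sweeps.  SSE
#' coordinates are never touched; the anchor RMSD is non-increasing
#' across sweeps.  Geometrically unclosable loops are reported with
#' their final distance rather than raising an error.
#'
#' @param model a [ProteinModel-class] with all residues present (from
#'   [growLoops])
#' @param tolerance anchor RMSD target in Angstrom (default 0.08)
#' @param maxSweeps maximum CCD sweeps per loop (default 200)
#' @return list with `model` and `closure` (data.frame: loop, first,
#'   last, distance, sweeps, closed)
#' @export
ccdClose <- function(model, tolerance = 0.08, maxSweeps = 200L) {
  gaps <- Filter(function(g) !is.na(g$up) && !is.na(g$down), modelGaps(model))
  res <- data.frame(loop = integer(0), first = integer(0), last = integer(0),
                    distance = numeric(0), sweeps = integer(0),
                    closed = logical(0))
  traces <- list()
  aa <- strsplit(model@sequence, "")[[1]]
  coil <- model@coil
  li <- 0L
  for (gap in gaps) {
    li <- li + 1L
    mob <- loopMobileAtoms(model, gap)
    cc <- ccdLoop(mob$atoms, mob$anchor, mob$target, mob$k, tolerance,
                  maxSweeps)
    if (mob$k > 0) {
      upd <- completeLoopResidues(cc$atoms[seq_len(3 * mob$k), , drop = FALSE],
                                  gap$residues, aa[gap$residues],
                                  mob$target[1, ])
      coil[names(upd)] <- upd
    }
    res <- rbind(res, data.frame(
      loop = li, first = if (mob$k) gap$residues[1] else NA_integer_,
      last = if (mob$k) gap$residues[mob$k] else NA_integer_,
      distance = cc$rmsd, sweeps = cc$sweeps,
      closed = cc$rmsd <= tolerance))
    traces[[li]] <- cc$trace
  }
  out <- newModel(model@sequence, model@sses, coil, model@provenance)
  list(model = out, closure = res, traces = traces)
}

#' Force-close remaining open loops
#'
#' Loops still open after [ccdClose] are re-grown with fresh random
#' dihedrals and re-closed, up to `maxRounds` times; if a loop still
#' fails, the conformation with the smallest closure distance is kept
#' and flagged.
#'
#' @param model a [ProteinModel-class] after [ccdClose]
#' @param rama Ramachandran tables
#' @param tolerance,maxSweeps CCD parameters
#' @param maxRounds re-growth rounds (default 5)
#' @return list with `model` and `closure` (with a `forced` column)
#' @export
forceClose <- function(model, rama = ramachandranTable(), tolerance = 0.08,
                       maxSweeps = 200L, maxRounds = 5L) {
  cur <- ccdClose(model, tolerance, maxSweeps)
  closure <- cur$closure
  closure$forced <- FALSE
  if (all(closure$closed)) return(list(model = cur$model, closure = closure))
  aa <- strsplit(model@sequence, "")[[1]]
  gaps <- Filter(function(g) !is.na(g$up) && !is.na(g$down),
                 modelGaps(model))
  best <- cur
  for (li in which(!closure$closed)) {
    gap <- gaps[[li]]
    if (!length(gap$residues)) next
    bestDist <- closure$distance[li]
    bestCoil <- best$model@coil[as.character(gap$residues)]
    up <- model@sses[[gap$up]]
    anchor <- sseResidueAtoms(up, up@last)[1:3, ]
    down <- model@sses[[gap$down]]
    target <- sseResidueAtoms(down, down@first)[1:3, ]
    for (round in seq_len(maxRounds)) {
      if (round == 1L) {
        # first, simply continue the descent from the best conformation
        tmpCoil <- best$model@coil
        tmpCoil[names(bestCoil)] <- bestCoil
        tmp <- newModel(model@sequence, model@sses, tmpCoil)
        atoms <- loopMobileAtoms(tmp, gap)$atoms
      } else {
        atoms <- growLoopBiased(anchor, target, aa[gap$residues], rama,
                                IDEAL_DIHEDRALS[[down@ssType]]["phi"])
      }
      cc <- ccdLoop(atoms, anchor, target, length(gap$residues), tolerance,
                    maxSweeps)
      if (cc$rmsd < bestDist) {
        bestDist <- cc$rmsd
        bestCoil <- completeLoopResidues(
          cc$atoms[seq_len(3 * length(gap$residues)), , drop = FALSE],
          gap$residues, aa[gap$residues], target[1, ])
      }
      if (bestDist <= tolerance) break
    }
    coil <- best$model@coil
    coil[names(bestCoil)] <- bestCoil
    best$model <- newModel(model@sequence, model@sses, coil,
                           model@provenance)
    closure$distance[li] <- bestDist
    closure$closed[li] <- bestDist <= tolerance
    closure$forced[li] <- TRUE
  }
  list(model = best$model, closure = closure)
}

#' Build all loops of an SSE-only model
#'
#' Convenience wrapper: trim, grow, CCD-close, force-close.
#'
#' @param model SSE-only [ProteinModel-class]
#' @param config run configuration (loop parameters)
#' @param rama Ramachandran tables
#' @return list with `model` (complete) and `closure` report
#' @export
buildLoops <- function(model, config = defaultConfig(),
                       rama = ramachandranTable()) {
  lp <- config$loops
  m <- trimSses(model)
  m <- growLoops(m, rama, lp$n_candidates)
  forceClose(m, rama, lp$ccd_tolerance, lp$max_sweeps, lp$force_rounds)
}
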