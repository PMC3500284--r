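# Model quality metrics and benchmark aggregation: RMSD/RMSD100, the
# contact order family, contact recovery, native-like classification,
# summary tables, and the move-correlation statistic.

#' Minimal RMSD after optimal rigid superposition
#'
#' Kabsch superposition (rotation + translation, no reflection) of two
#' index-matched CA coordinate sets.
#'
#' @param coordsA,coordsB n x 3 coordinate matrices, n >= 3
#' @return RMSD in Angstrom
#' @export
kabschRmsd <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("coordinate sets must have matching dimensions")
  if (nrow(coordsA) < 3L) stop("need at least 3 points")
  if (!all(is.finite(coordsA)) || !all(is.finite(coordsB)))
    stop("non-finite coordinates")
  kabsch(coordsA, coordsB)$rmsd
}

#' Length-normalized RMSD (RMSD100)
#'
#' Normalizes a CA RMSD to a 100-residue protein:
#' `rmsd / (1 + ln sqrt(n / 100))`.
#'
#' @param rmsd RMSD in Angstrom
#' @param n number of residues the RMSD was computed over
#' @return RMSD100 in Angstrom
#' @export
rmsd100 <- function(rmsd, n) {
  if (any(n < 1) || any(rmsd < 0)) stop("rmsd must be >= 0 and n >= 1")
  den <- 1 + log(sqrt(n / 100))
  if (any(den <= 0))
    stop("RMSD100 undefined for n <= ", floor(100 * exp(-2)),
         " residues (denominator <= 0)")
  rmsd / den
}

#' Contact order family
#'
#' Contacts are unordered residue pairs with sequence separation
#' >= `minSep` and CB (pseudo-CB for glycine) distance < `cutoff`.
#' CO is the mean sequence separation over contacts, RCO = CO / L,
#' NCO = CO^2 / L.
#'
#' @param cb n x 3 CB coordinate matrix of the residues present
#' @param resno 1-based sequence indices matching the rows of `cb`
#' @param L full sequence length used for normalization
#' @param cutoff contact distance cutoff in Angstrom (default 8)
#' @param minSep minimum sequence separation (default 1)
#' @return list with `co`, `rco`, `nco` and `nContacts`
#' @export
contactOrder <- function(cb, resno, L, cutoff = 8, minSep = 1L) {
  cb <- as.matrix(cb)
  if (nrow(cb) < 2L) stop("need at least 2 residues")
  if (length(resno) != nrow(cb)) stop("resno length mismatch")
  pairs <- .contactPairs(cb, as.integer(resno), as.integer(minSep), cutoff)
  if (!nrow(pairs)) stop("no contacts: contact order undefined")
  sep <- abs(pairs[, 1] - pairs[, 2])
  co <- mean(sep)
  list(co = co, rco = co / L, nco = co^2 / L, nContacts = nrow(pairs))
}

#' Contact recovery
#'
#' Percentage of native contacts (sequence separation >= `minSep`,
#' CB distance < `cutoff`) recovered in the model.  Only residues present
#' in both structures are compared.
#'
#' @param modelCb,nativeCb CB coordinate matrices
#' @param modelResno,nativeResno 1-based sequence indices per row
#' @param minSep minimum sequence separation (default 12)
#' @param cutoff contact cutoff in Angstrom (default 8)
#' @return contact recovery in percent
#' @export
contactRecovery <- function(modelCb, nativeCb, modelResno, nativeResno,
                            minSep = 12L, cutoff = 8) {
  common <- intersect(modelResno, nativeResno)
  mi <- match(common, modelResno); ni <- match(common, nativeResno)
  if (length(common) < 2L) stop("fewer than 2 shared residues")
  asKeys <- function(p) paste(p[, 1], p[, 2])
  nat <- .contactPairs(as.matrix(nativeCb)[ni, , drop = FALSE],
                       as.integer(common), as.integer(minSep), cutoff)
  if (!nrow(nat)) stop("native structure has no qualifying contacts")
  mod <- .contactPairs(as.matrix(modelCb)[mi, , drop = FALSE],
                       as.integer(common), as.integer(minSep), cutoff)
  100 * sum(asKeys(nat) %in% asKeys(mod)) / nrow(nat)
}

#' Quality metrics of a model against a native structure
#'
#' CA RMSD (Kabsch) over the residues shared between model and native,
#' RMSD100, the contact order family of the model, and contact recovery.
#'
#' @param model,native [ProteinModel-class] objects over the same sequence
#' @param crMinSep sequence separation for contact recovery (default 12)
#' @return list with rmsd, rmsd100, co, rco, nco, cr, nResidues
#' @export
qualityMetrics <- function(model, native, crMinSep = 12L) {
  mca <- atomCoords(model, "CA"); nca <- atomCoords(native, "CA")
  common <- intersect(rownames(mca), rownames(nca))
  rmsd <- kabschRmsd(mca[common, , drop = FALSE], nca[common, , drop = FALSE])
  r100 <- rmsd100(rmsd, length(common))
  mt <- modelCbTableFull(model); nt <- modelCbTableFull(native)
  co <- contactOrder(mt$cb, mt$resno, L = nchar(model@sequence))
  cr <- contactRecovery(mt$cb, nt$cb, mt$resno, nt$resno, minSep = crMinSep)
  list(rmsd = rmsd, rmsd100 = r100, co = co$co, rco = co$rco, nco = co$nco,
       cr = cr, nResidues = length(common))
}

# CB table including built coil residues
modelCbTableFull <- function(model) {
  cb <- atomCoords(model, "CB")
  list(cb = cb, resno = as.integer(rownames(cb)))
}

#' Summaries of a benchmark quality table
#'
#' For a table with per-protein best RMSD100 and best contact recovery
#' columns, counts models strictly below the native-like RMSD100 cutoff
#' and strictly above the contact recovery cutoff, column means and
#' standard deviations, and per-column counts of proteins where a method
#' improves on the comparator column.
#'
#' @param table data.frame keyed by protein; RMSD100 columns are taken as
#'   those named in `rmsdCols`, contact recovery columns as `crCols`
#' @param rmsdCut native-like RMSD100 cutoff in Angstrom (default 8.0)
#' @param crCut native-like contact recovery cutoff in percent (default 20)
#' @param rmsdCols,crCols column names; defaults cover the benchmark
#'   layout (native/predicted pool, SSE-only/complete, comparator)
#' @param comparator name of the comparator method column suffix
#' @return list with `nBelowRmsd`, `nAboveCr`, `means`, `sds`,
#'   `nImprovedRmsd`, `nImprovedCr`, `nProteins`
#' @export
benchmarkSummary <- function(table, rmsdCut = 8.0, crCut = 20,
                             rmsdCols = paste0("rmsd100_", c("nsse", "n", "psse", "p", "rosetta")),
                             crCols = paste0("cr_", c("nsse", "n", "psse", "p", "rosetta")),
                             comparator = "rosetta") {
  missing <- setdiff(c(rmsdCols, crCols), names(table))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(table)) stop("empty benchmark table")
  nBelow <- vapply(rmsdCols, function(cl) sum(table[[cl]] < rmsdCut), numeric(1))
  nAbove <- vapply(crCols, function(cl) sum(table[[cl]] > crCut), numeric(1))
  allCols <- c(rmsdCols, crCols)
  means <- vapply(allCols, function(cl) mean(table[[cl]]), numeric(1))
  sds <- vapply(allCols, function(cl) sd(table[[cl]]), numeric(1))
  compR <- grep(comparator, rmsdCols, value = TRUE)
  compC <- grep(comparator, crCols, value = TRUE)
  nImpR <- vapply(setdiff(rmsdCols, compR), function(cl)
    sum(table[[cl]] < table[[compR]]), numeric(1))
  nImpC <- vapply(setdiff(crCols, compC), function(cl)
    sum(table[[cl]] > table[[compC]]), numeric(1))
  list(nBelowRmsd = nBelow, nAboveCr = nAbove, means = means, sds = sds,
       nImprovedRmsd = nImpR, nImprovedCr = nImpC, nProteins = nrow(table))
}

#' Move correlation matrix
#'
#' A non-symmetric measure of how likely a move i is to set up a later
#' improving application of move j.  Over all trajectories:
#' f1(i, j) = fraction of j-improved steps preceded by an i
#' accepted-or-improved step within the previous `window` steps;
#' f2(i) = fraction of i steps that improved; f3(i) = fraction of i steps
#' that improved or were accepted.  C(i -> j) = log10(f1 / f3), floored to
#' -3 whenever f1, f2 or f3 is zero.
#'
#' @param trajectories list of trajectory data.frames (columns `move`,
#'   `outcome`)
#' @param window number of preceding steps searched for the i move
#'   (default 50)
#' @param moves optional character vector fixing the move order
#' @return square matrix C with rows i and columns j
#' @export
moveCorrelation <- function(trajectories, window = 50L, moves = NULL) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  allMoves <- unique(unlist(lapply(trajectories, function(t) t$move)))
  if (is.null(moves)) moves <- sort(allMoves)
  if (length(setdiff(allMoves, moves)))
    stop("unknown move names: ", paste(setdiff(allMoves, moves), collapse = ", "))
  k <- length(moves)
  nI <- setNames(numeric(k), moves)        # steps using move i
  nImp <- setNames(numeric(k), moves)      # i steps that improved
  nAccImp <- setNames(numeric(k), moves)   # i steps improved or accepted
  nJImp <- setNames(numeric(k), moves)     # j improved steps (denominator of f1)
  pre <- matrix(0, k, k, dimnames = list(moves, moves))  # f1 numerator
  for (tr in trajectories) {
    mv <- tr$move; oc <- tr$outcome
    n <- length(mv)
    good <- oc %in% c("improved", "accepted")
    for (s in seq_len(n)) {
      nI[mv[s]] <- nI[mv[s]] + 1
      if (oc[s] == "improved") nImp[mv[s]] <- nImp[mv[s]] + 1
      if (good[s]) nAccImp[mv[s]] <- nAccImp[mv[s]] + 1
      if (oc[s] == "improved") {
        nJImp[mv[s]] <- nJImp[mv[s]] + 1
        lo <- max(1L, s - window)
        if (window >= 1L && lo <= s - 1L) {
          idx <- seq.int(lo, s - 1L)
          preceders <- unique(mv[idx][good[idx]])
          pre[preceders, mv[s]] <- pre[preceders, mv[s]] + 1
        }
      }
    }
  }
  C <- matrix(-3, k, k, dimnames = list(moves, moves))
  for (i in moves) for (j in moves) {
    f1 <- if (nJImp[j] > 0) pre[i, j] / nJImp[j] else 0
    f2 <- if (nI[i] > 0) nImp[i] / nI[i] else 0
    f3 <- if (nI[i] > 0) nAccImp[i] / nI[i] else 0
    C[i, j] <- if (f1 == 0 || f2 == 0 || f3 == 0) -3 else log10(f1 / f3)
  }
  C
}
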