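# Consensus SSE pool: initial pool from three-state predictions, greedy
# Monte Carlo refinement of per-method assignments, pool agreement
# scoring, and evaluation against native assignments.

PROB_FLOOR <- 1e-4

# per-residue 3-state assignment ("H"/"E"/"C") from one method's matrix
argmaxAssignment <- function(p, threshold) {
  states <- SS_STATES[max.col(p, ties.method = "first")]
  win <- p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))]
  states[states %in% c("H", "E") & win < threshold] <- "C"
  states
}

# maximal H/E runs of an assignment -> entry data.frame
runsToEntries <- function(assign, minH, minS, source) {
  r <- rle(assign)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "H" & r$lengths >= minH) |
          (r$values == "E" & r$lengths >= minS)
  data.frame(type = ifelse(r$values[keep] == "H", "helix", "strand"),
             first = starts[keep], last = ends[keep],
             source = rep(source, sum(keep)), stringsAsFactors = FALSE)
}

collapsePoolEntries <- function(entries) {
  if (!nrow(entries)) return(entries)
  key <- paste(entries$type, entries$first, entries$last)
  src <- vapply(split(entries$source, key), function(s)
    paste(sort(unique(s)), collapse = "+"), character(1))
  uniq <- entries[!duplicated(key), c("type", "first", "last")]
  uniq$source <- src[paste(uniq$type, uniq$first, uniq$last)]
  uniq <- uniq[order(uniq$first, uniq$last, uniq$type), ]
  rownames(uniq) <- NULL
  uniq
}

#' Initial SSE pool from three-state predictions
#'
#' Per prediction method each residue is assigned its argmax state,
#' demoted to coil when the winning helix/strand probability falls below
#' the threshold.  Maximal helix/strand runs become pool entries; entries
#' below the minimum lengths (5 for helices, 3 for strands) are dropped,
#' and the union over methods is returned with duplicates collapsed.
#'
#' @param pred an [SSPrediction-class]
#' @param threshold probability threshold below which helix/strand
#'   assignments fall back to coil (default 0.5)
#' @param minHelix,minStrand minimum element lengths
#' @param sequence optional amino acid sequence to attach to the pool
#' @return an [SSEPool-class]
#' @export
initialPool <- function(pred, threshold = 0.5, minHelix = 5L, minStrand = 3L,
                        sequence = pred@sequence) {
  validObject(pred)
  entries <- do.call(rbind, lapply(names(pred@prob), function(m)
    runsToEntries(argmaxAssignment(pred@prob[[m]], threshold),
                  minHelix, minStrand, m)))
  if (is.null(entries))
    entries <- data.frame(type = character(), first = integer(),
                          last = integer(), source = character())
  if (!nzchar(sequence))
    sequence <- strrep("A", nrow(pred@prob[[1]]))
  p <- new("SSEPool")
  p@entries <- collapsePoolEntries(entries)
  p@sequence <- sequence
  p@source <- paste(names(pred@prob), collapse = "+")
  validObject(p)
  p
}

#' Agreement of an assignment with the predictions
#'
#' Sum over residues, averaged over prediction methods, of
#' `-log p(assigned state)`, with a probability floor of 1e-4; lower is
#' better.
#'
#' @param assignment character vector of per-residue states ("H"/"E"/"C")
#' @param pred an [SSPrediction-class]
#' @return numeric score (arbitrary energy units)
#' @export
poolAgreementScore <- function(assignment, pred) {
  n <- nrow(pred@prob[[1]])
  if (length(assignment) != n)
    stop("assignment length does not match prediction length")
  col <- match(assignment, SS_STATES)
  if (anyNA(col)) stop("assignment states must be H/E/C")
  per <- vapply(pred@prob, function(p)
    -log(pmax(p[cbind(seq_len(n), col)], PROB_FLOOR)), numeric(n))
  sum(rowMeans(as.matrix(per)))
}

# agreement of a single method's assignment with its own prediction
methodScore <- function(assignment, p) {
  col <- match(assignment, SS_STATES)
  sum(-log(pmax(p[cbind(seq_along(col), col)], PROB_FLOOR)))
}

# min-length-respecting check for a full assignment
assignmentValid <- function(assign, minH, minS) {
  r <- rle(assign)
  !any((r$values == "H" & r$lengths < minH) |
       (r$values == "E" & r$lengths < minS))
}

# greedy-descent MC on one method's assignment: single-residue state flips
# and SSE splits, accepting only score improvements.
refineAssignment <- function(assign, p, steps, minH, minS) {
  score <- methodScore(assign, p)
  n <- length(assign)
  for (step in seq_len(steps)) {
    cand <- assign
    if (runif(1) < 0.8) {
      i <- sample.int(n, 1)
      cand[i] <- sample(setdiff(SS_STATES, assign[i]), 1)
    } else {
      # divide an SSE: set one interior residue of a run to coil
      r <- rle(assign)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- which(r$values != "C" & r$lengths >= 3)
      if (!length(ok)) next
      k <- if (length(ok) == 1) ok else sample(ok, 1)
      span <- seq.int(starts[k] + 1L, ends[k] - 1L)
      i <- span[if (length(span) == 1L) 1L else sample.int(length(span), 1L)]
      cand[i] <- "C"
    }
    if (!assignmentValid(cand, minH, minS)) next
    candScore <- methodScore(cand, p)
    if (candScore < score) {
      assign <- cand
      score <- candScore
    }
  }
  assign
}

#' Refine an SSE pool by Monte Carlo minimization
#'
#' Each prediction method's per-residue assignment (reconstructed from
#' the pool entries tagged with that method) is refined for `steps`
#' iterations with moves that flip a single residue's state or divide an
#' SSE, accepting only moves that improve the agreement score
#' (greedy descent).  The refined pool's agreement score never exceeds
#' the input's, all entries still satisfy the minimum lengths, and the
#' result is deterministic for a fixed seed.
#'
#' @param pool an [SSEPool-class] (typically from [initialPool])
#' @param pred the [SSPrediction-class] the pool was built from
#' @param steps number of Monte Carlo steps per method (default 1000)
#' @param seed integer seed
#' @return refined [SSEPool-class]
#' @export
refinePool <- function(pool, pred, steps = 1000L, seed = 1L) {
  if (steps < 1L) stop("steps must be >= 1")
  validObject(pool)
  n <- nrow(pred@prob[[1]])
  entries <- NULL
  withr_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(withr_seed))
  set.seed(seed)
  for (m in names(pred@prob)) {
    assign <- rep("C", n)
    e <- pool@entries[grepl(m, pool@entries$source, fixed = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(e)))
      assign[seq.int(e$first[k], e$last[k])] <-
        ifelse(e$type[k] == "helix", "H", "E")
    assign <- refineAssignment(assign, pred@prob[[m]], steps,
                               minH = 5L, minS = 3L)
    entries <- rbind(entries, runsToEntries(assign, 5L, 3L, m))
  }
  out <- pool
  out@entries <- collapsePoolEntries(entries)
  validObject(out)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(saved) {
  if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
}

#' Combined per-method agreement score of a pool
#'
#' Sum over prediction methods of the agreement score of that method's
#' assignment (reconstructed from the pool's entries) with its own
#' prediction; the quantity [refinePool] minimizes.
#'
#' @inheritParams refinePool
#' @return numeric score
#' @export
poolScore <- function(pool, pred) {
  n <- nrow(pred@prob[[1]])
  total <- 0
  for (m in names(pred@prob)) {
    assign <- rep("C", n)
    e <- pool@entries[grepl(m, pool@entries$source, fixed = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(e)))
      assign[seq.int(e$first[k], e$last[k])] <-
        ifelse(e$type[k] == "helix", "H", "E")
    total <- total + methodScore(assign, pred@prob[[m]])
  }
  total
}

# per-residue state implied by a pool: helix/strand entries take
# precedence over coil; ties between H and E covering the same residue
# break toward the entry type backed by the higher predicted probability
# when a prediction is supplied, else toward helix.
poolStates <- function(pool, n, pred = NULL) {
  state <- rep("C", n)
  e <- pool@entries
  for (k in seq_len(nrow(e))) {
    idx <- seq.int(e$first[k], e$last[k])
    s <- ifelse(e$type[k] == "helix", "H", "E")
    clash <- state[idx] != "C" & state[idx] != s
    state[idx][!clash] <- s
    if (any(clash)) {
      if (is.null(pred)) next  # keep earlier (helix-first after sorting)
      probs <- Reduce(`+`, pred@prob) / length(pred@prob)
      i2 <- idx[clash]
      cur <- probs[cbind(i2, match(state[i2], SS_STATES))]
      alt <- probs[cbind(i2, match(s, SS_STATES))]
      state[i2][alt > cur] <- s
    }
  }
  state
}

#' Evaluate an SSE pool against native secondary structure
#'
#' Computes the pool Q3 (percent of residues whose pool-implied state
#' matches the native three-state label), the percentage of native SSEs
#' identified (matched by at least one same-type overlapping pool entry)
#' and the average shift (for each matched native SSE, the minimum over
#' matching entries of |dFirst| + |dLast|, averaged over matched SSEs).
#'
#' @param pool an [SSEPool-class]
#' @param nativeLabels character vector of native per-residue states
#'   ("H"/"E"/"C")
#' @param nativeSses data.frame with columns type/first/last of native
#'   elements
#' @param pred optional [SSPrediction-class] used to resolve residues
#'   covered by both helix and strand entries
#' @return list with `q3`, `pctFound` (percent) and `shift` (residues)
#' @export
evaluatePool <- function(pool, nativeLabels, nativeSses, pred = NULL) {
  n <- length(nativeLabels)
  if (nchar(pool@sequence) && n != nchar(pool@sequence))
    stop("native assignment length does not match pool sequence")
  if (!nrow(nativeSses)) stop("empty native SSE list: pctFound undefined")
  state <- poolStates(pool, n, pred)
  q3 <- 100 * mean(state == nativeLabels)
  e <- pool@entries
  shifts <- rep(NA_real_, nrow(nativeSses))
  for (k in seq_len(nrow(nativeSses))) {
    cand <- e[e$type == nativeSses$type[k] &
              e$first <= nativeSses$last[k] &
              e$last >= nativeSses$first[k], , drop = FALSE]
    if (nrow(cand))
      shifts[k] <- min(abs(cand$first - nativeSses$first[k]) +
                       abs(cand$last - nativeSses$last[k]))
  }
  matched <- !is.na(shifts)
  list(q3 = q3, pctFound = 100 * mean(matched),
       shift = if (any(matched)) mean(shifts[matched]) else NA_real_)
}

#' Derive native SSE definitions from per-residue labels
#'
#' Maximal helix/strand runs satisfying the minimum lengths.
#'
#' @param labels character vector of "H"/"E"/"C" states
#' @return data.frame with columns type/first/last
#' @export
labelsToSses <- function(labels) {
  runsToEntries(labels, 5L, 3L, "native")[, c("type", "first", "last")]
}
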