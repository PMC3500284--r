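# Monte Carlo Metropolis engine: four step outcomes (improved, accepted,
# rejected, skipped), adaptive temperature steering the cumulative
# acceptance ratio from 0.5 to 0.2, and the two-stage assembly /
# refinement schedule.
#
# The Metropolis criterion compares the energy of each new model against
# the energy of the BEST model observed so far, and a rejected step
# continues from the best model; this is the engine's defining (and
# unconventional) bookkeeping.  A flag switches to the conventional
# last-accepted comparison for experimentation.

#' Temperature controller
#'
#' Adaptive annealing: the temperature starts at `t0` and is adjusted at
#' every `adjust_every`-th step so that the cumulative acceptance ratio
#' (improved + accepted over non-skipped steps) approaches a target that
#' decreases linearly from `start_target` (0.5) to `end_target` (0.2)
#' over the stage.
#'
#' @param config run configuration (uses `config$temperature`)
#' @return controller list with the current temperature and parameters
#' @export
temperatureController <- function(config = defaultConfig()) {
  tc <- config$temperature
  list(T = tc$t0, t0 = tc$t0, adjustEvery = tc$adjust_every,
       startTarget = tc$start_target, endTarget = tc$end_target,
       factorUp = tc$factor_up, factorDown = tc$factor_down,
       tMin = tc$t_min, tMax = tc$t_max, k = tc$k)
}

#' Metropolis decision
#'
#' `improved` when the new energy is below the reference (best) energy;
#' otherwise `accepted` with probability `exp(-(eNew - eBest) / (k T))`,
#' else `rejected`.
#'
#' @param eNew,eBest energies of the proposed and reference model
#' @param T temperature (> 0)
#' @param k Boltzmann-like constant (default 1, so T is in energy units)
#' @return one of "improved", "accepted", "rejected"
#' @export
metropolisDecide <- function(eNew, eBest, T, k = 1) {
  if (!is.finite(eNew) || !is.finite(eBest)) stop("non-finite energy")
  if (T <= 0) stop("temperature must be > 0")
  if (eNew < eBest) return("improved")
  p <- exp(-(eNew - eBest) / (k * T))
  if (runif(1) < p) "accepted" else "rejected"
}

#' Step bookkeeping
#'
#' improved: the new model becomes both working and best model;
#' accepted: the new model becomes the working model, best is unchanged;
#' rejected: the working model is reset to the best model; skipped: a
#' no-op on both.
#'
#' @param outcome one of the four step outcomes
#' @param newState list(model, energy) of the proposal (NULL for skipped)
#' @param working,best list(model, energy) states
#' @return list(working, best)
#' @export
stepBookkeeping <- function(outcome, newState, working, best) {
  switch(outcome,
    improved = list(working = newState, best = newState),
    accepted = list(working = newState, best = best),
    rejected = list(working = best, best = best),
    skipped = list(working = working, best = best),
    stop("unknown outcome: ", outcome))
}

#' Adaptive temperature update
#'
#' Called at step indices divisible by `adjust_every`.  The target
#' acceptance ratio at fractional progress f is
#' `start_target - (start_target - end_target) f`; the temperature is
#' multiplied by `factor_up` (1.05) when the cumulative acceptance ratio
#' is below target, else by `factor_down` (0.95), clamped to
#' [t_min, t_max].  Skipped steps carry no Metropolis evaluation and are
#' excluded from the ratio's denominator.
#'
#' @param ctrl controller from [temperatureController]
#' @param nAccepted improved + accepted steps so far
#' @param nEvaluated non-skipped steps so far
#' @param progress fraction of the stage completed, in [0, 1]
#' @return updated controller
#' @export
updateTemperature <- function(ctrl, nAccepted, nEvaluated, progress) {
  target <- ctrl$startTarget - (ctrl$startTarget - ctrl$endTarget) * progress
  ratio <- if (nEvaluated > 0) nAccepted / nEvaluated else 0
  f <- if (ratio < target) ctrl$factorUp else ctrl$factorDown
  ctrl$T <- min(ctrl$tMax, max(ctrl$tMin, ctrl$T * f))
  ctrl
}

#' Run one minimization stage
#'
#' Draws moves from the move set by their probabilities (inapplicable
#' moves count as skipped), scores proposals, applies the Metropolis
#' decision against the best energy, adapts the temperature, and stops
#' at `max_steps` total steps or `max_nonimproving` consecutive steps
#' that did not improve the score (accepted, rejected and skipped steps
#' all count as non-improving).
#'
#' @param model0 starting [ProteinModel-class]
#' @param moveSet move set from [buildMoveSet]
#' @param scorer function(model) returning a total energy
#' @param schedule list(max_steps, max_nonimproving)
#' @param ctrl controller from [temperatureController]
#' @param pool the [SSEPool-class] moves draw from
#' @param config run configuration
#' @param conventionalMetropolis compare against the last accepted
#'   energy instead of the best energy (default FALSE)
#' @return list with `best` (model), `bestEnergy`, and `trajectory`
#'   (data.frame: step, move, outcome, e_new, e_best, temperature)
#' @export
runStage <- function(model0, moveSet, scorer, schedule, ctrl, pool,
                     config = defaultConfig(),
                     conventionalMetropolis = FALSE) {
  maxSteps <- schedule$max_steps
  maxNon <- schedule$max_nonimproving
  e0 <- scorer(model0)
  working <- list(model = model0, energy = e0)
  best <- working
  moves <- character(maxSteps); outcomes <- character(maxSteps)
  eNewV <- numeric(maxSteps); eBestV <- numeric(maxSteps)
  tempV <- numeric(maxSteps)
  behaviors <- moveBehaviors()
  amps <- config$moves$amplitudes
  ampClass <- ifelse(moveSet$amplitude == "both", "small", moveSet$amplitude)
  nonImproving <- 0L
  nAccepted <- 0L; nEvaluated <- 0L
  step <- 0L
  while (step < maxSteps && nonImproving < maxNon) {
    step <- step + 1L
    mi <- sample.int(nrow(moveSet), 1L, prob = moveSet$prob)
    name <- moveSet$name[mi]
    proposal <- behaviors[[name]](working$model, pool, amps[[ampClass[mi]]])
    if (is.null(proposal)) {
      outcome <- "skipped"
      eNew <- NA_real_
    } else {
      eNew <- scorer(proposal)
      ref <- if (conventionalMetropolis) working$energy else best$energy
      outcome <- metropolisDecide(eNew, ref, ctrl$T, ctrl$k)
      nEvaluated <- nEvaluated + 1L
      if (outcome != "rejected") nAccepted <- nAccepted + 1L
    }
    st <- stepBookkeeping(outcome,
                          if (is.null(proposal)) NULL
                          else list(model = proposal, energy = eNew),
                          working, best)
    working <- st$working; best <- st$best
    nonImproving <- if (outcome == "improved") 0L else nonImproving + 1L
    moves[step] <- name; outcomes[step] <- outcome
    eNewV[step] <- eNew; eBestV[step] <- best$energy; tempV[step] <- ctrl$T
    if (step %% ctrl$adjustEvery == 0L)
      ctrl <- updateTemperature(ctrl, nAccepted, nEvaluated, step / maxSteps)
  }
  if (nEvaluated == 0L && step > 0L)
    stop("stagnation: every proposed move was skipped")
  idx <- seq_len(step)
  list(best = best$model, bestEnergy = best$energy, ctrl = ctrl,
       trajectory = data.frame(step = idx, move = moves[idx],
                               outcome = outcomes[idx], e_new = eNewV[idx],
                               e_best = eBestV[idx],
                               temperature = tempV[idx],
                               stringsAsFactors = FALSE))
}

#' Fold a sequence by two-stage SSE assembly
#'
#' For each model: start from a single randomly drawn pool SSE placed at
#' the origin, run the assembly stage (large-amplitude moves), then the
#' refinement stage (small-amplitude moves), both under the adaptive
#' Metropolis engine.  Models are returned sorted by final energy.
#' Per-model seeds are derived deterministically from `seed` and the
#' model index.
#'
#' @param sequence amino acid string
#' @param pool [SSEPool-class] of candidate elements
#' @param pred [SSPrediction-class] (NULL disables agreement terms)
#' @param config run configuration
#' @param nModels number of independent models to generate
#' @param seed integer seed
#' @return list with `models` (list of [ProteinModel-class]), `energies`
#'   (sorted, non-decreasing), `breakdowns` and `trajectories` (one per
#'   model, in the sorted order)
#' @export
fold <- function(sequence, pool, pred = NULL, config = defaultConfig(),
                 nModels = 1L, seed = 1L) {
  if (!nrow(pool@entries)) stop("empty pool")
  weights <- configWeights(config)
  if (is.null(pred)) {
    weights[["ss_agreement_method1"]] <- 0
    weights[["ss_agreement_method2"]] <- 0
  }
  const <- configConstants(config)
  ctx <- energyContext(sequence, pred, const)
  wv <- weights[energyTermNames()]
  scorer <- function(model)
    sum(computeRawTerms(model, pred, const, ctx) * wv)
  asmSet <- buildMoveSet(pool, "assembly", config)
  refSet <- buildMoveSet(pool, "refinement", config)
  models <- vector("list", nModels)
  energies <- numeric(nModels)
  trajectories <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    set.seed((seed * 10007L + m * 7919L) %% .Machine$integer.max)
    e <- pool@entries[sample.int(nrow(pool@entries), 1L), ]
    start <- newModel(sequence,
                      list(buildIdealSse(sequence, e$first, e$last, e$type)),
                      provenance = pool@source)
    asm <- runStage(start, asmSet, scorer, config$schedules$assembly,
                    temperatureController(config), pool, config)
    ref <- runStage(asm$best, refSet, scorer, config$schedules$refinement,
                    temperatureController(config), pool, config)
    models[[m]] <- ref$best
    energies[m] <- ref$bestEnergy
    asm$trajectory$stage <- "assembly"
    ref$trajectory$stage <- "refinement"
    trajectories[[m]] <- rbind(asm$trajectory, ref$trajectory)
  }
  o <- order(energies)
  breakdowns <- lapply(models[o], scoreModel, pred = pred, weights = weights,
                       const = const)
  list(models = models[o], energies = energies[o],
       breakdowns = breakdowns, trajectories = trajectories[o])
}
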