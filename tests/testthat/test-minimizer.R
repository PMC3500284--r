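# Metropolis engine: decisions, bookkeeping, temperature control,
# stage termination and the two-stage fold driver.

test_that("downhill proposals always improve and extreme uphill ones reject", {
  set.seed(1)
  for (rep in 1:20)
    expect_equal(metropolisDecide(-1, 0, runif(1, 0.01, 1000)), "improved")
  expect_equal(metropolisDecide(1e6, 0, 1), "rejected")
  expect_error(metropolisDecide(NaN, 0, 1), "non-finite")
  expect_error(metropolisDecide(0, 0, -1), "temperature")
})

test_that("acceptance at dE = kT ln 2 is one half", {
  set.seed(42)
  T <- 10
  dE <- T * log(2)
  outcomes <- replicate(1e5, metropolisDecide(dE, 0, T))
  rate <- mean(outcomes == "accepted")
  sigma <- sqrt(0.25 / 1e5)
  expect_lt(abs(rate - 0.5), 3 * sigma)
})

test_that("acceptance approaches 1 at high T and 0 at low T", {
  set.seed(2)
  hot <- replicate(2000, metropolisDecide(10, 0, 1e9))
  cold <- replicate(2000, metropolisDecide(10, 0, 1e-9))
  expect_gt(mean(hot == "accepted"), 0.999)
  expect_equal(unique(cold), "rejected")
})

test_that("bookkeeping follows the improved/accepted/rejected/skipped contract", {
  w <- list(model = "w", energy = 5)
  b <- list(model = "b", energy = 3)
  new <- list(model = "n", energy = 1)
  st <- stepBookkeeping("improved", new, w, b)
  expect_identical(st$working, new)
  expect_identical(st$best, new)
  st <- stepBookkeeping("accepted", new, w, b)
  expect_identical(st$working, new)
  expect_identical(st$best, b)   # best is not updated
  st <- stepBookkeeping("rejected", NULL, w, b)
  expect_identical(st$working, b)  # continue from the best model
  st <- stepBookkeeping("skipped", NULL, w, b)
  expect_identical(st$working, w)  # no-op
  expect_identical(st$best, b)
})

test_that("temperature updates implement the linear target and tie rule", {
  ctrl <- temperatureController()
  expect_equal(ctrl$T, 500)
  # ratio below target -> warm up
  up <- updateTemperature(ctrl, nAccepted = 0, nEvaluated = 10, progress = 0)
  expect_equal(up$T, 500 * 1.05)
  # ratio above target -> cool down
  down <- updateTemperature(ctrl, nAccepted = 9, nEvaluated = 10, progress = 0)
  expect_equal(down$T, 500 * 0.95)
  # exact tie takes the cooling branch
  tie <- updateTemperature(ctrl, nAccepted = 5, nEvaluated = 10, progress = 0)
  expect_equal(tie$T, 500 * 0.95)
  # target decreases linearly from 0.5 to 0.2
  mid <- updateTemperature(ctrl, nAccepted = 4, nEvaluated = 10, progress = 0.5)
  expect_equal(mid$T, 500 * 0.95)  # 0.4 > 0.35 target at mid-run
  end <- updateTemperature(ctrl, nAccepted = 3, nEvaluated = 10, progress = 1)
  expect_equal(end$T, 500 * 0.95)  # 0.3 > 0.2
  # all-rejected histories warm up monotonically to the clamp
  for (i in 1:400) ctrl <- updateTemperature(ctrl, 0, 10 * i, 0)
  expect_lte(ctrl$T, 1e6)
  expect_equal(ctrl$T, 1e6)
})

test_that("the controller steers the acceptance ratio toward the target", {
  # synthetic logistic landscape: acceptance probability of a proposal is
  # a smooth increasing function of T
  set.seed(10)
  ctrl <- temperatureController()
  nAcc <- 0; nEval <- 0
  maxSteps <- 2000
  accProb <- function(T) 1 / (1 + (50 / T)^1.5)
  for (step in 1:maxSteps) {
    nEval <- nEval + 1
    if (runif(1) < accProb(ctrl$T)) nAcc <- nAcc + 1
    if (step %% 10 == 0)
      ctrl <- updateTemperature(ctrl, nAcc, nEval, step / maxSteps)
  }
  # by the end of the run the cumulative acceptance ratio sits near the
  # final target of the linear schedule
  expect_lt(abs(nAcc / nEval - 0.2), 0.05)
  expect_gt(ctrl$T, 0)
})

test_that("stages stop after the configured non-improving run", {
  toy <- toyBundle()
  ms <- buildMoveSet(toy$pool, "refinement")
  # pathological scorer: every model is worse than the last best
  worse <- local({
    k <- 0
    function(model) { k <<- k + 1; k }
  })
  set.seed(4)
  res <- runStage(toy$sseModel, ms, worse,
                  list(max_steps = 5000, max_nonimproving = 120),
                  temperatureController(), toy$pool)
  tr <- res$trajectory
  lastImp <- max(c(0, which(tr$outcome == "improved")))
  expect_equal(nrow(tr) - lastImp, 120)
  expect_true(all(tr$outcome %in% c("improved", "accepted", "rejected", "skipped")))
})

test_that("stages stop at max_steps and outcomes partition the steps", {
  toy <- toyBundle()
  ms <- buildMoveSet(toy$pool, "refinement")
  scorer <- function(model) scoreModel(model, toy$prediction)@total
  set.seed(6)
  res <- runStage(toy$sseModel, ms, scorer,
                  list(max_steps = 150, max_nonimproving = 1000),
                  temperatureController(), toy$pool)
  tr <- res$trajectory
  expect_equal(nrow(tr), 150)
  counts <- table(factor(tr$outcome,
                         c("improved", "accepted", "rejected", "skipped")))
  expect_equal(sum(counts), 150)
  # E_best is non-increasing
  expect_true(all(diff(tr$e_best) <= 1e-12))
})

test_that("stage runs are reproducible for a fixed seed", {
  toy <- toyBundle()
  ms <- buildMoveSet(toy$pool, "assembly")
  scorer <- function(model) scoreModel(model, toy$prediction)@total
  run <- function() {
    set.seed(33)
    runStage(proteinModel(toy$sseModel@sequence, toy$sseModel@sses[1]),
             ms, scorer, list(max_steps = 300, max_nonimproving = 300),
             temperatureController(), toy$pool)$trajectory
  }
  expect_identical(run(), run())
})

test_that("fold returns reproducible, energy-sorted models", {
  toy <- toyBundle()
  cfg <- defaultConfig()
  cfg$schedules$assembly <- list(max_steps = 400L, max_nonimproving = 200L)
  cfg$schedules$refinement <- list(max_steps = 150L, max_nonimproving = 100L)
  r1 <- fold(toy$sseModel@sequence, toy$pool, toy$prediction, cfg,
             nModels = 3, seed = 9)
  r2 <- fold(toy$sseModel@sequence, toy$pool, toy$prediction, cfg,
             nModels = 3, seed = 9)
  expect_equal(r1$energies, r2$energies)
  expect_true(all(diff(r1$energies) >= 0))
  expect_identical(lapply(r1$models, atomCoords),
                   lapply(r2$models, atomCoords))
})

test_that("a single-entry pool folds to exactly that element", {
  n <- 30
  seqs <- strrep("A", n)
  pool <- new("SSEPool")
  pool@entries <- data.frame(type = "helix", first = 5L, last = 18L,
                             source = "x", stringsAsFactors = FALSE)
  pool@sequence <- seqs
  cfg <- defaultConfig()
  cfg$schedules$assembly <- list(max_steps = 150L, max_nonimproving = 80L)
  cfg$schedules$refinement <- list(max_steps = 80L, max_nonimproving = 50L)
  labels <- rep("C", n); labels[5:18] <- "H"
  pred <- ssPrediction(psipred = local({
    p <- matrix(0.05, n, 3, dimnames = list(NULL, c("H", "E", "C")))
    p[cbind(1:n, match(labels, c("H", "E", "C")))] <- 0.9
    p / rowSums(p)
  }))
  res <- fold(seqs, pool, pred, cfg, nModels = 1, seed = 2)
  m <- res$models[[1]]
  expect_equal(length(m@sses), 1L)
  expect_equal(sseRange(m@sses[[1]]), c(5L, 18L))
  tr <- res$trajectories[[1]]
  expect_gt(mean(tr$outcome == "skipped"), 0.3)
})
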