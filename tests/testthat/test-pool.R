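# Consensus pool construction, refinement and evaluation.

test_that("initial pool keeps confident runs and drops short or weak ones", {
  labels <- rep("C", 12)
  labels[3:8] <- "H"
  pred <- predFromLabels(labels, p = 0.9, methods = "psipred")
  pool <- initialPool(pred)
  expect_equal(nrow(pool@entries), 1L)
  expect_equal(pool@entries$type, "helix")
  expect_equal(pool@entries$first, 3L)
  expect_equal(pool@entries$last, 8L)

  # a 4-residue helix run is below the minimum length of 5
  labels4 <- rep("C", 12); labels4[3:6] <- "H"
  pool4 <- initialPool(predFromLabels(labels4, p = 0.9, methods = "psipred"))
  expect_equal(nrow(pool4@entries), 0L)

  # a 3-residue strand run is kept
  labels3 <- rep("C", 12); labels3[3:5] <- "E"
  pool3 <- initialPool(predFromLabels(labels3, p = 0.9, methods = "psipred"))
  expect_equal(nrow(pool3@entries), 1L)
  expect_equal(pool3@entries$type, "strand")
})

test_that("argmax helix below the probability threshold reads as coil", {
  n <- 10
  p <- matrix(c(0.45, 0.1, 0.45), n, 3, byrow = TRUE,
              dimnames = list(NULL, c("H", "E", "C")))
  p[, 1] <- 0.45 + 1e-9  # helix wins the argmax but sits below 0.5
  p <- p / rowSums(p)
  pool <- initialPool(ssPrediction(psipred = p))
  expect_equal(nrow(pool@entries), 0L)
})

test_that("pool union collapses duplicates across methods", {
  labels <- rep("C", 15); labels[4:10] <- "H"
  pred <- predFromLabels(labels, p = 0.9)  # psipred + jufo, identical
  pool <- initialPool(pred)
  expect_equal(nrow(pool@entries), 1L)
  expect_match(pool@entries$source, "jufo\\+psipred")
})

test_that("agreement score is the per-method average of -log p", {
  labels <- c("H", "H", "H", "H", "H", "C", "C", "C")
  pred <- predFromLabels(labels, p = 0.9)
  s0 <- poolAgreementScore(labels, pred)
  expect_equal(s0, 8 * -log(0.9), tolerance = 1e-9)
  flipped <- labels; flipped[2] <- "E"
  s1 <- poolAgreementScore(flipped, pred)
  expect_equal(s1 - s0, log(0.9 / 0.05), tolerance = 1e-9)
  # permutation covariance
  perm <- sample(length(labels))
  predP <- ssPrediction(psipred = pred@prob$psipred[perm, ],
                        jufo = pred@prob$jufo[perm, ])
  expect_equal(poolAgreementScore(labels[perm], predP), s0, tolerance = 1e-12)
  expect_error(poolAgreementScore(labels[1:3], pred), "length")
})

test_that("probability floor keeps scores finite", {
  p <- matrix(c(1, 0, 0), 6, 3, byrow = TRUE,
              dimnames = list(NULL, c("H", "E", "C")))
  pred <- ssPrediction(psipred = p)
  s <- poolAgreementScore(rep("C", 6), pred)
  expect_true(is.finite(s))
  expect_equal(s, 6 * -log(1e-4), tolerance = 1e-9)
})

test_that("refinement is seed-deterministic and never raises the score", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 25
    p <- matrix(rexp(n * 3)^2, n, 3)
    p <- p / rowSums(p)
    colnames(p) <- c("H", "E", "C")
    pred <- ssPrediction(psipred = p)
    pool <- initialPool(pred)
    if (!nrow(pool@entries)) next
    r1 <- refinePool(pool, pred, steps = 300, seed = 7)
    r2 <- refinePool(pool, pred, steps = 300, seed = 7)
    expect_identical(r1@entries, r2@entries)
    expect_lte(poolScore(r1, pred), poolScore(pool, pred) + 1e-9)
    # refined entries still satisfy the minimum lengths (validity checks)
    expect_true(isTRUE(validObject(r1, test = TRUE)))
  }
})

test_that("refinement finds the downhill move an exhaustive search finds", {
  # a helix whose boundary is mis-set by 2 residues: the true helix is
  # 4..9 but the initial pool reads 4..11
  n <- 14
  labels <- rep("C", n); labels[4:9] <- "H"
  p <- predFromLabels(labels, p = 0.95, methods = "psipred")@prob$psipred
  pred <- ssPrediction(psipred = p)
  start <- rep("C", n); start[4:11] <- "H"
  pool <- new("SSEPool")
  pool@entries <- data.frame(type = "helix", first = 4L, last = 11L,
                             source = "psipred", stringsAsFactors = FALSE)
  pool@sequence <- strrep("A", n)
  # oracle: exhaustive single-residue flips confirm a strictly downhill
  # move exists from the mis-set assignment
  base <- poolAgreementScore(start, pred)
  downhill <- FALSE
  for (i in seq_len(n)) for (s in c("H", "E", "C")) {
    cand <- start; cand[i] <- s
    if (poolAgreementScore(cand, pred) < base - 1e-12) downhill <- TRUE
  }
  expect_true(downhill)
  refined <- refinePool(pool, pred, steps = 1000, seed = 1)
  expect_lt(poolScore(refined, pred), poolScore(pool, pred))
})

test_that("optimal pools pass through refinement unchanged in score", {
  labels <- rep("C", 20); labels[5:12] <- "H"
  pred <- predFromLabels(labels, p = 0.99, methods = "psipred")
  pool <- initialPool(pred)
  refined <- refinePool(pool, pred, steps = 500, seed = 3)
  expect_equal(poolScore(refined, pred), poolScore(pool, pred))
})

test_that("pool evaluation reproduces the self-match and shift examples", {
  labels <- rep("C", 30)
  labels[3:12] <- "H"; labels[18:22] <- "E"
  native <- labelsToSses(labels)
  pool <- new("SSEPool")
  pool@entries <- cbind(native, source = "x")
  pool@sequence <- strrep("A", 30)
  ev <- evaluatePool(pool, labels, native)
  expect_equal(ev$q3, 100)
  expect_equal(ev$pctFound, 100)
  expect_equal(ev$shift, 0)

  # a native helix (10,20) matched only by pool helix (12,20) shifts by 2
  labels2 <- rep("C", 25); labels2[10:20] <- "H"
  native2 <- labelsToSses(labels2)
  pool2 <- new("SSEPool")
  pool2@entries <- data.frame(type = "helix", first = 12L, last = 20L,
                              source = "x", stringsAsFactors = FALSE)
  pool2@sequence <- strrep("A", 25)
  ev2 <- evaluatePool(pool2, labels2, native2)
  expect_equal(ev2$shift, 2)
  expect_equal(ev2$pctFound, 100)

  # the empty pool recovers nothing; Q3 equals the native coil percent
  pool0 <- new("SSEPool")
  pool0@entries <- data.frame(type = character(), first = integer(),
                              last = integer(), source = character())
  pool0@sequence <- strrep("A", 25)
  ev0 <- evaluatePool(pool0, labels2, native2)
  expect_equal(ev0$pctFound, 0)
  expect_equal(ev0$q3, 100 * mean(labels2 == "C"))
  expect_error(evaluatePool(pool2, labels2, native2[0, ]), "empty native")
})

test_that("initial pools never contain sub-minimum entries (fuzz)", {
  set.seed(2024)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    p <- matrix(runif(n * 3)^2, n, 3)
    p <- p / rowSums(p)
    colnames(p) <- c("H", "E", "C")
    pool <- initialPool(ssPrediction(psipred = p))
    if (!nrow(pool@entries)) next
    len <- pool@entries$last - pool@entries$first + 1L
    expect_true(all(len >= ifelse(pool@entries$type == "helix", 5L, 3L)))
    expect_true(all(pool@entries$first >= 1 & pool@entries$last <= n))
  }
})

test_that("prediction readers parse, renormalize and reject malformed input", {
  ss2 <- tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT",
               "1 M C 0.97 0.02 0.01",
               "2 K H 0.03 0.95 0.02",
               "3 V H 0.02 0.97 0.02"), ss2)  # row 3 sums to 1.01
  pred <- readSs2(ss2)
  p <- pred@prob$psipred
  expect_equal(p[1, ], c(H = 0.02, E = 0.01, C = 0.97))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-12)
  expect_equal(pred@sequence, "MKV")

  bad <- tempfile(fileext = ".ss2")
  writeLines("1 M C 0.2 0.2 0.1", bad)  # sums to 0.5
  expect_error(readSs2(bad), "sum")

  gap <- tempfile(fileext = ".ss2")
  writeLines(c("1 M C 0.9 0.05 0.05", "3 K H 0.1 0.8 0.1"), gap)
  expect_error(readSs2(gap), "contiguous")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("1\tM\t0.8\t0.1\t0.1", "2\tK\t0.1\t0.8\t0.1"), tsv)
  jufo <- readPredTsv(tsv)
  expect_equal(jufo@prob$jufo[1, ], c(H = 0.8, E = 0.1, C = 0.1))
})

test_that("pool files round-trip", {
  toy <- toyBundle()
  path <- tempfile(fileext = ".pool")
  writePoolFile(toy$pool, path)
  back <- readPoolFile(path, toy$sseModel@sequence)
  expect_equal(back@entries[, c("type", "first", "last")],
               toy$pool@entries[, c("type", "first", "last")])
  bad <- tempfile()
  writeLines("COIL 1 5", bad)
  expect_error(readPoolFile(bad, ALA20), "malformed")
})
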