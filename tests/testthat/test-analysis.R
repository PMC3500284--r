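# Quality metrics, benchmark aggregation and move correlation.

test_that("kabsch RMSD is zero for identical and rigidly moved sets", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabschRmsd(x, x), 0, tolerance = 1e-12)
  for (rep in 1:20) {
    t <- randomTransform()
    expect_lt(kabschRmsd(x, rtApply(t, x)), 1e-9)
  }
  expect_error(kabschRmsd(x, x[1:5, ]), "dimensions")
})

test_that("kabsch RMSD matches a rotation-grid brute force", {
  # coarse-to-fine grid over Euler angles on a 4-point toy
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0), c(0, 1.5, 1))
  y <- x
  y[2, ] <- y[2, ] + c(0.6, -0.4, 0.3)  # displace one point
  gridRmsd <- function(x, y, centers, width, steps) {
    best <- Inf
    ang <- function(c, w) seq(c - w, c + w, length.out = steps)
    cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
    for (a in ang(centers[1], width))
      for (b in ang(centers[2], width))
        for (g in ang(centers[3], width)) {
          R <- rtRotation(c(0, 0, 1), a)@rotation %*%
               rtRotation(c(0, 1, 0), b)@rotation %*%
               rtRotation(c(1, 0, 0), g)@rotation
          r <- sqrt(mean(rowSums((cx %*% t(R) - cy)^2)))
          if (r < best) { best <- r; bestAng <- c(a, b, g) }
        }
    list(rmsd = best, ang = bestAng)
  }
  coarse <- gridRmsd(x, y, c(0, 0, 0), 180, 25)   # 15 degree grid
  fine <- gridRmsd(x, y, coarse$ang, 15, 61)      # refine to 0.5 degrees
  expect_equal(kabschRmsd(x, y), fine$rmsd, tolerance = 1e-3)
  expect_lte(kabschRmsd(x, y), fine$rmsd + 1e-9)  # Kabsch is the optimum
})

test_that("kabsch RMSD agrees with the bio3d superposition", {
  set.seed(9)
  x <- matrix(rnorm(45, sd = 4), 15, 3)
  y <- x + matrix(rnorm(45, sd = 0.7), 15, 3)
  fit <- bio3d::fit.xyz(as.vector(t(y)), as.vector(t(x)),
                        fixed.inds = 1:45, mobile.inds = 1:45)
  ref <- sqrt(mean(colSums(matrix((fit - as.vector(t(y)))^2, nrow = 3))))
  expect_equal(kabschRmsd(x, y), ref, tolerance = 1e-6)
})

test_that("rmsd100 applies the length normalization", {
  expect_equal(rmsd100(3, 100), 3)
  expect_equal(rmsd100(0, 57), 0)
  expect_equal(rmsd100(4, 200), 4 / (1 + log(sqrt(2))), tolerance = 1e-12)
  expect_equal(rmsd100(4, 200), 2.9707, tolerance = 1e-4)
  expect_error(rmsd100(3, 13), "undefined")
  expect_error(rmsd100(-1, 50), ">= 0")
})

test_that("contact order matches the printed benchmark example", {
  # CO 44.41 over a 102-residue protein prints RCO 0.44
  co <- 44.41
  expect_equal(round(co / 102, 2), 0.44)
  # and our arithmetic agrees: rco * L = co, nco * L = co^2
  set.seed(4)
  cb <- matrix(rnorm(90, sd = 6), 30, 3)
  r <- contactOrder(cb, 1:30, L = 30)
  expect_equal(r$rco * 30, r$co, tolerance = 1e-12)
  expect_equal(r$nco * 30, r$co^2, tolerance = 1e-12)
})

test_that("contact order equals a brute-force recount on random clouds", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    cb <- matrix(rnorm(3 * n, sd = 5), n, 3)
    resno <- sort(sample(1:(n * 2), n))
    oracle <- bruteContacts(cb, resno, minSep = 1, cutoff = 8)
    if (is.null(oracle)) {
      expect_error(contactOrder(cb, resno, L = max(resno)), "no contacts")
      next
    }
    r <- contactOrder(cb, resno, L = max(resno))
    expect_equal(r$nContacts, nrow(oracle))
    expect_equal(r$co, mean(abs(oracle[, 1] - oracle[, 2])), tolerance = 1e-12)
  }
  # minimal example: two residues in contact
  cb2 <- rbind(c(0, 0, 0), c(5, 0, 0))
  r2 <- contactOrder(cb2, 1:2, L = 10)
  expect_equal(r2$co, 1)
  expect_equal(r2$rco, 0.1)
})

test_that("contact recovery counts recovered native contacts", {
  toy <- toyBundle()
  cb <- atomCoords(toy$sseModel, "CB")
  resno <- as.integer(rownames(cb))
  expect_equal(contactRecovery(cb, cb, resno, resno), 100)
  # a model blown apart recovers nothing
  far <- cb + outer(seq_len(nrow(cb)), c(1, 0, 0)) * 50
  expect_equal(contactRecovery(far, cb, resno, resno), 0)
})

test_that("contact recovery matches a hand-counted brute-force fixture", {
  set.seed(14)
  n <- 40
  native <- matrix(rnorm(3 * n, sd = 5.5), n, 3)
  model <- native + matrix(rnorm(3 * n, sd = 2.0), n, 3)
  natC <- bruteContacts(native, 1:n, minSep = 12, cutoff = 8)
  modC <- bruteContacts(model, 1:n, minSep = 12, cutoff = 8)
  skip_if(is.null(natC))
  key <- function(m) paste(m[, 1], m[, 2])
  expected <- 100 * sum(key(natC) %in% key(modC)) / nrow(natC)
  expect_equal(contactRecovery(model, native, 1:n, 1:n), expected,
               tolerance = 1e-12)
})

test_that("benchmark summaries reproduce the printed headline statistics", {
  t3 <- readBenchmarkTable(system.file("extdata", "model_quality.tsv",
                                       package = "sseFold"))
  expect_equal(nrow(t3), 66)
  s <- benchmarkSummary(t3)
  expect_equal(unname(s$nBelowRmsd),
               c(61, 50, 61, 41, 45))
  expect_equal(unname(s$nAboveCr["cr_n"]), 64)
  expect_equal(unname(s$nAboveCr["cr_p"]), 62)
  expect_equal(unname(s$nAboveCr["cr_rosetta"]), 60)
  expect_equal(round(unname(s$means[paste0("rmsd100_",
    c("nsse", "n", "psse", "p", "rosetta"))]), 2),
    c(5.50, 6.81, 6.04, 7.21, 6.42))
  expect_equal(round(unname(s$means[paste0("cr_",
    c("nsse", "n", "psse", "p", "rosetta"))]), 2),
    c(44.55, 44.96, 39.63, 41.88, 39.42))
  expect_equal(unname(s$nImprovedRmsd[c("rmsd100_n", "rmsd100_p")]), c(24, 19))
  expect_equal(unname(s$nImprovedCr[c("cr_n", "cr_p")]), c(47, 40))
})

test_that("benchmark summaries use strict inequalities", {
  t <- data.frame(pdb_id = "X", rmsd100_nsse = 8.0, rmsd100_n = 8.0,
                  rmsd100_psse = 8.0, rmsd100_p = 8.0, rmsd100_rosetta = 8.0,
                  cr_nsse = 20, cr_n = 20, cr_psse = 20, cr_p = 20,
                  cr_rosetta = 20)
  s <- benchmarkSummary(t)
  expect_true(all(s$nBelowRmsd == 0))
  expect_true(all(s$nAboveCr == 0))
  s0 <- benchmarkSummary(t, rmsdCut = 0)
  expect_true(all(s0$nBelowRmsd == 0))
  expect_error(benchmarkSummary(t[, -2]), "missing columns")
})

test_that("pool statistics table reproduces the printed averages", {
  t2 <- readBenchmarkTable(system.file("extdata", "pool_statistics.tsv",
                                       package = "sseFold"))
  expect_equal(nrow(t2), 66)
  m <- colMeans(t2[, -1])
  expect_equal(round(unname(m["psipred_q3"]), 1), 79.6)
  expect_equal(round(unname(m["psipred_found"]), 1), 96.1)
  expect_equal(round(unname(m["psipred_shift"]), 1), 3.1)
  expect_equal(unname(m["jufo_q3"]), 70.2, tolerance = 0.1)
  expect_equal(round(unname(m["combined_found"]), 1), 96.6)
  expect_equal(round(unname(m["combined_shift"]), 1), 2.7)
})

test_that("move correlation implements the windowed f1/f3 statistic", {
  # synthetic trajectory: move b improves only ever right after an
  # accepted a
  tr <- data.frame(
    move = rep(c("a", "b"), 20),
    outcome = rep(c("accepted", "improved", "improved", "improved"), 10),
    stringsAsFactors = FALSE)
  C <- moveCorrelation(tr, window = 50)
  # f1(a -> b) = 1, f3(a) = 1 -> C = 0
  expect_equal(C["a", "b"], 0)
  # brute-force recount of f1 for the window
  jImp <- which(tr$move == "b" & tr$outcome == "improved")
  f1 <- mean(vapply(jImp, function(s) {
    lo <- max(1, s - 50)
    any(tr$move[lo:(s - 1)] == "a" &
        tr$outcome[lo:(s - 1)] %in% c("accepted", "improved"))
  }, logical(1)))
  expect_equal(f1, 1)
  # move b never precedes itself improving within the window on step 2
  # floor rule: a move that never improves nor gets accepted scores -3
  tr2 <- data.frame(move = c(rep("a", 10), rep("b", 10)),
                    outcome = c(rep("rejected", 10),
                                rep(c("improved", "accepted"), 5)),
                    stringsAsFactors = FALSE)
  C2 <- moveCorrelation(tr2, window = 50)
  expect_true(all(C2["a", ] == -3))
  # degenerate window: f1 = 0 everywhere
  C0 <- moveCorrelation(tr, window = 0)
  expect_true(all(C0 == -3))
  expect_error(moveCorrelation(tr, moves = "a"), "unknown move")
})

test_that("quality metrics of a model against itself are perfect", {
  toy <- toyBundle()
  q <- qualityMetrics(toy$sseModel, toy$sseModel)
  expect_equal(q$rmsd, 0, tolerance = 1e-9)
  expect_equal(q$rmsd100, 0, tolerance = 1e-9)
  expect_equal(q$cr, 100)
  expect_equal(q$rco * nchar(toy$sseModel@sequence), q$co, tolerance = 1e-12)
})
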