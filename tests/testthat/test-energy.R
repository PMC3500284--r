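# Composite energy: term behavior, linearity, invariances.

test_that("zero weights zero the total and weight changes act linearly", {
  toy <- toyBundle()
  m <- toy$sseModel
  b0 <- scoreModel(m, toy$prediction, weightSet() * 0)
  expect_equal(b0@total, 0)
  b1 <- scoreModel(m, toy$prediction)
  w2 <- weightSet(aa_solvation = 2)
  b2 <- scoreModel(m, toy$prediction, w2)
  expect_equal(b2@total - b1@total, b1@raw[["aa_solvation"]],
               tolerance = 1e-9)
})

test_that("scoring is deterministic and the total is the weighted sum", {
  toy <- toyBundle()
  b1 <- scoreModel(toy$sseModel, toy$prediction)
  b2 <- scoreModel(toy$sseModel, toy$prediction)
  expect_identical(b1@raw, b2@raw)
  expect_equal(b1@total, sum(b1@weighted), tolerance = 1e-9)
  expect_equal(b1@weighted, b1@raw * weightSet()[energyTermNames()],
               tolerance = 1e-12)
})

test_that("a prediction is required only when agreement terms carry weight", {
  toy <- toyBundle()
  expect_error(scoreModel(toy$sseModel, NULL), "prediction required")
  w <- weightSet(ss_agreement_method1 = 0, ss_agreement_method2 = 0)
  expect_no_error(scoreModel(toy$sseModel, NULL, w))
})

test_that("clash terms are non-negative and vanish for separated SSEs", {
  m <- twoHelixModel(offset = c(15, 0, 0))
  cl <- clashTerms(m)
  expect_equal(cl$aa_clash, 0)
  expect_equal(cl$sse_pair_clash, 0)
  # parallel helices moved from 10 to 5 A separation gain axis clash
  m10 <- twoHelixModel(offset = c(10, 0, 0))
  m5 <- twoHelixModel(offset = c(5, 0, 0))
  expect_gt(clashTerms(m5)$sse_pair_clash, clashTerms(m10)$sse_pair_clash)
  expect_gte(clashTerms(m5)$aa_clash, 0)
})

test_that("aa clash only counts pairs in different SSEs", {
  # a single SSE can never clash with itself
  m <- proteinModel(ALA20, list(buildIdealSse(ALA20, 1, 12, "helix")))
  expect_equal(clashTerms(m)$aa_clash, 0)
})

test_that("removing an SSE never increases aa_clash", {
  toy <- toyBundle()
  m <- toy$sseModel
  full <- clashTerms(m)$aa_clash
  for (i in seq_along(m@sses)) {
    sub <- proteinModel(m@sequence, m@sses[-i])
    expect_lte(clashTerms(sub)$aa_clash, full + 1e-12)
  }
})

test_that("loop terms implement the declared closure rule", {
  m <- twoHelixModel(gapRes = 5L, offset = c(2, 0, 0))
  lt <- loopTerms(m)
  expect_gte(lt$loop_length, 0)
  expect_equal(lt$loop_closure, 0)
  # n_loop = 2 with a 20 A gap violates 2.56*3 + 2.0 = 9.68 A
  m2 <- twoHelixModel(gapRes = 2L, offset = c(25, 0, 0))
  g <- chainBreakGap(m2, 1)
  expect_gt(g$euclid, 2.56 * 3 + 2.0)
  expect_equal(loopTerms(m2)$loop_closure, 1000)
  # single-SSE models score zero
  single <- proteinModel(ALA20, list(buildIdealSse(ALA20, 1, 10, "helix")))
  expect_equal(unlist(loopTerms(single)), c(loop_length = 0, loop_closure = 0))
})

test_that("loop_length is non-decreasing in the gap distance", {
  prev <- -Inf
  for (off in seq(4, 30, by = 2)) {
    m <- twoHelixModel(gapRes = 4L, offset = c(off, 0, 0))
    ll <- loopTerms(m)$loop_length
    expect_gte(ll, prev - 1e-12)
    prev <- ll
  }
})

test_that("strand pairing is most favorable at the ideal distance", {
  seqs <- strrep("V", 20)
  s1 <- buildIdealSse(seqs, 1, 6, "strand")
  vals <- vapply(seq(3.2, 7.5, by = 0.25), function(d) {
    s2 <- applyTransform(buildIdealSse(seqs, 10, 15, "strand"),
                         rtTranslation(c(d, 0, 0)))
    geometryTerms(proteinModel(seqs, list(s1, s2)))$strand_pairing
  }, numeric(1))
  dists <- seq(3.2, 7.5, by = 0.25)
  expect_equal(dists[which.min(vals)], 4.75, tolerance = 0.3)
  expect_lt(min(vals), 0)
  expect_equal(vals[length(vals)], 0)  # outside the well
})

test_that("single-SSE models have no packing or pairing energy", {
  single <- proteinModel(ALA20, list(buildIdealSse(ALA20, 1, 10, "helix")))
  gt <- geometryTerms(single)
  expect_equal(gt$sse_packing, 0)
  expect_equal(gt$strand_pairing, 0)
})

test_that("extended arrangements pay more Rg penalty than compact ones", {
  seqs <- strrep("A", 70)
  mk <- function(positions) {
    sses <- lapply(1:3, function(i)
      applyTransform(buildIdealSse(seqs, (i - 1) * 24 + 1, (i - 1) * 24 + 14,
                                   "helix"),
                     rtTranslation(positions[[i]])))
    proteinModel(seqs, sses)
  }
  compact <- mk(list(c(0, 0, 0), c(10, 0, 0), c(5, 8.7, 0)))
  extended <- mk(list(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0)))
  expect_gt(geometryTerms(extended)$radius_of_gyration,
            geometryTerms(compact)$radius_of_gyration)
})

test_that("burying a hydrophobic residue lowers aa_solvation", {
  # two parallel leucine helices approach: neighbor counts rise, and the
  # hydrophobic solvation term must drop
  seqs <- strrep("L", 30)
  h1 <- buildIdealSse(seqs, 1, 12, "helix")
  far <- applyTransform(buildIdealSse(seqs, 16, 27, "helix"),
                        rtTranslation(c(25, 0, 0)))
  near <- applyTransform(buildIdealSse(seqs, 16, 27, "helix"),
                         rtTranslation(c(8, 0, 0)))
  sFar <- profileTerms(proteinModel(seqs, list(h1, far)))$aa_solvation
  sNear <- profileTerms(proteinModel(seqs, list(h1, near)))$aa_solvation
  expect_lt(sNear, sFar)
})

test_that("agreement terms follow -log p ordering", {
  n <- 20
  labels <- rep("C", n); labels[4:13] <- "E"
  pred <- predFromLabels(labels, p = 0.9)
  seqs <- strrep("A", n)
  asStrand <- proteinModel(seqs, list(buildIdealSse(seqs, 4, 13, "strand")))
  asHelix <- proteinModel(seqs, list(buildIdealSse(seqs, 4, 13, "helix")))
  pS <- profileTerms(asStrand, pred)
  pH <- profileTerms(asHelix, pred)
  expect_lt(pS$ss_agreement_method1, pH$ss_agreement_method1)
  # covering the true strand with the right state at p = 0.9 everywhere
  expect_equal(pS$ss_agreement_method1, n * -log(0.9), tolerance = 1e-9)
})

test_that("total energy is invariant under global rigid transforms", {
  toy <- toyBundle()
  m <- toy$sseModel
  b0 <- scoreModel(m, toy$prediction)@total
  set.seed(21)
  for (rep in 1:5) {
    t <- randomTransform()
    moved <- proteinModel(m@sequence,
                          lapply(m@sses, applyTransform, t = t))
    expect_equal(scoreModel(moved, toy$prediction)@total, b0,
                 tolerance = 1e-6)
  }
})

test_that("the designed native beats almost all random rigid shuffles", {
  toy <- toyBundle()
  m <- toy$sseModel
  native <- scoreModel(m, toy$prediction)@total
  set.seed(314)
  shuffled <- vapply(1:200, function(i) {
    sses <- lapply(m@sses, function(s) {
      t <- rtCompose(rtTranslation(rnorm(3, sd = 8)),
                     rtRotation(rnorm(3), runif(1, 0, 360), sseAxis(s)$center))
      applyTransform(s, t)
    })
    scoreModel(proteinModel(m@sequence, sses), toy$prediction)@total
  }, numeric(1))
  expect_gte(mean(native < shuffled), 0.95)
})
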