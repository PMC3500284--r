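# Move registry, stage move sets, proposals and their invariants.

test_that("move sets renormalize and exclude by pool content", {
  toy <- toyBundle()
  asm <- buildMoveSet(toy$pool, "assembly")
  expect_equal(sum(asm$prob), 1, tolerance = 1e-9)
  # helix-only pool: every strand/sheet move has probability 0
  strandMoves <- asm$name[asm$strandSpecific]
  expect_true(length(strandMoves) > 0)
  expect_true(all(asm$prob[asm$strandSpecific] == 0))
  ref <- buildMoveSet(toy$pool, "refinement")
  expect_equal(sum(ref$prob), 1, tolerance = 1e-9)
  expect_true(all(ref$prob[ref$strandSpecific] == 0))
  # mixed pool: add/remove/swap moves present with nonzero probability
  mixed <- new("SSEPool")
  mixed@entries <- data.frame(type = c("helix", "strand", "strand"),
                              first = c(1L, 12L, 20L),
                              last = c(8L, 16L, 24L), source = "x",
                              stringsAsFactors = FALSE)
  mixed@sequence <- strrep("A", 30)
  asmMix <- buildMoveSet(mixed, "assembly")
  for (cat in c("add", "remove", "swap", "single_sse", "sse_pair", "domain"))
    expect_gt(sum(asmMix$prob[asmMix$category == cat]), 0)
  expect_error(buildMoveSet(new("SSEPool"), "assembly"), "empty pool")
})

test_that("resize moves participate in both stages", {
  toy <- toyBundle()
  for (stage in c("assembly", "refinement")) {
    ms <- buildMoveSet(toy$pool, stage)
    expect_true(all(c("sse_resize_nterm", "sse_resize_cterm") %in%
                    ms$name[ms$prob > 0]))
  }
})

test_that("inapplicable proposals are the skipped marker, not an error", {
  toy <- toyBundle()
  full <- toy$sseModel  # already contains every pool region
  set.seed(1)
  out <- propose("add_sse_random", full, toy$pool)
  expect_true(out$skipped)
  expect_null(out$model)
  # sheet moves on a strand-free model skip
  expect_true(propose("domain_flip_sheet", full, toy$pool)$skipped)
  expect_true(propose("sheet_divide", full, toy$pool)$skipped)
  # removing from a single-SSE model skips
  single <- proteinModel(full@sequence, full@sses[1])
  expect_true(propose("remove_random", single, toy$pool)$skipped)
})

test_that("proposals are reproducible for a fixed seed and never mutate the input", {
  toy <- toyBundle()
  m <- toy$sseModel
  snapshot <- lapply(m@sses, function(s) s@coords)
  set.seed(7); a <- propose("sse_translate_large", m, toy$pool)
  set.seed(7); b <- propose("sse_translate_large", m, toy$pool)
  expect_identical(a$model@sses[[1]]@coords, b$model@sses[[1]]@coords)
  expect_identical(lapply(m@sses, function(s) s@coords), snapshot)
})

test_that("swap exchanges placements and sequence segments", {
  toy <- toyBundle()
  m <- toy$sseModel
  set.seed(3)
  out <- propose("swap_sses", m, toy$pool)
  expect_false(out$skipped)
  before <- lapply(m@sses, function(s) s@frame@translation)
  after <- lapply(out$model@sses, function(s) s@frame@translation)
  # the multiset of occupied positions is unchanged
  fmt <- function(x) sort(vapply(x, function(v) paste(round(v, 6), collapse = ","),
                                 character(1)))
  expect_equal(fmt(before), fmt(after))
  # bounds unchanged as a set
  expect_equal(sort(vapply(out$model@sses, function(s) s@first, integer(1))),
               sort(vapply(m@sses, function(s) s@first, integer(1))))
})

test_that("short-loop additions always satisfy the closure rule", {
  toy <- toyBundle()
  base <- proteinModel(toy$sseModel@sequence, toy$sseModel@sses[1])
  set.seed(11)
  hits <- 0
  for (rep in 1:100) {
    out <- propose("add_sse_short_loop", base, toy$pool)
    if (out$skipped) next
    hits <- hits + 1
    m <- out$model
    for (i in seq_len(length(m@sses) - 1)) {
      g <- chainBreakGap(m, i)
      expect_lte(g$euclid, 2.56 * (g$nLoop + 1) + 2.0)
    }
  }
  expect_gt(hits, 50)
})

test_that("resize moves respect bounds and minimum lengths", {
  toy <- toyBundle()
  m <- toy$sseModel
  set.seed(5)
  for (rep in 1:50) {
    for (mv in c("sse_resize_nterm", "sse_resize_cterm")) {
      out <- propose(mv, m, toy$pool)
      if (out$skipped) next
      expect_true(isTRUE(validObject(out$model, test = TRUE)))
      for (s in out$model@sses)
        expect_gte(sseLength(s), minSseLength(s@ssType))
    }
  }
})

test_that("splitting keeps both parts at minimum length and preserves coordinates", {
  seqs <- strrep("A", 30)
  m <- proteinModel(seqs, list(buildIdealSse(seqs, 1, 14, "helix")))
  pool <- new("SSEPool")
  pool@entries <- data.frame(type = "helix", first = 1L, last = 14L,
                             source = "x", stringsAsFactors = FALSE)
  pool@sequence <- seqs
  set.seed(2)
  out <- propose("sse_split", m, pool)
  expect_false(out$skipped)
  expect_equal(length(out$model@sses), 2L)
  ca0 <- atomCoords(m, "CA"); ca1 <- atomCoords(out$model, "CA")
  expect_equal(ca1, ca0, tolerance = 1e-9)
  for (s in out$model@sses) expect_gte(sseLength(s), 5L)
})

test_that("sheet flips preserve internal sheet geometry", {
  seqs <- strrep("V", 40)
  mk <- function(first, x) applyTransform(
    buildIdealSse(seqs, first, first + 5L, "strand"),
    rtTranslation(c(x, 0, 0)))
  m <- proteinModel(seqs, list(mk(1, 0), mk(10, 4.75), mk(20, 9.5)))
  pool <- new("SSEPool")
  pool@entries <- data.frame(type = "strand", first = c(1L, 10L, 20L),
                             last = c(6L, 15L, 25L), source = "x",
                             stringsAsFactors = FALSE)
  pool@sequence <- seqs
  set.seed(9)
  out <- propose("domain_flip_sheet", m, pool)
  expect_false(out$skipped)
  d0 <- dist(atomCoords(m, "CA"))
  d1 <- dist(atomCoords(out$model, "CA"))
  expect_lt(max(abs(d0 - d1)), 1e-6)
  # the sheet moved as a rigid body but is not identical in place
  expect_gt(max(abs(atomCoords(m, "CA") - atomCoords(out$model, "CA"))), 0.1)
})

test_that("assembly amplitudes stochastically dominate refinement amplitudes", {
  toy <- toyBundle()
  m <- toy$sseModel
  ca0 <- atomCoords(m@sses[[1]], "CA")
  shift <- function(mv) {
    out <- propose(mv, m, toy$pool)
    idx <- which(vapply(seq_along(m@sses), function(i)
      !isTRUE(all.equal(out$model@sses[[i]]@coords, m@sses[[i]]@coords)),
      logical(1)))[1]
    mean(sqrt(rowSums((atomCoords(out$model@sses[[idx]], "CA") -
                       atomCoords(m@sses[[idx]], "CA"))^2)))
  }
  set.seed(31)
  large <- replicate(120, shift("sse_translate_large"))
  small <- replicate(120, shift("sse_translate_small"))
  # empirical CDF dominance on a grid
  grid <- seq(0, 8, by = 0.5)
  cdfL <- ecdf(large)(grid); cdfS <- ecdf(small)(grid)
  expect_true(all(cdfS >= cdfL - 0.05))
  expect_gt(mean(large), mean(small))
})

test_that("move selection frequencies match the configured probabilities", {
  toy <- toyBundle()
  ms <- buildMoveSet(toy$pool, "assembly")
  set.seed(77)
  draws <- sample.int(nrow(ms), 1e5, replace = TRUE, prob = ms$prob)
  freq <- tabulate(draws, nbins = nrow(ms)) / 1e5
  # 3-sigma multinomial bounds
  for (i in seq_len(nrow(ms))) {
    sigma <- sqrt(ms$prob[i] * (1 - ms$prob[i]) / 1e5)
    expect_lt(abs(freq[i] - ms$prob[i]), 3.5 * sigma + 1e-12)
  }
})

test_that("random moves always yield valid models (fuzz)", {
  toy <- toyBundle()
  pool <- toy$pool
  ms <- buildMoveSet(pool, "assembly")
  active <- ms[ms$prob > 0, ]
  set.seed(123)
  m <- proteinModel(toy$sseModel@sequence, toy$sseModel@sses[2])
  bad <- 0
  for (step in 1:2000) {
    mv <- active[sample.int(nrow(active), 1, prob = active$prob), ]
    out <- propose(mv, m, pool)
    if (out$skipped) next
    v <- validObject(out$model, test = TRUE)
    if (!isTRUE(v)) bad <- bad + 1
    else if (runif(1) < 0.5) m <- out$model  # walk the model space
    expect_true(all(is.finite(atomCoords(out$model, "CA"))))
  }
  expect_equal(bad, 0)
})
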