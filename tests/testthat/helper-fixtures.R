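# Shared fixtures, built in code.

ALA20 <- strrep("A", 60)

# a two-helix model with a given chain-break geometry
twoHelixModel <- function(gapRes = 5L, offset = c(10, 0, 0), len = 10L) {
  seq <- strrep("A", 2L * len + gapRes + 10L)
  h1 <- buildIdealSse(seq, 1L, len, "helix")
  h2 <- buildIdealSse(seq, len + gapRes + 1L, 2L * len + gapRes, "helix")
  proteinModel(seq, list(h1, applyTransform(h2, rtTranslation(offset))))
}

# deterministic toy bundle shared across tests (cached per session)
toyBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateToyProtein(threeHelixBundleSpec(),
                                                     seed = 42)
    cache
  }
})

# small perfect prediction matrix for a label string
predFromLabels <- function(labels, p = 0.9, methods = c("psipred", "jufo")) {
  n <- length(labels)
  m <- matrix((1 - p) / 2, n, 3, dimnames = list(NULL, c("H", "E", "C")))
  m[cbind(seq_len(n), match(labels, c("H", "E", "C")))] <- p
  args <- rep(list(m), length(methods))
  names(args) <- methods
  do.call(ssPrediction, args)
}

# random rigid transform
randomTransform <- function() {
  ax <- rnorm(3)
  rtCompose(rtTranslation(rnorm(3, sd = 5)),
            rtRotation(ax, runif(1, 0, 360), rnorm(3, sd = 3)))
}

# brute-force contact list oracle (O(n^2) recount in plain R)
bruteContacts <- function(cb, resno, minSep, cutoff) {
  out <- NULL
  n <- nrow(cb)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (abs(resno[i] - resno[j]) < minSep) next
    if (sqrt(sum((cb[i, ] - cb[j, ])^2)) < cutoff)
      out <- rbind(out, sort(c(resno[i], resno[j])))
  }
  out
}
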