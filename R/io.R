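# File formats: PDB coordinates (through bio3d), PSIPRED .ss2 and the
# generic three-column prediction TSV, pool files, DSSP-style assignment
# files, trajectory TSVs and run manifests.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

#' Construct a secondary structure prediction object
#'
#' @param ... named n x 3 probability matrices (columns H, E, C), e.g.
#'   `psipred = m1, jufo = m2`
#' @param sequence optional amino acid sequence
#' @return an [SSPrediction-class]
#' @export
ssPrediction <- function(..., sequence = "") {
  prob <- list(...)
  if (length(prob) == 1L && is.list(prob[[1]]) && !is.matrix(prob[[1]]))
    prob <- prob[[1]]
  if (!length(prob)) stop("at least one prediction method required")
  prob <- lapply(prob, function(p) {
    p <- as.matrix(p)
    colnames(p) <- SS_STATES
    p
  })
  obj <- new("SSPrediction")
  obj@prob <- prob
  obj@sequence <- sequence
  validObject(obj)
  obj
}

# renormalize rows whose sums are within tol of 1, else error
normalizeProbs <- function(p, tol = 0.02, what = "prediction") {
  s <- rowSums(p)
  bad <- abs(s - 1) > tol
  if (any(bad))
    stop(sprintf("%s probabilities at row %d sum to %.3f (must be 1 +/- %.2f)",
                 what, which(bad)[1], s[which(bad)[1]], tol))
  p / s
}

#' Read a PSIPRED .ss2 prediction file
#'
#' Standard six-column ss2 layout: index, residue, state, p(coil),
#' p(helix), p(strand).  Probabilities off by at most 0.02 are
#' renormalized; larger deviations raise an error, as do non-contiguous
#' residue indices.
#'
#' @param path file path
#' @param method slot name for the prediction (default "psipred")
#' @return an [SSPrediction-class] with a single method
#' @export
readSs2 <- function(path, method = "psipred") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop("malformed ss2 line ", bad[1], ": expected 6 fields")
  idx <- as.integer(vapply(parts, `[`, character(1), 1))
  if (anyNA(idx) || !identical(idx, seq_along(idx)))
    stop("non-contiguous residue indices in ", path)
  aa <- vapply(parts, `[`, character(1), 2)
  num <- function(k) as.numeric(vapply(parts, `[`, character(1), k))
  p <- cbind(H = num(5), E = num(6), C = num(4))
  if (anyNA(p)) stop("non-numeric probability in ", path)
  p <- normalizeProbs(p, what = "ss2")
  args <- list(p)
  names(args) <- method
  ssPrediction(args, sequence = paste(aa, collapse = ""))
}

#' Read a generic three-state prediction TSV
#'
#' Columns: index, residue, p(helix), p(strand), p(coil).
#'
#' @param path file path
#' @param method slot name for the prediction (default "jufo")
#' @return an [SSPrediction-class] with a single method
#' @export
readPredTsv <- function(path, method = "jufo") {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 5L) stop("prediction TSV must have 5 columns")
  idx <- as.integer(df[[1]])
  if (anyNA(idx) || !identical(idx, seq_along(idx)))
    stop("non-contiguous residue indices in ", path)
  p <- cbind(H = as.numeric(df[[3]]), E = as.numeric(df[[4]]),
             C = as.numeric(df[[5]]))
  p <- normalizeProbs(p, what = "prediction TSV")
  args <- list(p)
  names(args) <- method
  ssPrediction(args, sequence = paste(df[[2]], collapse = ""))
}

#' Combine per-method predictions
#'
#' @param ... [SSPrediction-class] objects with distinct method names
#' @return a combined [SSPrediction-class]
#' @export
combinePredictions <- function(...) {
  preds <- list(...)
  prob <- do.call(c, lapply(preds, function(p) p@prob))
  seqs <- unique(Filter(nzchar, vapply(preds, function(p) p@sequence,
                                       character(1))))
  if (length(seqs) > 1) stop("predictions disagree on the sequence")
  ssPrediction(prob, sequence = if (length(seqs)) seqs[1] else "")
}

#' Read and write pool files
#'
#' One entry per line: `HELIX <first> <last>` or `STRAND <first> <last>`,
#' 1-based inclusive.
#'
#' @param path file path
#' @param sequence amino acid sequence the pool refers to
#' @return `readPoolFile`: an [SSEPool-class]
#' @export
readPoolFile <- function(path, sequence) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 3L |
               !vapply(parts, function(x) x[1] %in% c("HELIX", "STRAND"),
                       logical(1)))
  if (length(bad))
    stop("malformed pool line ", bad[1], " in ", path)
  e <- data.frame(
    type = ifelse(vapply(parts, `[`, character(1), 1) == "HELIX",
                  "helix", "strand"),
    first = as.integer(vapply(parts, `[`, character(1), 2)),
    last = as.integer(vapply(parts, `[`, character(1), 3)),
    source = "file", stringsAsFactors = FALSE)
  p <- new("SSEPool")
  p@entries <- collapsePoolEntries(e)
  p@sequence <- sequence
  p@source <- basename(path)
  validObject(p)
  p
}

#' @rdname readPoolFile
#' @param pool an [SSEPool-class]
#' @export
writePoolFile <- function(pool, path) {
  e <- pool@entries
  writeLines(sprintf("%s %d %d",
                     ifelse(e$type == "helix", "HELIX", "STRAND"),
                     e$first, e$last), path)
  invisible(path)
}

#' Read a DSSP-style per-residue assignment file
#'
#' Two whitespace-separated columns: residue index and one-letter state.
#' DSSP letters are reduced to three states (H/G/I to helix, E/B to
#' strand, everything else coil).
#'
#' @param path file path
#' @return character vector of "H"/"E"/"C" states
#' @export
readAssignment <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("assignment file needs index + state columns")
  idx <- as.integer(df[[1]])
  if (anyNA(idx) || !identical(idx, seq_along(idx)))
    stop("non-contiguous residue indices in ", path)
  st <- toupper(df[[2]])
  out <- ifelse(st %in% c("H", "G", "I"), "H",
                ifelse(st %in% c("E", "B"), "E", "C"))
  out
}

#' @rdname readAssignment
#' @param labels character vector of states
#' @export
writeAssignment <- function(labels, path) {
  writeLines(sprintf("%d %s", seq_along(labels), labels), path)
  invisible(path)
}

#' Write a protein model as PDB
#'
#' Emits fixed-column ATOM records for the five tracked atoms per
#' residue through bio3d.  The glycine pseudo-CB is written with the
#' distinguishing atom name HA2 (its geometric position); [readPdbModel]
#' maps it back.
#'
#' @param model a [ProteinModel-class]
#' @param path output file
#' @param chain chain identifier (default "A")
#' @export
writePdbModel <- function(model, path, chain = "A") {
  aa <- strsplit(model@sequence, "")[[1]]
  pieces <- list()
  for (s in model@sses) {
    for (r in seq_len(sseLength(s))) {
      idx <- s@first + r - 1L
      pieces[[as.character(idx)]] <- s@coords[(r - 1L) * N_ATOMS + 1:5, ,
                                              drop = FALSE]
    }
  }
  for (nm in names(model@coil)) pieces[[nm]] <- model@coil[[nm]]
  idx <- sort(as.integer(names(pieces)))
  xyz <- c(); resno <- c(); resid <- c(); elety <- c()
  for (i in idx) {
    m <- pieces[[as.character(i)]]
    names <- ATOM_NAMES
    if (aa[i] == "G") names[5] <- "HA2"
    for (k in 1:5) {
      xyz <- c(xyz, m[k, ])
      resno <- c(resno, i)
      resid <- c(resid, AA1TO3[[aa[i]]])
      elety <- c(elety, names[k])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(chain, length(resno)))
  invisible(path)
}

#' Read a protein model from PDB
#'
#' Extracts N, CA, C, O and CB (HA2 for glycine) ATOM records.  Residues
#' missing any of N/CA/C are excluded with a warning; missing O or CB
#' atoms are rebuilt from ideal geometry.  When no SSE definitions are
#' supplied, contiguous residue runs become SSEs typed by their
#' per-residue rise (> 2.5 Angstrom reads as strand), and runs shorter
#' than the minimum SSE lengths become coil.
#'
#' @param path PDB file
#' @param chain chain selector (default: first chain present)
#' @param sseDefs optional data.frame (type, first, last) defining the
#'   SSE layout
#' @param sequence optional full sequence; defaults to the file content
#'   with unobserved positions filled with alanine
#' @return a [ProteinModel-class]
#' @export
readPdbModel <- function(path, chain = NULL, sseDefs = NULL, sequence = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  resnos <- sort(unique(at$resno))
  coords <- list(); aaMap <- c(); dropped <- 0L
  for (i in resnos) {
    rows <- at[at$resno == i, , drop = FALSE]
    aa1 <- AA3TO1[rows$resid[1]]
    if (is.na(aa1)) { dropped <- dropped + 1L; next }
    get <- function(name) {
      r <- rows[rows$elety == name, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      as.numeric(r[1, c("x", "y", "z")])
    }
    nA <- get("N"); caA <- get("CA"); cA <- get("C")
    if (is.null(nA) || is.null(caA) || is.null(cA)) {
      warning("residue ", i, ": incomplete backbone, excluded")
      dropped <- dropped + 1L
      next
    }
    oA <- get("O")
    if (is.null(oA))
      oA <- placeAtom(nA, caA, cA, BOND_C_O, ANGLE_CA_C_O, 140)
    cbA <- if (aa1 == "G") get("HA2") else get("CB")
    if (is.null(cbA)) cbA <- get("CB")
    if (is.null(cbA)) {
      bb <- if (aa1 == "G") BOND_CA_HA else BOND_CA_CB
      cbA <- placeAtom(cA, nA, caA, bb, ANGLE_N_CA_CB, DIHEDRAL_CB)
    }
    m <- rbind(nA, caA, cA, oA, cbA)
    rownames(m) <- ATOM_NAMES
    coords[[as.character(i)]] <- m
    aaMap[as.character(i)] <- aa1
  }
  if (!length(coords)) stop("no usable residues in ", path)
  if (dropped) message(dropped, " residue(s) excluded or skipped")
  present <- sort(as.integer(names(coords)))
  n <- max(present)
  if (is.null(sequence)) {
    seqv <- rep("A", n)
    seqv[present] <- aaMap[as.character(present)]
    sequence <- paste(seqv, collapse = "")
  }
  if (is.null(sseDefs)) {
    runs <- split(present, cumsum(c(1, diff(present) != 1)))
    sseDefs <- do.call(rbind, lapply(runs, function(r) {
      if (length(r) < 3L) return(NULL)
      ca <- t(vapply(as.character(r), function(k) coords[[k]][2, ], numeric(3)))
      span <- norm3(ca[nrow(ca), ] - ca[1, ]) / (length(r) - 1)
      type <- if (span > 2.5) "strand" else "helix"
      if (length(r) < minSseLength(type)) return(NULL)
      data.frame(type = type, first = r[1], last = r[length(r)])
    }))
  }
  sses <- list()
  inSse <- integer(0)
  for (k in seq_len(NROW(sseDefs))) {
    d <- sseDefs[k, ]
    res <- seq.int(d$first, d$last)
    if (!all(as.character(res) %in% names(coords))) next
    cm <- do.call(rbind, lapply(as.character(res), function(i) coords[[i]]))
    s <- newSSE(d$type, d$first, d$last,
                substring(sequence, d$first, d$last), cm,
                new("RigidTransform"))
    s@frame <- deriveFrame(s)
    sses <- c(sses, s)
    inSse <- c(inSse, res)
  }
  coil <- coords[setdiff(as.character(present), as.character(inSse))]
  m <- newModel(sequence, sses, coil)
  validObject(m)
  m
}

#' Read and write trajectory TSVs
#'
#' Tab-separated per-step records with a versioned header line.
#'
#' @param trajectory trajectory data.frame from [runStage]/[fold]
#' @param path file path
#' @export
writeTrajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sseFold trajectory v1", con)
  write.table(trajectory, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# sseFold trajectory", first))
    stop("not a trajectory file (missing version header): ", path)
  read.table(path, header = TRUE, sep = "\t", skip = 1,
             stringsAsFactors = FALSE)
}

# tiny polynomial rolling hash for run manifests (hex string)
textHash <- function(text) {
  bytes <- utf8ToInt(text)
  h1 <- 17; h2 <- 59
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 65521
    h2 <- (h2 * 37 + b) %% 65519
  }
  sprintf("%04x%04x", h1, h2)
}

#' Write a run manifest
#'
#' Records the seed and a hash of the configuration so that runs can be
#' reproduced byte-identically.
#'
#' @param path output file
#' @param seed integer seed of the run
#' @param config configuration list
#' @export
writeManifest <- function(path, seed, config) {
  writeLines(c(sprintf("seed: %d", as.integer(seed)),
               sprintf("config_hash: %s",
                       textHash(yaml::as.yaml(config)))), path)
  invisible(path)
}

#' Read a transcribed benchmark quality table
#'
#' TSV with a protein id column and the benchmark column roles (RMSD100
#' and contact recovery for native/predicted pools, SSE-only/complete
#' models, and the comparator method).
#'
#' @param path TSV file
#' @return data.frame
#' @export
readBenchmarkTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
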