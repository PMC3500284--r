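# Idealized backbone geometry: internal-coordinate chain building (NeRF),
# canonical SSE templates, rigid transforms, axes and chain-break gaps.

# Textbook backbone internal coordinates.  The source publication leaves
# the idealization parameters open; these standard values are declared
# package defaults (see the methods vignette).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.521
BOND_CA_HA <- 1.090  # glycine pseudo-CB bond length (HA2 position)
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 116.5
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
ANGLE_N_CA_CB <- 110.4
DIHEDRAL_CB <- -122.6  # C-N-CA-CB improper placing CB for L-amino acids

IDEAL_DIHEDRALS <- list(
  helix = c(phi = -57, psi = -47, omega = 180),
  strand = c(phi = -135, psi = 135, omega = 180))

deg2rad <- function(x) x * pi / 180

norm3 <- function(v) sqrt(sum(v * v))
unit3 <- function(v) v / norm3(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) placement: returns the
#' position of atom D given the three preceding atoms A, B, C, the C-D
#' bond length, the B-C-D bond angle and the A-B-C-D torsion.
#'
#' @param a,b,c numeric length-3 positions of the three reference atoms
#' @param bond C-D bond length (Angstrom)
#' @param angle B-C-D angle (degrees)
#' @param torsion A-B-C-D torsion (degrees)
#' @return numeric length-3 position of D
#' @export
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an n-residue backbone with fixed (phi, psi, omega), returning a
# (5n) x 3 matrix (atom order N, CA, C, O, CB per residue).  glyMask marks
# residues whose pseudo-CB goes to the HA2 position.
buildChain <- function(n, phi, psi, omega, glyMask) {
  stopifnot(n >= 1)
  coords <- matrix(NA_real_, N_ATOMS * n, 3)
  row <- function(i, atom) (i - 1L) * N_ATOMS + match(atom, ATOM_NAMES)
  # seed the first three backbone atoms in a local frame
  nPos <- c(0, 0, 0)
  caPos <- c(BOND_N_CA, 0, 0)
  angNCA <- deg2rad(ANGLE_N_CA_C)
  cPos <- caPos + BOND_CA_C * c(-cos(angNCA), sin(angNCA), 0)
  coords[row(1, "N"), ] <- nPos
  coords[row(1, "CA"), ] <- caPos
  coords[row(1, "C"), ] <- cPos
  for (i in seq_len(n)) {
    nI <- coords[row(i, "N"), ]
    caI <- coords[row(i, "CA"), ]
    cI <- coords[row(i, "C"), ]
    coords[row(i, "O"), ] <- placeAtom(nI, caI, cI, BOND_C_O, ANGLE_CA_C_O,
                                       psi + 180)
    bb <- if (glyMask[i]) BOND_CA_HA else BOND_CA_CB
    coords[row(i, "CB"), ] <- placeAtom(cI, nI, caI, bb, ANGLE_N_CA_CB,
                                        DIHEDRAL_CB)
    if (i < n) {
      nNext <- placeAtom(nI, caI, cI, BOND_C_N, ANGLE_CA_C_N, psi)
      caNext <- placeAtom(caI, cI, nNext, BOND_N_CA, ANGLE_C_N_CA, omega)
      cNext <- placeAtom(cI, nNext, caNext, BOND_CA_C, ANGLE_N_CA_C, phi)
      coords[row(i + 1, "N"), ] <- nNext
      coords[row(i + 1, "CA"), ] <- caNext
      coords[row(i + 1, "C"), ] <- cNext
    }
  }
  coords
}

# Deterministic canonicalization: CA centroid at the origin, the
# element axis along +z with the N-terminus at negative z, and the first
# CA fixing the azimuth.  For helices the axis is the exact rotation
# axis recovered from cross products of successive second differences
# of the CA trace; strands use the dominant principal axis.
helixAxis <- function(ca) {
  n <- nrow(ca)
  v <- ca[seq_len(n - 2), , drop = FALSE] +
       ca[seq.int(3, n), , drop = FALSE] -
       2 * ca[seq.int(2, n - 1), , drop = FALSE]
  h <- c(0, 0, 0)
  for (j in seq_len(nrow(v) - 1)) h <- h + cross3(v[j, ], v[j + 1, ])
  if (norm3(h) < 1e-8) return(NULL)
  unit3(h)
}

canonicalize <- function(coords, n, ssType = "strand") {
  ca <- coords[seq.int(2L, by = N_ATOMS, length.out = n), , drop = FALSE]
  ctr <- colMeans(ca)
  m <- sweep(ca, 2, ctr)
  ax <- if (ssType == "helix" && n >= 4L) helixAxis(ca) else NULL
  if (is.null(ax)) ax <- svd(m)$v[, 1]
  if (sum((m[n, ] - m[1, ]) * ax) < 0) ax <- -ax
  ref <- m[1, ] - sum(m[1, ] * ax) * ax
  if (norm3(ref) < 1e-8) ref <- c(1, 0, 0) - ax[1] * ax
  x <- unit3(ref)
  y <- cross3(ax, x)
  q <- rbind(x, y, ax)  # world -> canonical
  sweep(coords, 2, ctr) %*% t(q)
}

canonicalTemplateCache <- new.env(parent = emptyenv())

# prototype objects cloned by the fast internal constructors (S4
# instantiation via new() is too slow for the Monte Carlo hot path)
protoCache <- new.env(parent = emptyenv())
proto <- function(class) {
  hit <- protoCache[[class]]
  if (is.null(hit)) {
    hit <- new(class)
    protoCache[[class]] <- hit
  }
  hit
}

# template lookup keyed directly by type + segment sequence
templateForSse <- function(ssType, aaSeq) {
  key <- paste0(ssType, ":", aaSeq)
  hit <- canonicalTemplateCache[[key]]
  if (is.null(hit)) {
    hit <- canonicalTemplate(ssType, strsplit(aaSeq, "")[[1]] == "G")
    canonicalTemplateCache[[key]] <- hit
  }
  hit
}

# Canonical-frame coordinates for a segment: cached by type + glycine mask.
canonicalTemplate <- function(ssType, glyMask) {
  key <- paste0(ssType, ":", paste(as.integer(glyMask), collapse = ""))
  hit <- canonicalTemplateCache[[key]]
  if (!is.null(hit)) return(hit)
  d <- IDEAL_DIHEDRALS[[ssType]]
  n <- length(glyMask)
  coords <- buildChain(n, d["phi"], d["psi"], d["omega"], glyMask)
  coords <- canonicalize(coords, n, ssType)
  z <- coords[seq.int(2L, by = N_ATOMS, length.out = n), 3]
  attr(coords, "axisLength") <- max(z) - min(z)
  canonicalTemplateCache[[key]] <- coords
  coords
}

#' Build an idealized secondary structure element
#'
#' Constructs an SSE with ideal backbone dihedrals (helix phi = -57,
#' psi = -47; strand phi = -135, psi = +135; omega = 180) in the canonical
#' frame: CA centroid at the origin, principal axis along +z, first
#' residue at negative z.  Construction is deterministic.
#'
#' @param sequence full amino acid sequence (one-letter codes)
#' @param first,last 1-based inclusive bounds of the segment
#' @param ssType "helix" or "strand"
#' @return an [SSE-class] in the canonical frame (identity body frame)
#' @examples
#' h <- buildIdealSse(strrep("A", 20), 3, 12, "helix")
#' sseAxis(h)$direction  # (0, 0, 1)
#' @export
buildIdealSse <- function(sequence, first, last, ssType) {
  ssType <- match.arg(ssType, c("helix", "strand"))
  first <- as.integer(first); last <- as.integer(last)
  if (last < first) stop("last must be >= first")
  n <- last - first + 1L
  if (n < minSseLength(ssType))
    stop(sprintf("segment too short: %s needs >= %d residues", ssType,
                 minSseLength(ssType)))
  if (last > nchar(sequence)) stop("segment bounds exceed sequence")
  seg <- substring(sequence, first, last)
  aa <- strsplit(seg, "")[[1]]
  if (!all(aa %in% AA1)) stop("unknown residue code in segment: ", seg)
  coords <- templateForSse(ssType, seg)
  newSSE(ssType, first, last, seg, coords, newRT(diag(3), c(0, 0, 0)))
}

# Internal constructors skipping validity and slot-class checks (the
# Monte Carlo hot path); slots are set as attributes directly.
newSSE <- function(ssType, first, last, aaSeq, coords, frame) {
  s <- proto("SSE")
  attr(s, "ssType") <- ssType
  attr(s, "first") <- as.integer(first)
  attr(s, "last") <- as.integer(last)
  attr(s, "aaSeq") <- aaSeq
  attr(s, "coords") <- coords
  attr(s, "frame") <- frame
  s
}

newRT <- function(rotation, translation) {
  t <- proto("RigidTransform")
  attr(t, "rotation") <- rotation
  attr(t, "translation") <- translation
  t
}

#' Compose, invert and apply rigid transforms
#'
#' `rtCompose(t2, t1)` is the transform applying `t1` first, then `t2`.
#'
#' @param t,t1,t2 [RigidTransform-class] objects
#' @return a [RigidTransform-class]
#' @export
rtCompose <- function(t2, t1) {
  newRT(t2@rotation %*% t1@rotation,
        as.vector(t2@rotation %*% t1@translation) + t2@translation)
}

#' @rdname rtCompose
#' @export
rtInverse <- function(t) {
  newRT(t(t@rotation), as.vector(-t(t@rotation) %*% t@translation))
}

#' @rdname rtCompose
#' @param x an n x 3 coordinate matrix
#' @export
rtApply <- function(t, x) {
  y <- x %*% t(t@rotation)
  tr <- t@translation
  y[, 1] <- y[, 1] + tr[1]
  y[, 2] <- y[, 2] + tr[2]
  y[, 3] <- y[, 3] + tr[3]
  y
}

#' Rotation about an arbitrary axis
#'
#' @param axis direction vector (normalized internally)
#' @param angle rotation angle in degrees
#' @param center a point on the rotation axis
#' @return [RigidTransform-class] rotating by `angle` about the line
#'   through `center` along `axis`
#' @export
rtRotation <- function(axis, angle, center = c(0, 0, 0)) {
  u <- unit3(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  newRT(R, as.vector(center - R %*% center))
}

#' @rdname rtRotation
#' @param shift translation vector
#' @export
rtTranslation <- function(shift) {
  newRT(diag(3), as.numeric(shift))
}

#' Apply a rigid transform to an SSE
#'
#' Maps all atom coordinates by `t` and composes the body frame with `t`;
#' internal distances are preserved exactly.
#'
#' @param sse an [SSE-class]
#' @param t a [RigidTransform-class]
#' @return the transformed [SSE-class]
#' @export
applyTransform <- function(sse, t) {
  R <- t@rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rotation must be a proper orthonormal matrix")
  s <- sse
  attr(s, "coords") <- rtApply(t, sse@coords)
  attr(s, "frame") <- rtCompose(t, sse@frame)
  s
}

# Kabsch superposition core: optimal proper rotation + translation mapping
# x onto y (both n x 3).  Returns list(rotation, translation, rmsd).
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  h <- crossprod(x0, y0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- x0 %*% t(R)
  list(rotation = R, translation = as.vector(cy - R %*% cx),
       rmsd = sqrt(mean(rowSums((fit - y0)^2))))
}

#' Re-derive the body frame of a placed SSE
#'
#' Superimposes the canonical template onto the SSE's coordinates
#' (Kabsch); for rigidly placed ideal elements this reproduces the stored
#' body frame to machine precision.
#'
#' @param sse an [SSE-class]
#' @return a [RigidTransform-class]
#' @export
deriveFrame <- function(sse) {
  tmpl <- templateForSse(sse@ssType, sse@aaSeq)
  k <- kabsch(tmpl, sse@coords)
  newRT(k$rotation, k$translation)
}

# Rebuild a segment's ideal coordinates and place them with a given frame.
placeIdealSse <- function(sequence, first, last, ssType, frame) {
  applyTransform(fastIdealSse(sequence, first, last, ssType), frame)
}

# buildIdealSse without input validation (hot path; inputs are
# internally generated)
fastIdealSse <- function(sequence, first, last, ssType) {
  seg <- substring(sequence, first, last)
  newSSE(ssType, first, last, seg, templateForSse(ssType, seg),
         newRT(diag(3), c(0, 0, 0)))
}

#' Axis of a secondary structure element
#'
#' The principal axis of the element, oriented from the N- to the
#' C-terminus.  In the canonical frame the axis is +z with the CA
#' centroid at the origin, so for a rigidly placed ideal element the
#' axis is the body frame applied to (0, 0, 1); [sseAxisFit] computes
#' the same quantity by fitting the CA coordinates directly.
#'
#' @param sse an [SSE-class]
#' @return list with `center` (CA centroid), `direction` (unit vector,
#'   N to C), and `length` (span of CA projections onto the axis, Angstrom)
#' @export
sseAxis <- function(sse) {
  tmpl <- templateForSse(sse@ssType, sse@aaSeq)
  list(center = as.vector(sse@frame@translation),
       direction = as.vector(sse@frame@rotation[, 3]),
       length = attr(tmpl, "axisLength"))
}

#' @rdname sseAxis
#' @export
sseAxisFit <- function(sse) {
  ca <- atomCoords(sse, "CA")
  ctr <- colMeans(ca)
  m <- sweep(ca, 2, ctr)
  ax <- svd(m)$v[, 1]
  if (sum((m[nrow(m), ] - m[1, ]) * ax) < 0) ax <- -ax
  proj <- m %*% ax
  list(center = ctr, direction = as.vector(ax),
       length = max(proj) - min(proj))
}

#' Chain-break gap between adjacent SSEs
#'
#' For the i-th pair of sequence-adjacent SSEs, the Euclidean distance
#' between the C atom of the upstream SSE's last residue and the N atom
#' of the downstream SSE's first residue, and the number of unmodeled
#' residues between them.
#'
#' @param model a [ProteinModel-class] with at least two SSEs
#' @param i pair index (1 = first/second SSE, ...)
#' @return list with `euclid` (Angstrom) and `nLoop` (count)
#' @export
chainBreakGap <- function(model, i) {
  ns <- length(model@sses)
  if (ns < 2L) stop("model has no adjacent SSE pair")
  if (i < 1L || i > ns - 1L) stop("pair index out of range")
  up <- model@sses[[i]]; down <- model@sses[[i + 1L]]
  nUp <- sseLength(up)
  cAtom <- up@coords[(nUp - 1L) * N_ATOMS + 3L, ]
  nAtom <- down@coords[1L, ]
  list(euclid = norm3(cAtom - nAtom), nLoop = down@first - up@last - 1L)
}

# Maximum chain-break distance closable by an n-residue loop: each loop
# residue plus the closing bond spans at most ~2.56 A of extended chain,
# with a 2 A allowance for the anchor geometry.
loopClosureLimit <- function(nLoop) 2.56 * (nLoop + 1) + 2.0

#' Construct a protein model from placed SSEs
#'
#' @param sequence full amino acid string
#' @param sses list of placed [SSE-class] objects (sorted internally)
#' @param provenance free-text identifier
#' @return a [ProteinModel-class]
#' @export
proteinModel <- function(sequence, sses = list(), provenance = "") {
  if (length(sses)) sses <- sses[order(vapply(sses, function(s) s@first, integer(1)))]
  m <- new("ProteinModel")
  m@sequence <- sequence; m@sses <- sses; m@coil <- list()
  m@provenance <- provenance
  validObject(m)
  m
}

# fast internal variant without validity (hot path)
newModel <- function(sequence, sses, coil = list(), provenance = "") {
  ns <- length(sses)
  if (ns > 1L) {
    firsts <- integer(ns)
    for (i in seq_len(ns)) firsts[i] <- sses[[i]]@first
    if (is.unsorted(firsts)) sses <- sses[order(firsts)]
  }
  m <- proto("ProteinModel")
  attr(m, "sequence") <- sequence
  attr(m, "sses") <- sses
  attr(m, "coil") <- coil
  attr(m, "provenance") <- provenance
  m
}
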