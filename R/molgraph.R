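# Standard atomic weights (amu), most common elements in drug-like
# molecules; used when a connection table carries no explicit masses.
.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.948, K = 39.098, Ca = 40.078, Fe = 55.845,
  Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90)

#' Construct a molecular graph
#'
#' A light container for the hydrogen-suppressed or explicit-hydrogen
#' molecular graph: element symbols, an undirected bond list, and optional
#' 3D coordinates and atomic masses for geometry descriptors.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds two-column integer matrix (or list of pairs) of bonded atom
#'   indices; undirected, no self-bonds, no duplicates.
#' @param coords optional numeric matrix of 3D coordinates in Angstrom,
#'   one row per atom.
#' @param masses optional numeric vector of atomic masses in amu; defaults
#'   to standard atomic weights looked up by element.
#' @param hydrogen_policy `"heavy"` (default) computes topological
#'   descriptors on the hydrogen-suppressed graph, `"explicit"` keeps all
#'   atoms.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(elements, bonds, coords = NULL, masses = NULL,
                            hydrogen_policy = c("heavy", "explicit")) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("graph needs at least one atom")
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
  }
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bond not allowed")
    key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                 pmax(bonds[, 1L], bonds[, 2L]))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3L)
    if (nrow(coords) != n) stop("coords must have one row per atom")
    if (!all(is.finite(coords))) stop("non-finite coordinates")
  }
  if (is.null(masses)) {
    masses <- unname(.atomic_masses[elements])
    if (anyNA(masses))
      stop("unknown element(s): ",
           paste(unique(elements[is.na(masses)]), collapse = ", "),
           "; supply masses explicitly")
  } else {
    masses <- as.numeric(masses)
    if (length(masses) != n) stop("masses must have one value per atom")
  }
  structure(list(elements = elements, bonds = bonds, coords = coords,
                 masses = masses, hydrogen_policy = hydrogen_policy),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("Molecular graph:", length(x$elements), "atoms,",
      nrow(x$bonds), "bonds (hydrogen policy:", x$hydrogen_policy, ")\n")
  cat("  formula:", paste(names(tf <- table(x$elements)), tf,
                          sep = "", collapse = " "), "\n")
  invisible(x)
}

# atoms retained under the graph's hydrogen policy
.active_atoms <- function(g) {
  if (g$hydrogen_policy == "heavy") which(g$elements != "H")
  else seq_along(g$elements)
}

# unweighted adjacency matrix over the active atoms
.adjacency <- function(g) {
  act <- .active_atoms(g)
  if (!length(act)) stop("no atoms left after hydrogen suppression")
  idx <- match(seq_along(g$elements), act)
  A <- matrix(0, length(act), length(act))
  if (nrow(g$bonds)) {
    b <- g$bonds
    keep <- !is.na(idx[b[, 1L]]) & !is.na(idx[b[, 2L]])
    b <- b[keep, , drop = FALSE]
    if (nrow(b)) {
      A[cbind(idx[b[, 1L]], idx[b[, 2L]])] <- 1
      A[cbind(idx[b[, 2L]], idx[b[, 1L]])] <- 1
    }
  }
  A
}

#' Leading adjacency eigenvalue (Lovasz-Pelikan index, LP1)
#'
#' The largest eigenvalue of the unweighted adjacency matrix of the
#' molecular graph, a classical branching index: chain (path) graphs give
#' the smallest values at fixed atom count and heavily branched graphs the
#' largest.
#'
#' @param g a [molecular_graph()]. Hydrogens are suppressed or kept per the
#'   graph's `hydrogen_policy`.
#' @return nonnegative scalar.
#' @export
lp1 <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  A <- .adjacency(g)
  if (nrow(A) == 1L) return(0)
  max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

#' Structural information content of order 1 (SIC1)
#'
#' Atoms are partitioned into equivalence classes by their own element plus
#' the multiset of neighbouring elements (first-order neighbourhood
#' symmetry); the Shannon entropy of the class-size distribution,
#' normalised by log2(n), gives a value in [0, 1]. Highly symmetric
#' molecules score near 0, molecules whose atoms are all distinguishable
#' near 1.
#'
#' @param g a [molecular_graph()] with at least two atoms after applying
#'   the hydrogen policy.
#' @return scalar in [0, 1].
#' @export
sic1 <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  act <- .active_atoms(g)
  n <- length(act)
  if (n < 2L)
    stop("SIC1 undefined for fewer than 2 atoms (log2(1) = 0)")
  A <- .adjacency(g)
  el <- g$elements[act]
  keys <- vapply(seq_len(n), function(i) {
    nb <- sort(el[A[i, ] > 0])
    paste(el[i], paste(nb, collapse = ","), sep = "|")
  }, character(1L))
  cls <- table(keys)
  p <- as.numeric(cls) / n
  h <- -sum(p * log2(p))
  h / log2(n)
}

#' Principal moments of inertia
#'
#' Translates the molecule to its centre of mass, builds the 3x3 inertia
#' tensor from atomic masses and coordinates, and returns its sorted
#' eigenvalues IA <= IB <= IC in amu A^2. All atoms contribute regardless
#' of hydrogen policy, since mass distribution is a whole-molecule
#' property.
#'
#' @param g a [molecular_graph()] with coordinates and masses.
#' @return named numeric vector `c(IA =, IB =, IC =)`.
#' @seealso [pmic()] for the largest moment as a scalar descriptor.
#' @export
principal_moments <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (is.null(g$coords)) stop("coordinates required for inertia moments")
  m <- g$masses
  xyz <- sweep(g$coords, 2L, colSums(g$coords * m) / sum(m))
  x <- xyz[, 1L]; y <- xyz[, 2L]; z <- xyz[, 3L]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),       -sum(m * x * z),
    -sum(m * x * y),       sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),        sum(m * (x^2 + y^2))),
    nrow = 3L, byrow = TRUE)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  ev[abs(ev) < 1e-12] <- 0
  c(IA = ev[1L], IB = ev[2L], IC = ev[3L])
}

#' Principal moment of inertia C
#'
#' The largest principal moment (IC under the spectroscopic convention
#' IA <= IB <= IC), a descriptor of how mass is distributed away from the
#' molecule's main rotational axis.
#'
#' @param g a [molecular_graph()] with coordinates and masses.
#' @return scalar, amu A^2.
#' @export
pmic <- function(g) unname(principal_moments(g)["IC"])

#' Read a minimal connection table
#'
#' Parses the package's plain-text connection-table format: an atom block
#' of lines `index element [x y z]`, a separator line `bonds`, then a bond
#' block of lines `i j`. Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @param hydrogen_policy passed to [molecular_graph()].
#' @return a [molecular_graph()].
#' @export
read_connection_table <- function(path,
                                  hydrogen_policy = c("heavy", "explicit")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sep <- which(tolower(lines) == "bonds")
  atom_lines <- if (length(sep)) lines[seq_len(sep[1L] - 1L)] else lines
  bond_lines <- if (length(sep)) lines[-seq_len(sep[1L])] else character()
  if (!length(atom_lines)) stop("no atoms in ", path)
  atoms <- strsplit(atom_lines, "[[:space:]]+")
  elements <- vapply(atoms, `[`, character(1L), 2L)
  has_xyz <- all(lengths(atoms) >= 5L)
  coords <- if (has_xyz)
    t(vapply(atoms, function(a) as.numeric(a[3:5]), numeric(3L)))
  else NULL
  bonds <- if (length(bond_lines))
    t(vapply(strsplit(bond_lines, "[[:space:]]+"),
             function(b) as.integer(b[1:2]), integer(2L)))
  else NULL
  molecular_graph(elements, bonds, coords,
                  hydrogen_policy = match.arg(hydrogen_policy))
}
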