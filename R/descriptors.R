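# Molecular descriptors: scalar 1D/2D counts, topological autocorrelation,
# radial distribution functions and 3D autocorrelations.

# Fold explicit hydrogens into the heavy-atom hcount so descriptors see the
# same heavy-atom graph whichever input dialect supplied the molecule.
.heavyMolecule <- function(mol) {
  el <- mol@atoms$element
  hIdx <- which(el == "H")
  if (!length(hIdx)) return(mol)
  a <- mol@atoms; b <- mol@bonds
  keep <- setdiff(seq_len(nrow(a)), hIdx)
  newIdx <- integer(nrow(a)); newIdx[keep] <- seq_along(keep)
  extraH <- numeric(length(keep))
  keepBond <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    h1 <- b$a1[i] %in% hIdx; h2 <- b$a2[i] %in% hIdx
    if (h1 && h2) { keepBond[i] <- FALSE; next }  # H-H (e.g. H2): drop
    if (h1 || h2) {
      parent <- if (h1) b$a2[i] else b$a1[i]
      if (!parent %in% hIdx)
        extraH[newIdx[parent]] <- extraH[newIdx[parent]] + 1
      keepBond[i] <- FALSE
    }
  }
  b <- b[keepBond & b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  b$a1 <- newIdx[b$a1]; b$a2 <- newIdx[b$a2]
  a <- a[keep, , drop = FALSE]
  a$hcount <- a$hcount + extraH
  rownames(a) <- NULL; rownames(b) <- NULL
  out <- mol
  out@atoms <- a; out@bonds <- b
  out@properties <- matrix(numeric(), nrow(a), 0)
  methods::validObject(out)
  out
}

.molGraph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol@bonds$a1, to = mol@bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(numAtoms(mol))))
}

.propertyValues <- function(mol, property) {
  if (!ncol(mol@properties) || !property %in% colnames(mol@properties))
    mol <- assignAtomicProperties(mol)
  if (!property %in% colnames(mol@properties))
    stop("unknown atomic property '", property, "'")
  mol@properties[, property]
}

#' Scalar 1D descriptors (formula-level)
#'
#' @param mol a [Molecule-class].
#' @return named numeric vector: molecular weight `mw` in g/mol including
#'   implicit/explicit hydrogens, `total_charge` (sum of formal charges, e)
#'   and `heavy_atoms` count.
#' @export
scalar1D <- function(mol) {
  m <- .heavyMolecule(mol)
  a <- m@atoms
  mw <- sum(.elementLookup(a$element, "mass")) +
    sum(a$hcount) * elementProperties()["H", "mass"]
  c(mw = mw, total_charge = sum(a$charge), heavy_atoms = nrow(a))
}

#' Scalar 2D descriptors (connectivity-level)
#'
#' Hydrogen-bond donors (N/O bearing at least one hydrogen), acceptors
#' (N/O), ring count (smallest set of smallest rings, computed as the
#' cyclomatic number bonds - atoms + components of the heavy-atom graph),
#' and additive approximations of molecular surface area (Angstrom^2) and
#' volume (Angstrom^3) from per-element van der Waals radii.
#'
#' @param mol a [Molecule-class].
#' @return named numeric vector `hbd`, `hba`, `rings`, `surface_area`,
#'   `volume`.
#' @export
scalar2D <- function(mol) {
  m <- .heavyMolecule(mol)
  a <- m@atoms
  no <- a$element %in% c("N", "O")
  hbd <- sum(no & a$hcount >= 1)
  hba <- sum(no)
  g <- .molGraph(m)
  rings <- nrow(m@bonds) - nrow(a) + igraph::count_components(g)
  r <- .elementLookup(a$element, "vdw_radius")
  c(hbd = hbd, hba = hba, rings = rings,
    surface_area = sum(4 * pi * r^2), volume = sum(4 / 3 * pi * r^3))
}

.pairWeights <- function(mol, property) {
  p <- .propertyValues(mol, property)
  n <- length(p)
  if (n < 2) return(list(w = numeric(), i = integer(), j = integer()))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(w = p[ij[, 1]] * p[ij[, 2]], i = ij[, 1], j = ij[, 2])
}

#' Radial distribution function descriptor
#'
#' Gaussian-smoothed distribution of an atomic property over interatomic
#' distances: `RDF_k = sum_{i<j} p_i p_j exp(-B (r_k - d_ij)^2)` with
#' `r_k = k * dr`, `k = 0..K-1`. Self-pairs are excluded; the result is
#' invariant to rigid motions and atom reordering.
#'
#' @param mol a 3D [Molecule-class] (explicit hydrogens are folded onto
#'   heavy atoms first).
#' @param property atomic property name (see [assignAtomicProperties()]).
#' @param K number of bins; @param dr bin spacing in Angstrom.
#' @param B Gaussian smoothing parameter in 1/Angstrom^2.
#' @return numeric vector of length `K`.
#' @export
rdfDescriptor <- function(mol, property = "identity", K = 48, dr = 0.25,
                          B = 100) {
  m <- .heavyMolecule(mol)
  if (!m@is3D)
    stop("RDF requires 3D coordinates; molecule '", m@name,
         "' is 2D - supply a conformation")
  pw <- .pairWeights(m, property)
  r <- (seq_len(K) - 1) * dr
  if (!length(pw$w)) return(stats::setNames(numeric(K), NULL))
  D <- distanceMatrix(m)
  d <- D[cbind(pw$i, pw$j)]
  as.numeric(exp(-B * outer(r, d, "-")^2) %*% pw$w)
}

#' 3D autocorrelation descriptor
#'
#' Hard-binned sum of property products by interatomic distance:
#' `A_k = sum_{i<j} p_i p_j 1[k*delta <= d_ij < (k+1)*delta]`. Pairs beyond
#' `K*delta` are ignored; self-pairs excluded. Bins are half-open starting
#' at distance zero.
#'
#' @inheritParams rdfDescriptor
#' @param delta bin width in Angstrom.
#' @return numeric vector of length `K`.
#' @export
autocorrelation3D <- function(mol, property = "identity", K = 48,
                              delta = 0.25) {
  m <- .heavyMolecule(mol)
  if (!m@is3D)
    stop("3DA requires 3D coordinates; molecule '", m@name,
         "' is 2D - supply a conformation")
  pw <- .pairWeights(m, property)
  out <- numeric(K)
  if (!length(pw$w)) return(out)
  D <- distanceMatrix(m)
  d <- D[cbind(pw$i, pw$j)]
  bin <- floor(d / delta) + 1L
  ok <- bin >= 1L & bin <= K
  if (any(ok)) {
    s <- tapply(pw$w[ok], bin[ok], sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

#' Topological (2D) autocorrelation descriptor
#'
#' Sum of property products over atom pairs at shortest bond-path distance
#' `k` on the heavy-atom graph; bin 0 holds `sum_i p_i^2`. Disconnected
#' molecules are handled per component (cross-component pairs contribute
#' nothing) with a warning.
#'
#' @inheritParams rdfDescriptor
#' @param K number of bond-step bins (bins `0..K-1`).
#' @return numeric vector of length `K`.
#' @export
topoAutocorrelation2D <- function(mol, property = "identity", K = 8) {
  m <- .heavyMolecule(mol)
  p <- .propertyValues(m, property)
  g <- .molGraph(m)
  if (igraph::count_components(g) > 1 && numAtoms(m) > 1)
    warning("disconnected molecule '", m@name,
            "': topological autocorrelation computed per component")
  out <- numeric(K)
  out[1] <- sum(p^2)
  if (numAtoms(m) >= 2 && K >= 2) {
    SP <- igraph::distances(g)
    ij <- which(upper.tri(SP), arr.ind = TRUE)
    d <- SP[ij]
    w <- p[ij[, 1]] * p[ij[, 2]]
    ok <- is.finite(d) & d >= 1 & d <= (K - 1)
    if (any(ok)) {
      s <- tapply(w[ok], d[ok], sum)
      out[as.integer(names(s)) + 1L] <- out[as.integer(names(s)) + 1L] +
        as.numeric(s)
    }
  }
  out
}

.blockLengthOne <- function(kind, k) {
  switch(kind, scalar1d = 3L, scalar2d = 5L, as.integer(k))
}

#' @rdname DescriptorConfig-class
#' @export
blockLengths <- function(x) {
  bl <- x@blocks
  vapply(seq_len(nrow(bl)),
         function(i) .blockLengthOne(bl$kind[i], bl$k[i]), integer(1))
}

setMethod("featureLabels", "DescriptorConfig", function(x) {
  bl <- x@blocks
  unlist(lapply(seq_len(nrow(bl)), function(i) {
    switch(bl$kind[i],
      scalar1d = c("mw", "total_charge", "heavy_atoms"),
      scalar2d = c("hbd", "hba", "rings", "surface_area", "volume"),
      sprintf("%s_%s:%02d", bl$kind[i], bl$property[i],
              seq_len(bl$k[i]) - 1L))
  }))
})

#' Construct a descriptor configuration
#'
#' @param blocks data.frame with columns `kind`, `property`, `k`, `delta`,
#'   `b` (see [DescriptorConfig-class]).
#' @return a validated [DescriptorConfig-class].
#' @export
descriptorConfig <- function(blocks) {
  methods::new("DescriptorConfig", blocks = blocks)
}

#' The shipped 400-feature descriptor layout
#'
#' Eight scalar features (three 1D + five 2D), an 8-bin topological
#' autocorrelation over identity, and for each of the four atomic
#' properties identity, partial charge, electronegativity and
#' polarizability a 48-bin RDF (dr = 0.25 A, B = 100 /A^2) and a 48-bin 3D
#' autocorrelation (delta = 0.25 A): 8 + 8 + 192 + 192 = 400 features,
#' spanning interatomic distances up to ~12 A. The layout is a package
#' default and fully overridable through [descriptorConfig()].
#'
#' @return a [DescriptorConfig-class] with `totalLength()` 400.
#' @export
defaultDescriptorConfig <- function() {
  props <- c("identity", "partial_charge", "electronegativity",
             "polarizability")
  blocks <- rbind(
    data.frame(kind = c("scalar1d", "scalar2d"), property = "",
               k = 0L, delta = 0, b = 0),
    data.frame(kind = "topo2da", property = "identity", k = 8L,
               delta = 1, b = 0),
    data.frame(kind = "rdf", property = props, k = 48L, delta = 0.25,
               b = 100),
    data.frame(kind = "3da", property = props, k = 48L, delta = 0.25,
               b = 0)
  )
  descriptorConfig(blocks)
}

#' Compute the descriptor feature vector of a molecule
#'
#' Concatenates the configured descriptor blocks in declared order. All
#' blocks are sums over atoms or atom pairs, so the vector is invariant to
#' atom reordering and (for the 3D blocks, which only see interatomic
#' distances) to rigid rotations and translations. Explicit hydrogens are
#' folded onto their heavy atoms unless `includeHydrogens` is TRUE.
#'
#' @param mol a [Molecule-class]; must be 3D if the layout has rdf/3da
#'   blocks.
#' @param config a [DescriptorConfig-class]; default the shipped 400-length
#'   layout.
#' @param includeHydrogens keep explicit hydrogen atoms as graph nodes.
#' @return named numeric vector of length `totalLength(config)`.
#' @export
featurize <- function(mol, config = defaultDescriptorConfig(),
                      includeHydrogens = FALSE) {
  m <- if (includeHydrogens) mol else .heavyMolecule(mol)
  m <- assignAtomicProperties(m)
  bl <- config@blocks
  parts <- lapply(seq_len(nrow(bl)), function(i) {
    res <- tryCatch(switch(bl$kind[i],
      scalar1d = scalar1D(m),
      scalar2d = scalar2D(m),
      topo2da = topoAutocorrelation2D(m, bl$property[i], bl$k[i]),
      rdf = rdfDescriptor(m, bl$property[i], bl$k[i], bl$delta[i],
                          bl$b[i]),
      `3da` = autocorrelation3D(m, bl$property[i], bl$k[i], bl$delta[i])),
      error = function(e)
        stop("descriptor block ", bl$kind[i],
             if (nzchar(bl$property[i])) paste0("(", bl$property[i], ")"),
             " failed: ", conditionMessage(e), call. = FALSE))
    as.numeric(res)
  })
  v <- unlist(parts)
  names(v) <- featureLabels(config)
  if (any(!is.finite(v)))
    stop("non-finite feature values for molecule '", mol@name, "'")
  v
}

#' Featurize a list of molecules into a feature matrix
#'
#' @param mols list of [Molecule-class].
#' @inheritParams featurize
#' @return numeric matrix, one row per molecule (named by molecule),
#'   columns labelled by `featureLabels(config)`.
#' @export
featurizeSet <- function(mols, config = defaultDescriptorConfig(),
                         includeHydrogens = FALSE) {
  rows <- lapply(mols, featurize, config = config,
                 includeHydrogens = includeHydrogens)
  X <- do.call(rbind, rows)
  nm <- vapply(mols, moleculeName, character(1))
  if (anyDuplicated(nm) || any(!nzchar(nm)))
    nm <- sprintf("mol%03d", seq_along(mols))
  rownames(X) <- nm
  X
}
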