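#' @import methods
NULL

#' Molecule: atoms, bonds and per-atom properties
#'
#' A small-molecule container on the heavy-atom graph. Atoms carry an
#' element symbol, a formal charge, Cartesian coordinates in Angstrom
#' (meaningful only when `is3D` is `TRUE`), and an implicit-hydrogen count
#' derived from standard valences. Per-atom numeric properties (identity,
#' PEOE partial charge, electronegativity, polarizability, ...) are stored
#' as a column-named matrix aligned with the atom table; descriptor
#' functions aggregate these values over atom pairs.
#'
#' @slot name single character, molecule title.
#' @slot atoms data.frame with columns `element`, `charge`, `x`, `y`, `z`,
#'   `hcount` (implicit hydrogens folded onto each heavy atom).
#' @slot bonds data.frame with columns `a1`, `a2`, `order` (1-based atom
#'   indices; aromatic V2000 order 4 is stored as 1.5).
#' @slot is3D logical, whether coordinates are meaningful.
#' @slot properties numeric matrix, one row per atom, one named column per
#'   assigned atomic property.
#'
#' @seealso [readMoleculesSDF()], [readMoleculeSMILES()],
#'   [assignAtomicProperties()], [featurize()]
#' @export
setClass("Molecule",
  representation(
    name = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    is3D = "logical",
    properties = "matrix"
  ),
  prototype(
    name = "",
    atoms = data.frame(element = character(), charge = integer(),
                       x = numeric(), y = numeric(), z = numeric(),
                       hcount = numeric()),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = numeric()),
    is3D = FALSE,
    properties = matrix(numeric(), 0, 0)
  )
)

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need <- c("element", "charge", "x", "y", "z", "hcount")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (!all(c("a1", "a2", "order") %in% names(b)))
    return("bonds must have columns a1, a2, order")
  n <- nrow(a)
  if (any(!nzchar(a$element))) msgs <- c(msgs, "empty element symbol")
  if (nrow(b) > 0) {
    if (any(b$a1 < 1 | b$a1 > n | b$a2 < 1 | b$a2 > n))
      msgs <- c(msgs, "bond atom index out of range")
    else {
      if (any(b$a1 == b$a2)) msgs <- c(msgs, "self-bond not allowed")
      key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
      if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    }
  }
  if (object@is3D && n > 0 && any(!is.finite(c(a$x, a$y, a$z))))
    msgs <- c(msgs, "non-finite coordinates on a 3D molecule")
  if (nrow(object@properties) > 0 && nrow(object@properties) != n)
    msgs <- c(msgs, "property matrix rows must match atom count")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Descriptor layout configuration
#'
#' Ordered list of descriptor blocks that [featurize()] concatenates into a
#' fixed-length feature vector. Each block is one of `scalar1d`, `scalar2d`,
#' `topo2da` (topological autocorrelation, bins in bond steps), `rdf`
#' (Gaussian-smoothed radial distribution function over interatomic
#' distances) or `3da` (hard-binned 3D autocorrelation). `property` names
#' the per-atom property aggregated by the pairwise blocks, `k` the number
#' of bins, `delta` the bin width in Angstrom (bond steps for `topo2da`)
#' and `b` the Gaussian smoothing parameter in 1/Angstrom^2 (rdf only).
#'
#' @slot blocks data.frame with columns `kind`, `property`, `k`, `delta`, `b`.
#' @seealso [defaultDescriptorConfig()], [featurize()]
#' @export
setClass("DescriptorConfig",
  representation(blocks = "data.frame"),
  prototype(blocks = data.frame(kind = character(), property = character(),
                                k = integer(), delta = numeric(),
                                b = numeric()))
)

setValidity("DescriptorConfig", function(object) {
  bl <- object@blocks
  if (!all(c("kind", "property", "k", "delta", "b") %in% names(bl)))
    return("blocks must have columns kind, property, k, delta, b")
  ok <- c("scalar1d", "scalar2d", "topo2da", "rdf", "3da")
  if (!all(bl$kind %in% ok))
    return(paste("unknown block kind; must be one of",
                 paste(ok, collapse = ", ")))
  pair <- bl$kind %in% c("topo2da", "rdf", "3da")
  if (any(bl$k[pair] < 1)) return("pairwise blocks need k >= 1")
  if (any(bl$delta[bl$kind %in% c("rdf", "3da")] <= 0))
    return("rdf/3da blocks need delta > 0")
  if (any(bl$b[bl$kind == "rdf"] <= 0)) return("rdf blocks need b > 0")
  TRUE
})

#' Compound x kinase activity matrix (Kd, micromolar)
#'
#' Wraps a numeric matrix of equilibrium dissociation constants Kd in uM,
#' rows = compounds, columns = kinases. `NA` marks an unmeasured pair; the
#' downstream labelling convention treats unmeasured pairs as inactive at
#' every cutoff, matching panels that report binders only.
#'
#' @slot kd numeric matrix with unique row (compound) and column (kinase)
#'   names; non-negative where present.
#' @seealso [readActivityCSV()], [binarize()]
#' @export
setClass("ActivityMatrix", representation(kd = "matrix"))

setValidity("ActivityMatrix", function(object) {
  kd <- object@kd
  if (is.null(rownames(kd)) || is.null(colnames(kd)))
    return("kd matrix needs compound rownames and kinase colnames")
  if (anyDuplicated(rownames(kd))) return("duplicate compound ids")
  if (anyDuplicated(colnames(kd))) return("duplicate kinase ids")
  if (any(kd < 0, na.rm = TRUE)) return("negative Kd")
  TRUE
})

#' Binary activity labels at a Kd cutoff
#'
#' Binary view of an [ActivityMatrix-class]: label 1 iff Kd is present and
#' strictly below `cutoffUM`, else 0 (missing = inactive).
#'
#' @slot labels integer matrix in \{0, 1\} with the source dimnames.
#' @slot cutoffUM the Kd cutoff in uM.
#' @seealso [binarize()]
#' @export
setClass("LabelMatrix",
  representation(labels = "matrix", cutoffUM = "numeric"))

setValidity("LabelMatrix", function(object) {
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (length(object@cutoffUM) != 1 || object@cutoffUM <= 0)
    return("cutoffUM must be a single positive number")
  TRUE
})

#' Per-feature standardization statistics
#'
#' Column means and standard deviations learned on training rows; applying
#' the normalizer centres and scales to unit variance, with constant
#' columns (sd below tolerance) flagged and mapped to zero.
#'
#' @slot center,scale numeric vectors, per-feature mean and sd.
#' @slot constant logical vector flagging constant features.
#' @seealso [fitNormalizer()], [applyNormalizer()]
#' @export
setClass("Normalizer",
  representation(center = "numeric", scale = "numeric",
                 constant = "logical"))

setValidity("Normalizer", function(object) {
  if (length(object@center) != length(object@scale) ||
      length(object@center) != length(object@constant))
    return("center, scale, constant must have equal length")
  if (any(object@scale[!object@constant] <= 0))
    return("scale must be positive for non-constant features")
  TRUE
})

#' Multi-task feed-forward network model
#'
#' One-hidden-layer sigmoid network mapping a normalized feature vector to
#' one activity score per kinase. Holds the weight matrices, the momentum
#' velocity state carried between updates, the input normalizer, the kinase
#' id order of the outputs, the initialization seed and a snapshot of the
#' training configuration.
#'
#' @slot W1 hidden x input weight matrix; @slot b1 hidden biases.
#' @slot W2 output x hidden weight matrix; @slot b2 output biases.
#' @slot vW1,vb1,vW2,vb2 momentum velocities (previous weight deltas).
#' @slot normalizer [Normalizer-class] for the inputs.
#' @slot kinases character, output column ids.
#' @slot seed integer initialization seed.
#' @slot config list, training configuration snapshot.
#' @seealso [annInit()], [annTrain()], [predictProfile()]
#' @export
setClass("AnnModel",
  representation(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    vW1 = "matrix", vb1 = "numeric", vW2 = "matrix", vb2 = "numeric",
    normalizer = "ANY", kinases = "character", seed = "integer",
    config = "list"
  )
)

setValidity("AnnModel", function(object) {
  nh <- nrow(object@W1); ni <- ncol(object@W1)
  no <- nrow(object@W2)
  if (ncol(object@W2) != nh) return("W2 columns must match hidden size")
  if (length(object@b1) != nh || length(object@b2) != no)
    return("bias lengths inconsistent with weight shapes")
  if (!all(dim(object@vW1) == c(nh, ni)) ||
      !all(dim(object@vW2) == c(no, nh)))
    return("velocity shapes inconsistent")
  w <- c(object@W1, object@b1, object@W2, object@b2)
  if (any(!is.finite(w))) return("non-finite weights")
  if (length(object@kinases) && length(object@kinases) != no)
    return("kinase ids must match output count")
  TRUE
})
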