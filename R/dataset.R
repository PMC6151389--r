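# Activity-matrix ingest, binarization, feature normalization and
# compound-level cross-validation folds.

#' Construct an ActivityMatrix from a Kd matrix
#'
#' @param kd numeric matrix of Kd values in uM (NA = unmeasured), with
#'   compound rownames and kinase colnames.
#' @return an [ActivityMatrix-class].
#' @export
activityMatrix <- function(kd) {
  storage.mode(kd) <- "double"
  methods::new("ActivityMatrix", kd = kd)
}

#' Read a compound x kinase Kd matrix from CSV
#'
#' Expects compound ids in the first column, kinase ids in the header and
#' numeric or blank cells (blank = not measured). Values are taken as uM
#' unless the first header field declares nM (e.g. `compound_nM`), in
#' which case cells are divided by 1000.
#'
#' @param path CSV file path.
#' @return an [ActivityMatrix-class].
#' @export
readActivityCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idCol <- names(df)[1]
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate kinase id(s) in header")
  kd <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(kd) <- "double"
  rownames(kd) <- ids
  if (grepl("nM", idCol, ignore.case = FALSE)) kd <- kd / 1000
  if (any(kd < 0, na.rm = TRUE)) stop("negative Kd value in ", path)
  activityMatrix(kd)
}

#' Write an activity or label matrix to CSV
#'
#' @param x an [ActivityMatrix-class] or [LabelMatrix-class].
#' @param path output CSV path.
#' @export
writeActivityCSV <- function(x, path) {
  m <- if (methods::is(x, "ActivityMatrix")) kdMatrix(x) else labelMatrix(x)
  df <- data.frame(compound = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Binarize an activity matrix at a Kd cutoff
#'
#' A pair is active (label 1) iff its Kd is measured and strictly below the
#' cutoff; unmeasured pairs are inactive. Consequently the active set at a
#' lower cutoff is always a subset of the active set at a higher one.
#'
#' @param m an [ActivityMatrix-class].
#' @param cutoffUM Kd cutoff in uM (> 0); the canonical grid is
#'   0.1, 0.5, 1, 3 and 10 uM.
#' @return a [LabelMatrix-class].
#' @export
binarize <- function(m, cutoffUM) {
  stopifnot(length(cutoffUM) == 1, cutoffUM > 0)
  kd <- kdMatrix(m)
  lab <- ifelse(!is.na(kd) & kd < cutoffUM, 1L, 0L)
  dimnames(lab) <- dimnames(kd)
  methods::new("LabelMatrix", labels = lab, cutoffUM = as.numeric(cutoffUM))
}

#' Fit a per-feature standardizer on training rows
#'
#' Uses the population standard deviation (denominator n), so a two-point
#' column (0, 2) maps exactly to (-1, 1).
#'
#' @param X numeric feature matrix (>= 2 rows).
#' @param tol sd below which a feature is flagged constant.
#' @return a [Normalizer-class].
#' @export
fitNormalizer <- function(X, tol = 1e-12) {
  if (nrow(X) < 2) stop("need at least 2 rows to fit a normalizer")
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  const <- !is.finite(sc) | sc <= tol
  sc[const] <- 1
  methods::new("Normalizer", center = as.numeric(ctr),
               scale = as.numeric(sc), constant = const)
}

#' Apply / invert a fitted normalizer
#'
#' Transformed training columns have mean 0 and sd 1; constant columns map
#' to 0 (and are not restored by the inverse beyond their constant value).
#'
#' @param n a [Normalizer-class].
#' @param X matrix (or vector, treated as one row) with matching columns.
#' @return transformed matrix of the same shape.
#' @export
applyNormalizer <- function(n, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != length(n@center))
    stop("feature count mismatch: normalizer has ", length(n@center),
         ", data has ", ncol(X))
  Z <- sweep(sweep(X, 2, n@center), 2, n@scale, "/")
  Z[, n@constant] <- 0
  Z
}

#' @rdname applyNormalizer
#' @export
inverseNormalizer <- function(n, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  X <- sweep(sweep(Z, 2, n@scale, "*"), 2, n@center, "+")
  X[, n@constant] <- rep(n@center[n@constant], each = nrow(X))
  X
}

#' Compound-level k-fold assignment
#'
#' Partitions compounds (not compound x kinase cells) into k folds of size
#' differing by at most one, deterministically from the seed.
#'
#' @param n number of compounds; @param k number of folds (2 <= k <= n);
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k, length n.
#' @export
splitFolds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " folds but only ", n, " compounds")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
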