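# Synthetic fixtures: 3D molecules and planted-signal Kd panels, so the
# whole pipeline is exercisable and testable without external data.

.zigzagCoords <- function(n, bondLength = 1.54, angle = 111 * pi / 180) {
  i <- seq_len(n) - 1
  cbind(x = i * bondLength * sin(angle / 2),
        y = (i %% 2) * bondLength * cos(angle / 2),
        z = 0.15 * (i %% 3))  # slight out-of-plane twist
}

.buildChainMol <- function(elements, name, jitterSd = 0) {
  n <- length(elements)
  xyz <- .zigzagCoords(n)
  if (jitterSd > 0) xyz <- xyz + matrix(stats::rnorm(3 * n, 0, jitterSd),
                                        n, 3)
  bonds <- if (n > 1) data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1)
           else NULL
  newMolecule(elements, xyz, bonds, name = name, is3D = TRUE)
}

.buildRingMol <- function(ringElements, tailElements = character(),
                          name, jitterSd = 0, aromatic = FALSE) {
  stopifnot(length(ringElements) == 6)
  r <- 1.40
  th <- 2 * pi * (0:5) / 6
  ring <- cbind(x = r * cos(th), y = r * sin(th), z = 0)
  nT <- length(tailElements)
  tail <- if (nT) cbind(x = r + 1.5 * seq_len(nT),
                        y = 0.5 * (seq_len(nT) %% 2),
                        z = 0.3 * seq_len(nT))
          else NULL
  xyz <- rbind(ring, tail)
  n <- 6 + nT
  if (jitterSd > 0) xyz <- xyz + matrix(stats::rnorm(3 * n, 0, jitterSd),
                                        n, 3)
  ord <- if (aromatic) 1.5 else 1
  bonds <- data.frame(a1 = c(1:6, if (nT) c(1, 6 + seq_len(max(0, nT - 1)))),
                      a2 = c(2:6, 1, if (nT) 6 + seq_len(nT)),
                      order = c(rep(ord, 6), rep(1, nT)))
  newMolecule(c(ringElements, tailElements), xyz, bonds, name = name,
              is3D = TRUE)
}

#' Generate fixture molecules with 3D coordinates
#'
#' A curated base set of small structures (short alkane chains, six-rings,
#' hydrogen-bonding N/O variants) followed by seeded decorated variants:
#' random chain or ring-plus-tail scaffolds with heteroatom substitutions
#' and a small coordinate jitter that diversifies the interatomic distance
#' spectra. Every molecule validates and featurizes under the default
#' 400-feature layout. Identical seeds give identical lists.
#'
#' @param n number of molecules (>= 1).
#' @param seed RNG seed.
#' @return list of 3D [Molecule-class] objects named `cmp001`, ...
#' @export
makeFixtureMolecules <- function(n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  base <- list(
    function() .buildChainMol("C", "methane"),
    function() .buildChainMol(c("C", "C"), "ethane"),
    function() .buildChainMol(c("C", "C", "C"), "propane"),
    function() .buildChainMol(c("C", "C", "O"), "propanol-like"),
    function() .buildChainMol(c("C", "C", "N"), "ethylamine-like"),
    function() .buildRingMol(rep("C", 6), name = "benzene-like",
                             aromatic = TRUE),
    function() .buildRingMol(c("N", rep("C", 5)), name = "pyridine-like",
                             aromatic = TRUE),
    function() .buildRingMol(rep("C", 6), "O", name = "phenol-like",
                             aromatic = TRUE)
  )
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= length(base)) {
      mols[[i]] <- base[[i]]()
    } else if (stats::runif(1) < 0.5) {
      len <- sample(3:8, 1)
      el <- sample(c("C", "C", "C", "C", "C", "N", "O"), len,
                   replace = TRUE)
      mols[[i]] <- .buildChainMol(el, sprintf("chain%03d", i),
                                  jitterSd = 0.08)
    } else {
      ringEl <- sample(c("C", "C", "C", "C", "N"), 6, replace = TRUE)
      nT <- sample(0:3, 1)
      tailEl <- if (nT) sample(c("C", "C", "N", "O"), nT, replace = TRUE)
                else character()
      ringEl[1] <- "C"  # tail junction stays tetravalent carbon
      mols[[i]] <- .buildRingMol(ringEl, tailEl,
                                 sprintf("ring%03d", i), jitterSd = 0.08)
    }
    mols[[i]]@name <- sprintf("cmp%03d", i)
  }
  mols
}

#' Specification of a planted-signal kinase panel
#'
#' @param nKinases panel width; @param nSignalKinases how many kinases
#'   carry descriptor-driven signal (the rest are pure noise);
#' @param nSignalFeatures descriptor columns averaged into each signal
#'   kinase's latent activity;
#' @param beta effect size on the log10-Kd scale per standardized unit of
#'   the signal score;
#' @param sigma assay noise sd in log10-Kd units;
#' @param prevalence target fraction of compounds active at Kd < 10 uM;
#' @param seed RNG seed.
#' @return list used by [makePlantedKdMatrix()].
#' @export
plantedPanelSpec <- function(nKinases = 20, nSignalKinases = 5,
                             nSignalFeatures = 5, beta = 2, sigma = 0.3,
                             prevalence = 0.25, seed = 1) {
  stopifnot(nSignalKinases <= nKinases, sigma >= 0, beta >= 0,
            prevalence > 0, prevalence < 1)
  list(nKinases = nKinases, nSignalKinases = nSignalKinases,
       nSignalFeatures = nSignalFeatures, beta = beta, sigma = sigma,
       prevalence = prevalence, seed = as.integer(seed))
}

#' Generate a planted-signal compound x kinase Kd matrix
#'
#' For each signal kinase, `log10 Kd(uM) = a_k - beta * z_k + eps`,
#' `eps ~ Normal(0, sigma)`, where `z_k` is the standardized mean of that
#' kinase's randomly chosen descriptor columns (computed from the default
#' 400-feature layout) and the intercept `a_k` is calibrated so that the
#' realized fraction of compounds with Kd < 10 uM equals the prevalence
#' target (the threshold is placed between the order statistics around
#' `round(prevalence * n)`). Noise kinases draw log10 Kd independent of
#' the features, calibrated the same way. Kd is floored at 1e-4 uM. The
#' ground truth (signal kinases, their feature indices, intercepts) is
#' returned for recovery testing.
#'
#' @param mols list of molecules featurizable under the default layout.
#' @param spec a [plantedPanelSpec()].
#' @param features optional pre-computed feature matrix for `mols`.
#' @return list: `activity` ([ActivityMatrix-class]), `truth` (list with
#'   `signalKinases`, `featureIdx`, `z`, `aK`, and the spec).
#' @export
makePlantedKdMatrix <- function(mols, spec = plantedPanelSpec(),
                                features = NULL) {
  X <- if (is.null(features)) featurizeSet(mols) else features
  n <- nrow(X)
  m <- round(spec$prevalence * n)
  if (m < 1 || m >= n)
    stop("prevalence target ", spec$prevalence,
         " unachievable with ", n, " compounds")
  set.seed(spec$seed)
  sdev <- apply(X, 2, stats::sd)
  eligible <- which(sdev > 1e-8)
  if (length(eligible) < spec$nSignalFeatures)
    stop("not enough varying descriptor columns for the planted signal")
  Z <- scale(X[, eligible, drop = FALSE])
  kd <- matrix(NA_real_, n, spec$nKinases)
  rownames(kd) <- rownames(X)
  colnames(kd) <- sprintf("kin%02d", seq_len(spec$nKinases))
  featureIdx <- vector("list", spec$nKinases)
  aK <- numeric(spec$nKinases)
  zMat <- matrix(0, n, spec$nKinases)
  for (k in seq_len(spec$nKinases)) {
    isSignal <- k <= spec$nSignalKinases
    if (isSignal) {
      idx <- sample(seq_along(eligible), spec$nSignalFeatures)
      featureIdx[[k]] <- eligible[idx]
      z <- rowMeans(Z[, idx, drop = FALSE])
      z <- (z - mean(z)) / stats::sd(z)
    } else {
      featureIdx[[k]] <- integer()
      z <- numeric(n)
    }
    zMat[, k] <- z
    eps <- stats::rnorm(n, 0, spec$sigma)
    s <- -spec$beta * z + eps
    ss <- sort(s)
    aK[k] <- 1 - (ss[m] + ss[m + 1]) / 2
    kd[, k] <- pmax(10^(aK[k] + s), 1e-4)
  }
  truth <- list(signalKinases = colnames(kd)[seq_len(spec$nSignalKinases)],
                featureIdx = featureIdx, z = zMat, aK = aK, spec = spec)
  list(activity = activityMatrix(kd), truth = truth)
}
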