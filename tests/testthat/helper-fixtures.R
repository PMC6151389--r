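# Shared fixtures and independent oracles used across the test files.

# hand-written two-atom V2000 block: C at origin, O at (1.5, 0, 0)
handSdfBlock <- function() {
  c("diatomic fixture",
    "  test              3D",
    "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END",
    "$$$$")
}

# small random 3D molecule (chain) with seeded coordinates
randomChainMol <- function(n, seed, elements = NULL) {
  set.seed(seed)
  if (is.null(elements))
    elements <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  coords <- matrix(stats::rnorm(3 * n, sd = 1.2), n, 3)
  bonds <- if (n > 1) data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1)
  newMolecule(elements, coords, bonds, name = sprintf("rand%d", seed),
              is3D = TRUE)
}

# brute-force RDF oracle: explicit double loop over pairs and bins
bruteRdf <- function(coords, p, K, dr, B) {
  n <- nrow(coords)
  out <- numeric(K)
  for (k in seq_len(K)) {
    r <- (k - 1) * dr
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      out[k] <- out[k] + p[i] * p[j] * exp(-B * (r - d)^2)
    }
  }
  out
}

# brute-force 3DA oracle
brute3da <- function(coords, p, K, delta) {
  n <- nrow(coords)
  out <- numeric(K)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    k <- floor(d / delta) + 1
    if (k >= 1 && k <= K) out[k] <- out[k] + p[i] * p[j]
  }
  out
}

# BFS all-pairs shortest path oracle on the bond graph (no igraph)
bruteTopo2da <- function(nAtoms, bonds, p, K) {
  adj <- vector("list", nAtoms)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  out <- numeric(K)
  out[1] <- sum(p^2)
  for (s in seq_len(nAtoms)) {
    dist <- rep(-1L, nAtoms); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (dist[v] < 0) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
    for (t in seq_len(nAtoms)) {
      if (t <= s) next
      k <- dist[t]
      if (k >= 1 && k <= K - 1) out[k + 1] <- out[k + 1] + p[s] * p[t]
    }
  }
  out
}

# concordant-pair AUC oracle (ties count one half)
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# random rigid transform (proper rotation + translation)
rigidTransform <- function(coords) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr <- qr(M)
  Q <- qr.Q(qr)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t(Q %*% t(coords)) + matrix(stats::rnorm(3, sd = 5), nrow(coords), 3,
                              byrow = TRUE)
}

applyCoords <- function(mol, coords) {
  mol@atoms$x <- coords[, 1]; mol@atoms$y <- coords[, 2]
  mol@atoms$z <- coords[, 3]
  mol
}

molCoords <- function(mol) cbind(atomTable(mol)$x, atomTable(mol)$y,
                                 atomTable(mol)$z)

permuteMol <- function(mol, perm) {
  a <- atomTable(mol)[perm, , drop = FALSE]
  rownames(a) <- NULL
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  b <- bondTable(mol)
  newMolecule(a$element, cbind(a$x, a$y, a$z),
              data.frame(a1 = inv[b$a1], a2 = inv[b$a2], order = b$order),
              charges = a$charge, name = moleculeName(mol),
              is3D = is3D(mol))
}

# printed confusion-count tables (pooled over the kinase panel): cutoff,
# TP, FP, TN, FN and the printed MCC/ACC/SEN/SEL/PPV/NPV
printedPooledTable <- function() {
  data.frame(
    cutoff = c(0.1, 0.5, 1, 3, 10),
    tp = c(971, 1620, 2055, 2915, 3765),
    fp = c(7787, 4410, 3760, 3218, 2944),
    tn = c(17097, 19121, 18902, 17934, 17048),
    fn = c(675, 1379, 1813, 2463, 2773),
    mcc = c(0.14, 0.26, 0.31, 0.37, 0.42),
    acc = c(68.10, 78.18, 78.99, 78.59, 78.45),
    sen = c(58.99, 54.02, 53.13, 54.20, 57.59),
    sel = c(68.71, 81.26, 83.41, 84.79, 85.27),
    ppv = c(0.11, 0.27, 0.35, 0.47, 0.56),
    npv = c(0.96, 0.93, 0.91, 0.88, 0.86),
    accDigits = 2
  )
}

# comparison table for the 15-inhibitor subset (1-decimal percent columns)
printedSubsetTable <- function() {
  data.frame(
    model = c("signature-0.1", "signature-3", "ann-0.1", "ann-3",
              "ann-10"),
    tp = c(185, 342, 340, 944, 1174),
    fp = c(370, 213, 1727, 891, 762),
    tn = c(3521, 3098, 3507, 3526, 3332),
    fn = c(169, 592, 111, 324, 417),
    mcc = c(0.35, 0.37, 0.24, 0.48, 0.52),
    acc = c(87.3, 81.0, 67.7, 78.6, 79.3),
    sen = c(52.3, 36.6, 75.4, 74.5, 73.8),
    sel = c(90.5, 93.6, 67.0, 79.8, 81.4),
    ppv = c(0.33, 0.61, 0.16, 0.51, 0.61),
    npv = c(0.95, 0.83, 0.97, 0.91, 0.88),
    accDigits = 1
  )
}
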