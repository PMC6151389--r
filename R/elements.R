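# Element reference data and PEOE electronegativity parameters.

.pkgCache <- new.env(parent = emptyenv())

#' Element property reference table
#'
#' Atomic mass (g/mol), Pauling electronegativity, dipole polarizability
#' (Angstrom^3), van der Waals radius (Angstrom) and default valence for
#' the elements the package supports. Shipped as a versioned CSV under
#' `inst/extdata` so descriptor values are reproducible offline.
#'
#' @return data.frame keyed by element symbol.
#' @export
#' @examples
#' elementProperties()["C", "mass"]
elementProperties <- function() {
  if (is.null(.pkgCache$elements)) {
    path <- system.file("extdata", "element_properties.csv",
                        package = "KinomeQSAR", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .pkgCache$elements <- tab
  }
  .pkgCache$elements
}

.elementLookup <- function(elements, column) {
  tab <- elementProperties()
  unknown <- setdiff(unique(elements), rownames(tab))
  if (length(unknown))
    stop("unknown element(s) in property table: ",
         paste(unknown, collapse = ", "))
  tab[elements, column]
}

# Gasteiger PEOE polynomial coefficients chi(q) = a + b q + c q^2, keyed by
# element and sigma hybridization. chiPlus is the electronegativity of the
# cation (a + b + c), except hydrogen's conventional 20.02.
.peoeParams <- function() {
  if (is.null(.pkgCache$peoe)) {
    p <- rbind(
      H      = c(7.17,  6.24, -0.56),
      C.sp3  = c(7.98,  9.18,  1.88),
      C.sp2  = c(8.79,  9.32,  1.51),
      C.sp   = c(10.39, 9.45,  0.73),
      N.sp3  = c(11.54, 10.82, 1.36),
      N.sp2  = c(12.87, 11.15, 0.85),
      N.sp   = c(15.68, 11.70, -0.27),
      O.sp3  = c(14.18, 12.92, 1.39),
      O.sp2  = c(17.07, 13.79, 0.47),
      F      = c(14.66, 13.85, 2.31),
      Cl     = c(11.00, 9.69,  1.35),
      Br     = c(10.08, 8.47,  1.16),
      I      = c(9.90,  7.96,  0.96),
      S.sp3  = c(10.14, 9.13,  1.38),
      S.sp2  = c(10.88, 9.49,  1.33),
      P.sp3  = c(8.90,  8.24,  0.96),
      B.sp3  = c(7.50,  8.00,  1.50),
      Si.sp3 = c(7.30,  6.57,  0.66),
      Se.sp3 = c(9.80,  8.70,  1.20)
    )
    colnames(p) <- c("a", "b", "c")
    .pkgCache$peoe <- p
  }
  .pkgCache$peoe
}

# sigma hybridization from the heaviest bond order at the atom
.peoeKey <- function(element, maxOrder) {
  p <- .peoeParams()
  if (element %in% c("H", "F", "Cl", "Br", "I")) return(element)
  hyb <- if (maxOrder >= 3) "sp" else if (maxOrder >= 1.5) "sp2" else "sp3"
  key <- paste(element, hyb, sep = ".")
  if (!key %in% rownames(p)) key <- paste(element, "sp3", sep = ".")
  if (!key %in% rownames(p))
    stop("no PEOE parameters for element ", element)
  key
}
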