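# SMILES ingestion via OpenBabel (ChemmineOB), feeding the package's own
# V2000 reader so charges and implicit hydrogens follow one code path for
# both input dialects.

#' Read a molecule from a SMILES string
#'
#' Converts the SMILES to an SDF block with OpenBabel and parses it with
#' [readMoleculesSDF()]. The result is a connectivity-only molecule
#' (`is3D` is FALSE); implicit hydrogens are available per atom in the
#' `hcount` column of [atomTable()].
#'
#' @param smiles a single valid SMILES string.
#' @param name molecule title (defaults to the SMILES itself).
#' @return a [Molecule-class].
#' @export
#' @examples
#' \dontrun{
#' benzene <- readMoleculeSMILES("c1ccccc1")
#' numAtoms(benzene)  # 6 heavy atoms
#' }
readMoleculeSMILES <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdfText <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\n")),
    error = function(e)
      stop("invalid SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE))
  if (!nzchar(trimws(sdfText)))
    stop("invalid SMILES '", smiles, "'", call. = FALSE)
  mols <- readMoleculesSDF(sdfText)
  if (!length(mols))
    stop("invalid SMILES '", smiles, "': conversion produced no molecule",
         call. = FALSE)
  m <- mols[[1]]
  m@name <- as.character(name)
  m@is3D <- FALSE
  methods::validObject(m)
  m
}
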