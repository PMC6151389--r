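#' @rdname Molecule-class
#' @param object,x a [Molecule-class]
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))
#' @rdname Molecule-class
#' @export
setGeneric("numBonds", function(x) standardGeneric("numBonds"))
#' @rdname Molecule-class
#' @export
setGeneric("is3D", function(x) standardGeneric("is3D"))
#' @rdname Molecule-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname Molecule-class
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname Molecule-class
#' @export
setGeneric("atomProperties", function(x) standardGeneric("atomProperties"))
#' @rdname Molecule-class
#' @export
setGeneric("moleculeName", function(x) standardGeneric("moleculeName"))

#' @rdname ActivityMatrix-class
#' @param x an [ActivityMatrix-class] or [LabelMatrix-class]
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))
#' @rdname ActivityMatrix-class
#' @export
setGeneric("kinases", function(x) standardGeneric("kinases"))
#' @rdname ActivityMatrix-class
#' @export
setGeneric("kdMatrix", function(x) standardGeneric("kdMatrix"))

#' @rdname LabelMatrix-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname LabelMatrix-class
#' @export
setGeneric("cutoffUM", function(x) standardGeneric("cutoffUM"))

#' @rdname DescriptorConfig-class
#' @param x a [DescriptorConfig-class]
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @rdname DescriptorConfig-class
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

setMethod("numAtoms", "Molecule", function(x) nrow(x@atoms))
setMethod("numBonds", "Molecule", function(x) nrow(x@bonds))
setMethod("is3D", "Molecule", function(x) x@is3D)
setMethod("atomTable", "Molecule", function(x) x@atoms)
setMethod("bondTable", "Molecule", function(x) x@bonds)
setMethod("atomProperties", "Molecule", function(x) x@properties)
setMethod("moleculeName", "Molecule", function(x) x@name)

setMethod("compounds", "ActivityMatrix", function(x) rownames(x@kd))
setMethod("kinases", "ActivityMatrix", function(x) colnames(x@kd))
setMethod("kdMatrix", "ActivityMatrix", function(x) x@kd)
setMethod("compounds", "LabelMatrix", function(x) rownames(x@labels))
setMethod("kinases", "LabelMatrix", function(x) colnames(x@labels))
setMethod("labelMatrix", "LabelMatrix", function(x) x@labels)
setMethod("cutoffUM", "LabelMatrix", function(x) x@cutoffUM)

setMethod("totalLength", "DescriptorConfig", function(x) {
  sum(blockLengths(x))
})

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms, %d bonds, %s\n",
              object@name, nrow(object@atoms), nrow(object@bonds),
              if (object@is3D) "3D" else "2D"))
  if (ncol(object@properties))
    cat("  properties:", paste(colnames(object@properties), collapse = ", "),
        "\n")
})

setMethod("show", "DescriptorConfig", function(object) {
  cat(sprintf("DescriptorConfig: %d blocks, %d features\n",
              nrow(object@blocks), totalLength(object)))
  bl <- object@blocks
  for (i in seq_len(nrow(bl)))
    cat(sprintf("  %-8s %-18s k=%-3d\n", bl$kind[i], bl$property[i],
                blockLengths(object)[i]))
})

setMethod("show", "ActivityMatrix", function(object) {
  kd <- object@kd
  cat(sprintf("ActivityMatrix: %d compounds x %d kinases, %d measured (%.1f%%)\n",
              nrow(kd), ncol(kd), sum(!is.na(kd)),
              100 * mean(!is.na(kd))))
})

setMethod("show", "LabelMatrix", function(object) {
  cat(sprintf("LabelMatrix at Kd < %g uM: %d x %d, %d active (%.1f%%)\n",
              object@cutoffUM, nrow(object@labels), ncol(object@labels),
              sum(object@labels), 100 * mean(object@labels)))
})

setMethod("show", "AnnModel", function(object) {
  cat(sprintf("AnnModel: %d -> %d -> %d sigmoid network (seed %d)\n",
              ncol(object@W1), nrow(object@W1), nrow(object@W2),
              object@seed))
})

setMethod("show", "Normalizer", function(object) {
  cat(sprintf("Normalizer: %d features, %d constant\n",
              length(object@center), sum(object@constant)))
})
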