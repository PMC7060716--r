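#' @include AllClasses.R
NULL

#' Accessors for fragbind objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a fragbind object.
#' @return The corresponding component (atom table, hbond table, igraph
#'   graph, ...).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("hbonds", function(x) standardGeneric("hbonds"))

#' @rdname accessors
#' @export
setGeneric("partnerCoords", function(x) standardGeneric("partnerCoords"))

#' @rdname accessors
#' @export
setGeneric("ligandInstances", function(x) standardGeneric("ligandInstances"))

#' @rdname accessors
#' @export
setGeneric("complexId", function(x) standardGeneric("complexId"))

#' @rdname accessors
#' @export
setGeneric("referenceCoords", function(x) standardGeneric("referenceCoords"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("motifLabel", function(x) standardGeneric("motifLabel"))

#' @rdname accessors
#' @export
setGeneric("motifVariants", function(x) standardGeneric("motifVariants"))

setMethod("atoms", "ComplexStructure", function(x) x@atoms)
setMethod("atoms", "FragmentDefinition", function(x) x@atoms)
setMethod("hbonds", "InteractionSite", function(x) x@hbonds)
setMethod("partnerCoords", "InteractionSite", function(x) x@partnerCoords)
setMethod("ligandInstances", "ComplexStructure", function(x) x@ligandInstances)
setMethod("complexId", "ComplexStructure", function(x) x@id)
setMethod("complexId", "InteractionSite", function(x) x@complexId)
setMethod("referenceCoords", "FragmentDefinition",
          function(x) x@referenceCoords)
setMethod("networkGraph", "FragmentNetwork", function(x) x@graph)
setMethod("motifLabel", "MotifCall", function(x) x@label)
setMethod("motifVariants", "MotifCall", function(x) x@variants)

setMethod("show", "FragmentDefinition", function(object) {
  cat("FragmentDefinition:", object@name, "\n")
  cat(" ", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds\n")
  cat("  donors:", paste(object@donorAtoms, collapse = ", "),
      " acceptors:", paste(object@acceptorAtoms, collapse = ", "), "\n")
  cat("  attachment:", paste(object@attachmentAtoms, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ComplexStructure", function(object) {
  tab <- table(object@atoms$category)
  cat("ComplexStructure:", object@id,
      sprintf("(model %d)\n", object@modelNumber))
  cat(" ", nrow(object@atoms), "atoms:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  cat(" ", nrow(object@ligandInstances), "ligand instance(s)\n")
  invisible(object)
})

setMethod("show", "FragmentInstance", function(object) {
  cat("FragmentInstance in", object@complexId, "--",
      sprintf("%s %s%d", object@ligand$residue_name, object@ligand$chain_id,
              object@ligand$residue_seq),
      sprintf("[%s]\n", object@cofactorClass))
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (fit rmsd =",
      format(object@fitRmsd, digits = 4), "A)\n")
  invisible(object)
})

setMethod("show", "InteractionSite", function(object) {
  n <- nrow(object@hbonds)
  nw <- if (n) sum(object@hbonds$water_mediated) else 0L
  cat("InteractionSite:", object@complexId, "--", n, "hbond(s)",
      sprintf("(%d water-mediated)\n", nw))
  if (n) {
    cat("  edges:",
        paste(sort(unique(object@hbonds$edge)), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "MotifCall", function(object) {
  cat("MotifCall:", object@label)
  if (length(object@variants))
    cat(" [", paste(object@variants, collapse = ", "), "]", sep = "")
  cat("\n")
  pos <- c(I = object@positionI, II = object@positionII,
           III = object@positionIII)
  pos <- pos[!is.na(pos)]
  if (length(pos))
    cat(" ", paste(sprintf("position %s: %s", names(pos), pos),
                   collapse = "; "), "\n")
  invisible(object)
})

setMethod("show", "SiteSimilarity", function(object) {
  cat(sprintf("SiteSimilarity: fraction %.3f, rmsd %s (%d matched)\n",
              object@matchedFraction,
              format(object@partnerRmsd, digits = 4),
              nrow(object@matchedPairs)))
  invisible(object)
})

setMethod("show", "FragmentNetwork", function(object) {
  cat("FragmentNetwork [", object@kind, "]: ",
      igraph::vcount(object@graph), " nodes, ",
      igraph::ecount(object@graph), " edges\n", sep = "")
  invisible(object)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d/%d theme entries with ligand (%.1f%%) vs %.1f%% background; fold = %.3f\n",
    object@nThemeWithLigand, object@nThemeEntries,
    100 * object@themeFraction, 100 * object@backgroundFraction,
    object@fold))
  invisible(object)
})
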