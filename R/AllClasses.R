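#' @import methods
NULL

#' Binding-edge labels of a purine fragment
#'
#' The three hydrogen-bonding faces of a purine: the Watson-Crick edge
#' (N1/N6 side), the Hoogsteen edge (N6/N7 side) and the sugar edge
#' (N3/N9-substituent side).
#'
#' @return Character vector of the closed set of edge labels.
#' @export
edgeLevels <- function() c("watson_crick", "hoogsteen", "sugar")

#' FragmentDefinition: a rigid ligand fragment
#'
#' Chemical graph, hydrogen-bonding roles, binding-edge geometry and the
#' canonical reference frame of a rigid fragment.  The canonical frame puts
#' the centroid of the ring atoms at the origin, the ring plane on xy, and
#' the C4-C5 bond midpoint on +x.
#'
#' @slot name fragment name.
#' @slot atoms data.frame with columns \code{atom_name}, \code{element}.
#' @slot bonds two-column character matrix of bonded atom-name pairs.
#' @slot donorAtoms,acceptorAtoms,attachmentAtoms character vectors of atom
#'   names (attachment atoms are substituted positions such as N9 and are
#'   not available for hydrogen bonding).
#' @slot edgeMap named list mapping an atom name to one or two edge labels.
#' @slot referenceCoords numeric matrix (atoms x 3, rownames = atom names),
#'   Angstrom, in the canonical frame.
#' @export
setClass("FragmentDefinition", representation(
  name = "character",
  atoms = "data.frame",
  bonds = "matrix",
  donorAtoms = "character",
  acceptorAtoms = "character",
  attachmentAtoms = "character",
  edgeMap = "list",
  referenceCoords = "matrix"
))

setValidity("FragmentDefinition", function(object) {
  msg <- character()
  an <- object@atoms$atom_name
  if (anyDuplicated(an)) msg <- c(msg, "duplicate atom names")
  if (!all(object@bonds %in% an))
    msg <- c(msg, "bond references unknown atom name")
  # connectivity of the bond graph
  if (nrow(object@bonds) > 0L) {
    g <- igraph::graph_from_edgelist(object@bonds, directed = FALSE)
    g <- g + igraph::vertices(setdiff(an, igraph::V(g)$name))
    if (igraph::components(g)$no != 1L)
      msg <- c(msg, "bond graph is not connected")
  }
  if (length(intersect(object@donorAtoms, object@acceptorAtoms)) > 0L)
    msg <- c(msg, "donor and acceptor sets overlap")
  polar <- union(object@donorAtoms, object@acceptorAtoms)
  if (!all(polar %in% names(object@edgeMap)))
    msg <- c(msg, "every donor/acceptor atom needs an edge_map entry")
  if (!all(unlist(object@edgeMap) %in% edgeLevels()))
    msg <- c(msg, "edge_map contains an unknown edge label")
  if (!setequal(rownames(object@referenceCoords), an) ||
      ncol(object@referenceCoords) != 3L)
    msg <- c(msg, "reference_coords must cover all atoms (n x 3)")
  if (length(msg)) msg else TRUE
})

#' ComplexStructure: one parsed protein-ligand complex
#'
#' A uniform atom table for a single model of a structure, with every atom
#' categorised as protein, ligand, water or other, plus the enumeration of
#' distinct ligand residues.
#'
#' @slot id complex identifier (PDB id or fixture id).
#' @slot atoms data.frame; columns \code{serial}, \code{atom_name},
#'   \code{element}, \code{residue_name}, \code{residue_seq} (author
#'   numbering), \code{insertion_code}, \code{chain_id}, \code{x},
#'   \code{y}, \code{z}, \code{occupancy}, \code{category},
#'   \code{is_backbone}.
#' @slot ligandInstances data.frame with \code{residue_name},
#'   \code{chain_id}, \code{residue_seq}.
#' @slot modelNumber integer model number (single model only).
#' @export
setClass("ComplexStructure", representation(
  id = "character",
  atoms = "data.frame",
  ligandInstances = "data.frame",
  modelNumber = "integer"
))

setValidity("ComplexStructure", function(object) {
  msg <- character()
  need <- c("serial", "atom_name", "element", "residue_name", "residue_seq",
            "insertion_code", "chain_id", "x", "y", "z", "occupancy",
            "category", "is_backbone")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atom table misses required columns")
  else {
    if (!all(object@atoms$category %in%
             c("protein", "ligand", "water", "other")))
      msg <- c(msg, "unknown atom category")
    if (any(object@atoms$is_backbone & object@atoms$category != "protein"))
      msg <- c(msg, "is_backbone set on a non-protein atom")
    wat <- object@atoms$residue_name %in% c("HOH", "WAT", "DOD")
    if (!identical(unname(wat), unname(object@atoms$category == "water")))
      msg <- c(msg, "category=water must coincide with water residue names")
    lig <- unique(object@atoms[object@atoms$category == "ligand",
                               c("residue_name", "chain_id", "residue_seq")])
    li <- object@ligandInstances
    key <- function(d) sort(paste(d$residue_name, d$chain_id, d$residue_seq))
    if (!identical(key(lig), key(li)))
      msg <- c(msg, "ligandInstances must enumerate category=ligand residues")
  }
  if (length(object@modelNumber) != 1L)
    msg <- c(msg, "single model only")
  if (length(msg)) msg else TRUE
})

#' FragmentInstance: one located copy of the fragment inside a ligand
#'
#' @slot complexId complex identifier.
#' @slot ligand list with \code{residue_name}, \code{chain_id},
#'   \code{residue_seq} of the host ligand residue.
#' @slot atomMapping named integer vector: fragment atom name -> atom serial.
#' @slot cofactorClass one of ATP, NAD, FAD, SAM, CoA, other.
#' @export
setClass("FragmentInstance", representation(
  complexId = "character",
  ligand = "list",
  atomMapping = "integer",
  cofactorClass = "character"
))

setValidity("FragmentInstance", function(object) {
  msg <- character()
  if (is.null(names(object@atomMapping)))
    msg <- c(msg, "atomMapping must be named by fragment atom names")
  if (anyDuplicated(object@atomMapping))
    msg <- c(msg, "atomMapping must be injective")
  if (!object@cofactorClass %in% c("ATP", "NAD", "FAD", "SAM", "CoA", "other"))
    msg <- c(msg, "unknown cofactorClass")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: a proper rigid-body motion
#'
#' \code{y = R x + t} with \code{R} proper orthogonal (no reflection).
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation length-3 numeric, Angstrom.
#' @slot fitRmsd post-fit rmsd of the superposition that produced the
#'   transform (0 for exact constructions).
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric",
  fitRmsd = "numeric"
))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation is not orthogonal (tol 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det = +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(object@fitRmsd) != 1L || is.na(object@fitRmsd) ||
      object@fitRmsd < 0)
    msg <- c(msg, "fitRmsd must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' InteractionSite: the hydrogen-bond partners of one complex
#'
#' All hydrogen-bond partner atoms of one fragment instance, expressed in
#' the canonical fragment frame.  For water-mediated bonds the canonical
#' point is the bridging-water oxygen.
#'
#' @slot complexId complex identifier.
#' @slot instance the \linkS4class{FragmentInstance} the site belongs to.
#' @slot hbonds data.frame, one row per hydrogen bond (fragment_atom, edge,
#'   partner serial and descriptor, direction, distance, water_mediated,
#'   bridge_water, partner residue info).
#' @slot partnerCoords numeric matrix (nrow = number of hbonds, 3 columns):
#'   canonical-frame coordinates of each partner point.
#' @slot transform the \linkS4class{RigidTransform} into the canonical frame.
#' @slot meta free-form list (cofactor class etc.).
#' @export
setClass("InteractionSite", representation(
  complexId = "character",
  instance = "FragmentInstance",
  hbonds = "data.frame",
  partnerCoords = "matrix",
  transform = "RigidTransform",
  meta = "list"
))

setValidity("InteractionSite", function(object) {
  msg <- character()
  n <- nrow(object@hbonds)
  if (nrow(object@partnerCoords) != n)
    msg <- c(msg, "partnerCoords must cover all hbonds")
  if (n > 0L) {
    key <- paste(object@hbonds$fragment_atom, object@hbonds$partner_serial)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (fragment_atom, partner) pair")
    if (!all(object@hbonds$edge %in% edgeLevels()))
      msg <- c(msg, "unknown edge label in hbonds")
    if (!identical(unname(object@hbonds$water_mediated),
                   unname(!is.na(object@hbonds$bridge_water))))
      msg <- c(msg, "water_mediated must coincide with bridge_water being set")
  }
  if (length(msg)) msg else TRUE
})

#' MotifCall: classification of an interaction site
#'
#' The classic adenine-recognition motifs: \code{direct} and \code{reverse}
#' (backbone carbonyl/amide pair on the Watson-Crick edge, distinguished by
#' sequence order), \code{asp} (a side-chain oxygen/sulfur at position II
#' accepting from N6), or \code{other}.
#'
#' @slot label one of direct, reverse, asp, other.
#' @slot positionI,positionII,positionIII residue references
#'   ("chain:resseq:resname") or NA.
#' @slot variants subset of \code{c("asp_ser_cys",
#'   "reverse_plus_hoogsteen_XV_XVI", "position_III_hoogsteen")}.
#' @export
setClass("MotifCall", representation(
  label = "character",
  positionI = "character",
  positionII = "character",
  positionIII = "character",
  variants = "character"
))

setValidity("MotifCall", function(object) {
  msg <- character()
  if (!object@label %in% c("direct", "reverse", "asp", "other"))
    msg <- c(msg, "unknown motif label")
  if (object@label == "other" &&
      !all(is.na(c(object@positionI, object@positionII, object@positionIII))))
    msg <- c(msg, "label 'other' must have empty positions")
  if (object@label == "asp" && is.na(object@positionII))
    msg <- c(msg, "asp motif requires position II")
  ok <- c("asp_ser_cys", "reverse_plus_hoogsteen_XV_XVI",
          "position_III_hoogsteen")
  if (!all(object@variants %in% ok))
    msg <- c(msg, "unknown motif variant")
  if (length(msg)) msg else TRUE
})

#' SiteSimilarity: geometric comparison of two interaction sites
#'
#' @slot matchedPairs two-column integer matrix of matched hbond indices
#'   (site a, site b).
#' @slot matchedFraction |matched| / max(|a|, |b|).
#' @slot partnerRmsd rmsd over matched partner coordinates in the common
#'   canonical frame (no re-superposition); +Inf when nothing matches.
#' @export
setClass("SiteSimilarity", representation(
  matchedPairs = "matrix",
  matchedFraction = "numeric",
  partnerRmsd = "numeric"
))

setValidity("SiteSimilarity", function(object) {
  msg <- character()
  if (object@matchedFraction < 0 || object@matchedFraction > 1)
    msg <- c(msg, "matchedFraction must be in [0, 1]")
  if (!(object@partnerRmsd >= 0))
    msg <- c(msg, "partnerRmsd must be non-negative")
  mp <- object@matchedPairs
  if (nrow(mp) > 0L &&
      (anyDuplicated(mp[, 1L]) || anyDuplicated(mp[, 2L])))
    msg <- c(msg, "matching must be injective both ways")
  if (length(msg)) msg else TRUE
})

#' FragmentNetwork: a similarity or theme-sharing network of sites
#'
#' A simple undirected graph whose nodes are interaction sites (one per
#' complex/fragment-instance) and whose edges are either geometric
#' similarity relations or shared-theme relations.
#'
#' @slot graph an \pkg{igraph} graph with node/edge attributes.
#' @slot kind "site_similarity" or "theme_sharing".
#' @export
setClass("FragmentNetwork", representation(
  graph = "ANY",
  kind = "character"
))

setValidity("FragmentNetwork", function(object) {
  msg <- character()
  if (!object@kind %in% c("site_similarity", "theme_sharing"))
    msg <- c(msg, "kind must be site_similarity or theme_sharing")
  g <- object@graph
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g) || igraph::any_multiple(g))
      msg <- c(msg, "graph must be simple (no loops, no multi-edges)")
  }
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: fragment-ligand enrichment of theme-bearing entries
#'
#' Fold enrichment of fragment-containing ligands among corpus entries that
#' carry a binding theme: P(ligand | theme) / P(ligand).
#'
#' @slot nEntries,nLigand,nThemeEntries,nThemeWithLigand counts.
#' @slot backgroundFraction,themeFraction,fold derived fractions and ratio.
#' @export
setClass("EnrichmentResult", representation(
  nEntries = "integer",
  nLigand = "integer",
  nThemeEntries = "integer",
  nThemeWithLigand = "integer",
  backgroundFraction = "numeric",
  themeFraction = "numeric",
  fold = "numeric"
))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@nThemeEntries < 1L) msg <- c(msg, "no theme entries")
  if (object@backgroundFraction > 0 &&
      abs(object@fold -
          object@themeFraction / object@backgroundFraction) > 1e-12)
    msg <- c(msg, "fold must equal themeFraction / backgroundFraction")
  if (length(msg)) msg else TRUE
})
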