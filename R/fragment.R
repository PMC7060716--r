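#' @include AllClasses.R
NULL

#' Read a fragment definition from JSON
#'
#' Fragment definitions are data, not code: a JSON file carries the atom
#' list, bond graph, hydrogen-bonding roles, binding-edge map and canonical
#' reference coordinates, so that rigid fragments other than the shipped
#' adenine can be added without touching the package.
#'
#' @param path path to a JSON fragment definition.
#' @return A \linkS4class{FragmentDefinition}.
#' @export
readFragmentDefinition <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  atoms <- data.frame(atom_name = raw$atoms$atom_name,
                      element = raw$atoms$element,
                      stringsAsFactors = FALSE)
  bonds <- matrix(unlist(raw$bonds), ncol = 2L, byrow = is.list(raw$bonds))
  if (is.list(raw$bonds))
    bonds <- do.call(rbind, raw$bonds)
  rc <- do.call(rbind, raw$reference_coords)
  colnames(rc) <- c("x", "y", "z")
  edge_map <- lapply(raw$edge_map, as.character)
  new("FragmentDefinition",
      name = raw$name,
      atoms = atoms,
      bonds = bonds,
      donorAtoms = as.character(raw$donor_atoms),
      acceptorAtoms = as.character(raw$acceptor_atoms),
      attachmentAtoms = as.character(raw$attachment_atoms),
      edgeMap = edge_map,
      referenceCoords = rc)
}

.adenine_cache <- new.env(parent = emptyenv())

#' The built-in adenine fragment
#'
#' The 10-heavy-atom adenine fragment with conventional purine numbering:
#' ring atoms N1, C2, N3, C4, C5, C6, N7, C8, N9 plus the exocyclic amine
#' N6.  Acceptors are N1, N3, N7; the only donor is N6; N9 is the
#' attachment position (substituted by the ribose in nucleotide cofactors).
#' The edge map assigns N1 to the Watson-Crick edge, N7/C8 to the Hoogsteen
#' edge, N3/N9 to the sugar edge, and leaves N6 (Watson-Crick or Hoogsteen)
#' and C2 (Watson-Crick or sugar) ambivalent between two edges.
#'
#' Reference coordinates are an idealized, exactly planar adenine in the
#' canonical frame (ring centroid at the origin, ring plane = xy, the
#' C4-C5 bond midpoint on +x, N1 at positive y).
#'
#' @return A \linkS4class{FragmentDefinition}.
#' @examples
#' frag <- builtinAdenine()
#' frag
#' @export
builtinAdenine <- function() {
  if (is.null(.adenine_cache$frag)) {
    path <- system.file("extdata", "adenine.json", package = "fragbind",
                        mustWork = TRUE)
    .adenine_cache$frag <- readFragmentDefinition(path)
  }
  .adenine_cache$frag
}

#' Planarity residual of a point set
#'
#' Root-mean-square distance of the points from their least-squares plane.
#'
#' @param coords numeric matrix (n x 3).
#' @return rms residual in the units of \code{coords}.
#' @export
planarityResidual <- function(coords) {
  q <- scale(coords, scale = FALSE)
  sv <- svd(q)$d
  sqrt(sv[3L]^2 / nrow(coords))
}

# In-plane projection relative to the fragment's canonical frame: the
# canonical plane is xy, so projection just zeroes z.
.in_plane <- function(v) c(v[1L], v[2L])

.norm2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction (zero-length vector)")
  v / n
}

.rot2 <- function(v, theta) {
  c(cos(theta) * v[1L] - sin(theta) * v[2L],
    sin(theta) * v[1L] + cos(theta) * v[2L])
}

# Fragment-graph neighbors of an atom
.frag_neighbors <- function(frag, atom_name) {
  b <- frag@bonds
  unique(c(b[b[, 1L] == atom_name, 2L], b[b[, 2L] == atom_name, 1L]))
}

#' Assign the binding edge of a hydrogen-bond partner
#'
#' Atoms whose edge-map entry is unique inherit that edge.  For the
#' exocyclic amine N6, which sits between the Watson-Crick and Hoogsteen
#' edges, the partner is assigned by which idealized amine-hydrogen
#' direction its in-plane projection is closer to: the two N-H directions
#' of the sp2 amine lie at +/-60 degrees from the C6->N6 bond extension,
#' one pointing to the N1 (Watson-Crick) side and one to the N7 (Hoogsteen)
#' side.  The decision boundary is therefore the C6-N6 axis itself, so
#' mirror-image partners across that axis always land on opposite edges.
#'
#' @param frag a \linkS4class{FragmentDefinition}.
#' @param atomName a donor or acceptor atom of \code{frag}.
#' @param partnerPos partner position (length-3), canonical frame.
#' @return One of \code{edgeLevels()}.
#' @examples
#' frag <- builtinAdenine()
#' resolveEdge(frag, "N1", c(-4, 1.5, 0))   # unique edge: watson_crick
#' @export
resolveEdge <- function(frag, atomName, partnerPos) {
  if (!atomName %in% frag@atoms$atom_name)
    stop("unknown atom name: ", atomName)
  if (atomName %in% frag@attachmentAtoms)
    stop("atom ", atomName, " is an attachment position, ",
         "not available for bonding")
  edges <- frag@edgeMap[[atomName]]
  if (is.null(edges))
    stop("atom ", atomName, " has no edge_map entry")
  if (length(edges) == 1L) return(edges)

  rc <- frag@referenceCoords
  pos <- rc[atomName, ]
  nb <- .frag_neighbors(frag, atomName)
  # outward axis: away from the (single) ring neighbor for exocyclic atoms,
  # away from the mean of ring neighbors otherwise
  axis <- .norm2(.in_plane(pos - colMeans(rc[nb, , drop = FALSE])))
  # representative atoms anchoring each candidate edge side
  side_atom <- c(watson_crick = "N1", hoogsteen = "N7", sugar = "N3")
  p <- .norm2(.in_plane(partnerPos - pos))
  score <- vapply(edges, function(e) {
    towards <- .norm2(.in_plane(rc[side_atom[[e]], ] - pos))
    # idealized substituent direction: outward axis rotated 60 degrees
    # toward the edge's side
    sgn <- sign(axis[1L] * towards[2L] - axis[2L] * towards[1L])
    if (sgn == 0) sgn <- 1
    bis <- .rot2(axis, sgn * pi / 3)
    sum(p * bis) # cosine of the angle to the bisector
  }, numeric(1L))
  edges[which.max(score)]
}
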