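#' @include AllClasses.R fragment.R structio.R
NULL

# Covalent radii (Angstrom) for bond inference; pairs are bonded when their
# distance is below r1 + r2 + 0.4 (slack absorbs coordinate error in the
# wild, where HETATM CONECT records are unreliable).
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
                FE = 1.32, MG = 1.41, ZN = 1.22, MN = 1.39, "NA" = 1.66)

.cov_radius <- function(el) {
  r <- .COV_RADII[toupper(el)]
  ifelse(is.na(r), 0.77, unname(r))
}

#' Infer covalent bonds of a ligand from interatomic distances
#'
#' @param coords numeric matrix (n x 3).
#' @param elements character vector of element symbols (length n).
#' @param slack extra distance allowed beyond the sum of covalent radii.
#' @return Two-column integer matrix of bonded atom indices.
#' @export
inferBonds <- function(coords, elements, slack = 0.4) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  d <- as.matrix(stats::dist(coords))
  r <- .cov_radius(elements)
  cutoff <- outer(r, r, "+") + slack
  hit <- which(d < cutoff & upper.tri(d) & d > 0.4, arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2L,
         dimnames = list(NULL, c("i", "j")))
}

.element_color <- function(elements) {
  as.integer(factor(toupper(elements),
                    levels = c("C", "N", "O", "S", "P", "H", "X")))
}

#' Locate a rigid fragment inside a ligand by labeled-graph matching
#'
#' Builds the element-labeled bond graph of each ligand residue (bonds
#' inferred from interatomic distances) and enumerates all subgraph
#' isomorphisms of the fragment's bond graph into it (VF2 with element
#' colors).  Symmetry-equivalent self-mappings are deduplicated to one
#' instance per distinct atom set.  Attachment atoms must be substituted in
#' the ligand or terminal; ligands with fewer atoms than the fragment
#' yield no instances.
#'
#' @param cs a \linkS4class{ComplexStructure}.
#' @param ligand optional single ligand as a list/row with
#'   \code{residue_name}, \code{chain_id}, \code{residue_seq}; by default
#'   all ligand instances of \code{cs} are searched.
#' @param frag a \linkS4class{FragmentDefinition}.
#' @return List of \linkS4class{FragmentInstance}.
#' @export
matchFragment <- function(cs, ligand = NULL, frag = builtinAdenine()) {
  ligs <- if (is.null(ligand)) cs@ligandInstances else
    as.data.frame(ligand, stringsAsFactors = FALSE)
  if (nrow(ligs) == 0L) return(list())

  fa <- frag@atoms
  fidx <- stats::setNames(seq_len(nrow(fa)), fa$atom_name)
  fg <- igraph::graph_from_edgelist(
    cbind(fidx[frag@bonds[, 1L]], fidx[frag@bonds[, 2L]]), directed = FALSE)
  igraph::V(fg)$color <- .element_color(fa$element)
  fdeg <- igraph::degree(fg)

  out <- list()
  for (k in seq_len(nrow(ligs))) {
    li <- ligs[k, ]
    sel <- cs@atoms$category == "ligand" &
      cs@atoms$residue_name == li$residue_name &
      cs@atoms$chain_id == li$chain_id &
      cs@atoms$residue_seq == li$residue_seq &
      cs@atoms$element != "H"
    lat <- cs@atoms[sel, , drop = FALSE]
    if (nrow(lat) < nrow(fa)) next
    bonds <- inferBonds(as.matrix(lat[, c("x", "y", "z")]), lat$element)
    lg <- igraph::make_empty_graph(n = nrow(lat), directed = FALSE)
    if (nrow(bonds)) lg <- igraph::add_edges(lg, t(bonds))
    igraph::V(lg)$color <- .element_color(lat$element)
    maps <- igraph::subgraph_isomorphisms(pattern = fg, target = lg,
                                          method = "vf2")
    if (!length(maps)) next
    seen <- character()
    for (m in maps) {
      tgt <- as.integer(m)
      key <- paste(sort(tgt), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      # attachment constraint: substituted (degree above the free fragment's)
      # or terminal
      ldeg <- igraph::degree(lg)
      ok <- all(vapply(frag@attachmentAtoms, function(a) {
        ldeg[tgt[fidx[[a]]]] >= fdeg[fidx[[a]]]
      }, logical(1L)))
      if (!ok) next
      mapping <- stats::setNames(as.integer(lat$serial[tgt]), fa$atom_name)
      out[[length(out) + 1L]] <- new(
        "FragmentInstance",
        complexId = cs@id,
        ligand = list(residue_name = li$residue_name,
                      chain_id = li$chain_id,
                      residue_seq = li$residue_seq),
        atomMapping = mapping,
        cofactorClass = cofactorClass(li$residue_name))
    }
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rigid transform (rotation + translation, reflections
#' rejected) that maps the fragment instance's coordinates in the complex
#' onto the fragment's canonical reference coordinates, minimizing the
#' rmsd over all mapped atoms (unweighted).
#'
#' @param instance a \linkS4class{FragmentInstance}.
#' @param cs the complex the instance lives in.
#' @param frag the fragment definition.
#' @return A \linkS4class{RigidTransform}; \code{fitRmsd} is the post-fit
#'   rmsd over the mapped atoms.
#' @export
superpose <- function(instance, cs, frag = builtinAdenine()) {
  serials <- instance@atomMapping
  idx <- match(serials, cs@atoms$serial)
  if (anyNA(idx)) stop("instance serials not found in complex")
  X <- as.matrix(cs@atoms[idx, c("x", "y", "z")])
  Y <- frag@referenceCoords[names(serials), , drop = FALSE]
  kabsch(X, Y)
}

#' Kabsch algorithm on paired coordinate sets
#'
#' @param X,Y numeric matrices (n x 3) of paired points; the returned
#'   transform maps \code{X} onto \code{Y}.
#' @return A \linkS4class{RigidTransform}.
#' @export
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3L, ncol(Y) == 3L,
            nrow(X) >= 3L)
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc); Yc <- sweep(Y, 2L, yc)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  # collinear (or coincident) input: no unique rotation about the axis
  spread <- svd(Xc)$d
  if (spread[2L] < 1e-6 * max(spread[1L], 1e-12))
    stop("degenerate geometry: mapped atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(yc - R %*% xc)
  fitted <- sweep(X %*% t(R), 2L, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  new("RigidTransform", rotation = R, translation = t, fitRmsd = rmsd)
}

#' Apply a rigid transform to points
#'
#' @param t a \linkS4class{RigidTransform}.
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @return Transformed points, same shape as the input.
#' @export
applyTransform <- function(t, points) {
  if (is.null(dim(points))) {
    as.numeric(t@rotation %*% points + t@translation)
  } else {
    sweep(points %*% t(t@rotation), 2L, t@translation, "+")
  }
}

#' Invert a rigid transform
#' @param t a \linkS4class{RigidTransform}.
#' @return The inverse transform.
#' @export
invertTransform <- function(t) {
  R <- t(t@rotation)
  new("RigidTransform", rotation = R,
      translation = as.numeric(-R %*% t@translation), fitRmsd = 0)
}

#' Compose two rigid transforms (apply \code{a} first, then \code{b})
#' @param a,b \linkS4class{RigidTransform} objects.
#' @return The composed transform.
#' @export
composeTransforms <- function(b, a) {
  new("RigidTransform",
      rotation = b@rotation %*% a@rotation,
      translation = as.numeric(b@rotation %*% a@translation + b@translation),
      fitRmsd = 0)
}

#' A rigid transform from Euler angles and a translation
#'
#' Convenience constructor used by the synthetic-data generator and tests.
#'
#' @param angles rotations about z, y, x (radians), applied in that order.
#' @param translation length-3 numeric.
#' @return A \linkS4class{RigidTransform}.
#' @export
eulerTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  cz <- cos(angles[1L]); sz <- sin(angles[1L])
  cy <- cos(angles[2L]); sy <- sin(angles[2L])
  cx <- cos(angles[3L]); sx <- sin(angles[3L])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  new("RigidTransform", rotation = Rx %*% Ry %*% Rz,
      translation = as.numeric(translation), fitRmsd = 0)
}
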