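#' @include AllClasses.R geometry.R
NULL

# Protein hydrogen-bond capability tables (heavy atoms only).  Criteria are
# hydrogen-free on purpose: most PDB structures lack hydrogens, so donors
# are recognised by name/residue and constrained by the antecedent angle.
.SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH")

.SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

.SIDECHAIN_S_ACCEPTORS <- list(CYS = "SG", MET = "SD")

#' Hydrogen-bond detection parameters
#'
#' Geometric, hydrogen-free criteria in the style of heavy-atom polar
#' contact detection: a donor-acceptor distance cutoff plus an antecedent
#' angle (the angle X-D...A for every covalent neighbor X of the donor
#' heavy atom D must be at least \code{minAntecedentAngle}, which rejects
#' partners buried behind the donor).  The default distance of 3.5 A sits
#' between the 3.2 A (strict) and 3.9 A (lax) presets used for sensitivity
#' analysis; the three thresholds give nested bond sets on any input.
#'
#' @param maxDaDistance donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (2.2-4.5 allowed; presets of interest: 3.2, 3.5, 3.9).
#' @param minAntecedentAngle minimum antecedent angle, degrees.
#' @param waterBridgeMax per-leg distance cutoff for water bridges.
#' @param includeWeakCh also treat the aromatic C2/C8 C-H groups as weak
#'   donors (off by default: polar N/O chemistry only).
#' @param includeS accept Cys/Met sulfur as a weak acceptor.
#' @return A validated parameter list of class \code{HBondParams}.
#' @export
hbondParams <- function(maxDaDistance = 3.5, minAntecedentAngle = 90,
                        waterBridgeMax = 3.5, includeWeakCh = FALSE,
                        includeS = TRUE) {
  if (maxDaDistance < 2.2 || maxDaDistance > 4.5)
    stop("maxDaDistance must be within [2.2, 4.5] Angstrom")
  if (minAntecedentAngle < 0 || minAntecedentAngle > 180)
    stop("minAntecedentAngle must be within [0, 180] degrees")
  structure(list(maxDaDistance = maxDaDistance,
                 minAntecedentAngle = minAntecedentAngle,
                 waterBridgeMax = waterBridgeMax,
                 includeWeakCh = isTRUE(includeWeakCh),
                 includeS = isTRUE(includeS)),
            class = "HBondParams")
}

.descriptor <- function(atom_name, element, category) {
  if (category == "water") return("water_O")
  if (atom_name %in% c("N")) return("backbone_N")
  if (atom_name %in% c("O", "OXT")) return("backbone_O")
  paste0("sidechain_", switch(toupper(element), N = "N", O = "O", S = "S",
                              toupper(element)))
}

.protein_donor_atoms <- function(atoms) {
  side <- mapply(function(rn, an) {
    an %in% .SIDECHAIN_DONORS[[rn]]
  }, atoms$residue_name, atoms$atom_name)
  atoms$category == "protein" &
    (atoms$atom_name == "N" | as.logical(side))
}

.protein_acceptor_atoms <- function(atoms, includeS = TRUE) {
  side <- mapply(function(rn, an) {
    an %in% .SIDECHAIN_ACCEPTORS[[rn]] ||
      (includeS && an %in% .SIDECHAIN_S_ACCEPTORS[[rn]])
  }, atoms$residue_name, atoms$atom_name)
  atoms$category == "protein" &
    (atoms$atom_name %in% c("O", "OXT") | as.logical(side))
}

# covalent heavy-atom neighbors of one atom within the whole structure
.covalent_neighbors <- function(atoms, i) {
  p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
  d2 <- (atoms$x - p[1L])^2 + (atoms$y - p[2L])^2 + (atoms$z - p[3L])^2
  cutoff <- (.cov_radius(atoms$element[i]) + .cov_radius(atoms$element) +
               0.4)^2
  which(d2 < cutoff & d2 > 0.16 & atoms$element != "H" &
          atoms$category == atoms$category[i])
}

.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.antecedent_ok <- function(atoms, donor_idx, acceptor_pos, min_angle) {
  nb <- .covalent_neighbors(atoms, donor_idx)
  if (!length(nb)) return(TRUE)
  d <- c(atoms$x[donor_idx], atoms$y[donor_idx], atoms$z[donor_idx])
  all(vapply(nb, function(j) {
    x <- c(atoms$x[j], atoms$y[j], atoms$z[j])
    .angle_deg(x, d, acceptor_pos) >= min_angle
  }, logical(1L)))
}

.empty_hbonds <- function() {
  data.frame(fragment_atom = character(), edge = character(),
             partner_serial = integer(), partner_atom_name = character(),
             partner_chain = character(), partner_resname = character(),
             partner_resseq = integer(), partner_insert = character(),
             descriptor = character(), direction = character(),
             distance = numeric(), leg2 = numeric(),
             water_mediated = logical(), bridge_water = integer(),
             stringsAsFactors = FALSE)
}

.hbond_row <- function(frag_atom, edge, atoms, j, direction, distance,
                       leg2 = NA_real_, bridge = NA_integer_) {
  data.frame(fragment_atom = frag_atom, edge = edge,
             partner_serial = atoms$serial[j],
             partner_atom_name = atoms$atom_name[j],
             partner_chain = atoms$chain_id[j],
             partner_resname = atoms$residue_name[j],
             partner_resseq = atoms$residue_seq[j],
             partner_insert = atoms$insertion_code[j],
             descriptor = .descriptor(atoms$atom_name[j], atoms$element[j],
                                      atoms$category[j]),
             direction = direction, distance = distance, leg2 = leg2,
             water_mediated = !is.na(bridge), bridge_water = bridge,
             stringsAsFactors = FALSE)
}

.frag_positions <- function(cs, instance) {
  idx <- match(instance@atomMapping, cs@atoms$serial)
  m <- as.matrix(cs@atoms[idx, c("x", "y", "z")])
  rownames(m) <- names(instance@atomMapping)
  m
}

#' Detect direct hydrogen bonds between the fragment and the protein
#'
#' For every fragment donor/acceptor atom, every protein atom with the
#' complementary role within \code{maxDaDistance} that satisfies the
#' antecedent-angle criterion yields one hydrogen bond.  Acceptor
#' candidates on the protein side are backbone carbonyl O, side-chain
#' O/N with a lone pair and (optionally) Cys/Met sulfur; donor candidates
#' are backbone amide N and side-chain N/O-H groups.  The binding edge is
#' assigned from the partner's position in the canonical fragment frame.
#'
#' @param cs a \linkS4class{ComplexStructure}.
#' @param instance the fragment instance to probe.
#' @param frag the fragment definition.
#' @param params a \code{\link{hbondParams}} object.
#' @param transform canonical-frame transform; computed by
#'   \code{\link{superpose}} when not supplied.
#' @return data.frame of hydrogen bonds (possibly empty).
#' @export
detectHBonds <- function(cs, instance, frag = builtinAdenine(),
                         params = hbondParams(), transform = NULL) {
  if (is.null(transform)) transform <- superpose(instance, cs, frag)
  at <- cs@atoms
  fpos <- .frag_positions(cs, instance)

  frag_donors <- frag@donorAtoms
  if (params$includeWeakCh)
    frag_donors <- union(frag_donors,
                         intersect(c("C2", "C8"), frag@atoms$atom_name))
  frag_acceptors <- frag@acceptorAtoms

  don_idx <- which(.protein_donor_atoms(at))
  acc_idx <- which(.protein_acceptor_atoms(at, params$includeS))

  rows <- list()
  for (fa in union(frag_donors, frag_acceptors)) {
    if (!fa %in% rownames(fpos)) next
    fp <- fpos[fa, ]
    cand <- if (fa %in% frag_donors) acc_idx else don_idx
    if (!length(cand)) next
    d <- sqrt((at$x[cand] - fp[1L])^2 + (at$y[cand] - fp[2L])^2 +
                (at$z[cand] - fp[3L])^2)
    hit <- cand[d <= params$maxDaDistance]
    dist <- d[d <= params$maxDaDistance]
    if (!length(hit)) next
    for (k in seq_along(hit)) {
      j <- hit[k]
      pp <- c(at$x[j], at$y[j], at$z[j])
      if (fa %in% frag_donors) {
        # fragment donates: antecedent angle at the fragment donor
        nbn <- .frag_neighbors(frag, fa)
        nbn <- nbn[nbn %in% rownames(fpos)]
        ok <- all(vapply(nbn, function(x) {
          .angle_deg(fpos[x, ], fp, pp) >= params$minAntecedentAngle
        }, logical(1L)))
        direction <- "fragment_donates"
      } else {
        ok <- .antecedent_ok(at, j, fp, params$minAntecedentAngle)
        direction <- "fragment_accepts"
      }
      if (!ok) next
      edge <- resolveEdge(frag, fa, applyTransform(transform, pp))
      rows[[length(rows) + 1L]] <-
        .hbond_row(fa, edge, at, j, direction, dist[k])
    }
  }
  hb <- if (length(rows)) do.call(rbind, rows) else .empty_hbonds()
  # one bond per (fragment atom, partner): keep the shortest
  if (nrow(hb) > 1L) {
    hb <- hb[order(hb$fragment_atom, hb$partner_serial, hb$distance), ]
    hb <- hb[!duplicated(hb[, c("fragment_atom", "partner_serial")]), ]
  }
  rownames(hb) <- NULL
  hb
}

#' Detect single-water-mediated hydrogen bonds
#'
#' A water oxygen within \code{waterBridgeMax} of a fragment donor/acceptor
#' atom and within \code{waterBridgeMax} of a protein N/O atom yields one
#' mediated bond recording both legs and the bridging-water serial.  Water
#' is ambivalent, so the direction is left as \code{fragment_accepts} by
#' convention.  Only single-water bridges count: chains of two or more
#' waters are bulk solvent, not a structured bridge.
#'
#' @inheritParams detectHBonds
#' @return data.frame of mediated hydrogen bonds (possibly empty).
#' @export
detectWaterMediated <- function(cs, instance, frag = builtinAdenine(),
                                params = hbondParams(), transform = NULL) {
  if (is.null(transform)) transform <- superpose(instance, cs, frag)
  at <- cs@atoms
  fpos <- .frag_positions(cs, instance)
  wat_idx <- which(at$category == "water" & at$element == "O")
  if (!length(wat_idx)) return(.empty_hbonds())
  polar <- which((.protein_donor_atoms(at) |
                    .protein_acceptor_atoms(at, includeS = FALSE)) &
                   at$element %in% c("N", "O"))
  if (!length(polar)) return(.empty_hbonds())

  frag_polar <- union(frag@donorAtoms, frag@acceptorAtoms)
  rows <- list()
  for (fa in frag_polar) {
    if (!fa %in% rownames(fpos)) next
    fp <- fpos[fa, ]
    dw <- sqrt((at$x[wat_idx] - fp[1L])^2 + (at$y[wat_idx] - fp[2L])^2 +
                 (at$z[wat_idx] - fp[3L])^2)
    near_w <- wat_idx[dw <= params$waterBridgeMax]
    leg1s <- dw[dw <= params$waterBridgeMax]
    for (k in seq_along(near_w)) {
      w <- near_w[k]
      wp <- c(at$x[w], at$y[w], at$z[w])
      dp <- sqrt((at$x[polar] - wp[1L])^2 + (at$y[polar] - wp[2L])^2 +
                   (at$z[polar] - wp[3L])^2)
      prot <- polar[dp <= params$waterBridgeMax]
      legs2 <- dp[dp <= params$waterBridgeMax]
      if (!length(prot)) next # dangling (bulk) water
      edge <- resolveEdge(frag, fa, applyTransform(transform, wp))
      for (q in seq_along(prot)) {
        rows[[length(rows) + 1L]] <-
          .hbond_row(fa, edge, at, prot[q], "fragment_accepts",
                     leg1s[k], leg2 = legs2[q],
                     bridge = as.integer(at$serial[w]))
      }
    }
  }
  hb <- if (length(rows)) do.call(rbind, rows) else .empty_hbonds()
  # among duplicate mediated bonds keep the shortest total leg length
  if (nrow(hb) > 1L) {
    hb <- hb[order(hb$fragment_atom, hb$partner_serial,
                   hb$distance + hb$leg2), ]
    hb <- hb[!duplicated(hb[, c("fragment_atom", "partner_serial")]), ]
  }
  rownames(hb) <- NULL
  hb
}

#' Assemble the interaction site of one fragment instance
#'
#' Merges direct and water-mediated hydrogen bonds, deduplicates per
#' (fragment atom, partner atom) keeping the direct bond over the mediated
#' one, and expresses every partner in the canonical fragment frame.  For
#' mediated bonds the canonical point is the bridging-water oxygen (waters
#' are what superposed displays show).
#'
#' @inheritParams detectHBonds
#' @param transform transform from \code{\link{superpose}} on the same
#'   instance; computed when not supplied.
#' @return An \linkS4class{InteractionSite}.
#' @export
buildSite <- function(cs, instance, frag = builtinAdenine(),
                      params = hbondParams(), transform = NULL) {
  if (!identical(instance@complexId, cs@id))
    stop("instance/complex mismatch: instance belongs to ",
         instance@complexId)
  if (is.null(transform)) transform <- superpose(instance, cs, frag)
  direct <- detectHBonds(cs, instance, frag, params, transform)
  mediated <- detectWaterMediated(cs, instance, frag, params, transform)
  hb <- rbind(direct, mediated)
  if (nrow(hb)) {
    # direct beats mediated on the same (fragment atom, partner)
    hb <- hb[order(hb$fragment_atom, hb$partner_serial, hb$water_mediated), ]
    hb <- hb[!duplicated(hb[, c("fragment_atom", "partner_serial")]), ]
    hb <- hb[order(hb$fragment_atom, hb$partner_serial), ]
    rownames(hb) <- NULL
  }
  pc <- matrix(numeric(), nrow = 0L, ncol = 3L)
  if (nrow(hb)) {
    pts <- t(vapply(seq_len(nrow(hb)), function(i) {
      ser <- if (hb$water_mediated[i]) hb$bridge_water[i] else
        hb$partner_serial[i]
      j <- match(ser, cs@atoms$serial)
      c(cs@atoms$x[j], cs@atoms$y[j], cs@atoms$z[j])
    }, numeric(3L)))
    pc <- applyTransform(transform, pts)
  }
  colnames(pc) <- c("x", "y", "z")
  new("InteractionSite", complexId = cs@id, instance = instance,
      hbonds = hb, partnerCoords = pc, transform = transform,
      meta = list(cofactor_class = instance@cofactorClass))
}

#' Run the full per-complex pipeline
#'
#' Convenience wrapper: locate every fragment instance in the complex,
#' superpose each and build its interaction site.
#'
#' @param cs a \linkS4class{ComplexStructure}.
#' @param frag fragment definition.
#' @param params hydrogen-bond parameters.
#' @return List of \linkS4class{InteractionSite} (possibly empty).
#' @export
profileComplex <- function(cs, frag = builtinAdenine(),
                           params = hbondParams()) {
  instances <- matchFragment(cs, frag = frag)
  lapply(instances, function(ins) buildSite(cs, ins, frag, params))
}
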