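#' @include AllClasses.R geometry.R interactions.R
NULL

# run code under a local, seeded RNG without disturbing the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.unit <- function(v) v / sqrt(sum(v^2))

# direction at a fragment atom: outward in-plane lone-pair axis rotated by
# theta (deg, counterclockwise in the canonical plane) and elevated by phi
# (deg, toward +z)
.bond_direction <- function(frag, atom, theta, phi) {
  rc <- frag@referenceCoords
  nb <- .frag_neighbors(frag, atom)
  u3 <- rc[atom, ] - colMeans(rc[nb, , drop = FALSE])
  u <- .unit(c(u3[1L], u3[2L], 0))
  th <- theta * pi / 180
  ur <- c(cos(th) * u[1L] - sin(th) * u[2L],
          sin(th) * u[1L] + cos(th) * u[2L], 0)
  ph <- phi * pi / 180
  .unit(cos(ph) * ur + sin(ph) * c(0, 0, 1))
}

#' Plan a synthetic binding site
#'
#' A \code{SitePlan} describes the hydrogen bonds to plant around the
#' fragment: for each bond the fragment atom, the partner descriptor, the
#' donor-acceptor distance, the in-plane angle (degrees away from the
#' atom's outward lone-pair axis; positive = counterclockwise in the
#' canonical plane) and optionally an out-of-plane elevation, whether the
#' bond is water-mediated, and the partner residue's identity and author
#' numbering (so sequence-order motif rules are exercisable).
#'
#' @param bonds data.frame with columns \code{fragment_atom},
#'   \code{descriptor} (\code{backbone_N}, \code{backbone_O},
#'   \code{sidechain_O}, \code{sidechain_S}), \code{distance} (Angstrom,
#'   must lie in [2.5, 3.4] so planted bonds sit inside all preset
#'   thresholds), \code{in_plane_angle} (deg); optional columns
#'   \code{out_of_plane_angle} (deg, default 0), \code{mediated} (default
#'   FALSE), \code{resname} (default GLY for backbone, SER/CYS for
#'   side-chain descriptors), \code{chain} (default "A"), \code{resseq}
#'   (default 10, 20, 30, ...).
#' @param motifLabel intended motif label (ground truth), or NA.
#' @param familyId integer family label for network fixtures, or NA.
#' @param jitterSigma isotropic Gaussian jitter (Angstrom) applied as a
#'   rigid displacement per partner residue (and per water).
#' @param seed RNG seed; every generator is a pure function of
#'   (plan, seed).
#' @param id complex identifier; derived from the seed when NULL.
#' @return A validated \code{SitePlan} list.
#' @export
sitePlan <- function(bonds, motifLabel = NA_character_,
                     familyId = NA_integer_, jitterSigma = 0, seed = 1L,
                     id = NULL) {
  stopifnot(is.data.frame(bonds), nrow(bonds) >= 1L,
            all(c("fragment_atom", "descriptor", "distance",
                  "in_plane_angle") %in% names(bonds)))
  if (any(bonds$distance < 2.5 | bonds$distance > 3.4))
    stop("planted bond distances must lie in [2.5, 3.4] Angstrom")
  if (is.null(bonds$out_of_plane_angle)) bonds$out_of_plane_angle <- 0
  if (is.null(bonds$mediated)) bonds$mediated <- FALSE
  if (is.null(bonds$chain)) bonds$chain <- "A"
  if (is.null(bonds$resseq)) bonds$resseq <- 10L * seq_len(nrow(bonds))
  if (is.null(bonds$resname))
    bonds$resname <- ifelse(bonds$descriptor == "sidechain_O", "SER",
                            ifelse(bonds$descriptor == "sidechain_S",
                                   "CYS", "GLY"))
  if (is.null(id)) id <- sprintf("SYN%06d", as.integer(seed) %% 1000000L)
  structure(list(bonds = bonds, motifLabel = motifLabel,
                 familyId = familyId, jitterSigma = jitterSigma,
                 seed = as.integer(seed), id = id),
            class = "SitePlan")
}

# anchor atom name per descriptor/residue
.anchor_atom <- function(descriptor, resname) {
  switch(descriptor,
         backbone_N = "N",
         backbone_O = "O",
         sidechain_O = switch(resname, SER = "OG", THR = "OG1",
                              TYR = "OH", ASP = "OD1", ASN = "OD1",
                              GLU = "OE1", GLN = "OE1",
                              stop("no side-chain O in ", resname)),
         sidechain_S = switch(resname, CYS = "SG", MET = "SD",
                              stop("no side-chain S in ", resname)),
         stop("unknown descriptor: ", descriptor))
}

.mix <- function(u, w, deg) {
  a <- deg * pi / 180
  .unit(cos(a) * u + sin(a) * w)
}

# build one partner residue extending outward from `anchor` along `u`
# (w = in-plane-ish perpendicular used to avoid collinearity)
.build_residue <- function(descriptor, resname, anchor, u, w) {
  A <- function(name, el, pos) data.frame(
    atom_name = name, element = el, x = pos[1L], y = pos[2L], z = pos[3L],
    stringsAsFactors = FALSE)
  if (descriptor == "backbone_N") {
    n <- anchor
    ca <- n + 1.46 * .mix(u, w, 20)
    c_ <- ca + 1.52 * .mix(u, w, -20)
    o <- c_ + 1.23 * .mix(u, w, 60)
    rbind(A("N", "N", n), A("CA", "C", ca), A("C", "C", c_), A("O", "O", o))
  } else if (descriptor == "backbone_O") {
    o <- anchor
    c_ <- o + 1.23 * .mix(u, w, 15)
    ca <- c_ + 1.52 * .mix(u, w, -25)
    n <- ca + 1.46 * .mix(u, w, 15)
    rbind(A("N", "N", n), A("CA", "C", ca), A("C", "C", c_), A("O", "O", o))
  } else if (descriptor == "sidechain_O" &&
             resname %in% c("ASP", "ASN", "GLU", "GLN")) {
    names2 <- if (resname %in% c("ASP", "ASN")) c("OD1", "CG", "OD2", "CB")
      else c("OE1", "CD", "OE2", "CG")
    o1 <- anchor
    cg <- o1 + 1.25 * .mix(u, w, 10)
    o2 <- cg + 1.25 * .mix(u, w, -60)
    cb <- cg + 1.52 * .mix(u, w, 40)
    ca <- cb + 1.53 * .mix(u, w, 10)
    n <- ca + 1.46 * .mix(u, w, -25)
    c_ <- ca + 1.52 * .mix(u, w, 45)
    o <- c_ + 1.23 * .mix(u, w, 0)
    e2 <- if (resname %in% c("ASN", "GLN")) "N" else "O"
    n2 <- if (resname == "ASN") "ND2" else if (resname == "GLN") "NE2"
      else names2[3L]
    rbind(A(names2[1L], "O", o1), A(names2[2L], "C", cg),
          A(n2, e2, o2), A(names2[4L], "C", cb), A("CA", "C", ca),
          A("N", "N", n), A("C", "C", c_), A("O", "O", o))
  } else if (descriptor %in% c("sidechain_O", "sidechain_S")) {
    blen <- if (descriptor == "sidechain_S") 1.81 else 1.41
    an <- .anchor_atom(descriptor, resname)
    el <- if (descriptor == "sidechain_S") "S" else "O"
    og <- anchor
    cb <- og + blen * .mix(u, w, 10)
    ca <- cb + 1.53 * .mix(u, w, -25)
    n <- ca + 1.46 * .mix(u, w, 25)
    c_ <- ca + 1.52 * .mix(u, w, -45)
    o <- c_ + 1.23 * .mix(u, w, 0)
    rbind(A(an, el, og), A("CB", "C", cb), A("CA", "C", ca),
          A("N", "N", n), A("C", "C", c_), A("O", "O", o))
  } else stop("unknown descriptor: ", descriptor)
}

# paired builder: one residue whose backbone N sits at anchor_n and whose
# backbone O sits at anchor_o (the position-III Hoogsteen/N7 pattern)
.build_residue_pair <- function(anchor_n, anchor_o, out_dir) {
  A <- function(name, el, pos) data.frame(
    atom_name = name, element = el, x = pos[1L], y = pos[2L], z = pos[3L],
    stringsAsFactors = FALSE)
  v <- anchor_o - anchor_n
  dno <- sqrt(sum(v^2))
  if (dno < 2.2 || dno > 3.6)
    stop("infeasible N/O pair: anchors ", round(dno, 2), " A apart")
  v <- v / dno
  w <- out_dir - sum(out_dir * v) * v
  w <- .unit(w)
  # CA 1.46 A from N, placed so that |CA - O| ~ 2.75 A
  target <- 2.75
  cosa <- (1.46^2 + dno^2 - target^2) / (2 * 1.46 * dno)
  cosa <- pmin(1, pmax(-1, cosa))
  sina <- sqrt(1 - cosa^2)
  ca <- anchor_n + 1.46 * (cosa * v + sina * w)
  c_ <- anchor_o + 1.23 * .unit(ca - anchor_o)
  rbind(A("N", "N", anchor_n), A("CA", "C", ca), A("C", "C", c_),
        A("O", "O", anchor_o))
}

#' Generate one synthetic complex from a site plan
#'
#' The adenine fragment is placed at its reference coordinates and
#' embedded in a minimal ligand (N9 capped by a carbon stand-in for the
#' ribose C1').  Partner pseudo-residues (glycine backbones, or the
#' side chain the descriptor requires) are placed at the planted polar
#' geometry plus the plan's Gaussian jitter; waters are inserted for
#' mediated bonds.  The whole complex is then moved by a random rigid
#' pose (seeded), so superposition back into the canonical frame is
#' exercised for real.  If a plan row shares (chain, resseq) between a
#' backbone_N and a backbone_O bond, one residue is built whose amide and
#' carbonyl serve both bonds.
#'
#' @param plan a \code{\link{sitePlan}}.
#' @param frag fragment definition.
#' @param randomPose move the complex by a random rigid motion (default
#'   TRUE); with FALSE the complex stays in the canonical frame.
#' @return list with \code{structure} (a
#'   \linkS4class{ComplexStructure}) and \code{truth} (planted bonds with
#'   residue identities, motif label, family id, and the applied pose).
#' @export
generateSite <- function(plan, frag = builtinAdenine(),
                         randomPose = TRUE) {
  stopifnot(inherits(plan, "SitePlan"))
  .with_seed(plan$seed, {
    rc <- frag@referenceCoords
    # ligand: fragment + C1' cap on the attachment atom
    lig <- data.frame(atom_name = rownames(rc),
                      element = frag@atoms$element[
                        match(rownames(rc), frag@atoms$atom_name)],
                      x = rc[, 1L], y = rc[, 2L], z = rc[, 3L],
                      stringsAsFactors = FALSE)
    for (att in frag@attachmentAtoms) {
      d <- .bond_direction(frag, att, 0, 0)
      cap <- rc[att, ] + 1.47 * d
      lig <- rbind(lig, data.frame(atom_name = "C1'", element = "C",
                                   x = cap[1L], y = cap[2L], z = cap[3L]))
    }

    bonds <- plan$bonds
    key <- paste(bonds$chain, bonds$resseq)
    residues <- list()   # per residue: df of atoms + meta
    waters <- list()
    truth_rows <- list()
    for (k in unique(key)) {
      idx <- which(key == k)
      rows <- bonds[idx, , drop = FALSE]
      anchors <- list(); dirs <- list()
      for (r in seq_len(nrow(rows))) {
        fa <- rows$fragment_atom[r]
        dir <- .bond_direction(frag, fa, rows$in_plane_angle[r],
                               rows$out_of_plane_angle[r])
        fp <- rc[fa, ]
        if (isTRUE(rows$mediated[r])) {
          wpos <- fp + rows$distance[r] * dir
          waters[[length(waters) + 1L]] <- list(pos = wpos, bond = rows[r, ])
          anchors[[r]] <- wpos + 2.75 * dir
        } else {
          anchors[[r]] <- fp + rows$distance[r] * dir
        }
        dirs[[r]] <- dir
      }
      two_bb <- nrow(rows) == 2L &&
        setequal(rows$descriptor, c("backbone_N", "backbone_O"))
      if (two_bb) {
        ni <- which(rows$descriptor == "backbone_N")
        oi <- which(rows$descriptor == "backbone_O")
        outd <- .unit(dirs[[ni]] + dirs[[oi]])
        res <- .build_residue_pair(anchors[[ni]], anchors[[oi]], outd)
      } else if (nrow(rows) == 1L) {
        dir <- dirs[[1L]]
        wv <- if (abs(dir[3L]) < 0.9) .unit(c(-dir[2L], dir[1L], 0)) else
          c(1, 0, 0)
        res <- .build_residue(rows$descriptor[1L], rows$resname[1L],
                              anchors[[1L]], dir, wv)
      } else stop("a planned residue can carry at most one bond, or a ",
                  "backbone N/O pair")
      residues[[length(residues) + 1L]] <-
        list(atoms = res, chain = rows$chain[1L],
             resseq = rows$resseq[1L], resname = rows$resname[1L],
             bond_rows = idx)
    }

    jitter_and_check <- function(sig) {
      for (try in seq_len(200L)) {
        rs <- lapply(residues, function(r) {
          sh <- if (sig > 0) stats::rnorm(3L, 0, sig) else c(0, 0, 0)
          r$atoms[, c("x", "y", "z")] <-
            sweep(as.matrix(r$atoms[, c("x", "y", "z")]), 2L, -sh)
          r
        })
        ws <- lapply(waters, function(wt) {
          sh <- if (sig > 0) stats::rnorm(3L, 0, sig) else c(0, 0, 0)
          wt$pos <- wt$pos + sh
          wt
        })
        # clash check across residues / ligand / waters (>= 2.0 A)
        blocks <- c(list(as.matrix(lig[, c("x", "y", "z")])),
                    lapply(rs, function(r)
                      as.matrix(r$atoms[, c("x", "y", "z")])),
                    lapply(ws, function(wt) matrix(wt$pos, 1L)))
        ok <- TRUE
        nb <- length(blocks)
        for (i in seq_len(nb - 1L)) for (j in seq((i + 1L), nb)) {
          dmin <- min(sqrt(outer(rowSums(blocks[[i]]^2), rep(1, nrow(blocks[[j]]))) +
                             outer(rep(1, nrow(blocks[[i]])), rowSums(blocks[[j]]^2)) -
                             2 * blocks[[i]] %*% t(blocks[[j]])))
          if (dmin < 2.0) { ok <- FALSE; break }
          if (!ok) break
        }
        if (ok) return(list(residues = rs, waters = ws))
        if (sig == 0) stop("geometrically infeasible plan: partner ",
                           "clash below 2.0 A with zero jitter")
      }
      stop("could not draw a clash-free jitter in 200 tries")
    }
    placed <- jitter_and_check(plan$jitterSigma)

    # assemble the atom table: protein residues (chain, resseq order),
    # then the ligand HETATM, then waters
    ord <- order(vapply(placed$residues, function(r) r$chain,
                        character(1L)),
                 vapply(placed$residues, function(r) r$resseq,
                        numeric(1L)))
    prot <- do.call(rbind, lapply(placed$residues[ord], function(r) {
      data.frame(atom_name = r$atoms$atom_name, element = r$atoms$element,
                 residue_name = r$resname, residue_seq = r$resseq,
                 chain_id = r$chain, x = r$atoms$x, y = r$atoms$y,
                 z = r$atoms$z, category = "protein",
                 stringsAsFactors = FALSE)
    }))
    ligdf <- data.frame(atom_name = lig$atom_name, element = lig$element,
                        residue_name = "ATP", residue_seq = 1L,
                        chain_id = "L", x = lig$x, y = lig$y, z = lig$z,
                        category = "ligand", stringsAsFactors = FALSE)
    watdf <- NULL
    if (length(placed$waters))
      watdf <- do.call(rbind, lapply(seq_along(placed$waters), function(i) {
        wp <- placed$waters[[i]]$pos
        data.frame(atom_name = "O", element = "O", residue_name = "HOH",
                   residue_seq = i, chain_id = "W", x = wp[1L], y = wp[2L],
                   z = wp[3L], category = "water",
                   stringsAsFactors = FALSE)
      }))
    df <- rbind(prot, ligdf, watdf)
    df$serial <- seq_len(nrow(df))
    df$insertion_code <- ""
    df$occupancy <- 1
    df$is_backbone <- df$category == "protein" &
      df$atom_name %in% c("N", "CA", "C", "O")

    pose <- if (randomPose) {
      q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
      R <- matrix(c(
        1 - 2 * (q[3L]^2 + q[4L]^2), 2 * (q[2L] * q[3L] - q[1L] * q[4L]),
        2 * (q[2L] * q[4L] + q[1L] * q[3L]),
        2 * (q[2L] * q[3L] + q[1L] * q[4L]), 1 - 2 * (q[2L]^2 + q[4L]^2),
        2 * (q[3L] * q[4L] - q[1L] * q[2L]),
        2 * (q[2L] * q[4L] - q[1L] * q[3L]),
        2 * (q[3L] * q[4L] + q[1L] * q[2L]), 1 - 2 * (q[2L]^2 + q[3L]^2)),
        3L, byrow = TRUE)
      new("RigidTransform", rotation = R,
          translation = stats::runif(3L, -10, 10), fitRmsd = 0)
    } else eulerTransform()
    xyz <- applyTransform(pose, as.matrix(df[, c("x", "y", "z")]))
    df$x <- round(xyz[, 1L], 3L)
    df$y <- round(xyz[, 2L], 3L)
    df$z <- round(xyz[, 3L], 3L)
    df <- df[, c("serial", "atom_name", "element", "residue_name",
                 "residue_seq", "insertion_code", "chain_id", "x", "y",
                 "z", "occupancy", "category", "is_backbone")]

    ligins <- unique(df[df$category == "ligand",
                        c("residue_name", "chain_id", "residue_seq")])
    rownames(ligins) <- NULL
    cs <- new("ComplexStructure", id = plan$id, atoms = df,
              ligandInstances = ligins, modelNumber = 1L)

    truth_bonds <- data.frame(
      fragment_atom = bonds$fragment_atom,
      descriptor = bonds$descriptor,
      mediated = bonds$mediated,
      chain = bonds$chain, resseq = bonds$resseq,
      resname = bonds$resname,
      partner_atom_name = ifelse(
        bonds$descriptor %in% c("backbone_N", "backbone_O"),
        ifelse(bonds$descriptor == "backbone_N", "N", "O"),
        mapply(.anchor_atom, bonds$descriptor, bonds$resname)),
      stringsAsFactors = FALSE)
    list(structure = cs,
         truth = list(bonds = truth_bonds, motif_label = plan$motifLabel,
                      family_id = plan$familyId, pose = pose))
  })
}

# family slot directions: four out-of-plane elevations along each atom's
# outward lone-pair axis.  Elevation-only slots never lean toward a
# neighboring ring position (N1/N6 and N3/N9 are close in plane), and
# adjacent slots are 44 degrees apart -- a chord of 2.17 A at the planted
# 2.9 A bond radius
.FAMILY_SLOTS <- list(c(0, -66), c(0, -22), c(0, 22), c(0, 66))

#' Generate a dataset of site families with controlled jitter
#'
#' Each family is a base site plan with four planted hydrogen bonds (at
#' N1, N3, N6, N7); members are jittered copies under random rigid poses.
#' Families are separated by assigning each polar atom's partner to one of
#' four direction slots and giving the families codewords of a length-4
#' parity code over the slots, so any two families differ in at least two
#' of their four partners (shared fraction at most 0.5) and differing
#' partners sit at least 2.9 A apart -- cleanly below/above the default
#' network thresholds.
#'
#' @param nFamilies number of families (at most 64).
#' @param membersPerFamily members per family.
#' @param sigmaWithin within-family jitter sigma, Angstrom.
#' @param minBetween required minimum distance between differing partners
#'   of two families (at most the 2.9 A slot separation).
#' @param seed RNG seed.
#' @param frag fragment definition.
#' @return list with \code{structures} (list of
#'   \linkS4class{ComplexStructure}) and \code{truth} (data.frame
#'   complex_id, family).
#' @export
generateFamilyDataset <- function(nFamilies = 4L, membersPerFamily = 6L,
                                  sigmaWithin = 0.05, minBetween = 2.0,
                                  seed = 1L, frag = builtinAdenine()) {
  stopifnot(nFamilies >= 1L, membersPerFamily >= 1L)
  if (nFamilies > 64L) stop("at most 64 distinguishable families")
  slot_sep <- 2 * 2.9 * sin(22 * pi / 180) # chord of the 44 deg separation
  if (minBetween > slot_sep + 1e-9)
    stop("infeasible separation: slots are ", round(slot_sep, 2),
         " A apart, which is below minBetween")
  atoms <- c("N1", "N3", "N6", "N7")
  descr <- c(N1 = "backbone_N", N3 = "backbone_N", N6 = "backbone_O",
             N7 = "backbone_N")
  codes <- list()
  for (a in 0:3) for (b in 0:3) for (c_ in 0:3) {
    codes[[length(codes) + 1L]] <- c(a, b, c_, (a + b + c_) %% 4L)
  }
  structures <- list()
  truth <- NULL
  for (f in seq_len(nFamilies)) {
    cw <- codes[[f]]
    bonds <- do.call(rbind, lapply(seq_along(atoms), function(i) {
      sl <- .FAMILY_SLOTS[[cw[i] + 1L]]
      data.frame(fragment_atom = atoms[i],
                 descriptor = unname(descr[atoms[i]]),
                 distance = 2.9, in_plane_angle = sl[1L],
                 out_of_plane_angle = sl[2L], mediated = FALSE,
                 chain = "A", resseq = 10L * i,
                 resname = "GLY", stringsAsFactors = FALSE)
    }))
    for (m in seq_len(membersPerFamily)) {
      cid <- sprintf("F%02d_M%02d", f, m)
      plan <- sitePlan(bonds, familyId = f, jitterSigma = sigmaWithin,
                       seed = as.integer(seed) + 997L * f + m, id = cid)
      g <- generateSite(plan, frag)
      structures[[cid]] <- g$structure
      truth <- rbind(truth, data.frame(complex_id = cid, family = f,
                                       stringsAsFactors = FALSE))
    }
  }
  list(structures = structures, truth = truth)
}

#' Generate a theme-network fixture with known truth edges
#'
#' Every complex gets the same three-bond base site (partners at residues
#' 10, 20, 30 of chain A).  Theme annotations either cover the binding
#' residues (\code{covers_binder = TRUE}: range 5-45) or deliberately miss
#' them (range 101-140), so the dual-participation rule is exercised: a
#' truth edge exists between two complexes exactly when they share a
#' theme whose copy binds in both.
#'
#' @param assignments data.frame with columns \code{complex_id},
#'   \code{theme_id}, \code{covers_binder}.
#' @param seed RNG seed.
#' @param sigma jitter for the generated sites.
#' @param frag fragment definition.
#' @return list with \code{structures}, \code{annotations} (theme table)
#'   and \code{truthEdges} (data.frame from, to).
#' @export
generateThemeFixture <- function(assignments, seed = 1L, sigma = 0.02,
                                 frag = builtinAdenine()) {
  stopifnot(all(c("complex_id", "theme_id", "covers_binder") %in%
                  names(assignments)))
  base <- data.frame(
    fragment_atom = c("N1", "N6", "N7"),
    descriptor = c("backbone_N", "backbone_O", "backbone_N"),
    distance = 2.9, in_plane_angle = c(0, 55, 0),
    out_of_plane_angle = 0, mediated = FALSE, chain = "A",
    resseq = c(10L, 20L, 30L), resname = "GLY",
    stringsAsFactors = FALSE)
  ids <- unique(assignments$complex_id)
  structures <- list()
  for (i in seq_along(ids)) {
    plan <- sitePlan(base, jitterSigma = sigma,
                     seed = as.integer(seed) + i, id = ids[i])
    structures[[ids[i]]] <- generateSite(plan, frag)$structure
  }
  annotations <- data.frame(
    theme_id = as.integer(assignments$theme_id),
    complex_id = assignments$complex_id,
    chain_id = "A",
    start = ifelse(assignments$covers_binder, 5L, 101L),
    end = ifelse(assignments$covers_binder, 45L, 140L),
    stringsAsFactors = FALSE)
  edges <- NULL
  for (t in unique(assignments$theme_id)) {
    binders <- sort(assignments$complex_id[assignments$theme_id == t &
                                             assignments$covers_binder])
    if (length(binders) >= 2L) {
      cmb <- utils::combn(binders, 2L)
      edges <- rbind(edges, data.frame(from = cmb[1L, ], to = cmb[2L, ],
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  edges <- unique(edges)
  rownames(edges) <- NULL
  list(structures = structures, annotations = annotations,
       truthEdges = edges)
}

#' Canned site plans for the classic motifs
#'
#' Convenience plans whose ground-truth labels cover the motif classifier:
#' \code{direct}, \code{reverse}, \code{asp}, \code{asp_ser} (the Ser/Cys
#' variant), \code{reverse_xv_xvi} (reverse plus the downstream Hoogsteen
#' carbonyl at offset +22) and \code{position_iii} (one residue bonding
#' N6-Hoogsteen with its amide and N7 with its carbonyl).
#'
#' @param label which motif to plant.
#' @param seed RNG seed for the resulting plan.
#' @param jitterSigma jitter, Angstrom.
#' @return A \code{\link{sitePlan}}.
#' @export
motifPlan <- function(label = c("direct", "reverse", "asp", "asp_ser",
                                "reverse_xv_xvi", "position_iii"),
                      seed = 1L, jitterSigma = 0) {
  label <- match.arg(label)
  b <- function(fa, de, th, rs, rn = "GLY", ph = 0) data.frame(
    fragment_atom = fa, descriptor = de, distance = 2.9,
    in_plane_angle = th, out_of_plane_angle = ph, mediated = FALSE,
    chain = "A", resseq = rs, resname = rn, stringsAsFactors = FALSE)
  bonds <- switch(label,
    direct = rbind(b("N6", "backbone_O", 55, 10L),
                   b("N1", "backbone_N", 0, 12L)),
    reverse = rbind(b("N6", "backbone_O", 55, 14L),
                    b("N1", "backbone_N", 0, 12L)),
    asp = rbind(b("N6", "sidechain_O", 55, 20L, "ASP", ph = 35),
                b("N1", "backbone_N", 0, 12L)),
    asp_ser = rbind(b("N6", "sidechain_O", 55, 20L, "SER", ph = 35),
                    b("N1", "backbone_N", 0, 12L)),
    reverse_xv_xvi = rbind(b("N6", "backbone_O", 55, 14L),
                           b("N1", "backbone_N", 0, 12L),
                           b("N6", "backbone_O", -60, 36L)),
    position_iii = rbind(b("N6", "backbone_O", -30, 40L),
                         b("N7", "backbone_N", 0, 40L)))
  truth <- switch(label, direct = "direct", reverse = "reverse",
                  asp = "asp", asp_ser = "asp", reverse_xv_xvi = "reverse",
                  position_iii = "other")
  sitePlan(bonds, motifLabel = truth, jitterSigma = jitterSigma,
           seed = seed)
}
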