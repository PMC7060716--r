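# Fixtures are built in code; nothing binary ships with the tests.

.std_atom_cols <- function(df) {
  df$serial <- seq_len(nrow(df))
  df$insertion_code <- ""
  df$occupancy <- 1
  df$is_backbone <- df$category == "protein" &
    df$atom_name %in% c("N", "CA", "C", "O")
  df[, c("serial", "atom_name", "element", "residue_name", "residue_seq",
         "insertion_code", "chain_id", "x", "y", "z", "occupancy",
         "category", "is_backbone")]
}

makeStructure <- function(id, atom_rows) {
  df <- .std_atom_cols(atom_rows)
  lig <- unique(df[df$category == "ligand",
                   c("residue_name", "chain_id", "residue_seq")])
  rownames(lig) <- NULL
  new("ComplexStructure", id = id, atoms = df, ligandInstances = lig,
      modelNumber = 1L)
}

ligRow <- function(name, el, pos, resname = "LIG", resseq = 1L,
                   chain = "L", category = "ligand") {
  data.frame(atom_name = name, element = el, residue_name = resname,
             residue_seq = resseq, chain_id = chain,
             x = pos[1L], y = pos[2L], z = pos[3L], category = category,
             stringsAsFactors = FALSE)
}

# adenine reference coordinates plus decorations, as ligand-only complexes
adenineCoords <- function() referenceCoords(builtinAdenine())

#' adenosine-like ligand: adenine + a short ribose-mimicking carbon chain
#' hanging off N9
makeAtpLikeComplex <- function(id = "atp_like", resname = "ATP") {
  rc <- adenineCoords()
  frag <- builtinAdenine()
  els <- atoms(frag)$element[match(rownames(rc), atoms(frag)$atom_name)]
  rows <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i)
    ligRow(rownames(rc)[i], els[i], rc[i, ], resname = resname)))
  n9 <- rc["N9", ]
  dir <- c(0.26, -0.97, 0) / sqrt(0.26^2 + 0.97^2)
  c1 <- n9 + 1.47 * dir
  o4 <- c1 + 1.43 * c(0.9, 0.2, 0.38)
  c2 <- c1 + 1.52 * c(0.1, -0.8, -0.59)
  rows <- rbind(rows,
                ligRow("C1'", "C", c1, resname = resname),
                ligRow("O4'", "O", o4, resname = resname),
                ligRow("C2'", "C", c2, resname = resname))
  makeStructure(id, rows)
}

#' guanine-like ligand: adenine scaffold with O6 replacing N6 and an extra
#' exocyclic N2 on C2 (breaks the element labeling of adenine)
makeGuanineComplex <- function(id = "gua") {
  rc <- adenineCoords()
  frag <- builtinAdenine()
  els <- atoms(frag)$element[match(rownames(rc), atoms(frag)$atom_name)]
  rows <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i) {
    nm <- rownames(rc)[i]; el <- els[i]
    if (nm == "N6") { nm <- "O6"; el <- "O" }
    ligRow(nm, el, rc[i, ], resname = "GUN")
  }))
  c2 <- rc["C2", ]
  out <- c2 - (rc["N1", ] + rc["N3", ]) / 2
  out <- out / sqrt(sum(out^2))
  rows <- rbind(rows, ligRow("N2", "N", c2 + 1.35 * out, resname = "GUN"))
  makeStructure(id, rows)
}

#' NAD-like ligand: one adenine (capped at N9) plus a distant
#' nicotinamide-like pyridine ring in the same residue
makeNadLikeComplex <- function(id = "nad_like") {
  rc <- adenineCoords()
  frag <- builtinAdenine()
  els <- atoms(frag)$element[match(rownames(rc), atoms(frag)$atom_name)]
  rows <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i)
    ligRow(rownames(rc)[i], els[i], rc[i, ], resname = "NAD")))
  n9 <- rc["N9", ]
  rows <- rbind(rows, ligRow("C1'", "C", n9 + 1.47 * c(0.26, -0.97, 0),
                             resname = "NAD"))
  # pyridine ring + amide, 9 A away on +x
  th <- seq(0, 2 * pi, length.out = 7L)[1:6]
  ring <- cbind(9 + 1.39 * cos(th), 1.39 * sin(th), 0)
  ringel <- c("N", "C", "C", "C", "C", "C")
  ringnm <- c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N")
  for (i in 1:6)
    rows <- rbind(rows, ligRow(ringnm[i], ringel[i], ring[i, ],
                               resname = "NAD"))
  c3 <- ring[3L, ]
  c7 <- c3 + 1.5 * c(0.87, 0.5, 0)
  rows <- rbind(rows,
                ligRow("C7N", "C", c7, resname = "NAD"),
                ligRow("O7N", "O", c7 + 1.23 * c(0.5, -0.87, 0),
                       resname = "NAD"),
                ligRow("N7N", "N", c7 + 1.34 * c(0.26, 0.97, 0),
                       resname = "NAD"))
  makeStructure(id, rows)
}

#' pyrimidine-only decoy (six-membered C4N2 ring, no fused system)
makePyrimidineComplex <- function(id = "pyr") {
  th <- seq(0, 2 * pi, length.out = 7L)[1:6]
  ring <- cbind(1.36 * cos(th), 1.36 * sin(th), 0)
  el <- c("N", "C", "N", "C", "C", "C")
  nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
  rows <- do.call(rbind, lapply(1:6, function(i)
    ligRow(nm[i], el[i], ring[i, ], resname = "PYR")))
  makeStructure(id, rows)
}

# ------------------------------------------------------------------
# independent brute-force rigid-superposition oracle: dense rotation grid
# (Euler angles) followed by Nelder-Mead refinement of the best starts;
# the optimal translation for a fixed rotation aligns the centroids.
bruteForceFitRmsd <- function(X, Y, n_grid = 10L, n_refine = 5L) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  rotmat <- function(a) {
    cz <- cos(a[1L]); sz <- sin(a[1L])
    cy <- cos(a[2L]); sy <- sin(a[2L])
    cx <- cos(a[3L]); sx <- sin(a[3L])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
    Rx %*% Ry %*% Rz
  }
  obj <- function(a) {
    R <- rotmat(a)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  g1 <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  g2 <- seq(-pi / 2, pi / 2, length.out = n_grid)
  grid <- as.matrix(expand.grid(g1, g2, g1))
  vals <- apply(grid, 1L, obj)
  starts <- grid[order(vals)[seq_len(n_refine)], , drop = FALSE]
  best <- min(vals)
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 3000L))
    best <- min(best, fit$value)
  }
  best
}

# adjusted Rand index of components vs ground-truth families
componentsVsFamiliesARI <- function(sites, truth, net) {
  cc <- connectedComponents(net)
  ids <- vapply(sites, siteId, character(1L))
  memb <- cc$membership$component[match(ids, cc$membership$id)]
  # sites dropped from the network count as their own singletons
  memb[is.na(memb)] <- max(memb, na.rm = TRUE) + seq_len(sum(is.na(memb)))
  fam <- truth$family[match(vapply(sites, complexId, character(1L)),
                            truth$complex_id)]
  mclust::adjustedRandIndex(memb, fam)
}

buildAllSites <- function(structures, params = hbondParams()) {
  out <- list()
  for (cs in structures) {
    for (ins in matchFragment(cs))
      out[[length(out) + 1L]] <- buildSite(cs, ins, params = params)
  }
  out
}

protRow <- function(name, el, pos, resname = "GLY", resseq = 10L,
                    chain = "A") {
  data.frame(atom_name = name, element = el, residue_name = resname,
             residue_seq = resseq, chain_id = chain,
             x = pos[1L], y = pos[2L], z = pos[3L], category = "protein",
             stringsAsFactors = FALSE)
}

watRow <- function(pos, resseq = 1L) {
  data.frame(atom_name = "O", element = "O", residue_name = "HOH",
             residue_seq = resseq, chain_id = "W",
             x = pos[1L], y = pos[2L], z = pos[3L], category = "water",
             stringsAsFactors = FALSE)
}

# adenine ligand at reference coordinates plus arbitrary extra atom rows
makeAdenineWith <- function(id, extra_rows = NULL) {
  rc <- adenineCoords()
  frag <- builtinAdenine()
  els <- atoms(frag)$element[match(rownames(rc), atoms(frag)$atom_name)]
  rows <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i)
    ligRow(rownames(rc)[i], els[i], rc[i, ], resname = "ATP")))
  rows <- rbind(rows, ligRow("C1'", "C",
                             rc["N9", ] + 1.47 * c(0.26, -0.97, 0),
                             resname = "ATP"))
  if (!is.null(extra_rows)) rows <- rbind(rows, extra_rows)
  makeStructure(id, rows)
}

# outward in-plane lone-pair direction at a fragment atom
outwardDir <- function(atom) {
  fragbind:::.bond_direction(builtinAdenine(), atom, 0, 0)
}

# a glycine whose amide N sits at `pos`, tail extending along `dir`
glyDonorAt <- function(pos, dir, resseq = 10L, chain = "A") {
  w <- c(-dir[2L], dir[1L], 0); w <- w / sqrt(sum(w^2))
  mix <- function(deg) {
    a <- deg * pi / 180
    v <- cos(a) * dir + sin(a) * w
    v / sqrt(sum(v^2))
  }
  ca <- pos + 1.46 * mix(20)
  c_ <- ca + 1.52 * mix(-20)
  o <- c_ + 1.23 * mix(60)
  rbind(protRow("N", "N", pos, resseq = resseq, chain = chain),
        protRow("CA", "C", ca, resseq = resseq, chain = chain),
        protRow("C", "C", c_, resseq = resseq, chain = chain),
        protRow("O", "O", o, resseq = resseq, chain = chain))
}

# a glycine whose carbonyl O sits at `pos`
glyAcceptorAt <- function(pos, dir, resseq = 10L, chain = "A") {
  w <- c(-dir[2L], dir[1L], 0); w <- w / sqrt(sum(w^2))
  mix <- function(deg) {
    a <- deg * pi / 180
    v <- cos(a) * dir + sin(a) * w
    v / sqrt(sum(v^2))
  }
  c_ <- pos + 1.23 * mix(15)
  ca <- c_ + 1.52 * mix(-25)
  n <- ca + 1.46 * mix(15)
  rbind(protRow("N", "N", n, resseq = resseq, chain = chain),
        protRow("CA", "C", ca, resseq = resseq, chain = chain),
        protRow("C", "C", c_, resseq = resseq, chain = chain),
        protRow("O", "O", pos, resseq = resseq, chain = chain))
}

# random well-formed site plan: 3-4 bonds at distinct polar atoms, safe
# out-of-plane elevations, distances inside every preset threshold with
# headroom for the jitter (3.0 + 4 sigma stays under the 3.5 A default)
randomPlan <- function(seed, sigma = 0.1) {
  set.seed(seed)
  n <- sample(3:4, 1L)
  fragatoms <- sample(c("N1", "N3", "N6", "N7"), n)
  descr <- ifelse(fragatoms == "N6",
                  sample(c("backbone_O", "sidechain_O"), 1L), "backbone_N")
  bonds <- data.frame(
    fragment_atom = fragatoms, descriptor = descr,
    distance = round(stats::runif(n, 2.6, 3.0), 2L),
    in_plane_angle = 0,
    out_of_plane_angle = round(stats::runif(n, -65, 65)),
    mediated = FALSE,
    chain = "A", resseq = 10L * seq_len(n),
    resname = ifelse(descr == "sidechain_O", "SER", "GLY"),
    stringsAsFactors = FALSE)
  sitePlan(bonds, jitterSigma = sigma, seed = seed)
}

# recovered (fragment_atom, partner residue) pairs vs the planted truth
recoveredExactly <- function(gen, params = hbondParams()) {
  cs <- gen$structure
  s <- buildSite(cs, matchFragment(cs)[[1L]], params = params)
  got <- hbonds(s)[, c("fragment_atom", "partner_resseq",
                       "water_mediated")]
  got <- got[order(got$fragment_atom, got$partner_resseq), ]
  want <- gen$truth$bonds[, c("fragment_atom", "resseq", "mediated")]
  names(want) <- names(got)
  want <- want[order(want$fragment_atom, want$partner_resseq), ]
  rownames(got) <- rownames(want) <- NULL
  isTRUE(all.equal(got, want))
}

# minimal hand-built interaction site with given partner points
fakeSite <- function(id, coords, categories = NULL, cofactor = "ATP") {
  n <- nrow(coords)
  if (is.null(categories)) categories <- rep("backbone_N", n)
  hb <- if (n == 0L) fragbind:::.empty_hbonds() else data.frame(
    fragment_atom = paste0("N", seq_len(n)), edge = "watson_crick",
    partner_serial = seq_len(n), partner_atom_name = "N",
    partner_chain = "A", partner_resname = "GLY",
    partner_resseq = 10L * seq_len(n), partner_insert = "",
    descriptor = categories, direction = "fragment_accepts",
    distance = 2.9, leg2 = NA_real_,
    water_mediated = grepl("water", categories),
    bridge_water = ifelse(grepl("water", categories), 999L, NA_integer_),
    stringsAsFactors = FALSE)
  pc <- as.matrix(coords)
  if (ncol(pc) == 3L) colnames(pc) <- c("x", "y", "z")
  inst <- new("FragmentInstance", complexId = id,
              ligand = list(residue_name = "ATP", chain_id = "L",
                            residue_seq = 1L),
              atomMapping = stats::setNames(1:10,
                                            atoms(builtinAdenine())$atom_name),
              cofactorClass = cofactor)
  new("InteractionSite", complexId = id, instance = inst, hbonds = hb,
      partnerCoords = pc, transform = eulerTransform(),
      meta = list(cofactor_class = cofactor))
}
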