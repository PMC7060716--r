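#' @include AllClasses.R
NULL

.WATER_NAMES <- c("HOH", "WAT", "DOD")

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

# Cofactor whitelist: residue name -> cofactor class.  Mirrors the common
# adenine-bearing cofactors and their analogs found as HETATM residues.
.COFACTOR_CLASS <- c(
  ATP = "ATP", ADP = "ATP", AMP = "ATP", ANP = "ATP", ACP = "ATP",
  AGS = "ATP", ADN = "ATP", APC = "ATP",
  NAD = "NAD", NAI = "NAD", NAP = "NAD", NDP = "NAD", NAJ = "NAD",
  FAD = "FAD", FDA = "FAD",
  SAM = "SAM", SAH = "SAM", SFG = "SAM",
  COA = "CoA", ACO = "CoA", COS = "CoA", SCA = "CoA"
)

#' Cofactor class of a ligand residue name
#'
#' @param residueName HETATM residue name (e.g. "ATP", "NAI").
#' @return One of "ATP", "NAD", "FAD", "SAM", "CoA" or "other".
#' @export
cofactorClass <- function(residueName) {
  cl <- .COFACTOR_CLASS[toupper(residueName)]
  unname(ifelse(is.na(cl), "other", cl))
}

.element_from_name <- function(atom_name) {
  # strip digits and primes, first remaining character(s)
  nm <- gsub("[0-9']", "", toupper(atom_name))
  two <- substr(nm, 1L, 2L)
  one <- substr(nm, 1L, 1L)
  ifelse(two %in% c("CL", "BR", "FE", "MG", "ZN", "MN", "NA", "SE"),
         two, one)
}

.categorize <- function(type, residue_name) {
  ifelse(residue_name %in% .WATER_NAMES, "water",
         ifelse(type == "HETATM", "ligand",
                ifelse(residue_name %in% .AA3, "protein", "other")))
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) into a uniform atom model with every
#' atom categorised as protein / ligand / water / other.  A residue is a
#' ligand when it is a HETATM record and not water.  Only the first model
#' of multi-model files is kept; alternate locations are resolved to the
#' highest-occupancy copy (ties go to altloc "A").  Hydrogens are retained
#' when present but never required.
#'
#' @param path PDB file.
#' @param id complex identifier; defaults to the file name without
#'   extension.
#' @param altlocPolicy "occupancy" (default, highest occupancy wins, ties
#'   to altloc A) or "first".
#' @param modelPolicy only "first" is supported.
#' @return A \linkS4class{ComplexStructure}.
#' @export
readComplex <- function(path, id = NULL,
                        altlocPolicy = c("occupancy", "first"),
                        modelPolicy = "first") {
  altlocPolicy <- match.arg(altlocPolicy)
  if (!identical(modelPolicy, "first"))
    stop("only modelPolicy = 'first' is supported")
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      rec <- grep("^(ATOM|HETATM)", lines)
      bad <- NA_integer_
      for (i in rec) {
        flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                  substr(lines[i], 47, 54))
        if (anyNA(suppressWarnings(as.numeric(flds)))) { bad <- i; break }
      }
      stop("PDB parse error in ", path,
           if (!is.na(bad)) paste0(" (line ", bad, ")"),
           ": ", conditionMessage(e), call. = FALSE)
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("zero atoms in ", path)

  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  df <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = as.character(at$elety),
    alt_loc = blank(at$alt),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     .element_from_name(at$elety),
                     toupper(as.character(at$elesy))),
    residue_name = toupper(as.character(at$resid)),
    residue_seq = as.integer(at$resno),
    insertion_code = blank(at$insert),
    chain_id = blank(at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    type = as.character(at$type),
    stringsAsFactors = FALSE)

  # altloc resolution
  if (any(df$alt_loc != "")) {
    key <- paste(df$chain_id, df$residue_seq, df$insertion_code,
                 df$residue_name, df$atom_name, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      if (altlocPolicy == "first") return(idx[1L])
      occ <- df$occupancy[idx]
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        alt <- df$alt_loc[best]
        best <- if ("A" %in% alt) best[alt == "A"][1L] else
          best[order(alt)][1L]
      }
      best
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }

  df$category <- .categorize(df$type, df$residue_name)
  df$is_backbone <- df$category == "protein" &
    df$atom_name %in% c("N", "CA", "C", "O")
  df$type <- NULL
  df$alt_loc <- NULL
  rownames(df) <- NULL

  lig <- unique(df[df$category == "ligand",
                   c("residue_name", "chain_id", "residue_seq")])
  rownames(lig) <- NULL
  if (is.null(id))
    id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  new("ComplexStructure", id = id, atoms = df, ligandInstances = lig,
      modelNumber = 1L)
}

#' Write a complex to a PDB file
#'
#' The writer is the inverse of \code{\link{readComplex}}: a round trip
#' preserves coordinates to the format's 3 decimals, names and numbering.
#'
#' @param cs a \linkS4class{ComplexStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeComplex <- function(cs, path) {
  df <- cs@atoms
  xyz <- as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  if (any(df$x >= 1e4 | df$x <= -1e3 |
          df$y >= 1e4 | df$y <= -1e3 |
          df$z >= 1e4 | df$z <= -1e3))
    stop("coordinates out of PDB fixed-width range")
  type <- ifelse(df$category %in% c("ligand", "water"), "HETATM", "ATOM")
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   eleno = df$serial, elety = df$atom_name,
                   resid = df$residue_name, chain = df$chain_id,
                   resno = df$residue_seq, insert = df$insertion_code,
                   o = df$occupancy, b = rep(0, nrow(df)),
                   elesy = df$element)
  invisible(path)
}

#' Write a PyMOL command script displaying superposed interaction sites
#'
#' Emits a plain-text .pml script that builds the canonical fragment as
#' pseudoatoms and marks every hydrogen-bond partner: protein nitrogen and
#' oxygen partners as spheres, bridging-water oxygens as nonbonded "+"
#' markers.  The script is inert data; this package never executes it.
#'
#' @param sites list of \linkS4class{InteractionSite} (canonical frame).
#' @param path output .pml file.
#' @param frag fragment whose reference coordinates to draw.
#' @return \code{path}, invisibly.
#' @export
writePymolScript <- function(sites, path, frag = builtinAdenine()) {
  fmt <- function(x) sprintf("%.3f", x)
  out <- c("# fragbind interaction-site overlay",
           "# fragment and partner atoms in the canonical fragment frame",
           "bg_color white")
  rc <- frag@referenceCoords
  for (a in rownames(rc)) {
    el <- frag@atoms$element[frag@atoms$atom_name == a]
    out <- c(out, sprintf(
      "pseudoatom frag, name=%s, elem=%s, pos=[%s, %s, %s]",
      a, el, fmt(rc[a, 1L]), fmt(rc[a, 2L]), fmt(rc[a, 3L])))
  }
  out <- c(out, "show nb_spheres, frag", "color grey70, frag")
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    hb <- s@hbonds
    pc <- s@partnerCoords
    obj <- sprintf("site%03d", i)
    if (nrow(hb)) {
      for (j in seq_len(nrow(hb))) {
        el <- if (hb$water_mediated[j]) "O" else
          sub("^.*_", "", hb$descriptor[j])
        out <- c(out, sprintf(
          "pseudoatom %s, name=P%d, elem=%s, pos=[%s, %s, %s]",
          obj, j, toupper(el),
          fmt(pc[j, 1L]), fmt(pc[j, 2L]), fmt(pc[j, 3L])))
      }
      wat <- which(hb$water_mediated)
      dir <- setdiff(seq_len(nrow(hb)), wat)
      if (length(dir))
        out <- c(out,
                 sprintf("show spheres, %s and name %s", obj,
                         paste(sprintf("P%d", dir), collapse = "+")),
                 sprintf("set sphere_scale, 0.3, %s", obj))
      if (length(wat))
        out <- c(out, sprintf(
          "show nonbonded, %s and name %s", obj,
          paste(sprintf("P%d", wat), collapse = "+")),
          sprintf("color red, %s and name %s", obj,
                  paste(sprintf("P%d", wat), collapse = "+")))
    }
  }
  out <- c(out, "zoom")
  writeLines(out, path)
  invisible(path)
}

#' Write a hydrogen-bond table as TSV
#'
#' One row per hydrogen bond: complex id, fragment atom, edge, partner
#' descriptor and residue, distance, water mediation and bridging-water id.
#'
#' @param sites list of \linkS4class{InteractionSite}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeHBondTable <- function(sites, path) {
  rows <- lapply(sites, function(s) {
    hb <- s@hbonds
    if (!nrow(hb)) return(NULL)
    data.frame(complex_id = s@complexId, hb, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(complex_id = character(), fragment_atom = character(),
                      edge = character(), partner_serial = integer(),
                      descriptor = character(), direction = character(),
                      distance = numeric(), water_mediated = logical(),
                      bridge_water = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
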