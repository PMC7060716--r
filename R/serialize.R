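#' @include AllClasses.R interactions.R
NULL

.site_to_list <- function(s) {
  list(complex_id = s@complexId,
       ligand = s@instance@ligand,
       atom_mapping = as.list(s@instance@atomMapping),
       cofactor_class = s@instance@cofactorClass,
       hbonds = s@hbonds,
       partner_coords = unname(apply(s@partnerCoords, 1L, as.numeric,
                                     simplify = FALSE)),
       rotation = unname(apply(s@transform@rotation, 1L, as.numeric,
                               simplify = FALSE)),
       translation = as.numeric(s@transform@translation),
       fit_rmsd = s@transform@fitRmsd,
       meta = s@meta)
}

.site_from_list <- function(l) {
  inst <- new("FragmentInstance", complexId = l$complex_id,
              ligand = list(residue_name = l$ligand$residue_name,
                            chain_id = l$ligand$chain_id,
                            residue_seq = as.integer(l$ligand$residue_seq)),
              atomMapping = stats::setNames(
                as.integer(unlist(l$atom_mapping)), names(l$atom_mapping)),
              cofactorClass = l$cofactor_class)
  tmpl <- .empty_hbonds()
  if (!length(l$hbonds)) hb <- tmpl else {
    rows <- lapply(l$hbonds, function(r) {
      out <- lapply(names(tmpl), function(col) {
        v <- r[[col]]
        if (is.null(v)) v <- NA
        v
      })
      as.data.frame(stats::setNames(out, names(tmpl)),
                    stringsAsFactors = FALSE)
    })
    hb <- do.call(rbind, rows)
    hb$partner_serial <- as.integer(hb$partner_serial)
    hb$partner_resseq <- as.integer(hb$partner_resseq)
    hb$bridge_water <- as.integer(hb$bridge_water)
    hb$water_mediated <- as.logical(hb$water_mediated)
    hb$distance <- as.numeric(hb$distance)
    hb$leg2 <- as.numeric(hb$leg2)
    hb$partner_insert[is.na(hb$partner_insert)] <- ""
  }
  pc <- if (length(l$partner_coords))
    do.call(rbind, lapply(l$partner_coords, as.numeric)) else
      matrix(numeric(), 0L, 3L)
  colnames(pc) <- c("x", "y", "z")
  tr <- new("RigidTransform",
            rotation = do.call(rbind, lapply(l$rotation, as.numeric)),
            translation = as.numeric(l$translation),
            fitRmsd = as.numeric(l$fit_rmsd))
  new("InteractionSite", complexId = l$complex_id, instance = inst,
      hbonds = hb, partnerCoords = pc, transform = tr,
      meta = lapply(l$meta, unlist))
}

#' Serialize interaction sites to JSON
#'
#' Plain-text, byte-stable record format used to pass site records between
#' pipeline commands.
#'
#' @param sites list of \linkS4class{InteractionSite}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeSites <- function(sites, path) {
  payload <- lapply(sites, .site_to_list)
  json <- jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read interaction sites from JSON
#'
#' @param path JSON file written by \code{\link{writeSites}}.
#' @return List of \linkS4class{InteractionSite}.
#' @export
readSites <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, .site_from_list)
}
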