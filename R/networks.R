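#' @include AllClasses.R interactions.R
NULL

#' Stable identifier of an interaction site
#'
#' One node per (complex, fragment instance): complex id plus the host
#' ligand residue.
#'
#' @param site an \linkS4class{InteractionSite}.
#' @return character id.
#' @export
siteId <- function(site) {
  li <- site@instance@ligand
  sprintf("%s|%s_%s_%d", site@complexId, li$residue_name,
          ifelse(li$chain_id == "", "-", li$chain_id), li$residue_seq)
}

# matching category of each hbond partner point: waters are their own
# category, everything else matches by element
.match_category <- function(hb) {
  ifelse(hb$water_mediated, "water", sub("^.*_", "", hb$descriptor))
}

#' Geometric similarity of two interaction sites
#'
#' Greedy mutual-nearest-neighbor matching of the canonical-frame partner
#' points of two sites (both already in the common fragment frame, so no
#' re-superposition happens): candidate pairs are same-category points
#' within \code{matchCutoff}; the globally closest pair is matched first,
#' both points retired, and so on.  The matched fraction uses the larger
#' site as denominator (conservative); the rmsd is over matched pairs.
#'
#' @param a,b \linkS4class{InteractionSite} objects, canonical frame.
#' @param matchCutoff distance below which two partner points can count as
#'   "the same" atom, Angstrom.
#' @param byCategory restrict matching to partners of the same element
#'   category (waters are their own category).
#' @return A \linkS4class{SiteSimilarity}.
#' @export
siteSimilarity <- function(a, b, matchCutoff = 1.0, byCategory = TRUE) {
  na <- nrow(a@hbonds); nb <- nrow(b@hbonds)
  empty <- new("SiteSimilarity",
               matchedPairs = matrix(integer(), ncol = 2L,
                                     dimnames = list(NULL, c("a", "b"))),
               matchedFraction = 0, partnerRmsd = Inf)
  if (na == 0L || nb == 0L) return(empty)
  ca <- .match_category(a@hbonds); cb <- .match_category(b@hbonds)
  pa <- a@partnerCoords; pb <- b@partnerCoords
  cand <- NULL
  for (i in seq_len(na)) {
    d <- sqrt(colSums((t(pb) - pa[i, ])^2))
    ok <- which(d <= matchCutoff & (!byCategory | cb == ca[i]))
    if (length(ok))
      cand <- rbind(cand, cbind(i = i, j = ok, d = d[ok]))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand[, "d"], cand[, "i"], cand[, "j"]), ,
               drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- matrix(integer(), ncol = 2L)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  colnames(pairs) <- c("a", "b")
  frac <- nrow(pairs) / max(na, nb)
  rmsd <- if (nrow(pairs) == 0L) Inf else
    sqrt(mean(rowSums((pa[pairs[, 1L], , drop = FALSE] -
                         pb[pairs[, 2L], , drop = FALSE])^2)))
  new("SiteSimilarity", matchedPairs = pairs, matchedFraction = frac,
      partnerRmsd = rmsd)
}

#' Build the interaction-site similarity network
#'
#' Nodes are interaction sites with at least \code{minHbonds} hydrogen
#' bonds (three are needed to anchor the rigid fragment); an edge connects
#' two sites when at least \code{minFraction} of the partner atoms of the
#' larger site match (same category, within \code{matchCutoff} in the
#' common frame) and the rmsd of the matched partners is below
#' \code{maxRmsd}.  Relaxing either threshold can only add edges.
#'
#' @param sites list of \linkS4class{InteractionSite}.
#' @param minHbonds minimum number of hydrogen bonds for a node.
#' @param minFraction minimum matched fraction for an edge.
#' @param maxRmsd maximum partner rmsd (Angstrom) for an edge.
#' @param matchCutoff see \code{\link{siteSimilarity}}.
#' @param nodeAttrs optional data.frame of extra node attributes with an
#'   \code{id} column matching \code{siteId}.
#' @return A \linkS4class{FragmentNetwork} of kind "site_similarity".
#' @export
buildSiteNetwork <- function(sites, minHbonds = 3L, minFraction = 0.6,
                             maxRmsd = 0.3, matchCutoff = 1.0,
                             nodeAttrs = NULL) {
  keep <- vapply(sites, function(s) nrow(s@hbonds) >= minHbonds,
                 logical(1L))
  sites <- sites[keep]
  ids <- vapply(sites, siteId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate site ids")
  n <- length(sites)
  vert <- data.frame(name = ids,
                     cofactor_class = vapply(sites, function(s) {
                       cc <- s@meta$cofactor_class
                       if (is.null(cc)) "other" else cc
                     }, character(1L)),
                     n_hbonds = vapply(sites, function(s)
                       nrow(s@hbonds), integer(1L)),
                     stringsAsFactors = FALSE)
  if (!is.null(nodeAttrs)) {
    m <- match(vert$name, nodeAttrs$id)
    for (col in setdiff(names(nodeAttrs), "id"))
      vert[[col]] <- nodeAttrs[[col]][m]
  }
  edges <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      sim <- siteSimilarity(sites[[i]], sites[[j]], matchCutoff)
      if (sim@matchedFraction >= minFraction &&
          sim@partnerRmsd < maxRmsd)
        edges <- rbind(edges, data.frame(
          from = ids[i], to = ids[j],
          matched_fraction = sim@matchedFraction,
          partner_rmsd = sim@partnerRmsd, stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        matched_fraction = numeric(),
                        partner_rmsd = numeric())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vert)
  new("FragmentNetwork", graph = g, kind = "site_similarity")
}

#' Connected components of a network
#'
#' Deterministic ordering: components sorted by size (descending), ties by
#' the lexicographically smallest member id; members sorted within each
#' component.
#'
#' @param net a \linkS4class{FragmentNetwork}.
#' @return List with \code{components} (list of character vectors) and
#'   \code{membership} (data.frame id -> component index).
#' @export
connectedComponents <- function(net) {
  g <- net@graph
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1L)),
               vapply(groups, `[`, character(1L), 1L))
  groups <- unname(groups[ord])
  membership <- data.frame(
    id = unlist(groups),
    component = rep(seq_along(groups),
                    vapply(groups, length, integer(1L))),
    stringsAsFactors = FALSE)
  list(components = groups, membership = membership)
}

#' Read theme annotations from TSV
#'
#' Columns: \code{theme_id}, \code{complex_id}, \code{chain_id},
#' \code{start}, \code{end} (inclusive author numbering).  Ranges outside
#' the expected 35-200 residue theme length produce a warning, not an
#' error.
#'
#' @param path TSV file.
#' @return data.frame of annotations.
#' @export
readThemeAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(theme_id = "integer",
                                          complex_id = "character",
                                          chain_id = "character",
                                          start = "integer",
                                          end = "integer"))
  .check_theme_ranges(ann)
  ann
}

.check_theme_ranges <- function(ann) {
  if (!nrow(ann)) return(invisible(ann))
  if (any(ann$start > ann$end)) stop("theme annotation with start > end")
  len <- ann$end - ann$start + 1L
  if (any(len < 35L | len > 200L))
    warning("theme annotation range length outside 35-200 residues")
  invisible(ann)
}

# theme ids participating in one site: a theme participates when at least
# one residue of its range on that chain is a hydrogen-bond partner
# residue of the site
.participating_themes <- function(site, ann) {
  hb <- site@hbonds
  if (!nrow(hb)) return(integer())
  rows <- ann[ann$complex_id == site@complexId, , drop = FALSE]
  if (!nrow(rows)) return(integer())
  hits <- vapply(seq_len(nrow(rows)), function(k) {
    any(hb$partner_chain == rows$chain_id[k] &
          hb$partner_resseq >= rows$start[k] &
          hb$partner_resseq <= rows$end[k])
  }, logical(1L))
  sort(unique(rows$theme_id[hits]))
}

#' Build the theme-sharing network
#'
#' A theme \emph{participates} in a site when at least one residue of its
#' annotated range hydrogen-bonds the fragment there.  Two sites are
#' connected when some theme participates in both -- participation is
#' required on both endpoints, so a theme that is merely present (but not
#' binding) on one side does not create an edge.
#'
#' @param sites list of \linkS4class{InteractionSite}.
#' @param annotations data.frame as from
#'   \code{\link{readThemeAnnotations}}.
#' @return A \linkS4class{FragmentNetwork} of kind "theme_sharing"; each
#'   edge carries the shared theme ids.
#' @export
buildThemeNetwork <- function(sites, annotations) {
  .check_theme_ranges(annotations)
  ids <- vapply(sites, siteId, character(1L))
  known <- vapply(sites, complexId, character(1L))
  unknown <- setdiff(unique(annotations$complex_id), known)
  if (length(unknown)) {
    warning("theme annotations reference unknown complex(es): ",
            paste(unknown, collapse = ", "), " -- skipped")
    annotations <- annotations[annotations$complex_id %in% known, ,
                               drop = FALSE]
  }
  part <- lapply(sites, .participating_themes, ann = annotations)
  vert <- data.frame(name = ids,
                     cofactor_class = vapply(sites, function(s) {
                       cc <- s@meta$cofactor_class
                       if (is.null(cc)) "other" else cc
                     }, character(1L)),
                     themes = vapply(part, paste, character(1L),
                                     collapse = ","),
                     stringsAsFactors = FALSE)
  edges <- NULL
  n <- length(sites)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      shared <- intersect(part[[i]], part[[j]])
      if (length(shared))
        edges <- rbind(edges, data.frame(
          from = ids[i], to = ids[j],
          shared_themes = paste(shared, collapse = ","),
          stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        shared_themes = character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vert)
  new("FragmentNetwork", graph = g, kind = "theme_sharing")
}

#' Consensus binding mode of a cluster of sites
#'
#' An interaction class is the tuple (fragment atom, edge, partner
#' descriptor, water-mediated flag).  Classes present in at least
#' \code{minShare} of the cluster's sites form the consensus; the default
#' 1.0 keeps only interactions shared by every member.  Each consensus
#' class reports the mean canonical partner position and the rms spread
#' about it.
#'
#' @param sitesInCluster list of at least two sites.
#' @param minShare fraction of sites a class must appear in.
#' @return data.frame of consensus interaction classes, ordered by
#'   fragment atom.
#' @export
clusterConsensus <- function(sitesInCluster, minShare = 1.0) {
  if (length(sitesInCluster) == 0L) stop("empty cluster")
  if (length(sitesInCluster) < 2L)
    stop("a cluster needs at least 2 sites")
  nsite <- length(sitesInCluster)
  per_site <- lapply(sitesInCluster, function(s) {
    hb <- s@hbonds
    if (!nrow(hb)) return(NULL)
    cls <- paste(hb$fragment_atom, hb$edge, hb$descriptor,
                 hb$water_mediated, sep = "\r")
    agg <- lapply(split(seq_len(nrow(hb)), cls), function(idx)
      colMeans(s@partnerCoords[idx, , drop = FALSE]))
    agg
  })
  all_classes <- sort(unique(unlist(lapply(per_site, names))))
  rows <- lapply(all_classes, function(cl) {
    pts <- do.call(rbind, lapply(per_site, function(p) p[[cl]]))
    share <- nrow(pts) / nsite
    if (share < minShare) return(NULL)
    ctr <- colMeans(pts)
    spread <- sqrt(mean(rowSums(sweep(pts, 2L, ctr)^2)))
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1L]]
    data.frame(fragment_atom = parts[1L], edge = parts[2L],
               descriptor = parts[3L],
               water_mediated = as.logical(parts[4L]), share = share,
               mean_x = ctr[1L], mean_y = ctr[2L], mean_z = ctr[3L],
               spread = spread, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fragment_atom = character(), edge = character(),
                      descriptor = character(), water_mediated = logical(),
                      share = numeric(), mean_x = numeric(),
                      mean_y = numeric(), mean_z = numeric(),
                      spread = numeric())
  out <- out[order(out$fragment_atom, out$edge, out$descriptor), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold enrichment of fragment ligands among theme-bearing entries
#'
#' \code{fold = P(fragment ligand | theme present) / P(fragment ligand)}
#' over a corpus of structure entries.
#'
#' @param corpus data.frame with columns \code{entry_id},
#'   \code{has_theme}, \code{has_fragment_ligand} (logical).
#' @return An \linkS4class{EnrichmentResult}.
#' @export
themeEnrichment <- function(corpus) {
  stopifnot(nrow(corpus) > 0L,
            all(c("has_theme", "has_fragment_ligand") %in% names(corpus)))
  n <- nrow(corpus)
  n_lig <- sum(corpus$has_fragment_ligand)
  n_theme <- sum(corpus$has_theme)
  if (n_theme == 0L) stop("corpus contains no theme entries")
  n_both <- sum(corpus$has_theme & corpus$has_fragment_ligand)
  bg <- n_lig / n
  tf <- n_both / n_theme
  new("EnrichmentResult", nEntries = as.integer(n),
      nLigand = as.integer(n_lig), nThemeEntries = as.integer(n_theme),
      nThemeWithLigand = as.integer(n_both),
      backgroundFraction = bg, themeFraction = tf,
      fold = if (bg > 0) tf / bg else NA_real_)
}

#' Report large clusters of a network
#'
#' Connected components with at least \code{minSize} nodes, numbered by
#' size rank.
#'
#' @param net a \linkS4class{FragmentNetwork}.
#' @param minSize minimum component size.
#' @return data.frame with \code{cluster}, \code{size}, \code{members}
#'   (comma-separated ids).
#' @export
reportLargeClusters <- function(net, minSize = 10L) {
  cc <- connectedComponents(net)
  sizes <- vapply(cc$components, length, integer(1L))
  keep <- which(sizes >= minSize)
  data.frame(cluster = seq_along(keep), size = sizes[keep],
             members = vapply(cc$components[keep], paste, character(1L),
                              collapse = ","),
             stringsAsFactors = FALSE)
}

#' Export a network as GraphML
#'
#' @param net a \linkS4class{FragmentNetwork}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(net@graph, path, format = "graphml")
  invisible(path)
}

#' Export a network edge list (plus node table) as TSV
#'
#' Writes \code{<path>} with the edges and \code{<path>.nodes.tsv} with
#' the node attributes.
#'
#' @param net a \linkS4class{FragmentNetwork}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  g <- net@graph
  ed <- igraph::as_data_frame(g, what = "edges")
  vt <- igraph::as_data_frame(g, what = "vertices")
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(vt, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
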