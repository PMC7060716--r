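#' @include AllClasses.R interactions.R
NULL

.ASP_MOTIF_RESIDUES <- c("ASP", "GLU", "ASN", "GLN", "SER", "CYS")

.res_ref <- function(chain, resseq, resname) {
  sprintf("%s:%d:%s", chain, resseq, resname)
}

#' Classify the adenine-recognition motif of an interaction site
#'
#' Applies the classic three-residue loop-motif rules on the Watson-Crick
#' edge, in priority order asp > direct > reverse:
#' \itemize{
#'   \item \strong{asp} -- a side-chain O (or S) of Asp/Glu/Asn/Gln/Ser/Cys
#'     accepts from N6 on the Watson-Crick side while a backbone amide N
#'     donates to N1; position II is the side-chain residue, and the
#'     \code{asp_ser_cys} variant is flagged for Ser/Cys.
#'   \item \strong{direct} -- a backbone carbonyl O of residue i accepts
#'     from N6 and a backbone amide N of residue j donates to N1, with
#'     i < j on the same chain and j - i at most \code{window}.
#'   \item \strong{reverse} -- the same two bonds with i > j,
#'     i - j at most \code{window}.
#' }
#' Candidates whose two partners sit on different chains are rejected;
#' anything else is \strong{other}.  Only direct (non-water-mediated)
#' bonds enter the rules.  The classification depends only on the set of
#' hydrogen bonds, not on their order.
#'
#' @param site an \linkS4class{InteractionSite}.
#' @param cs optional; unused for standard sites but kept in the signature
#'   for API symmetry.
#' @param window maximum sequence separation between the carbonyl and
#'   amide residues (default 3, the loop-proximity window).
#' @param priority order in which the rules fire.
#' @return A \linkS4class{MotifCall}.
#' @export
classifyMotif <- function(site, cs = NULL, window = 3L,
                          priority = c("asp", "direct", "reverse")) {
  hb <- site@hbonds
  none <- new("MotifCall", label = "other", positionI = NA_character_,
              positionII = NA_character_, positionIII = NA_character_,
              variants = character())
  if (!nrow(hb)) return(none)
  direct_hb <- hb[!hb$water_mediated, , drop = FALSE]
  if (!nrow(direct_hb)) return(none)

  n6_wc_bb <- direct_hb[direct_hb$fragment_atom == "N6" &
                          direct_hb$edge == "watson_crick" &
                          direct_hb$descriptor == "backbone_O", ,
                        drop = FALSE]
  n6_wc_side <- direct_hb[direct_hb$fragment_atom == "N6" &
                            direct_hb$edge == "watson_crick" &
                            direct_hb$descriptor %in%
                              c("sidechain_O", "sidechain_S") &
                            direct_hb$partner_resname %in%
                              .ASP_MOTIF_RESIDUES, , drop = FALSE]
  n1_bb <- direct_hb[direct_hb$fragment_atom == "N1" &
                       direct_hb$descriptor == "backbone_N", ,
                     drop = FALSE]
  if (!nrow(n1_bb)) return(none)

  best_pair <- function(a, b, constraint) {
    # all same-chain combinations satisfying the constraint; pick the
    # tightest (smallest |i - j|, then lowest residue numbers)
    out <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$partner_chain[i] != b$partner_chain[j]) next
      di <- a$partner_resseq[i]; dj <- b$partner_resseq[j]
      if (!constraint(di, dj)) next
      cand <- c(abs(di - dj), di, dj, i, j)
      if (is.null(out) || cand[1L] < out[1L] ||
          (cand[1L] == out[1L] && cand[2L] < out[2L]))
        out <- cand
    }
    out
  }

  for (rule in priority) {
    if (rule == "asp" && nrow(n6_wc_side)) {
      for (i in order(n6_wc_side$partner_resseq)) {
        same <- n1_bb$partner_chain == n6_wc_side$partner_chain[i]
        if (!any(same)) next
        jj <- which(same)[order(n1_bb$partner_resseq[same])][1L]
        variants <- if (n6_wc_side$partner_resname[i] %in% c("SER", "CYS"))
          "asp_ser_cys" else character()
        return(new("MotifCall", label = "asp",
                   positionI = NA_character_,
                   positionII = .res_ref(n6_wc_side$partner_chain[i],
                                         n6_wc_side$partner_resseq[i],
                                         n6_wc_side$partner_resname[i]),
                   positionIII = .res_ref(n1_bb$partner_chain[jj],
                                          n1_bb$partner_resseq[jj],
                                          n1_bb$partner_resname[jj]),
                   variants = variants))
      }
    }
    if (rule %in% c("direct", "reverse") && nrow(n6_wc_bb)) {
      constraint <- if (rule == "direct") {
        function(i, j) i < j && (j - i) <= window
      } else {
        function(i, j) i > j && (i - j) <= window
      }
      hit <- best_pair(n6_wc_bb, n1_bb, constraint)
      if (!is.null(hit)) {
        i <- hit[4L]; j <- hit[5L]
        return(new("MotifCall", label = rule,
                   positionI = .res_ref(n6_wc_bb$partner_chain[i],
                                        n6_wc_bb$partner_resseq[i],
                                        n6_wc_bb$partner_resname[i]),
                   positionII = NA_character_,
                   positionIII = .res_ref(n1_bb$partner_chain[j],
                                          n1_bb$partner_resseq[j],
                                          n1_bb$partner_resname[j]),
                   variants = character()))
      }
    }
  }
  none
}

.ref_parts <- function(ref) {
  p <- strsplit(ref, ":", fixed = TRUE)[[1L]]
  list(chain = p[1L], resseq = as.integer(p[2L]), resname = p[3L])
}

#' Detect extended motif variants
#'
#' Adds two documented extensions to a motif call:
#' \itemize{
#'   \item \code{reverse_plus_hoogsteen_XV_XVI}: a reverse-motif site where
#'     a backbone carbonyl O of a residue 22-23 positions downstream of the
#'     reverse-motif residues additionally accepts from N6 on the Hoogsteen
#'     side ("position XV/XVI").
#'   \item \code{position_III_hoogsteen}: one residue whose backbone
#'     carbonyl O accepts from N6 on the Hoogsteen edge while its backbone
#'     amide N donates to N7 (the SET-domain pattern, role-complementary
#'     by construction); flagged regardless of the base label.
#' }
#'
#' @param site the interaction site.
#' @param cs optional, unused (API symmetry).
#' @param call the \linkS4class{MotifCall} from \code{\link{classifyMotif}}.
#' @param offsets downstream offsets accepted for the XV/XVI extension.
#' @return The augmented \linkS4class{MotifCall}.
#' @export
detectExtendedVariants <- function(site, cs = NULL, call,
                                   offsets = c(22L, 23L)) {
  hb <- site@hbonds[!site@hbonds$water_mediated, , drop = FALSE]
  variants <- call@variants
  if (nrow(hb)) {
    if (call@label == "reverse") {
      anchors <- c(call@positionI, call@positionIII)
      anchors <- anchors[!is.na(anchors)]
      ext <- hb[hb$fragment_atom == "N6" & hb$edge == "hoogsteen" &
                  hb$descriptor == "backbone_O", , drop = FALSE]
      if (nrow(ext) && length(anchors)) {
        hitsit <- any(vapply(anchors, function(ref) {
          rp <- .ref_parts(ref)
          any(ext$partner_chain == rp$chain &
                (ext$partner_resseq - rp$resseq) %in% offsets)
        }, logical(1L)))
        if (hitsit)
          variants <- union(variants, "reverse_plus_hoogsteen_XV_XVI")
      }
    }
    n6_hg_o <- hb[hb$fragment_atom == "N6" & hb$edge == "hoogsteen" &
                    hb$descriptor == "backbone_O", , drop = FALSE]
    n7_n <- hb[hb$fragment_atom == "N7" & hb$descriptor == "backbone_N", ,
               drop = FALSE]
    if (nrow(n6_hg_o) && nrow(n7_n)) {
      shared <- merge(n6_hg_o[, c("partner_chain", "partner_resseq")],
                      n7_n[, c("partner_chain", "partner_resseq")])
      if (nrow(shared))
        variants <- union(variants, "position_III_hoogsteen")
    }
  }
  new("MotifCall", label = call@label, positionI = call@positionI,
      positionII = call@positionII, positionIII = call@positionIII,
      variants = variants)
}

#' Summarise motif calls per cofactor class
#'
#' Counts (and row percentages) of direct / reverse / asp / other calls
#' per cofactor class, in the style of a motif-occurrence summary table.
#'
#' @param calls data.frame with columns \code{cofactor_class} and
#'   \code{label}, one row per classified site.
#' @return data.frame with one row per cofactor class (plus percentages
#'   and totals); zero rows for empty input.
#' @export
tabulateMotifs <- function(calls) {
  labs <- c("direct", "reverse", "asp", "other")
  if (!nrow(calls)) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(integer()), 4L),
        list(integer()), rep(list(numeric()), 4L)),
      c("cofactor_class", labs, "total", paste0("pct_", labs))))
    return(out)
  }
  stopifnot(all(calls$label %in% labs))
  classes <- sort(unique(calls$cofactor_class))
  rows <- lapply(classes, function(cl) {
    sub <- calls[calls$cofactor_class == cl, , drop = FALSE]
    cnt <- vapply(labs, function(l) sum(sub$label == l), integer(1L))
    tot <- nrow(sub)
    c(list(cofactor_class = cl), as.list(cnt), list(total = tot),
      stats::setNames(as.list(round(100 * cnt / tot, 1L)),
                      paste0("pct_", labs)))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
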