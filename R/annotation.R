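#' Annotate ions as deprotonated metabolites
#'
#' Matches measured ion m/z values against neutral monoisotopic metabolite
#' masses assuming the [M-H]- ionisation: metabolite `m` is a candidate for
#' ion `i` iff `|mz(i) - (mass(m) - 1.00728)| <= tolerance`. Ions without a
#' candidate are flagged unannotated but retained, so that they still enter
#' the differential statistics.
#'
#' @param ionMz numeric ion m/z values; names (if any) become ion ids,
#'   otherwise ids `"ion%04d"` are assigned in order.
#' @param metabolites data.frame with columns `metabolite_id` and `mass`
#'   (neutral monoisotopic, Da), or a named numeric vector of masses.
#' @param tolerance mass tolerance in Da (must be >= 0; 0 keeps only exact
#'   matches).
#' @return data.frame with columns `ion` (id), `ion_mz`, `candidates`
#'   (list column of metabolite ids), `n_candidates` and `annotated`.
#' @examples
#' met <- data.frame(metabolite_id = "glucose", mass = 180.0634)
#' annotateIons(179.0561, met, tolerance = 0.005)
#' @export
annotateIons <- function(ionMz, metabolites, tolerance = 0.005) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.numeric(metabolites))
    metabolites <- data.frame(metabolite_id = names(metabolites),
                              mass = as.numeric(metabolites))
  ids <- names(ionMz)
  if (is.null(ids)) ids <- sprintf("ion%04d", seq_along(ionMz))
  if (nrow(metabolites) == 0L) {
    warning("empty metabolite mass list: all ions unannotated")
    cand <- rep(list(character()), length(ionMz))
  } else {
    expected <- metabolites$mass - PROTON_MASS
    cand <- lapply(ionMz, function(mz)
      metabolites$metabolite_id[abs(mz - expected) <= tolerance])
  }
  out <- data.frame(ion = ids, ion_mz = as.numeric(ionMz))
  out$candidates <- cand
  out$n_candidates <- lengths(cand)
  out$annotated <- out$n_candidates > 0L
  out
}

#' Lump multi-annotated ions into per-pathway entries
#'
#' Builds the counting units for pathway enrichment: an ion annotated to
#' several metabolites of the same pathway collapses to a single entry for
#' that pathway; an ion whose candidates span several pathways contributes
#' one entry per pathway; annotated ions whose candidates belong to no
#' pathway form pathway-less entries (they stay in the enrichment
#' population but can never be pathway hits).
#'
#' @param annotations output of [annotateIons()].
#' @param pathways data.frame with columns `pathway_id`, `metabolite_id`.
#' @return data.frame with columns `entry_id`, `ion`, `ion_mz`,
#'   `pathway_id` (NA for pathway-less entries) and `n_lumped` (number of
#'   member metabolites collapsed into the entry).
#' @export
lumpPathwayEntries <- function(annotations, pathways) {
  ann <- annotations[annotations$annotated, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    cc <- ann$candidates[[i]]
    pw <- unique(pathways$pathway_id[pathways$metabolite_id %in% cc])
    if (length(pw) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        ion = ann$ion[i], ion_mz = ann$ion_mz[i],
        pathway_id = NA_character_, n_lumped = length(cc))
    } else {
      for (p in pw) {
        members <- pathways$metabolite_id[pathways$pathway_id == p]
        rows[[length(rows) + 1L]] <- data.frame(
          ion = ann$ion[i], ion_mz = ann$ion_mz[i], pathway_id = p,
          n_lumped = sum(cc %in% members))
      }
      # candidates outside every pathway are absorbed by the pathway
      # entries of the same ion (the ion is already represented)
    }
  }
  if (!length(rows))
    return(data.frame(entry_id = character(), ion = character(),
                      ion_mz = numeric(), pathway_id = character(),
                      n_lumped = integer()))
  out <- do.call(rbind, rows)
  out$entry_id <- paste(out$ion, ifelse(is.na(out$pathway_id), "nopw",
                                        out$pathway_id), sep = ":")
  out[, c("entry_id", "ion", "ion_mz", "pathway_id", "n_lumped")]
}
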