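#' Region sets
#'
#' A region set fixes the node identity and ordering used by every stage of
#' the analysis: time-series columns, connectivity matrices, graphs and
#' result tables all index regions in region-set order.
#'
#' @param labels Character vector of unique region labels.
#' @param hemisphere Character vector, one of `"left"`, `"right"`,
#'   `"midline"` per region.
#' @param structure Optional character vector naming the anatomical
#'   structure of each region.
#'
#' @return A data frame of class `region_set` with columns `label`,
#'   `hemisphere` and `structure`.
#' @examples
#' region_set(c("A_L", "A_R", "M"), c("left", "right", "midline"))
#' @export
region_set <- function(labels, hemisphere, structure = labels) {
  labels <- as.character(labels)
  hemisphere <- as.character(hemisphere)
  if (anyDuplicated(labels)) {
    stop("region labels must be unique", call. = FALSE)
  }
  if (length(hemisphere) != length(labels)) {
    stop("`hemisphere` must have one entry per label", call. = FALSE)
  }
  bad <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad)) {
    stop("unknown hemisphere value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(label = labels, hemisphere = hemisphere,
                    structure = as.character(structure),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Default mode-like network region set
#'
#' The 25-node rodent DMLN parcellation used throughout the package:
#' bilateral cingulate cortex (areas 1 and 2), orbitofrontal, prelimbic,
#' primary and secondary visual, retrosplenial, hippocampal CA1/CA2/CA3,
#' auditory/temporal association and parietal association cortices, plus
#' the basal forebrain, which is treated as a single midline node.
#'
#' @return A `region_set` with 25 rows.
#' @examples
#' nrow(dmln_regions())
#' @export
dmln_regions <- function() {
  path <- system.file("extdata", "dmln_regions.tsv", package = "ndgraph",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_set(tab$label, tab$hemisphere, tab$structure)
}

#' Generic region set for simulations
#'
#' Builds an anonymous region set (`R01`, `R02`, ...) of arbitrary size,
#' used by the synthetic cohort generator when the requested region count
#' differs from the packaged DMLN set.
#'
#' @param n_regions Number of regions.
#' @return A `region_set` with `n_regions` midline rows.
#' @export
synthetic_regions <- function(n_regions) {
  stopifnot(n_regions >= 1)
  labels <- sprintf("R%02d", seq_len(n_regions))
  region_set(labels, rep("midline", n_regions))
}
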