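#' Curated class counts from a HoloSea plankton deployment
#'
#' Per-class counts of curated in-focus plankton images across 19 classes
#' (cultured and environmental micro-mesoplankton from Bedford Basin plus a
#' noise class), as imaged by a submersible point-source holographic
#' microscope. The class distribution is starkly imbalanced — 13 images for
#' the rarest class (Crustacean) against 1074 for the most abundant
#' (*Prorocentrum micans*) — which is what makes stratified folding and
#' ranked evaluation necessary. Useful as a realistic class-proportion
#' template for dataset-builder tests and examples.
#'
#' @param total Optional total to rescale the counts to (largest-remainder
#'   apportionment, preserving proportions). Default NULL (raw counts).
#' @return Tibble with `class`, `group`, and `n` columns.
#' @examples
#' sum(holosea_taxa_counts()$n) # 3527
#' @export
holosea_taxa_counts <- function(total = NULL) {
  counts <- tibble::tribble(
    ~class, ~group, ~n,
    "Alexandrium tamarense", "Dinoflagellate", 201L,
    "Ceratium fusus", "Dinoflagellate", 56L,
    "Ceratium lineatum", "Dinoflagellate", 44L,
    "Ceratium longpipes", "Dinoflagellate", 378L,
    "Ceratium sp.", "Dinoflagellate", 64L,
    "Chaetoceros socialis", "Diatom", 102L,
    "Chaetoceros straight", "Diatom", 25L,
    "Chaetoceros sp.", "Diatom", 114L,
    "Crustacean", "Animal", 13L,
    "Dictyocha speculum", "Silicoflagellate", 185L,
    "Melosira octagona", "Diatom", 173L,
    "Noise", "Artefact", 150L,
    "Parvicorbicula socialis", "Choanoflagellate", 36L,
    "Prorocentrum micans", "Dinoflagellate", 1074L,
    "Pseudo-nitchzia arctica", "Diatom", 33L,
    "Rhizosoenia setigera", "Diatom", 306L,
    "Rods", "Morphological", 396L,
    "Skeletonema costatum", "Diatom", 157L,
    "Tintinnid", "Ciliate", 20L
  )
  if (!is.null(total)) {
    counts$n <- largest_remainder(total, counts$n / sum(counts$n))
  }
  counts
}
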