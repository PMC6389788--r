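#' Consonant-vowel syllable inventory
#'
#' The 12 monosyllabic consonant-vowel utterances used throughout the
#' package, together with their axes of articulation: place of the
#' consonant (bilabial, alveolar, velar), consonant voicing, and vowel
#' height (/a/ vs /i/).
#'
#' @return data.frame with columns `label`, `place`, `voicing`, `vowel`.
#' @examples
#' syllable_inventory()
#' @export
syllable_inventory <- function() {
  consonants <- data.frame(
    c = c("b", "d", "g", "p", "t", "k"),
    place = rep(c("bilabial", "alveolar", "velar"), 2),
    voicing = rep(c("voiced", "unvoiced"), each = 3),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(c("a", "i"), function(v) {
    data.frame(
      label = sprintf("/%s%s/", consonants$c, v),
      place = consonants$place,
      voicing = consonants$voicing,
      vowel = v,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' All discrimination contrasts
#'
#' The 19 contrasts a template set is built for: the 12 individual
#' syllables, the 3 places of articulation, the 2 voicing classes, and the
#' 2 vowel heights.
#'
#' @return named list; each element is the character vector of syllable
#'   labels belonging to that contrast.
#' @export
contrast_members <- function() {
  syl <- syllable_inventory()
  out <- c(
    stats::setNames(as.list(syl$label), syl$label),
    lapply(stats::setNames(nm = unique(syl$place)),
           function(p) syl$label[syl$place == p]),
    lapply(stats::setNames(nm = unique(syl$voicing)),
           function(v) syl$label[syl$voicing == v]),
    lapply(stats::setNames(nm = c("/a/", "/i/")),
           function(v) syl$label[syl$vowel == sub("/", "", sub("/$", "", v))])
  )
  out
}
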