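#' Normalise miRNA identifiers
#'
#' Canonicalises miRNA IDs so the same mature miRNA matches across the
#' expression matrix, the regulatory network and literature lists:
#' lowercased, the species prefix `hsa-` stripped, and star (minor-arm)
#' markers — however typeset (`*`, the Unicode asterisk operator, or
#' caret-wrapped markup) — reduced to a single trailing `*`. Arm suffixes
#' (`-3p`/`-5p`) are preserved; star and non-star forms remain distinct IDs.
#' The transform is idempotent.
#'
#' @param x Character vector of raw miRNA identifiers.
#' @return Character vector of normalised identifiers.
#' @examples
#' normalize_mirna_id(c("hsa-miR-155", "miR-340*", "let-7g"))
#' @export
normalize_mirna_id <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  if (any(is.na(x) | x == "")) {
    stop("miRNA identifiers must be non-empty", call. = FALSE)
  }
  x <- tolower(x)
  x <- sub("^hsa-", "", x)
  # star markers: ASCII '*', U+2217 asterisk operator, optional caret markup,
  # optional space before the marker ("miR-340 *")
  starred <- grepl("[*∗]", x)
  x <- gsub("[\\^*∗]", "", x)
  x <- trimws(x)
  x[starred] <- paste0(x[starred], "*")
  x
}

#' Normalise gene identifiers
#'
#' Gene symbols are case-folded to upper case and stripped of surrounding
#' whitespace; no alias resolution is attempted.
#'
#' @param x Character vector of raw gene identifiers.
#' @return Character vector of normalised identifiers.
#' @export
normalize_gene_id <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  if (any(is.na(x) | x == "")) {
    stop("gene identifiers must be non-empty", call. = FALSE)
  }
  toupper(x)
}
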