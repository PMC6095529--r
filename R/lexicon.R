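#' Response-coding lexicons
#'
#' A lexicon maps normalized free-text naming responses to canonical
#' category labels. Strings with no mapping are coded into a literal
#' `"OTHER"` bucket that retains the original string, mirroring how
#' open-ended naming data contain responses (e.g. "kinked", "plastic")
#' outside the experiment's category sets. Matching is case-insensitive
#' after whitespace normalization.
#'
#' @param mapping Named character vector: names are free-text strings,
#'   values are canonical category labels.
#' @param design Optional [experiment_design()]; when given, every mapping
#'   target must be one of its material or transformation labels.
#'
#' @return An object of class `lexicon` (a named character vector with
#'   normalized names).
#' @examples
#' lex <- lexicon(c("twist" = "twisted", "Twisted " = "twisted"))
#' lookup_category(lex, c("TWIST", "kinked"))
#' @export
lexicon <- function(mapping, design = NULL) {
  if (length(mapping) == 0 || is.null(names(mapping))) {
    stop("mapping must be a non-empty named character vector", call. = FALSE)
  }
  nm <- normalize_response(names(mapping))
  mapping <- stats::setNames(as.character(mapping), nm)
  mapping <- mapping[!duplicated(names(mapping))]
  if (!is.null(design)) {
    ok <- mapping %in% c(design$materials, design$transformations)
    if (!all(ok)) {
      stop("lexicon targets not in the design's label sets: ",
           paste(unique(mapping[!ok]), collapse = ", "), call. = FALSE)
    }
  }
  structure(mapping, class = "lexicon")
}

#' @rdname lexicon
#' @details `default_lexicon()` covers the canonical labels themselves plus
#'   common English synonyms. It deliberately excludes near-category terms
#'   such as "kinked" or "squashed", which real observers produce and which
#'   should surface as OTHER responses rather than be force-coded.
#' @export
default_lexicon <- function(design = experiment_design("naming")) {
  base <- stats::setNames(
    c(design$materials, design$transformations),
    c(design$materials, design$transformations)
  )
  synonyms <- c(
    "aluminium foil" = "aluminum foil",
    "tin foil"       = "aluminum foil",
    "alu foil"       = "aluminum foil",
    "gold leaf"      = "gold foil",
    "chicken wire"   = "wire",
    "wire mesh"      = "wire",
    "modelling clay" = "putty",
    "plasticine"     = "putty",
    "paperboard"     = "cardboard",
    "carton"         = "cardboard",
    "candle wax"     = "wax",
    "twist"          = "twisted",
    "twisted up"     = "twisted",
    "crumple"        = "crumpled",
    "crumpled up"    = "crumpled",
    "scrunched"      = "crumpled",
    "bend"           = "bent",
    "bent over"      = "bent",
    "fold"           = "folded",
    "folded up"      = "folded"
  )
  synonyms <- synonyms[synonyms %in% c(design$materials,
                                       design$transformations)]
  lexicon(c(base, synonyms), design = design)
}

#' Normalize a free-text response string
#'
#' Lower-cases, trims, and collapses internal whitespace. This is the
#' canonical form used for lexicon lookup.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_response <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

#' @rdname lexicon
#' @param lex A `lexicon`.
#' @param x Character vector of raw response strings.
#' @return `lookup_category()` returns the canonical label for each string,
#'   or `"OTHER"` where the lexicon has no entry.
#' @export
lookup_category <- function(lex, x) {
  stopifnot(inherits(lex, "lexicon"))
  hit <- unname(lex[normalize_response(x)])
  hit[is.na(hit)] <- "OTHER"
  hit
}

#' Read or write a lexicon as a YAML mapping file
#'
#' @param path File path.
#' @param design Optional [experiment_design()] used to validate targets.
#' @return `read_lexicon()` returns a `lexicon`; `write_lexicon()` returns
#'   `path` invisibly.
#' @export
read_lexicon <- function(path, design = NULL) {
  raw <- yaml::read_yaml(path)
  lexicon(unlist(raw), design = design)
}

#' @rdname read_lexicon
#' @param lex A `lexicon` to serialize.
#' @export
write_lexicon <- function(lex, path) {
  yaml::write_yaml(as.list(unclass(lex)), path)
  invisible(path)
}
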