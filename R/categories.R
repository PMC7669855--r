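#' Stimulus category labels
#'
#' The eight stimulus categories used throughout the pipeline: aggressive,
#' neutral and happy dog faces (`AD`, `ND`, `HD`), aggressive, neutral and
#' happy human faces (`AH`, `NH`, `HH`), household objects (`OB`) and
#' phase-scrambled images (`S`).
#'
#' @return character vector of the 8 category codes.
#' @export
#' @examples
#' categories()
categories <- function() {
  c("AD", "ND", "HD", "AH", "NH", "HH", "OB", "S")
}

#' Face categories (the six species x expression cells)
#' @return character vector of the 6 face category codes.
#' @export
face_categories <- function() c("AD", "ND", "HD", "AH", "NH", "HH")

check_categories <- function(x) {
  bad <- setdiff(unique(as.character(x)), categories())
  if (length(bad) > 0) {
    stopf("unknown category label(s): %s", paste(bad, collapse = ", "))
  }
  invisible(as.character(x))
}

#' Decompose category labels into species and expression factors
#'
#' Each face category carries a species (`dog` or `human`) and an expression
#' (`aggressive`, `neutral` or `happy`); objects and scrambled images carry
#' `none` for both.
#'
#' @param x character vector of category codes.
#' @return for `category_species`, factor with levels dog/human/none; for
#'   `category_expression`, factor with levels aggressive/neutral/happy/none.
#' @export
#' @examples
#' category_species(c("AD", "HH", "S"))
category_species <- function(x) {
  check_categories(x)
  out <- rep("none", length(x))
  out[x %in% c("AD", "ND", "HD")] <- "dog"
  out[x %in% c("AH", "NH", "HH")] <- "human"
  factor(out, levels = c("dog", "human", "none"))
}

#' @rdname category_species
#' @export
category_expression <- function(x) {
  check_categories(x)
  out <- rep("none", length(x))
  out[x %in% c("AD", "AH")] <- "aggressive"
  out[x %in% c("ND", "NH")] <- "neutral"
  out[x %in% c("HD", "HH")] <- "happy"
  factor(out, levels = c("aggressive", "neutral", "happy", "none"))
}
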