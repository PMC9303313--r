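#' Nucleobase-modification registry
#'
#' A registry maps short modification codes (e.g. `"C1"`, `"G8"`) to the
#' canonical base letter they replace, an optional chemistry name, and a
#' flag marking novel chemistries. Codes are opaque labels: the registry
#' carries no thermodynamic or structural model, and a modified base is
#' assumed to retain the Watson-Crick pairing of its parent letter (the
#' modified ring positions sit away from the pairing face), so search and
#' complementarity calculations always run on the unmodified letters.
#'
#' The default registry holds the 17 derivatives used in the gapmer
#' hepatotoxicity study: C-series (5-position cytosine analogues, with C1 =
#' 5-hydroxycytosine), T-series (2-position thymine analogues, with T1 =
#' 2-thiothymine) and G-series (7/8-position guanine analogues, with G1 =
#' 8-bromoguanine). G4-G7 are novel chemistries. Codes whose chemistry is
#' not publicly named carry `chemistry_name = NA`.
#'
#' @param extra optional tibble/data.frame with columns `code`,
#'   `base_letter`, and optionally `chemistry_name`, `novel_flag`, appended
#'   to (or overriding) the defaults. `base_letter` must be one of A/C/G/T.
#' @return A tibble of class `mod_registry` with columns `code`,
#'   `base_letter`, `chemistry_name`, `novel_flag`.
#' @examples
#' reg <- mod_registry()
#' reg[reg$code == "C1", ]
#' @export
mod_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    code = c(
      "C1", "C2", "C3", "C4",
      "T1", "T2", "T3", "T4", "T5",
      "G1", "G2", "G3", "G4", "G5", "G6", "G7", "G8"
    ),
    base_letter = c(rep("C", 4), rep("T", 5), rep("G", 8)),
    chemistry_name = c(
      "5-hydroxycytosine", NA, NA, NA,
      "2-thiothymine", NA, NA, NA, NA,
      "8-bromoguanine", NA, NA, NA, NA, NA, NA, NA
    ),
    novel_flag = FALSE
  )
  reg$novel_flag[reg$code %in% c("G4", "G5", "G6", "G7")] <- TRUE
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!all(c("code", "base_letter") %in% names(extra))) {
      abort("`extra` needs at least columns `code` and `base_letter`.",
            class = "gapmertox_registry_error")
    }
    if (!"chemistry_name" %in% names(extra))
      extra$chemistry_name <- NA_character_
    if (!"novel_flag" %in% names(extra)) extra$novel_flag <- FALSE
    extra <- extra[, c("code", "base_letter", "chemistry_name", "novel_flag")]
    reg <- rbind(reg[!reg$code %in% extra$code, ], extra)
  }
  if (anyDuplicated(reg$code)) {
    abort("Modification codes must be unique.",
          class = "gapmertox_registry_error")
  }
  if (!all(reg$base_letter %in% c("A", "C", "G", "T"))) {
    abort("Registry base letters must be one of A/C/G/T.",
          class = "gapmertox_registry_error")
  }
  class(reg) <- c("mod_registry", class(reg))
  reg
}

#' Look up a modification code in a registry
#'
#' @param code a single modification code, e.g. `"C1"`.
#' @param registry a [mod_registry()].
#' @return One-row tibble with the registry entry.
#' @export
registry_lookup <- function(code, registry = mod_registry()) {
  hit <- registry[registry$code == code, ]
  if (nrow(hit) != 1L) {
    abort(paste0("Unknown modification code: ", code),
          class = "gapmertox_registry_error")
  }
  hit
}
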