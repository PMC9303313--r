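#' Construct a gapmer ASO
#'
#' A gapmer antisense oligonucleotide is a short DNA-like strand with
#' high-affinity modified "wings" (LNA by default) flanking a central DNA
#' "gap" that supports RNase H cleavage of bound RNA. The object carries
#' the base sequence, the wing/gap design, the (uniform) backbone
#' chemistry, and a list of nucleobase modifications annotated onto gap
#' positions. Modifications never alter the base sequence itself: every
#' registered derivative retains the Watson-Crick pairing of its parent
#' letter, so complementarity searches always use the plain sequence.
#'
#' Positions are 1-based over the full sequence; with the default 2-10-2
#' design of a 14-mer, the gap spans positions 3-12.
#'
#' @param id text label, e.g. `"TS1"`.
#' @param sequence DNA string (U accepted, normalized to T). Default
#'   designs assume 14-mers but any length consistent with the wing/gap
#'   arithmetic is accepted.
#' @param wing5,wing3 wing lengths (default 2 each).
#' @param gap gap length; default fills the remainder of the sequence.
#' @param backbone `"PS"` (phosphorothioate, default) or `"PO"`.
#' @param wing_chemistry wing sugar chemistry label (default `"LNA"`).
#' @param modifications optional tibble/data.frame with columns `code`,
#'   `position`; expanded against `registry`.
#' @param parent_id optional id of the unmodified parent ASO.
#' @param registry a [mod_registry()].
#' @param validate if `TRUE` (default), abort on any design violation;
#'   set `FALSE` to build an object for [validate_design()] inspection.
#' @return An object of class `gapmer_aso`.
#' @examples
#' ts1 <- gapmer("TS1", "GTTATGCCACCCTA")
#' gap_region(ts1)  # positions 3..12
#' @export
gapmer <- function(id, sequence, wing5 = 2L, gap = NULL, wing3 = 2L,
                   backbone = c("PS", "PO"), wing_chemistry = "LNA",
                   modifications = NULL, parent_id = NA_character_,
                   registry = mod_registry(), validate = TRUE) {
  sequence <- normalize_dna(sequence)
  if (nchar(sequence) == 0L) {
    abort("Gapmer sequence must be non-empty.",
          class = "gapmertox_validation_error")
  }
  backbone <- backbone[1]
  if (is.null(gap)) gap <- nchar(sequence) - wing5 - wing3
  mods <- empty_mods()
  if (!is.null(modifications) && nrow(modifications) > 0L) {
    mods <- do.call(rbind, lapply(seq_len(nrow(modifications)), function(i) {
      entry <- registry_lookup(modifications$code[i], registry)
      tibble::tibble(code = entry$code, base_letter = entry$base_letter,
                     position = as.integer(modifications$position[i]),
                     chemistry_name = entry$chemistry_name,
                     novel_flag = entry$novel_flag)
    }))
  }
  aso <- structure(
    list(id = id, sequence = sequence,
         wing5_len = as.integer(wing5), gap_len = as.integer(gap),
         wing3_len = as.integer(wing3), backbone = backbone,
         wing_chemistry = wing_chemistry, modifications = mods,
         parent_id = parent_id),
    class = "gapmer_aso")
  if (validate) {
    v <- validate_design(aso)
    if (length(v) > 0L) {
      abort(paste0("Invalid gapmer design for '", id, "': ",
                   paste(v, collapse = "; ")),
            class = "gapmertox_validation_error")
    }
  }
  aso
}

empty_mods <- function() {
  tibble::tibble(code = character(), base_letter = character(),
                 position = integer(), chemistry_name = character(),
                 novel_flag = logical())
}

#' Gap-region positions of a gapmer
#' @param aso a `gapmer_aso`.
#' @return integer vector of 1-based positions inside the gap.
#' @export
gap_region <- function(aso) {
  seq.int(aso$wing5_len + 1L, aso$wing5_len + aso$gap_len)
}

#' Check the design invariants of a gapmer ASO
#'
#' Returns violations rather than raising, so malformed candidate designs
#' can be audited in bulk. Checked: wing/gap arithmetic matches the
#' sequence length, gap length is at least 1, the backbone label is known,
#' every modification sits inside the gap, each modification's registry
#' base letter equals the sequence letter at its position, and no position
#' carries two modifications.
#'
#' @param aso a `gapmer_aso` (possibly built with `validate = FALSE`).
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_design <- function(aso) {
  v <- character()
  len <- nchar(aso$sequence)
  if (aso$wing5_len < 0L || aso$wing3_len < 0L)
    v <- c(v, "wing lengths must be >= 0")
  if (aso$gap_len < 1L)
    v <- c(v, "gap length must be >= 1")
  if (aso$wing5_len + aso$gap_len + aso$wing3_len != len)
    v <- c(v, sprintf("wing5 + gap + wing3 = %d but sequence length is %d",
                      aso$wing5_len + aso$gap_len + aso$wing3_len, len))
  if (!aso$backbone %in% c("PS", "PO"))
    v <- c(v, sprintf("unknown backbone '%s'", aso$backbone))
  m <- aso$modifications
  if (nrow(m) > 0L) {
    gapset <- tryCatch(gap_region(aso), error = function(e) integer())
    for (i in seq_len(nrow(m))) {
      pos <- m$position[i]
      if (pos < 1L || pos > len) {
        v <- c(v, sprintf("modification %s at position %d is outside the sequence",
                          m$code[i], pos))
        next
      }
      if (!pos %in% gapset)
        v <- c(v, sprintf("modification %s at position %d lies in a wing, not the gap",
                          m$code[i], pos))
      letter <- substring(aso$sequence, pos, pos)
      if (letter != m$base_letter[i])
        v <- c(v, sprintf("modification %s replaces %s but position %d holds %s",
                          m$code[i], m$base_letter[i], pos, letter))
    }
    if (anyDuplicated(m$position))
      v <- c(v, "duplicate modification positions")
  }
  v
}

#' Annotate a nucleobase modification onto a gapmer
#'
#' The returned ASO keeps the same base sequence (modifications are
#' annotations; base-pairing identity of the letter is retained for
#' off-target searching) and gains a registry-checked modification entry.
#' The id follows the study naming scheme: a single modification gives
#' `{parent}-{code}-{position}`; further modifications concatenate codes in
#' order of application (e.g. `TS1-G1T1C1`).
#'
#' @param aso a `gapmer_aso`.
#' @param code modification code registered in `registry`.
#' @param position 1-based position in the full sequence; must lie in the
#'   gap and hold the code's base letter.
#' @param registry a [mod_registry()].
#' @return A new `gapmer_aso`.
#' @examples
#' ts1 <- gapmer("TS1", "GTTATGCCACCCTA")
#' apply_modification(ts1, "C1", 7)$id  # "TS1-C1-7"
#' @export
apply_modification <- function(aso, code, position,
                               registry = mod_registry()) {
  position <- as.integer(position)
  if (position %in% aso$modifications$position) {
    abort(sprintf("Position %d already carries modification %s.", position,
                  aso$modifications$code[aso$modifications$position == position]),
          class = "gapmertox_validation_error")
  }
  parent <- if (is.na(aso$parent_id)) aso$id else aso$parent_id
  mods <- rbind(aso$modifications[, c("code", "position")],
                tibble::tibble(code = code, position = position))
  new_id <- if (nrow(mods) == 1L) {
    paste0(parent, "-", code, "-", position)
  } else {
    paste0(parent, "-", paste(mods$code, collapse = ""))
  }
  gapmer(new_id, aso$sequence, wing5 = aso$wing5_len, gap = aso$gap_len,
         wing3 = aso$wing3_len, backbone = aso$backbone,
         wing_chemistry = aso$wing_chemistry, modifications = mods,
         parent_id = parent, registry = registry)
}

#' Parse a gapmer from a name, a FASTA-style (id, sequence) pair, or a TSV row
#'
#' Three record conventions are accepted:
#' \itemize{
#'   \item a one-row data frame with columns `id`, `sequence`, `wing5`,
#'     `gap`, `wing3`, `backbone`, `mods` (semicolon-joined `code@pos`),
#'     as written by [format_gapmer()];
#'   \item an id plus an explicit `sequence` (FASTA header convention);
#'   \item a bare study-style name: `"TS1"` resolves against `parents`,
#'     and `"TS1-C1-7"` parses as parent TS1 with modification C1 at
#'     1-based position 7 (which must hold the letter C).
#' }
#'
#' @param x name string or one-row data frame.
#' @param sequence optional explicit sequence for a plain id.
#' @param parents named list of parent `gapmer_aso` objects used to resolve
#'   modified names; defaults to the five TS-ASOs of [ts_asos()].
#' @param wing5,wing3,backbone design defaults for plain sequences.
#' @param registry a [mod_registry()].
#' @return A `gapmer_aso`.
#' @examples
#' parse_gapmer("TS1-C1-7")$modifications
#' @export
parse_gapmer <- function(x, sequence = NULL, parents = ts_asos(),
                         wing5 = 2L, wing3 = 2L, backbone = "PS",
                         registry = mod_registry()) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    mods <- NULL
    mods_str <- if ("mods" %in% names(x)) x$mods else NA_character_
    if (!is.na(mods_str) && nzchar(mods_str)) {
      parts <- strsplit(strsplit(mods_str, ";", fixed = TRUE)[[1]], "@",
                        fixed = TRUE)
      mods <- tibble::tibble(code = vapply(parts, `[`, "", 1L),
                             position = as.integer(vapply(parts, `[`, "", 2L)))
    }
    pid <- if ("parent_id" %in% names(x)) x$parent_id else NA_character_
    return(gapmer(x$id, x$sequence, wing5 = x$wing5, gap = x$gap,
                  wing3 = x$wing3, backbone = x$backbone,
                  modifications = mods, parent_id = pid,
                  registry = registry))
  }
  if (!is.null(sequence)) {
    return(gapmer(x, sequence, wing5 = wing5, wing3 = wing3,
                  backbone = backbone, registry = registry))
  }
  if (x %in% names(parents)) return(parents[[x]])
  m <- regmatches(x, regexec("^(.+)-([A-Z][0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) == 4L) {
    parent <- parse_gapmer(m[2], parents = parents, registry = registry)
    return(apply_modification(parent, m[3], as.integer(m[4]),
                              registry = registry))
  }
  abort(paste0("Cannot parse gapmer name '", x,
               "': not a known parent and not {parent}-{code}-{position}."),
        class = "gapmertox_parse_error")
}

#' Serialize a gapmer to a one-row TSV record
#'
#' Inverse of the data-frame form of [parse_gapmer()].
#'
#' @param aso a `gapmer_aso`.
#' @return One-row tibble with columns `id`, `sequence`, `wing5`, `gap`,
#'   `wing3`, `backbone`, `mods`, `parent_id`.
#' @export
format_gapmer <- function(aso) {
  mods <- ""
  if (nrow(aso$modifications) > 0L) {
    mods <- paste(paste0(aso$modifications$code, "@",
                         aso$modifications$position), collapse = ";")
  }
  tibble::tibble(id = aso$id, sequence = aso$sequence,
                 wing5 = aso$wing5_len, gap = aso$gap_len,
                 wing3 = aso$wing3_len, backbone = aso$backbone,
                 mods = mods, parent_id = aso$parent_id)
}

#' Read / write gapmer TSV files
#'
#' @param path TSV file with the [format_gapmer()] columns.
#' @param registry a [mod_registry()].
#' @return `read_gapmer_tsv`: named list of `gapmer_aso`.
#' @export
read_gapmer_tsv <- function(path, registry = mod_registry()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    parse_gapmer(as.data.frame(tab[i, ]), registry = registry))
  setNames(out, vapply(out, `[[`, "", "id"))
}

#' @rdname read_gapmer_tsv
#' @param asos list of `gapmer_aso` objects.
#' @export
write_gapmer_tsv <- function(asos, path) {
  tab <- do.call(rbind, lapply(asos, format_gapmer))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @export
print.gapmer_aso <- function(x, ...) {
  gap <- gap_region(x)
  cat(sprintf("<gapmer_aso> %s  %s  (%d-%d-%d %s, %s wings; gap %d-%d)\n",
              x$id, x$sequence, x$wing5_len, x$gap_len, x$wing3_len,
              x$backbone, x$wing_chemistry, min(gap), max(gap)))
  if (nrow(x$modifications) > 0L) {
    cat("  modifications:",
        paste(paste0(x$modifications$code, "@", x$modifications$position),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' The five hepatotoxic TS-ASOs from the in vivo screen
#'
#' The screening table: sequence, TGC/TCC motif counts, and serum AST/ALT
#' (U/l) measured 96 h after a 20 mg/kg intravenous dose in mice. These
#' five 14-mers were the ones (out of 149 tested) that raised AST/ALT
#' above 100 U/l.
#'
#' @return A tibble with columns `name`, `sequence`, `tgc`, `tcc`, `ast`,
#'   `alt`.
#' @export
ts_aso_table <- function() {
  tibble::tibble(
    name = paste0("TS", 1:5),
    sequence = c("GTTATGCCACCCTA", "GTCCGCATGCCTAA", "GATATGCCCTACTA",
                 "GTATGCCTCCGTTA", "GCTATGTTAGTCCG"),
    tgc = c(1L, 1L, 1L, 1L, 0L),
    tcc = c(0L, 1L, 0L, 1L, 1L),
    ast = c(9437, 1364, 448, 2164, 287),
    alt = c(15602, 1617, 1061, 600, 291)
  )
}

#' @rdname ts_aso_table
#' @param wing5,wing3 wing design applied to all five (default 2-10-2).
#' @return `ts_asos`: named list of `gapmer_aso` objects.
#' @export
ts_asos <- function(wing5 = 2L, wing3 = 2L) {
  tab <- ts_aso_table()
  out <- lapply(seq_len(nrow(tab)), function(i)
    gapmer(tab$name[i], tab$sequence[i], wing5 = wing5, wing3 = wing3))
  setNames(out, tab$name)
}
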