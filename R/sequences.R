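#' Construct a validated nucleic-acid sequence
#'
#' Normalizes a raw character string into a canonical DNA or RNA sequence.
#' Input is case-insensitive; any character outside the canonical alphabet
#' (`A`, `C`, `G`, `T` for DNA; `A`, `C`, `G`, `U` for RNA) is replaced by the
#' neutral placeholder `N` and counted in `n_ambiguous`. Placeholders score 0
#' in the propensity engine and terminate G/C runs, so they can never inflate
#' a quadruplex score.
#'
#' With `alphabet = "auto"` the alphabet is inferred from the presence of `U`
#' versus `T`; a sequence containing both is rejected. When an alphabet is
#' forced, `T`/`U` are interconverted to match it (a convenience for catalogs
#' that list RNA aptamers with `T`s).
#'
#' @param residues single character string of residues.
#' @param id free-text identifier.
#' @param alphabet `"auto"` (default), `"DNA"`, or `"RNA"`.
#' @return An object of class `nucleic_sequence`: a list with elements `id`,
#'   `residues` (normalized, upper-case), `alphabet`, and `n_ambiguous`.
#' @examples
#' nucleic_sequence("GGTTGGTGTGGTTGG", id = "TBA")
#' nucleic_sequence("ggau")            # auto-detected RNA
#' nucleic_sequence("GGNNGG")$n_ambiguous
#' @export
nucleic_sequence <- function(residues, id = "seq", alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a single character string")
  up <- toupper(residues)
  if (!nzchar(up))
    stop("empty sequence (id: ", id, ")")
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  canonical <- chars %in% c("A", "C", "G", "T", "U")
  n_ambiguous <- sum(!canonical)
  chars[!canonical] <- "N"
  has_t <- any(chars == "T")
  has_u <- any(chars == "U")
  if (alphabet == "auto") {
    if (has_t && has_u)
      stop("record '", id, "' mixes T and U; set the alphabet explicitly")
    alphabet <- if (has_u) "RNA" else "DNA"
  } else if (alphabet == "DNA" && has_u) {
    chars[chars == "U"] <- "T"
  } else if (alphabet == "RNA" && has_t) {
    chars[chars == "T"] <- "U"
  }
  structure(
    list(id = as.character(id),
         residues = paste(chars, collapse = ""),
         alphabet = alphabet,
         n_ambiguous = as.integer(n_ambiguous)),
    class = "nucleic_sequence"
  )
}

#' @export
print.nucleic_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nucleic_sequence> %s [%s, %d nt%s]\n  %s\n",
              x$id, x$alphabet, n,
              if (x$n_ambiguous > 0) sprintf(", %d ambiguous", x$n_ambiguous) else "",
              shown))
  invisible(x)
}

#' @export
as.character.nucleic_sequence <- function(x, ...) x$residues

#' @export
length.nucleic_sequence <- function(x) nchar(x$residues)

#' Reverse complement of a DNA sequence
#'
#' Defined for DNA only: the propensity score of an RNA aptamer refers to the
#' molecule itself, so no complementary strand is ever scored for RNA.
#' `N` placeholders complement to `N`.
#'
#' @param x a `nucleic_sequence` (DNA).
#' @return A `nucleic_sequence` with the reverse-complemented residues.
#' @export
reverse_complement <- function(x) {
  x <- as_nucleic(x)
  if (x$alphabet != "DNA")
    stop("reverse_complement is defined for DNA sequences only")
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(x$residues, "", fixed = TRUE)[[1L]]),
                                       collapse = ""))
  out <- x
  out$residues <- rc
  out
}

#' Reverse a sequence (5'->3' order inverted, no complementation)
#'
#' @param x a `nucleic_sequence`.
#' @return A `nucleic_sequence` with residues in reverse order.
#' @export
reverse_sequence <- function(x) {
  x <- as_nucleic(x)
  out <- x
  out$residues <- paste(rev(strsplit(x$residues, "", fixed = TRUE)[[1L]]), collapse = "")
  out
}

#' Construct an aptamer record (sequence plus catalog metadata)
#'
#' @param sequence a `nucleic_sequence`, or a bare string passed on to
#'   [nucleic_sequence()].
#' @param target free-text target annotation (optional).
#' @param reference free-text literature reference (optional).
#' @param id identifier used when `sequence` is a bare string.
#' @param alphabet alphabet used when `sequence` is a bare string.
#' @return An object of class `aptamer_record` with elements `sequence`,
#'   `target`, `reference`, and `length_nt` (always the actual residue count).
#' @export
aptamer_record <- function(sequence, target = NA_character_, reference = NA_character_,
                           id = "seq", alphabet = "auto") {
  if (!inherits(sequence, "nucleic_sequence"))
    sequence <- nucleic_sequence(sequence, id = id, alphabet = alphabet)
  structure(
    list(sequence = sequence,
         target = as.character(target),
         reference = as.character(reference),
         length_nt = nchar(sequence$residues)),
    class = "aptamer_record"
  )
}

#' @export
print.aptamer_record <- function(x, ...) {
  cat(sprintf("<aptamer_record> %s [%s, %d nt]%s\n",
              x$sequence$id, x$sequence$alphabet, x$length_nt,
              if (!is.na(x$target)) paste0(" target: ", x$target) else ""))
  invisible(x)
}

# Coerce one object to nucleic_sequence.
as_nucleic <- function(x, alphabet = "auto") {
  if (inherits(x, "nucleic_sequence")) return(x)
  if (inherits(x, "aptamer_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(nucleic_sequence(x, alphabet = alphabet))
  stop("cannot interpret object of class '", class(x)[1L], "' as a nucleic sequence")
}

# Coerce a library (list of records/sequences, or character vector) to a
# list of nucleic_sequence, preserving order.
as_nucleic_list <- function(x, alphabet = "auto") {
  if (inherits(x, c("nucleic_sequence", "aptamer_record")))
    return(list(as_nucleic(x)))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(mapply(function(s, id) nucleic_sequence(s, id = id, alphabet = alphabet),
                  x, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  if (is.list(x)) return(lapply(x, as_nucleic))
  stop("cannot interpret input as a sequence collection")
}
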