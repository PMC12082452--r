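#' Read sequences from a FASTA file
#'
#' Records are normalized through [nucleic_sequence()]: case-folded, non-ACGT/U
#' characters replaced by `N` (counted per record), and the alphabet inferred
#' from `U` versus `T` when `alphabet = "auto"`. A record containing both `U`
#' and `T` is an error naming the record.
#'
#' @param path path to a FASTA file (wrapped or unwrapped, multi-record).
#' @param alphabet `"auto"`, `"DNA"`, or `"RNA"`, applied to every record.
#' @return A list of `nucleic_sequence`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  res <- as.character(set)
  if (any(!nzchar(res)))
    stop("empty sequence for record '", ids[which(!nzchar(res))[1L]], "' in ", path)
  mapply(function(s, id) nucleic_sequence(s, id = id, alphabet = alphabet),
         res, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x a sequence collection (list of `nucleic_sequence` or
#'   `aptamer_record`, or a named character vector).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as_nucleic_list(x)
  chr <- vapply(seqs, function(s) s$residues, "")
  names(chr) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(chr), path, width = width)
  invisible(path)
}

#' Read an aptamer catalog from delimited text
#'
#' Mirrors the tabular structure of published aptamer-database extracts:
#' one row per aptamer with an identifier, a sequence, and optional type,
#' target, reference, and length columns. The delimiter is inferred from the
#' file extension (`.csv` is comma, anything else tab) unless `sep` is given.
#'
#' Duplicate identifiers are kept but disambiguated with `_2`, `_3`, ...
#' suffixes (with a warning). If a length column is mapped and disagrees with
#' the residue count, the computed count wins (with a warning).
#'
#' @param path path to the delimited file.
#' @param column_map named character vector mapping roles to column names.
#'   Recognized roles: `id`, `sequence` (required), `alphabet`, `target`,
#'   `reference`, `length` (optional).
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @param alphabet default alphabet for rows when no alphabet column is mapped.
#' @return A list of `aptamer_record`, in file order.
#' @export
read_catalog <- function(path,
                         column_map = c(id = "id", sequence = "sequence"),
                         sep = NULL,
                         alphabet = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty catalog file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("catalog has no data rows: ", path)
  for (role in c("id", "sequence")) {
    if (!role %in% names(column_map))
      stop("column_map must map the '", role, "' role")
  }
  mapped <- column_map[column_map %in% names(tab)]
  missing <- setdiff(column_map, names(tab))
  if (length(missing))
    stop("mapped column(s) not in catalog: ", paste(missing, collapse = ", "))

  ids <- as.character(tab[[column_map[["id"]]]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate identifier(s) disambiguated with suffixes: ",
            paste(dup, collapse = ", "))
    for (d in dup) {
      hit <- which(ids == d)
      ids[hit[-1L]] <- paste0(d, "_", seq_along(hit[-1L]) + 1L)
    }
  }
  getcol <- function(role, default) {
    if (role %in% names(column_map)) tab[[column_map[[role]]]] else default
  }
  alpha_col <- getcol("alphabet", rep(alphabet, nrow(tab)))
  target <- getcol("target", rep(NA_character_, nrow(tab)))
  refs <- getcol("reference", rep(NA_character_, nrow(tab)))
  decl_len <- getcol("length", rep(NA_integer_, nrow(tab)))

  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    a <- as.character(alpha_col[i])
    if (is.na(a) || !a %in% c("DNA", "RNA")) a <- "auto"
    rec <- aptamer_record(as.character(tab[[column_map[["sequence"]]]][i]),
                          target = target[i], reference = refs[i],
                          id = ids[i], alphabet = a)
    if (!is.na(decl_len[i]) && as.integer(decl_len[i]) != rec$length_nt)
      warning("record '", ids[i], "': declared length ", decl_len[i],
              " != residue count ", rec$length_nt, "; using the residue count")
    records[[i]] <- rec
  }
  records
}

#' Write PQS regions in BED-like format
#'
#' Six tab-separated columns: sequence id, start, end (0-based half-open),
#' region subsequence, mean score (2 decimals), and sign (`+` G-rich,
#' `-` C-rich). Rows are sorted by (id, start); a header comment line is
#' always written, so an empty region set yields a header-only file.
#'
#' @param regions a data frame as returned by [find_pqs()] (rows from several
#'   sequences may be concatenated with `rbind`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#seqid\tstart\tend\tsequence\tscore\tsign", con)
  if (!is.null(regions) && nrow(regions)) {
    regions <- regions[order(regions$seqid, regions$start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.2f\t%s",
                       regions$seqid, regions$start, regions$end,
                       regions$sequence, regions$score, regions$sign),
               con)
  }
  invisible(path)
}
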