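# Sequence input/output: FASTA, SwissProt flat files, prediction writers.

#' Construct a sequence record collection
#'
#' A record collection is a plain `data.frame` with character columns `id`,
#' `description`, `organism` and `residues`. Residues are uppercase letters
#' over the 20 standard amino acids plus the ambiguity letters
#' B, J, O, U, X, Z. Most functions in the package accept either such a
#' data frame or a (optionally named) character vector of sequences.
#'
#' @param residues character vector of residue strings.
#' @param id record identifiers; defaults to `seq1`, `seq2`, ...
#' @param description free-text descriptions.
#' @param organism organism names (may be empty strings).
#' @return A `data.frame` with columns `id`, `description`, `organism`,
#'   `residues`.
#' @examples
#' sequence_records(c(a = "QNQN", b = "MKV"))
#' @export
sequence_records <- function(residues, id = NULL, description = "",
                             organism = "") {
  if (is.null(id)) {
    id <- if (!is.null(names(residues))) names(residues)
          else paste0("seq", seq_along(residues))
  }
  if (length(residues) == 0) {
    return(data.frame(id = character(), description = character(),
                      organism = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(residues)),
             organism = rep_len(as.character(organism), length(residues)),
             residues = toupper(as.character(residues)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Coerce an object to a record collection
#' @noRd
as_records <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "residues") %in% names(x)))
      stop_data("record data frame must have columns 'id' and 'residues'")
    if (is.null(x$description)) x$description <- ""
    if (is.null(x$organism)) x$organism <- ""
    return(x[, c("id", "description", "organism", "residues")])
  }
  if (is.character(x)) return(sequence_records(x))
  if (inherits(x, "XStringSet")) {
    return(sequence_records(as.character(x)))
  }
  stop_data("cannot interpret object of class '", class(x)[1],
            "' as sequence records")
}

#' Validate residue strings and flag duplicate ids
#' @noRd
validate_records <- function(records, source = "input") {
  bad <- !grepl(paste0("^[", paste(SEQUENCE_ALPHABET, collapse = ""), "]*$"),
                records$residues)
  if (any(bad)) {
    i <- which(bad)[1]
    chars <- strsplit(records$residues[i], "")[[1]]
    pos <- which(!chars %in% SEQUENCE_ALPHABET)[1]
    stop_data("illegal residue character '", chars[pos], "' at position ",
              pos, " in record '", records$id[i], "' (", source, ")")
  }
  if (any(nchar(records$residues) == 0)) {
    i <- which(nchar(records$residues) == 0)[1]
    stop_data("record '", records$id[i], "' has zero residues (", source, ")")
  }
  if (anyDuplicated(records$id)) {
    dups <- unique(records$id[duplicated(records$id)])
    warning("duplicate record ids (kept, suffixed for uniqueness): ",
            paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ..." else "", call. = FALSE)
    records$id <- make.unique(records$id, sep = "_dup")
  }
  records
}

#' Read protein sequences from a FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Record ids are the first
#' whitespace-delimited token of the header; the remainder of the header is
#' kept as the description. Sequences are uppercased and the gap characters
#' `-`, `.` and `*` are stripped with a warning. Illegal residue characters
#' and empty records are errors; duplicated ids are kept but suffixed, with
#' a warning.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return A record collection (see [sequence_records()]).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "QNQN"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0) {
    warning("no FASTA records read from '", path, "'", call. = FALSE)
    return(sequence_records(character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  n_gaps <- sum(nchar(seqs)) - sum(nchar(gsub("[-.*]", "", seqs)))
  if (n_gaps > 0) {
    warning("stripped ", n_gaps, " gap character(s) ('-', '.', '*') from '",
            path, "'", call. = FALSE)
    seqs <- gsub("[-.*]", "", seqs)
  }
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    stop_data("FASTA record with zero residues: '",
              headers[which(empty)[1]], "'")
  }
  validate_records(sequence_records(seqs, id = ids, description = desc),
                   source = path)
}

#' Write a record collection to FASTA
#'
#' @param records a record collection or named character vector.
#' @param path output file path (plain text; `.gz` writes compressed).
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  records <- as_records(records)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- paste0(">", records$id[i],
                     if (nzchar(records$description[i]))
                       paste0(" ", records$description[i]) else "")
    writeLines(header, con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read protein sequences from a SwissProt/UniProt flat file
#'
#' Parses the classic flat-file dialect: entries with `ID`, `OS` and `SQ`
#' line blocks terminated by `//`. The id is the first token of the `ID`
#' line, the organism is the concatenation of the `OS` lines (trailing
#' period stripped), and the residues come from the sequence block with
#' whitespace and digits removed. Entries without a sequence block are
#' skipped with a warning; a truncated final entry (no terminating `//`)
#' is an error.
#'
#' @param path path to a flat file (optionally `.gz`).
#' @return A record collection (see [sequence_records()]).
#' @export
read_uniprot_flatfile <- function(path) {
  con <- gzfile(path)  # reads plain files transparently as well
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0) {
    warning("no entries read from '", path, "'", call. = FALSE)
    return(sequence_records(character()))
  }
  term <- grep("^//", lines)
  if (length(term) == 0 || max(term) < length(lines)) {
    tail_lines <- if (length(term) == 0) lines else
      lines[(max(term) + 1):length(lines)]
    if (any(nzchar(trimws(tail_lines))))
      stop_data("truncated final entry (no terminating '//') in '", path, "'")
  }
  starts <- c(1, utils::head(term, -1) + 1)
  ids <- desc <- org <- seqs <- character(0)
  skipped <- 0L
  for (k in seq_along(term)) {
    entry <- lines[starts[k]:(term[k] - 1)]
    id_line <- grep("^ID\\s", entry, value = TRUE)
    id <- if (length(id_line)) strsplit(trimws(sub("^ID\\s+", "", id_line[1])),
                                        "\\s+")[[1]][1] else NA_character_
    os_lines <- sub("^OS\\s+", "", grep("^OS\\s", entry, value = TRUE))
    organism <- sub("\\.$", "", paste(os_lines, collapse = " "))
    de_lines <- sub("^DE\\s+", "", grep("^DE\\s", entry, value = TRUE))
    sq_at <- grep("^SQ\\s", entry)
    if (length(sq_at) == 0 || sq_at[1] == length(entry)) {
      skipped <- skipped + 1L
      next
    }
    seq_block <- entry[(sq_at[1] + 1):length(entry)]
    residues <- toupper(gsub("[0-9[:space:]]", "",
                             paste(seq_block, collapse = "")))
    ids <- c(ids, if (is.na(id)) paste0("entry", k) else id)
    desc <- c(desc, paste(de_lines, collapse = " "))
    org <- c(org, organism)
    seqs <- c(seqs, residues)
  }
  if (skipped > 0)
    warning(skipped, " entr(y/ies) without an SQ block skipped in '", path,
            "'", call. = FALSE)
  if (length(seqs) == 0) {
    warning("no sequence entries in '", path, "'", call. = FALSE)
    return(sequence_records(character()))
  }
  validate_records(sequence_records(seqs, id = ids, description = desc,
                                    organism = org), source = path)
}

#' Check that a data frame looks like a prediction table
#' @noRd
as_predictions <- function(pred) {
  needed <- c("protein_id", "start", "score_bits", "window_sequence")
  if (!is.data.frame(pred) || !all(needed %in% names(pred)))
    stop_data("predictions must be a data frame with columns ",
              paste(needed, collapse = ", "))
  if (is.null(pred$organism)) pred$organism <- ""
  pred
}

#' Write predictions in the per-taxon text dialect
#'
#' For each organism an organism line `>organism: count` is written,
#' followed by one line per prediction:
#' `protein_id<TAB>start;score|window_sequence`, with the score printed to a
#' fixed number of decimals. Organisms appear in order of first appearance;
#' predictions keep their input order within an organism. Predictions with
#' an empty organism are grouped under `fallback_organism`.
#'
#' @param pred a prediction data frame as produced by [scan_proteome()]
#'   (columns `organism`, `protein_id`, `start`, `score_bits`,
#'   `window_sequence`).
#' @param path output file path or connection.
#' @param digits number of decimals for the printed score.
#' @param fallback_organism group name for predictions lacking an organism.
#' @return `path`, invisibly.
#' @export
write_predictions_paper_format <- function(pred, path, digits = 2,
                                           fallback_organism = "unknown") {
  pred <- as_predictions(pred)
  out <- character(0)
  if (nrow(pred) > 0) {
    orgs <- ifelse(is.na(pred$organism) | pred$organism == "",
                   fallback_organism, pred$organism)
    for (o in unique(orgs)) {
      rows <- which(orgs == o)
      out <- c(out, paste0(">", o, ": ", length(rows)),
               paste0(pred$protein_id[rows], "\t", pred$start[rows], ";",
                      sprintf(paste0("%.", digits, "f"),
                              pred$score_bits[rows]),
                      "|", pred$window_sequence[rows]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write predictions as tab-separated values
#'
#' One header row plus one row per prediction with columns `organism`,
#' `protein_id`, `start`, `end`, `score_bits`, `compositional_bits`,
#' `proline_correction_bits`, `window_sequence`. Coordinates are 1-based
#' and inclusive.
#'
#' @inheritParams write_predictions_paper_format
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(pred, path) {
  pred <- as_predictions(pred)
  cols <- c("organism", "protein_id", "start", "end", "score_bits",
            "compositional_bits", "proline_correction_bits",
            "window_sequence")
  for (cc in cols) if (is.null(pred[[cc]])) pred[[cc]] <- NA
  utils::write.table(pred[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
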