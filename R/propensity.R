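# Amino-acid composition counting and log2-odds propensity tables.

#' Count amino-acid composition of a set of sequences
#'
#' Counts are pooled over all residues of all records (no per-sequence
#' weighting). Ambiguity letters (B, J, O, U, X, Z) are excluded from the
#' composition and only tallied in `n_skipped_residues`.
#'
#' @param records a record collection, named character vector of sequences,
#'   or `AAStringSet`.
#' @return An object of class `prd_composition`: a list with `counts`
#'   (named integer vector over the 20 standard amino acids), `total`,
#'   `n_sequences` and `n_skipped_residues`.
#' @examples
#' count_composition(c("QN", "NQ"))
#' @export
count_composition <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0) stop_data("no sequences to count")
  chars <- strsplit(paste(records$residues, collapse = ""), "")[[1]]
  unknown <- setdiff(unique(chars), SEQUENCE_ALPHABET)
  if (length(unknown) > 0)
    stop_data("illegal residue character(s): ",
              paste(unknown, collapse = ", "))
  tab <- table(factor(chars, levels = AMINO_ACIDS))
  counts <- as.integer(tab)
  names(counts) <- AMINO_ACIDS
  total <- sum(counts)
  if (total == 0) stop_data("sequences contain no standard residues")
  structure(list(counts = counts,
                 total = total,
                 n_sequences = nrow(records),
                 n_skipped_residues = length(chars) - total),
            class = "prd_composition")
}

#' @export
print.prd_composition <- function(x, ...) {
  cat("Amino-acid composition:", x$total, "residues in", x$n_sequences,
      "sequence(s)")
  if (x$n_skipped_residues > 0)
    cat(" (", x$n_skipped_residues, " ambiguity letters skipped)", sep = "")
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Estimate amino-acid frequencies from composition counts
#'
#' Applies additive smoothing: `f_i = (count_i + pseudocount) /
#' (total + 20 * pseudocount)`. The default pseudocount of 0.5 (Jeffreys)
#' keeps rare residues at finite log-odds; `pseudocount = 0` gives the raw
#' maximum-likelihood frequencies.
#'
#' @param counts a `prd_composition` object (or named count vector over the
#'   20 standard amino acids).
#' @param pseudocount non-negative smoothing constant added to each count.
#' @return A named probability vector over the 20 amino acids (sums to 1).
#' @examples
#' estimate_frequencies(count_composition(c("QQQ", "N")), pseudocount = 0)
#' @export
estimate_frequencies <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "prd_composition")) counts <- counts$counts
  counts <- counts[AMINO_ACIDS]
  if (anyNA(counts)) stop_data("counts must cover the 20 standard amino acids")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      is.na(pseudocount) || pseudocount < 0)
    stop_data("pseudocount must be a single non-negative number")
  total <- sum(counts)
  if (total <= 0) stop_data("total count must be positive")
  f <- (counts + pseudocount) / (total + 20 * pseudocount)
  names(f) <- AMINO_ACIDS
  f
}

#' Build a log2-odds propensity table
#'
#' Turns a class frequency vector `f` and a background frequency vector `p`
#' into statistical potentials: `odds_i = f_i / p_i` and
#' `lor_i = log2(odds_i)` in bits. A zero `f_i` yields a `-Inf` log-odds
#' sentinel, permitted only when the table was estimated without smoothing
#' (flagged in the metadata).
#'
#' @param f named frequency vector over the 20 standard amino acids
#'   (training-class composition; sums to 1).
#' @param p background frequency vector (strictly positive; sums to 1).
#' @param pseudocount the pseudocount used to estimate `f` (metadata only).
#' @param source short label describing the provenance of the table.
#' @return An object of class `prd_propensity`: a data frame with columns
#'   `residue`, `f`, `p`, `odds`, `lor` and a `metadata` attribute.
#' @examples
#' p <- setNames(rep(0.05, 20), prdscan:::AMINO_ACIDS)
#' build_propensity_table(p, p)  # identical vectors: all lor = 0
#' @export
build_propensity_table <- function(f, p, pseudocount = NA_real_,
                                   source = "user") {
  if (length(f) != 20 || length(p) != 20)
    stop_data("frequency vectors must have length 20")
  if (!is.null(names(f))) f <- f[AMINO_ACIDS]
  if (!is.null(names(p))) p <- p[AMINO_ACIDS]
  if (anyNA(f) || anyNA(p)) stop_data("frequency vectors contain NA")
  if (any(p <= 0)) stop_data("background frequencies must be > 0")
  if (abs(sum(f) - 1) > 1e-6 || abs(sum(p) - 1) > 1e-6)
    stop_data("frequency vectors must sum to 1 (within 1e-6)")
  if (any(f == 0) && !is.na(pseudocount) && pseudocount > 0)
    stop_data("zero class frequency despite nonzero pseudocount; ",
              "-Inf potentials require pseudocount = 0")
  # exact renormalisation so that the algebraic identity sum(odds * p) = 1
  # holds to the asserted 1e-9 regardless of how f/p were accumulated
  f <- f / sum(f)
  p <- p / sum(p)
  odds <- f / p
  tab <- data.frame(residue = AMINO_ACIDS, f = unname(f), p = unname(p),
                    odds = unname(odds), lor = unname(log2(odds)),
                    stringsAsFactors = FALSE)
  meta <- list(pseudocount = pseudocount, source = source,
               published = FALSE,
               has_zero_frequencies = any(f == 0))
  new_propensity_table(tab, meta)
}

#' Constructor asserting the PropensityTable invariants
#' @noRd
new_propensity_table <- function(tab, meta) {
  stopifnot(identical(tab$residue, AMINO_ACIDS))
  if (abs(sum(tab$f) - 1) > 1e-9 || abs(sum(tab$p) - 1) > 1e-9)
    stop_data("propensity table frequencies do not sum to 1")
  if (!isTRUE(meta$published) &&
      abs(sum(tab$odds * tab$p) - 1) > 1e-9)
    stop_data("propensity table violates sum(odds * p) = 1")
  attr(tab, "metadata") <- meta
  class(tab) <- c("prd_propensity", "data.frame")
  tab
}

#' @export
print.prd_propensity <- function(x, digits = 3, ...) {
  meta <- attr(x, "metadata")
  cat("Amino-acid propensity table (bits): ", meta$source, "\n", sep = "")
  df <- as.data.frame(x)
  df$f <- round(df$f, 4); df$p <- round(df$p, 4)
  df$odds <- round(df$odds, digits); df$lor <- round(df$lor, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Background amino-acid frequencies of the protein universe
#'
#' The shipped background table is the average amino-acid composition of
#' the Swiss-Prot knowledgebase (release statistics of the early-2010s
#' era), normalised to sum to 1.
#'
#' @return Named probability vector over the 20 standard amino acids.
#' @export
background_frequencies <- function() {
  bg <- utils::read.delim(prdscan_extdata("background_swissprot.tsv"))
  p <- bg$percent / sum(bg$percent)
  names(p) <- bg$residue
  p[AMINO_ACIDS]
}

#' The published prion-domain propensity table
#'
#' Returns the shipped table of per-residue odds ratios for prion-forming
#' domains (or, for comparison only, the mutagenesis-library propensities of
#' Toombs and colleagues via `set = "library1"`). Log-odds are recomputed as
#' `log2(odds)` from the printed odds ratios; residues whose recomputed
#' value differs from the printed log-odds by more than 0.002 bits are
#' recorded in the metadata (the printed log-odds derive from unrounded
#' odds). Class frequencies `f` are reconstructed as `odds * p` against the
#' shipped background and renormalised; the renormalisation factor (~1.003)
#' is kept in the metadata.
#'
#' @param set which propensity column set to load.
#' @return A `prd_propensity` table (see [build_propensity_table()]).
#' @examples
#' tab <- builtin_propensity_table()
#' tab[tab$residue == "N", ]
#' @export
builtin_propensity_table <- function(set = c("prion_domain", "library1")) {
  set <- match.arg(set)
  raw <- utils::read.delim(prdscan_extdata("table1_propensities.tsv"))
  raw <- raw[match(AMINO_ACIDS, raw$residue), ]
  odds <- raw[[paste0("odds_", set)]]
  lor_printed <- raw[[paste0("lor_", set)]]
  p <- unname(background_frequencies())
  f_raw <- odds * p
  renorm <- sum(f_raw)
  f <- f_raw / renorm
  lor <- log2(odds)
  discrepant <- AMINO_ACIDS[abs(lor - lor_printed) > 0.002]
  tab <- data.frame(residue = AMINO_ACIDS, f = f, p = p, odds = odds,
                    lor = lor, stringsAsFactors = FALSE)
  meta <- list(pseudocount = NA_real_,
               source = paste0("published (", set, ")"),
               published = TRUE,
               renormalisation = renorm,
               lor_printed = stats::setNames(lor_printed, AMINO_ACIDS),
               lor_discrepant = discrepant,
               has_zero_frequencies = FALSE)
  new_propensity_table(tab, meta)
}

#' Train a propensity table from sequences
#'
#' Convenience wrapper: pooled composition counting, frequency estimation
#' and table construction in one call.
#'
#' @param positive training sequences (record collection, character vector
#'   or FASTA path).
#' @param background background sequences, a named background frequency
#'   vector, or `NULL` for the shipped Swiss-Prot background.
#' @param pseudocount smoothing constant for the class frequencies (the
#'   background, when estimated from sequences, uses the same value).
#' @return A `prd_propensity` table.
#' @export
train_propensity_table <- function(positive, background = NULL,
                                   pseudocount = 0.5) {
  positive <- resolve_records(positive)
  f <- estimate_frequencies(count_composition(positive), pseudocount)
  if (is.null(background)) {
    p <- background_frequencies()
    src <- "trained vs Swiss-Prot background"
  } else if (is.numeric(background)) {
    p <- background[AMINO_ACIDS]
    p <- p / sum(p)
    src <- "trained vs user background frequencies"
  } else {
    background <- resolve_records(background)
    p <- estimate_frequencies(count_composition(background), pseudocount)
    src <- "trained vs user background sequences"
  }
  build_propensity_table(f, p, pseudocount = pseudocount, source = src)
}

#' Accept records, character vectors or a FASTA/flat-file path
#' @noRd
resolve_records <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[A-Z]+$", x)) {
    first <- readLines(if (grepl("\\.gz$", x)) gzfile(x) else x, n = 1L)
    if (startsWith(first, ">")) return(read_fasta(x))
    return(read_uniprot_flatfile(x))
  }
  as_records(x)
}

#' Write a propensity table to a TSV file
#'
#' Full double precision, deterministic alphabetical residue order, so that
#' tables round-trip exactly through [read_propensity_table()].
#'
#' @param table a `prd_propensity` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_propensity_table <- function(table, path) {
  stopifnot(inherits(table, "prd_propensity"))
  lines <- c("residue\tf\tp\todds\tlor",
             sprintf("%s\t%.17g\t%.17g\t%.17g\t%.17g",
                     table$residue, table$f, table$p, table$odds, table$lor))
  writeLines(lines, path)
  invisible(path)
}

#' Read a propensity table written by [write_propensity_table()]
#'
#' @param path input path.
#' @return A `prd_propensity` table.
#' @export
read_propensity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "f", "p", "odds", "lor") %in% names(df)))
    stop_data("not a propensity table file: ", path)
  df <- df[match(AMINO_ACIDS, df$residue), ]
  # odds/lor as stored take precedence over recomputation (published tables
  # carry printed odds that are not exactly f/p)
  meta <- list(pseudocount = NA_real_, source = paste0("file:", path),
               published = TRUE, has_zero_frequencies = any(df$f == 0))
  new_propensity_table(df[, c("residue", "f", "p", "odds", "lor")], meta)
}

#' Extract the per-residue log-odds vector (bits)
#' @noRd
lor_vector <- function(table) {
  stats::setNames(table$lor, table$residue)
}
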