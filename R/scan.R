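# Sliding-window scanning of protein sequences.

#' Scanning configuration
#'
#' @param window_length window length in residues (default 60).
#' @param cutoff predictive cutoff in bits (default 50). May be `-Inf`.
#' @param mode `"max"` reports the single best window per protein
#'   (leftmost on ties); `"all"` reports every window at or above the
#'   cutoff, greedily reduced to non-overlapping windows in descending
#'   score order.
#' @param ambiguity `"zero"` lets ambiguity letters (B, J, O, U, X, Z)
#'   contribute 0 bits; `"skip"` drops windows containing any of them.
#' @return An object of class `prd_scan_config`.
#' @export
scan_config <- function(window_length = 60, cutoff = 50,
                        mode = c("max", "all"),
                        ambiguity = c("zero", "skip")) {
  if (!is.numeric(window_length) || window_length < 2)
    stop_data("window_length must be >= 2")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff))
    stop_data("cutoff must be a single number")
  structure(list(window_length = as.integer(window_length),
                 cutoff = cutoff,
                 mode = match.arg(mode),
                 ambiguity = match.arg(ambiguity)),
            class = "prd_scan_config")
}

#' Compositional score from integer residue counts
#'
#' Both the naive and the incremental scanning paths compute window scores
#' through this single function (a 20-term dot product over the window's
#' exact integer composition), so the two are bitwise identical by
#' construction. Residues with zero count are excluded from the sum, which
#' also keeps `-Inf` potentials from poisoning windows that lack the
#' offending residue.
#' @noRd
comp_score_from_counts <- function(counts, lor) {
  keep <- counts != 0L
  sum(counts[keep] * lor[keep])
}

#' Score a single fixed-length window
#'
#' The compositional score is the sum of the per-residue log2-odds over the
#' window (ambiguity letters contribute 0 bits or, under the `"skip"`
#' policy, make the score `NA`); the proline term comes from
#' [proline_correction()]. `score_bits` is exactly their sum.
#'
#' @param window a single residue string whose length must equal
#'   `config$window_length`.
#' @param table a `prd_propensity` table.
#' @param model a `prd_proline_model`.
#' @param config a [scan_config()].
#' @return Named numeric vector: `compositional_bits`, `proline_bits`,
#'   `score_bits`.
#' @examples
#' tab <- builtin_propensity_table()
#' mod <- builtin_proline_model()
#' score_window(strrep("N", 60), tab, mod)
#' @export
score_window <- function(window, table, model, config = scan_config()) {
  stopifnot(inherits(table, "prd_propensity"))
  window <- toupper(window)
  if (nchar(window) != config$window_length)
    stop_data("window has ", nchar(window), " residues; expected ",
              config$window_length)
  chars <- strsplit(window, "")[[1]]
  if (!all(chars %in% SEQUENCE_ALPHABET))
    stop_data("window contains characters outside the residue alphabet")
  idx <- match(chars, AMINO_ACIDS)          # NA for ambiguity letters
  if (config$ambiguity == "skip" && anyNA(idx))
    return(c(compositional_bits = NA_real_, proline_bits = NA_real_,
             score_bits = NA_real_))
  counts <- tabulate(idx[!is.na(idx)], nbins = 20L)
  comp <- comp_score_from_counts(counts, table$lor)
  pro <- proline_correction(window, model)
  c(compositional_bits = comp, proline_bits = pro,
    score_bits = comp + pro)
}

#' Score every window of one sequence (internal)
#'
#' Integer residue counts are maintained incrementally while sliding
#' (exact updates), and each window's score is the same 20-term dot
#' product used by [score_window()].
#' @noRd
scan_windows_internal <- function(residues, table, model, config) {
  L <- config$window_length
  if (L > model$max_distance + 1L)
    stop_data("window_length exceeds what the proline model can score")
  n <- nchar(residues)
  n_win <- n - L + 1L
  if (n_win < 1L)
    return(data.frame(start = integer(), compositional_bits = numeric(),
                      proline_bits = numeric(), score_bits = numeric()))
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, AMINO_ACIDS)
  amb <- cumsum(is.na(idx))
  ppos <- which(chars == "P")
  lor <- table$lor
  plor <- model$lor
  counts <- tabulate(idx[seq_len(L)][!is.na(idx[seq_len(L)])], nbins = 20L)
  comp <- numeric(n_win)
  pro <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  # pointers delimiting prolines inside the current window
  lo <- 1L
  hi <- 0L
  while (hi < length(ppos) && ppos[hi + 1L] <= L) hi <- hi + 1L
  for (s in seq_len(n_win)) {
    if (s > 1L) {
      out_i <- idx[s - 1L]
      in_i <- idx[s + L - 1L]
      if (!is.na(out_i)) counts[out_i] <- counts[out_i] - 1L
      if (!is.na(in_i)) counts[in_i] <- counts[in_i] + 1L
      while (lo <= length(ppos) && ppos[lo] < s) lo <- lo + 1L
      while (hi < length(ppos) && ppos[hi + 1L] <= s + L - 1L) hi <- hi + 1L
    }
    if (config$ambiguity == "skip" &&
        (amb[s + L - 1L] - if (s > 1L) amb[s - 1L] else 0L) > 0L) {
      ok[s] <- FALSE
      next
    }
    comp[s] <- comp_score_from_counts(counts, lor)
    pro[s] <- if (hi > lo) sum(plor[diff(ppos[lo:hi])]) else 0
  }
  df <- data.frame(start = seq_len(n_win), compositional_bits = comp,
                   proline_bits = pro, score_bits = comp + pro)
  df[ok, , drop = FALSE]
}

#' Score all windows of a sequence
#'
#' Exposes the full per-window score profile (used for score landscapes
#' and for verifying the incremental scanner against naive recomputation).
#'
#' @param sequence a single residue string or one-row record collection.
#' @inheritParams score_window
#' @return Data frame with `start`, `compositional_bits`, `proline_bits`,
#'   `score_bits`, one row per window position (step 1).
#' @export
scan_windows <- function(sequence, table, model, config = scan_config()) {
  rec <- as_records(sequence)
  if (nrow(rec) != 1) stop_data("scan_windows expects a single sequence")
  if (config$window_length > model$max_distance + 1L)
    stop_data("window_length exceeds what the proline model can score")
  scan_windows_internal(rec$residues, table, model, config)
}

#' Select prediction rows from a window profile according to the mode
#' @noRd
select_windows <- function(win, config) {
  if (nrow(win) == 0) return(win)
  if (config$mode == "max") {
    return(win[which.max(win$score_bits), , drop = FALSE])  # leftmost tie
  }
  win <- win[win$score_bits >= config$cutoff, , drop = FALSE]
  if (nrow(win) <= 1) return(win)
  win <- win[order(-win$score_bits, win$start), , drop = FALSE]
  L <- config$window_length
  taken_start <- integer(0)
  keep <- logical(nrow(win))
  for (i in seq_len(nrow(win))) {
    s <- win$start[i]
    if (all(abs(taken_start - s) >= L)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
    }
  }
  win <- win[keep, , drop = FALSE]
  win[order(win$start), , drop = FALSE]
}

#' Scan one protein for prion-forming domains
#'
#' Slides a fixed-length window at step 1 over the sequence and reports
#' either the single best window (`mode = "max"`, leftmost on ties) or all
#' non-overlapping windows at or above the cutoff (`mode = "all"`).
#' Proteins shorter than the window return an empty result with a notice.
#'
#' @param record a one-row record collection or a single residue string.
#' @inheritParams score_window
#' @return Prediction data frame with columns `organism`, `protein_id`,
#'   `start`, `end`, `score_bits`, `compositional_bits`,
#'   `proline_correction_bits`, `window_sequence`.
#' @export
scan_sequence <- function(record, table, model, config = scan_config()) {
  rec <- as_records(record)
  if (nrow(rec) != 1) stop_data("scan_sequence expects a single record")
  if (nchar(rec$residues) < config$window_length) {
    message("protein '", rec$id, "' is shorter than the scanning window (",
            nchar(rec$residues), " < ", config$window_length, "); skipped")
    return(empty_predictions())
  }
  win <- scan_windows_internal(rec$residues, table, model, config)
  sel <- select_windows(win, config)
  predictions_from_windows(sel, rec, config)
}

#' @noRd
empty_predictions <- function() {
  data.frame(organism = character(), protein_id = character(),
             start = integer(), end = integer(), score_bits = numeric(),
             compositional_bits = numeric(),
             proline_correction_bits = numeric(),
             window_sequence = character(), stringsAsFactors = FALSE)
}

#' @noRd
predictions_from_windows <- function(sel, rec, config) {
  if (nrow(sel) == 0) return(empty_predictions())
  L <- config$window_length
  data.frame(organism = rec$organism, protein_id = rec$id,
             start = sel$start, end = sel$start + L - 1L,
             score_bits = sel$score_bits,
             compositional_bits = sel$compositional_bits,
             proline_correction_bits = sel$proline_bits,
             window_sequence = substring(rec$residues, sel$start,
                                         sel$start + L - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a proteome for prion-forming domains
#'
#' Applies [scan_sequence()] to every protein, keeping (in `"max"` mode)
#' proteins whose best window reaches the cutoff, or (in `"all"` mode)
#' every qualifying non-overlapping window. Output preserves the input
#' protein order; a per-organism prediction count is attached as the
#' `"summary"` attribute.
#'
#' @param records a record collection (e.g. from [read_fasta()] or
#'   [read_uniprot_flatfile()]).
#' @inheritParams score_window
#' @param quiet suppress the progress notice about skipped short proteins.
#' @return Prediction data frame (see [scan_sequence()]) with a
#'   `"summary"` attribute.
#' @export
scan_proteome <- function(records, table, model, config = scan_config(),
                          quiet = FALSE) {
  records <- resolve_records(records)
  out <- vector("list", nrow(records))
  n_short <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (nchar(rec$residues) < config$window_length) {
      n_short <- n_short + 1L
      next
    }
    win <- scan_windows_internal(rec$residues, table, model, config)
    sel <- select_windows(win, config)
    if (config$mode == "max") {
      sel <- sel[sel$score_bits >= config$cutoff, , drop = FALSE]
    }
    if (nrow(sel) > 0) out[[i]] <- predictions_from_windows(sel, rec, config)
  }
  if (!quiet && n_short > 0)
    message(n_short, " protein(s) shorter than the scanning window skipped")
  pred <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                           list(empty_predictions())))
  row.names(pred) <- NULL
  counts <- if (nrow(pred) > 0) base::table(pred$organism)
            else base::table(character())
  attr(pred, "summary") <- list(n_proteins = nrow(records),
                                n_short = n_short,
                                n_predictions = nrow(pred),
                                per_organism = counts)
  pred
}

#' Per-protein best-score distribution of a proteome
#'
#' The reference distribution for empirical p-values: the best window
#' score of every protein long enough to be scanned.
#'
#' @inheritParams scan_proteome
#' @return Numeric vector of per-protein best scores (class
#'   `prd_score_distribution`).
#' @export
proteome_score_distribution <- function(records, table, model,
                                        config = scan_config()) {
  records <- resolve_records(records)
  cfg <- config
  cfg$mode <- "max"
  scores <- numeric(0)
  for (i in seq_len(nrow(records))) {
    res <- records$residues[i]
    if (nchar(res) < cfg$window_length) next
    win <- scan_windows_internal(res, table, model, cfg)
    if (nrow(win) > 0) scores <- c(scores, max(win$score_bits))
  }
  structure(scores, class = "prd_score_distribution")
}

#' Empirical p-value of a score against a reference distribution
#'
#' Rank-based tail probability with the add-one rule,
#' `p = (1 + #\{x >= score\}) / (n + 1)`, so that p lies in (0, 1] and is
#' never exactly zero.
#'
#' @param score numeric score(s) in bits.
#' @param dist a [proteome_score_distribution()] result or numeric vector
#'   of reference scores.
#' @return Numeric vector of p-values, one per element of `score`.
#' @examples
#' empirical_pvalue(10, 1:9)   # beats all 9 references: p = 0.1
#' @export
empirical_pvalue <- function(score, dist) {
  n <- length(dist)
  if (n < 1) stop_data("reference distribution is empty")
  vapply(score, function(s) (1 + sum(dist >= s)) / (n + 1), numeric(1))
}
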