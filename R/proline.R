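# Proline P-(X)n-P spacing-pattern model and window correction term.

#' Count consecutive proline-pair separations
#'
#' For each sequence, with proline positions `q_1 < q_2 < ... < q_P`, every
#' consecutive pair `(q_j, q_{j+1})` with separation
#' `d = q_{j+1} - q_j <= max_distance` increments the count at distance `d`
#' (adjacent prolines give `d = 1`). Non-consecutive pairs are never
#' counted; pairs farther apart than `max_distance` are ignored.
#'
#' @param records a record collection or character vector of sequences.
#' @param max_distance largest separation tracked (default 60, the scanning
#'   window length).
#' @return A list with `counts` (integer vector indexed by distance
#'   `1..max_distance`) and `n_pairs` (total pairs counted).
#' @examples
#' count_proline_pairs("PAAP")$counts[3]  # one pair at distance 3
#' @export
count_proline_pairs <- function(records, max_distance = 60) {
  if (max_distance < 1) stop_data("max_distance must be >= 1")
  records <- as_records(records)
  counts <- integer(max_distance)
  for (s in records$residues) {
    pos <- which(strsplit(s, "")[[1]] == "P")
    if (length(pos) < 2) next
    d <- diff(pos)
    d <- d[d <= max_distance]
    if (length(d) > 0) {
      tab <- tabulate(d, nbins = max_distance)
      counts <- counts + tab
    }
  }
  list(counts = counts, n_pairs = sum(counts))
}

#' Expected proline-pair separation distribution
#'
#' Analytic null for independently placed prolines: separations follow a
#' geometric law, `P(d)` proportional to `(1 - q)^(d - 1) * q` with `q` the
#' background proline frequency, renormalised over `1..max_distance`.
#'
#' @param proline_freq background per-residue proline probability, in (0, 1).
#' @param max_distance largest separation modelled.
#' @return Probability vector over distances `1..max_distance`.
#' @examples
#' expected_distance_distribution(0.5, 2)  # (2/3, 1/3)
#' @export
expected_distance_distribution <- function(proline_freq, max_distance = 60) {
  if (!is.numeric(proline_freq) || length(proline_freq) != 1 ||
      is.na(proline_freq) || proline_freq <= 0 || proline_freq >= 1)
    stop_data("proline_freq must be a single number in (0, 1)")
  d <- seq_len(max_distance)
  w <- (1 - proline_freq)^(d - 1) * proline_freq
  w / sum(w)
}

#' Build a proline distance model from counts and expected frequencies
#'
#' Observed counts are normalised to frequencies and converted to
#' log-likelihood ratios `lor[d] = log2(observed[d] / expected[d])` in
#' bits. Distances never observed are floored with a half-count rule,
#' `lor = log2((0.5 / n_pairs) / expected[d])`, so corrections stay finite
#' on arbitrary input.
#'
#' @param observed_counts integer vector of pair counts per distance (as
#'   from [count_proline_pairs()], or the list it returns).
#' @param expected_freqs probability vector of the same length (as from
#'   [expected_distance_distribution()]).
#' @return An object of class `prd_proline_model`: a list with
#'   `max_distance`, `observed`, `expected`, `lor` and `n_pairs`.
#' @export
build_proline_model <- function(observed_counts, expected_freqs) {
  if (is.list(observed_counts)) observed_counts <- observed_counts$counts
  if (length(observed_counts) != length(expected_freqs))
    stop_data("observed and expected vectors must have equal length")
  n_pairs <- sum(observed_counts)
  if (n_pairs <= 0) stop_data("no proline pairs observed; cannot build model")
  if (any(expected_freqs <= 0))
    stop_data("expected frequencies must be strictly positive")
  expected <- expected_freqs / sum(expected_freqs)
  observed <- observed_counts / n_pairs
  floored <- observed == 0
  obs_for_lor <- ifelse(floored, 0.5 / n_pairs, observed)
  lor <- log2(obs_for_lor / expected)
  structure(list(max_distance = length(observed),
                 observed = observed,
                 expected = expected,
                 lor = lor,
                 floored = floored,
                 n_pairs = n_pairs),
            class = "prd_proline_model")
}

#' @export
print.prd_proline_model <- function(x, ...) {
  cat("Proline spacing model: distances 1..", x$max_distance, ", ",
      x$n_pairs, " pairs\n", sep = "")
  cat("lor range [", round(min(x$lor), 3), ", ", round(max(x$lor), 3),
      "] bits; ", sum(x$floored), " distance(s) floored\n", sep = "")
  invisible(x)
}

#' Train a proline distance model from reference sequences
#'
#' Counts consecutive proline-pair separations in the reference set and
#' compares them with a null spacing distribution: either the analytic
#' geometric null at the reference proline frequency (default), or an
#' empirical null from residue-shuffled copies of the reference sequences.
#'
#' @param records reference sequences (record collection, character vector
#'   or FASTA path).
#' @param max_distance largest separation modelled (default 60).
#' @param null `"geometric"` (deterministic, default) or `"shuffle"`.
#' @param proline_freq proline frequency for the geometric null; defaults
#'   to the observed frequency in `records`.
#' @param shuffles number of shuffled copies per sequence for the
#'   empirical null.
#' @return A `prd_proline_model`.
#' @export
train_proline_model <- function(records, max_distance = 60,
                                null = c("geometric", "shuffle"),
                                proline_freq = NULL, shuffles = 1) {
  null <- match.arg(null)
  records <- resolve_records(records)
  obs <- count_proline_pairs(records, max_distance)
  if (null == "geometric") {
    if (is.null(proline_freq)) {
      comp <- count_composition(records)
      proline_freq <- comp$counts[["P"]] / comp$total
    }
    expected <- expected_distance_distribution(proline_freq, max_distance)
  } else {
    counts <- integer(max_distance)
    for (k in seq_len(shuffles)) {
      shuf <- vapply(records$residues, function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      counts <- counts + count_proline_pairs(shuf, max_distance)$counts
    }
    if (sum(counts) == 0)
      stop_data("shuffle null produced no proline pairs")
    # half-count floor keeps the null strictly positive at every distance
    expected <- (counts + 0.5) / sum(counts + 0.5)
  }
  build_proline_model(obs, expected)
}

#' The shipped default proline model
#'
#' Trained on a packaged synthetic reference: 5,000 background-composition
#' sequences drawn with a fixed seed (see the methods vignette). Because
#' the reference places residues independently, the model is neutral
#' (log-likelihoods near 0 at every distance); retrain on a real
#' non-redundant reference set with [train_proline_model()] to obtain an
#' informative correction.
#'
#' @return A `prd_proline_model`.
#' @export
builtin_proline_model <- function() {
  read_proline_model(prdscan_extdata("proline_model_synthetic.tsv"))
}

#' Proline correction term for a scoring window (bits)
#'
#' Sums the model log-likelihood over the separations of consecutive
#' proline pairs inside the window. Windows with fewer than two prolines
#' contribute 0.
#'
#' @param window a single residue string (length at most
#'   `model$max_distance`).
#' @param model a `prd_proline_model`.
#' @return The correction in bits (scalar).
#' @export
proline_correction <- function(window, model) {
  stopifnot(inherits(model, "prd_proline_model"))
  if (nchar(window) > model$max_distance)
    stop_data("window longer than the proline model's max_distance")
  pos <- which(strsplit(toupper(window), "")[[1]] == "P")
  proline_correction_at(pos, model)
}

#' Correction from precomputed proline positions (internal fast path)
#' @noRd
proline_correction_at <- function(pos, model) {
  if (length(pos) < 2) return(0)
  sum(model$lor[diff(pos)])
}

#' Write a proline model to a TSV file
#'
#' Header line records `max_distance` and `n_pairs`; rows are
#' `distance<TAB>observed<TAB>expected<TAB>lor` at full double precision.
#'
#' @param model a `prd_proline_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proline_model <- function(model, path) {
  stopifnot(inherits(model, "prd_proline_model"))
  lines <- c(sprintf("# max_distance=%d n_pairs=%d", model$max_distance,
                     model$n_pairs),
             "distance\tobserved\texpected\tlor",
             sprintf("%d\t%.17g\t%.17g\t%.17g", seq_len(model$max_distance),
                     model$observed, model$expected, model$lor))
  writeLines(lines, path)
  invisible(path)
}

#' Read a proline model written by [write_proline_model()]
#'
#' @param path input path.
#' @return A `prd_proline_model`.
#' @export
read_proline_model <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  n_pairs <- as.integer(sub(".*n_pairs=([0-9]+).*", "\\1", header))
  df <- utils::read.delim(text = lines[-1])
  if (!all(c("distance", "observed", "expected", "lor") %in% names(df)))
    stop_data("not a proline model file: ", path)
  df <- df[order(df$distance), ]
  structure(list(max_distance = nrow(df),
                 observed = df$observed,
                 expected = df$expected,
                 lor = df$lor,
                 floored = df$observed == 0,
                 n_pairs = n_pairs),
            class = "prd_proline_model")
}
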