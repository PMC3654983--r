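# Shared fixtures and independent oracles used across test files.

# Independent reader for the per-taxon prediction dialect, used to
# round-trip the writer's output.
read_paper_format <- function(path) {
  lines <- readLines(path)
  out <- list()
  org <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      org <- sub("^>(.*): [0-9]+$", "\\1", ln)
    } else {
      id <- sub("\t.*$", "", ln)
      rest <- sub("^[^\t]*\t", "", ln)
      start <- as.integer(sub(";.*$", "", rest))
      score <- as.numeric(sub("^[^\t]*\t[0-9]+;([^|]*)\\|.*$", "\\1", ln))
      seqs <- sub("^.*\\|", "", ln)
      out[[length(out) + 1]] <- data.frame(
        organism = org, protein_id = id, start = start, score = score,
        window_sequence = seqs, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(organism = character(), protein_id = character(),
                      start = integer(), score = numeric(),
                      window_sequence = character()))
  do.call(rbind, out)
}

# Random residue string over the standard alphabet (optionally with
# ambiguity letters mixed in).
random_sequence <- function(len, p_ambiguity = 0) {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  amb <- c("B", "J", "O", "U", "X", "Z")
  pool <- c(letters20, amb)
  prob <- c(rep((1 - p_ambiguity) / 20, 20), rep(p_ambiguity / 6, 6))
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force confusion counts by direct comparison (threshold oracle).
brute_confusion <- function(pos, neg, cutoff) {
  list(TP = sum(pos >= cutoff), FP = sum(neg >= cutoff),
       TN = sum(neg < cutoff), FN = sum(pos < cutoff))
}

# Pair-counting AUC oracle: P(pos > neg) + 0.5 P(pos == neg).
pair_auc <- function(pos, neg) {
  grid <- outer(pos, neg, `-`)
  mean((grid > 0) + 0.5 * (grid == 0))
}

# Cached built-in model pieces (loading is cheap but repeated often).
builtin_table_cached <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- builtin_propensity_table()
    tab
  }
})

builtin_proline_cached <- local({
  mod <- NULL
  function() {
    if (is.null(mod)) mod <<- builtin_proline_model()
    mod
  }
})
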