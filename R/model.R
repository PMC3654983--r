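# The fitted prion-domain scoring model: one object bundling the
# propensity table, the proline spacing model and the scan configuration.

#' Fit (or load) a prion-domain scoring model
#'
#' With no training data, returns the published model: the shipped
#' prion-domain propensity table, the shipped (neutral, synthetic-reference)
#' proline spacing model, and the standard 60-residue / 50-bit scan
#' configuration. Supplying `positive` retrains the propensity table from
#' sequences; supplying `proline_reference` retrains the proline model.
#'
#' @param positive training sequences for the positive class (record
#'   collection, character vector, or FASTA/flat-file path); `NULL` loads
#'   the published propensity table.
#' @param background background composition: sequences, a named frequency
#'   vector, or `NULL` for the shipped Swiss-Prot background.
#' @param proline_reference reference sequences for the proline spacing
#'   model; `NULL` loads the shipped model.
#' @param pseudocount additive smoothing for trained frequencies.
#' @param window_length,cutoff,mode,ambiguity scan settings, see
#'   [scan_config()].
#' @return Object of class `prd_model` with components `table`
#'   (`prd_propensity`), `proline` (`prd_proline_model`) and `config`
#'   (`prd_scan_config`).
#' @examples
#' m <- prd_model()
#' coef(m)[c("Q", "N")]
#' @seealso [predict.prd_model()], [scan_proteome()]
#' @export
prd_model <- function(positive = NULL, background = NULL,
                      proline_reference = NULL, pseudocount = 0.5,
                      window_length = 60, cutoff = 50, mode = "max",
                      ambiguity = "zero") {
  tab <- if (is.null(positive)) builtin_propensity_table()
         else train_propensity_table(positive, background, pseudocount)
  pro <- if (is.null(proline_reference)) builtin_proline_model()
         else train_proline_model(proline_reference,
                                  max_distance = window_length)
  cfg <- scan_config(window_length = window_length, cutoff = cutoff,
                     mode = mode, ambiguity = ambiguity)
  structure(list(table = tab, proline = pro, config = cfg,
                 trained = !is.null(positive), call = match.call()),
            class = "prd_model")
}

#' @export
print.prd_model <- function(x, ...) {
  meta <- attr(x$table, "metadata")
  cat("Prion-domain scoring model\n")
  cat("  propensity table: ", meta$source, "\n", sep = "")
  cat("  proline model:    distances 1..", x$proline$max_distance, " (",
      x$proline$n_pairs, " pairs)\n", sep = "")
  cat("  scan:             window ", x$config$window_length, ", cutoff ",
      x$config$cutoff, " bits, mode '", x$config$mode, "'\n", sep = "")
  invisible(x)
}

#' @export
summary.prd_model <- function(object, ...) {
  structure(list(model = object), class = "summary.prd_model")
}

#' @export
print.summary.prd_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-residue statistical potentials (bits):\n")
  print(m$table)
  lo <- m$proline$lor
  cat("\nProline spacing log-likelihoods: median ",
      round(stats::median(lo), 3), " bits, range [",
      round(min(lo), 3), ", ", round(max(lo), 3), "]\n", sep = "")
  invisible(x)
}

#' Per-residue log2-odds coefficients of the model
#'
#' @param object a `prd_model`.
#' @param ... unused.
#' @return Named numeric vector of statistical potentials in bits.
#' @export
coef.prd_model <- function(object, ...) {
  lor_vector(object$table)
}

#' Predict prion-forming domains in new sequences
#'
#' @param object a `prd_model`.
#' @param newdata sequences: record collection, character vector, or
#'   FASTA/flat-file path.
#' @param type `"predictions"` returns the windows passing the cutoff
#'   (the per-taxon prediction content); `"windows"` returns the best (or
#'   all qualifying) window per protein regardless of cutoff; `"score"`
#'   returns the per-protein best score in bits.
#' @param ... unused.
#' @return A prediction data frame, or a named numeric vector for
#'   `type = "score"`.
#' @export
predict.prd_model <- function(object, newdata,
                              type = c("predictions", "windows", "score"),
                              ...) {
  type <- match.arg(type)
  records <- resolve_records(newdata)
  cfg <- object$config
  if (type == "predictions")
    return(scan_proteome(records, object$table, object$proline, cfg,
                         quiet = TRUE))
  if (type == "score") {
    s <- proteome_score_distribution(records, object$table, object$proline,
                                     cfg)
    long <- nchar(records$residues) >= cfg$window_length
    return(stats::setNames(as.numeric(s), records$id[long]))
  }
  cfg$cutoff <- -Inf
  scan_proteome(records, object$table, object$proline, cfg, quiet = TRUE)
}

#' Plot the fitted potentials
#'
#' Two-panel base-graphics display: per-residue statistical potentials
#' (bits) and the proline spacing log-likelihood profile.
#'
#' @param x a `prd_model`.
#' @param ... passed to `barplot()`.
#' @export
plot.prd_model <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  lor <- coef(x)
  graphics::barplot(lor, las = 2, ylab = "log2 odds (bits)",
                    main = "Residue propensities", ...)
  graphics::plot(seq_len(x$proline$max_distance), x$proline$lor,
                 type = "h", xlab = "proline pair separation (residues)",
                 ylab = "log2 likelihood (bits)",
                 main = "Proline spacing")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Simulate sequences from the model's class composition
#'
#' Draws synthetic sequences whose residues follow the fitted positive-class
#' composition `f` of the model's propensity table.
#'
#' @param object a `prd_model`.
#' @param nsim number of sequences.
#' @param seed integer seed or `NULL`.
#' @param min_length,max_length sequence length range.
#' @param ... unused.
#' @return A record collection.
#' @export
simulate.prd_model <- function(object, nsim = 1, seed = NULL,
                               min_length = 60, max_length = 700, ...) {
  f <- stats::setNames(object$table$f, object$table$residue)
  spec <- generator_spec(freqs = f, min_length = min_length,
                         max_length = max_length)
  sample_sequences(spec, nsim, seed = seed, id_prefix = "sim")
}
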