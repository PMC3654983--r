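# Classifier benchmarking: confusion metrics, ROC/AUC, precision-recall,
# accuracy against cutoff, rank-sum test, bootstrap ROC, enrichment z-scores.

#' Confusion counts at a score cutoff
#'
#' A score at or above the cutoff is a positive call (closed lower bound).
#'
#' @param pos_scores scores of the positive class (bits).
#' @param neg_scores scores of the negative class (bits).
#' @param cutoff classification cutoff.
#' @return An object of class `prd_confusion`: list with `TP`, `FP`, `TN`,
#'   `FN`, `P`, `N`.
#' @examples
#' confusion_at_cutoff(c(60, 40), c(30, 55), 50)
#' @export
confusion_at_cutoff <- function(pos_scores, neg_scores, cutoff) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop_data("both score classes must be non-empty")
  TP <- sum(pos_scores >= cutoff)
  FP <- sum(neg_scores >= cutoff)
  structure(list(TP = TP, FP = FP,
                 TN = length(neg_scores) - FP,
                 FN = length(pos_scores) - TP,
                 P = length(pos_scores), N = length(neg_scores)),
            class = "prd_confusion")
}

#' @export
print.prd_confusion <- function(x, ...) {
  cat("Confusion counts: TP =", x$TP, " FP =", x$FP, " TN =", x$TN,
      " FN =", x$FN, "\n")
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Standard definitions: `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`,
#' `Accuracy = (TP+TN)/(P+N)`, `Precision = TP/(TP+FP)`,
#' `FDR = FP/(FP+TP)`. Zero denominators yield `NA` (undefined), never an
#' error. Whenever precision and FDR are both defined they sum to 1.
#'
#' @param counts a `prd_confusion` object (or list with `TP`, `FP`, `TN`,
#'   `FN`).
#' @return Named list with `tpr`, `fpr`, `accuracy`, `precision`, `fdr`.
#' @examples
#' classification_metrics(list(TP = 8, FN = 2, FP = 1, TN = 9))
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    list(tpr = ratio(TP, TP + FN),
         fpr = ratio(FP, FP + TN),
         accuracy = ratio(TP + TN, TP + TN + FP + FN),
         precision = ratio(TP, TP + FP),
         fdr = ratio(FP, FP + TP))
  })
}

#' ROC curve with trapezoid AUC
#'
#' Thresholds at every distinct score (descending) plus the two endpoints;
#' tied scores move together, producing diagonal segments. The area under
#' the curve is computed with the trapezoid rule, which (including under
#' ties) equals the tie-corrected Mann-Whitney statistic `U/(n*m)`.
#'
#' @inheritParams confusion_at_cutoff
#' @return Object of class `prd_roc`: list with `fpr`, `tpr`,
#'   `thresholds` and `auc`.
#' @examples
#' roc_curve(c(2, 4), c(1, 3))$auc  # 0.75
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop_data("both score classes must be non-empty")
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos_scores >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(neg_scores >= t), numeric(1)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, thr), auc = auc),
            class = "prd_roc")
}

#' @export
print.prd_roc <- function(x, ...) {
  cat("ROC curve:", length(x$fpr), "points, trapezoid AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' @export
plot.prd_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Trapezoid AUC versus the rank-sum view of the same data
#'
#' Returns both the trapezoid area under the ROC curve and the
#' Mann-Whitney U statistic (with tie midpoints) divided by `n * m`. The
#' two are algebraically identical; the pair is exposed as a built-in
#' cross-check.
#'
#' @inheritParams confusion_at_cutoff
#' @return Named numeric vector `c(auc, rank_sum)`.
#' @export
auc_rank_sum_check <- function(pos_scores, neg_scores) {
  auc <- roc_curve(pos_scores, neg_scores)$auc
  n <- length(pos_scores)
  m <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))     # midranks under ties
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  c(auc = auc, rank_sum = U / (n * m))
}

#' Precision-recall curve
#'
#' One point per distinct threshold (descending scores). Stable under
#' heavy class skew.
#'
#' @inheritParams confusion_at_cutoff
#' @return Data frame with `threshold`, `recall`, `precision`.
#' @export
precision_recall_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop_data("both score classes must be non-empty")
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos_scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(neg_scores >= t), numeric(1))
  data.frame(threshold = thr,
             recall = tp / length(pos_scores),
             precision = tp / (tp + fp))
}

#' Accuracy along a cutoff grid
#'
#' Evaluates classification accuracy at each cutoff of the grid and reports
#' the maximising cutoff; ties are broken toward the largest (most
#' conservative) cutoff.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs numeric grid of cutoffs (non-empty).
#' @return Object of class `prd_accuracy`: list with `table` (data frame
#'   `cutoff`, `accuracy`) and `best_cutoff`.
#' @export
accuracy_vs_cutoff <- function(pos_scores, neg_scores, cutoffs) {
  if (length(cutoffs) == 0) stop_data("cutoff grid is empty")
  acc <- vapply(cutoffs, function(ct) {
    classification_metrics(confusion_at_cutoff(pos_scores, neg_scores,
                                               ct))$accuracy
  }, numeric(1))
  best <- max(cutoffs[acc == max(acc)])
  structure(list(table = data.frame(cutoff = cutoffs, accuracy = acc),
                 best_cutoff = best, best_accuracy = max(acc)),
            class = "prd_accuracy")
}

#' @export
print.prd_accuracy <- function(x, ...) {
  cat("Accuracy maximised at cutoff", x$best_cutoff, "bits (accuracy",
      round(x$best_accuracy, 4), ")\n")
  invisible(x)
}

#' Mann-Whitney-Wilcoxon rank-sum test between score classes
#'
#' Two-sided test that the positive and negative score distributions
#' differ. The p-value uses exact enumeration when `n * m <= 400` and the
#' data are tie-free, and the normal approximation with tie correction
#' (and continuity correction) otherwise.
#'
#' @inheritParams confusion_at_cutoff
#' @return List with `U` (Mann-Whitney statistic of the positive class),
#'   `p_value` and `method` (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop_data("both score classes must be non-empty")
  n <- length(pos_scores)
  m <- length(neg_scores)
  ties <- anyDuplicated(c(pos_scores, neg_scores)) > 0
  exact <- (n * m <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(pos_scores, neg_scores, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Half-exclusion bootstrap of the ROC curve
#'
#' Each iteration splits the positive sequences into two disjoint halves
#' uniformly at random, retrains the propensity table on one half
#' (against the fixed background), scores the held-out half and the fixed
#' negative set (best window per protein), and builds a ROC curve. Curves
#' are vertically averaged on a fixed 101-point FPR grid with linear
#' interpolation, and the AUC sample is collected. With
#' `resample_train = TRUE` the training half is additionally sampled with
#' replacement.
#'
#' @param pos_records positive (prion) sequence records; their count must
#'   be even.
#' @param neg_records negative sequence records (fixed across iterations).
#' @param model a `prd_proline_model`, fixed across iterations.
#' @param config a [scan_config()]; scoring uses the best window per
#'   protein.
#' @param n_iterations number of bootstrap iterations.
#' @param seed integer seed; results are fully reproducible given
#'   `(seed, n_iterations)`.
#' @param pseudocount smoothing for the retrained frequencies.
#' @param background background frequency vector (default: shipped
#'   Swiss-Prot background).
#' @param resample_train sample the training half with replacement.
#' @return Object of class `prd_bootstrap`: list with `fpr_grid`,
#'   `mean_tpr`, `sd_tpr`, `auc_samples`, `mean_auc`, `n_iterations`.
#' @export
bootstrap_roc <- function(pos_records, neg_records, model,
                          config = scan_config(), n_iterations = 10000,
                          seed = 1, pseudocount = 0.5, background = NULL,
                          resample_train = FALSE) {
  pos_records <- resolve_records(pos_records)
  neg_records <- resolve_records(neg_records)
  n_pos <- nrow(pos_records)
  if (n_pos < 4 || n_pos %% 2 != 0)
    stop_data("the positive set must have an even size >= 4 for the ",
              "half-exclusion split; supply explicit train/test sets ",
              "otherwise")
  if (is.null(background)) background <- background_frequencies()
  p <- background[AMINO_ACIDS] / sum(background[AMINO_ACIDS])

  # per-protein window composition (integer counts) and proline terms are
  # independent of the retrained table, so precompute them once
  profile_protein <- function(residues) {
    L <- config$window_length
    n_win <- nchar(residues) - L + 1L
    if (n_win < 1L) return(NULL)
    chars <- strsplit(residues, "")[[1]]
    idx <- match(chars, AMINO_ACIDS)
    onehot <- matrix(0, nrow = length(chars), ncol = 20L)
    onehot[cbind(which(!is.na(idx)), idx[!is.na(idx)])] <- 1
    cs <- apply(onehot, 2, cumsum)
    counts <- cs[L:nrow(cs), , drop = FALSE] -
      rbind(0, cs)[L:nrow(cs) - L + 1L, , drop = FALSE]
    ppos <- which(chars == "P")
    pro <- vapply(seq_len(n_win), function(s) {
      pp <- ppos[ppos >= s & ppos <= s + L - 1L]
      proline_correction_at(pp, model)
    }, numeric(1))
    list(counts = counts, pro = pro)
  }
  pos_prof <- lapply(pos_records$residues, profile_protein)
  neg_prof <- lapply(neg_records$residues, profile_protein)
  if (any(vapply(c(pos_prof, neg_prof), is.null, logical(1))))
    stop_data("all benchmark proteins must be at least one window long")
  comp_counts <- lapply(seq_len(n_pos), function(i) {
    count_composition(pos_records[i, ])
  })
  best_score <- function(prof, lor) max(prof$counts %*% lor + prof$pro)

  grid <- seq(0, 1, length.out = 101)
  half <- n_pos / 2
  set.seed(seed)
  auc_samples <- numeric(n_iterations)
  tpr_sum <- numeric(101)
  tpr_sq <- numeric(101)
  for (b in seq_len(n_iterations)) {
    train <- sample.int(n_pos, half)
    if (resample_train) train <- sample(train, half, replace = TRUE)
    test <- setdiff(seq_len(n_pos), unique(train))
    counts <- Reduce(`+`, lapply(comp_counts[train], `[[`, "counts"))
    f <- estimate_frequencies(counts, pseudocount)
    lor <- log2((f / sum(f)) / p)
    ps <- vapply(pos_prof[test], best_score, numeric(1), lor = lor)
    ns <- vapply(neg_prof, best_score, numeric(1), lor = lor)
    roc <- roc_curve(ps, ns)
    auc_samples[b] <- roc$auc
    g <- stats::approx(roc$fpr, roc$tpr, xout = grid, ties = max,
                       rule = 2)$y
    tpr_sum <- tpr_sum + g
    tpr_sq <- tpr_sq + g^2
  }
  mean_tpr <- tpr_sum / n_iterations
  var_tpr <- pmax(0, tpr_sq / n_iterations - mean_tpr^2)
  structure(list(fpr_grid = grid, mean_tpr = mean_tpr,
                 sd_tpr = sqrt(var_tpr), auc_samples = auc_samples,
                 mean_auc = mean(auc_samples),
                 n_iterations = n_iterations),
            class = "prd_bootstrap")
}

#' @export
print.prd_bootstrap <- function(x, ...) {
  cat("Bootstrap ROC:", x$n_iterations, "iterations, mean AUC =",
      round(x$mean_auc, 4), "\n")
  invisible(x)
}

#' @export
plot.prd_bootstrap <- function(x, ...) {
  plot(x$fpr_grid, x$mean_tpr, type = "l",
       xlab = "False positive rate", ylab = "Mean true positive rate", ...)
  graphics::lines(x$fpr_grid, pmin(1, x$mean_tpr + x$sd_tpr), lty = 2)
  graphics::lines(x$fpr_grid, pmax(0, x$mean_tpr - x$sd_tpr), lty = 2)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Randomization z-scores for category enrichment in a selection
#'
#' Compares the number of selected proteins carrying each category label
#' with the null distribution obtained by repeatedly drawing random
#' selections of the same size (without replacement) from the universe.
#' `z = (observed - null mean) / null sd`; a zero null standard deviation
#' yields `NA`.
#'
#' @param universe data frame with columns `id` and `category`
#'   (multi-label: one row per id-category pair), or a named list mapping
#'   ids to category vectors.
#' @param selection character vector of selected ids (must be a subset of
#'   the universe ids).
#' @param n_randomizations number of random selections (>= 100).
#' @param seed integer seed.
#' @return Data frame with `category`, `observed`, `null_mean`, `null_sd`,
#'   `z`, ordered by decreasing `z`.
#' @export
enrichment_zscores <- function(universe, selection,
                               n_randomizations = 10000, seed = 1) {
  if (is.list(universe) && !is.data.frame(universe)) {
    universe <- data.frame(
      id = rep(names(universe), lengths(universe)),
      category = unlist(universe, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!all(c("id", "category") %in% names(universe)))
    stop_data("universe must have columns 'id' and 'category'")
  if (n_randomizations < 100)
    stop_data("n_randomizations must be >= 100")
  ids <- unique(universe$id)
  if (!all(selection %in% ids))
    stop_data("selection contains ids absent from the universe")
  empty_cat <- is.na(universe$category) | universe$category == ""
  if (any(empty_cat)) {
    warning("dropped ", sum(empty_cat), " empty category label(s)",
            call. = FALSE)
    universe <- universe[!empty_cat, , drop = FALSE]
  }
  cats <- sort(unique(universe$category))
  membership <- matrix(FALSE, nrow = length(ids), ncol = length(cats),
                       dimnames = list(ids, cats))
  membership[cbind(match(universe$id, ids),
                   match(universe$category, cats))] <- TRUE
  k <- length(unique(selection))
  observed <- colSums(membership[unique(selection), , drop = FALSE])
  set.seed(seed)
  sums <- numeric(length(cats))
  sq <- numeric(length(cats))
  for (b in seq_len(n_randomizations)) {
    draw <- colSums(membership[sample.int(length(ids), k), , drop = FALSE])
    sums <- sums + draw
    sq <- sq + draw^2
  }
  null_mean <- sums / n_randomizations
  null_sd <- sqrt(pmax(0, sq / n_randomizations - null_mean^2))
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  out <- data.frame(category = cats, observed = as.numeric(observed),
                    null_mean = null_mean, null_sd = null_sd, z = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-ifelse(is.na(out$z), -Inf, out$z)), , drop = FALSE]
}
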