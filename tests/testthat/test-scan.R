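# Sliding-window scanning.

test_that("score_window matches arithmetic oracles from the table rows", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  lor <- setNames(tab$lor, tab$residue)
  sN <- score_window(strrep("N", 60), tab, mod)
  expect_equal(sN[["compositional_bits"]], 60 * lor[["N"]])
  expect_equal(sN[["compositional_bits"]], 150.66, tolerance = 1e-4)
  expect_equal(sN[["proline_bits"]], 0)
  expect_equal(sN[["score_bits"]], sN[["compositional_bits"]])

  sQ <- score_window(strrep("Q", 60), tab, mod)
  expect_equal(sQ[["compositional_bits"]], 60 * lor[["Q"]])
  expect_equal(sQ[["compositional_bits"]], 122.64, tolerance = 1e-3)

  expect_error(score_window(strrep("N", 59), tab, mod), "expected 60")
})

test_that("background-composition windows score below zero on average", {
  # E[lor under p] = -KL(p || f) <= 0 (Gibbs); sampled windows agree
  set.seed(31)
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  spec <- generator_spec("background", min_length = 60, max_length = 60)
  recs <- sample_sequences(spec, 200)
  scores <- vapply(recs$residues,
                   function(w) score_window(w, tab, mod)[["score_bits"]],
                   numeric(1))
  expect_lt(mean(scores), 0)
})

test_that("ambiguity letters contribute zero bits or skip the window", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  w_clean <- strrep("N", 60)
  w_amb <- paste0(strrep("N", 58), "XU")
  s_clean <- score_window(strrep("N", 58), tab, mod,
                          scan_config(window_length = 58))
  s_amb <- score_window(w_amb, tab, mod)
  expect_equal(s_amb[["compositional_bits"]],
               s_clean[["compositional_bits"]])
  skip <- score_window(w_amb, tab, mod, scan_config(ambiguity = "skip"))
  expect_true(is.na(skip[["score_bits"]]))
  expect_false(is.na(score_window(w_clean, tab, mod,
                                  scan_config(ambiguity = "skip"))[[3]]))
})

test_that("incremental sliding scores equal naive recomputation bitwise", {
  set.seed(17)
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  cfg <- scan_config(window_length = 60)
  for (k in 1:60) {
    s <- random_sequence(sample(60:160, 1), p_ambiguity = 0.02)
    win <- scan_windows(s, tab, mod, cfg)
    naive <- t(vapply(win$start, function(st) {
      score_window(substr(s, st, st + 59), tab, mod, cfg)
    }, numeric(3)))
    expect_identical(win$compositional_bits,
                     unname(naive[, "compositional_bits"]))
    expect_identical(win$proline_bits, unname(naive[, "proline_bits"]))
    expect_identical(win$score_bits, unname(naive[, "score_bits"]))
  }
})

test_that("window scores are permutation-invariant given fixed prolines", {
  set.seed(23)
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  w <- strsplit(random_sequence(60), "")[[1]]
  ref <- score_window(paste(w, collapse = ""), tab, mod)
  non_p <- which(w != "P")
  w2 <- w
  w2[non_p] <- sample(w[non_p])
  perm <- score_window(paste(w2, collapse = ""), tab, mod)
  expect_identical(perm[["proline_bits"]], ref[["proline_bits"]])
  expect_equal(perm[["compositional_bits"]], ref[["compositional_bits"]])
})

test_that("substituting a higher-lor residue never lowers the score", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  lor <- setNames(tab$lor, tab$residue)
  set.seed(27)
  w <- strsplit(random_sequence(60), "")[[1]]
  base <- score_window(paste(w, collapse = ""), tab, mod)
  at <- which(w != "P")[1]
  better <- names(lor)[lor >= lor[[w[at]]]]
  better <- setdiff(better, "P")  # avoid touching the proline pattern
  for (b in better) {
    w2 <- w
    w2[at] <- b
    s2 <- score_window(paste(w2, collapse = ""), tab, mod)
    expect_gte(s2[["compositional_bits"]], base[["compositional_bits"]])
  }
})

test_that("scan_sequence handles short proteins, ties and spikes", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  cfg <- scan_config()
  expect_message(short <- scan_sequence(strrep("A", 59), tab, mod, cfg),
                 "shorter than the scanning window")
  expect_equal(nrow(short), 0)

  # periodic sequence: all windows identical, leftmost wins
  tie <- scan_sequence(strrep("QN", 60), tab, mod, cfg)
  expect_equal(tie$start, 1L)

  # spiked core window is localised to within 2 residues
  set.seed(33)
  hits <- 0L
  for (k in 1:5) {
    bg <- sample_sequences(generator_spec("background", min_length = 300,
                                          max_length = 300), 1)$residues
    core <- paste(sample(prdscan:::AMINO_ACIDS, 60, replace = TRUE,
                         prob = flavor_frequencies("core")),
                  collapse = "")
    spiked <- paste0(substr(bg, 1, 100), core, substr(bg, 161, 300))
    best <- scan_sequence(spiked, tab, mod, cfg)
    if (abs(best$start - 101) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("all-above-cutoff mode returns non-overlapping windows", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  set.seed(35)
  bg <- sample_sequences(generator_spec("background", min_length = 400,
                                        max_length = 400), 1)$residues
  core <- function() paste(sample(prdscan:::AMINO_ACIDS, 60, replace = TRUE,
                                  prob = flavor_frequencies("core")),
                           collapse = "")
  two <- paste0(core(), substr(bg, 61, 200), core(), substr(bg, 261, 400))
  cfg <- scan_config(mode = "all", cutoff = 50)
  res <- scan_sequence(two, tab, mod, cfg)
  expect_gte(nrow(res), 2)
  if (nrow(res) > 1) {
    s <- sort(res$start)
    expect_true(all(diff(s) >= 60))
  }
})

test_that("scan_proteome keeps input order and counts per organism", {
  set.seed(37)
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  sim <- make_proteome(60, 0.1, seed = 41)
  pred <- scan_proteome(sim$records, tab, mod, scan_config(), quiet = TRUE)
  expect_setequal(pred$protein_id, sim$truth$protein_id)
  expect_false(is.unsorted(match(pred$protein_id, sim$records$id)))
  sm <- attr(pred, "summary")
  expect_equal(sm$n_predictions, nrow(pred))
  expect_equal(sum(sm$per_organism), nrow(pred))
  expect_identical(pred$score_bits,
                   pred$compositional_bits + pred$proline_correction_bits)

  # cutoff -Inf in max mode: every protein long enough appears exactly once
  all_pred <- scan_proteome(sim$records, tab, mod,
                            scan_config(cutoff = -Inf), quiet = TRUE)
  long <- sum(nchar(sim$records$residues) >= 60)
  expect_equal(nrow(all_pred), long)
  expect_equal(anyDuplicated(all_pred$protein_id), 0)
})

test_that("background proteomes yield no calls at the 50-bit cutoff", {
  tab <- builtin_table_cached()
  mod <- builtin_proline_cached()
  for (seed in 1:3) {
    sim <- make_proteome(100, 0, seed = seed)
    pred <- scan_proteome(sim$records, tab, mod, scan_config(),
                          quiet = TRUE)
    expect_equal(nrow(pred), 0)
  }
})

test_that("empirical p-values follow the add-one rule and separate spikes", {
  expect_equal(empirical_pvalue(1000, 1:999), 1 / 1000)
  expect_equal(empirical_pvalue(1, 1:999), 1.0)   # ties count against
  expect_error(empirical_pvalue(1, numeric(0)), "empty")

  # synthetic proteome-scale score distribution: multinomial window draws
  set.seed(43)
  tab <- builtin_table_cached()
  bg_scores <- as.vector(
    t(rmultinom(10000, 60, background_frequencies())) %*% tab$lor)
  spike_scores <- as.vector(
    t(rmultinom(20, 60, flavor_frequencies("core"))) %*% tab$lor)
  p_spike <- empirical_pvalue(spike_scores, bg_scores)
  p_bg <- empirical_pvalue(bg_scores[1:200], bg_scores)
  expect_true(all(p_spike <= 0.001))
  expect_gt(stats::median(p_bg), 0.4)
  expect_lt(stats::median(p_bg), 0.6)
})
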