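# Synthetic sequence generators with known ground truth.

#' Specification for a synthetic sequence generator
#'
#' Three named composition flavors are available:
#' `"prd"` — the class composition of the built-in propensity table
#' (training-set composition of prion proteins, diluted by their
#' non-prion flanks); `"core"` — a prion-domain-core-like enrichment of
#' that composition (odds-tilted, ~60% Q/N), matching the composition of
#' 60-residue stretches that actually pass the 50-bit cutoff; and
#' `"background"` — the shipped protein-universe background. A custom
#' frequency vector overrides the flavor.
#'
#' @param flavor one of `"prd"`, `"core"`, `"background"`.
#' @param freqs optional named frequency vector over the 20 standard amino
#'   acids (overrides `flavor`).
#' @param min_length,max_length sequence length range (uniform).
#' @param proline_mode `"iid"` places all residues independently;
#'   `"clustered"` plants prolines in clusters with intra-cluster spacing
#'   at most `cluster_gap`.
#' @param cluster_gap largest distance between consecutive prolines inside
#'   a cluster.
#' @return Object of class `prd_generator_spec`.
#' @export
generator_spec <- function(flavor = c("background", "prd", "core"),
                           freqs = NULL, min_length = 60, max_length = 700,
                           proline_mode = c("iid", "clustered"),
                           cluster_gap = 2) {
  flavor <- match.arg(flavor)
  if (is.null(freqs)) freqs <- flavor_frequencies(flavor)
  freqs <- freqs[AMINO_ACIDS]
  if (anyNA(freqs) || any(freqs < 0))
    stop_data("freqs must be a non-negative vector over the 20 amino acids")
  if (abs(sum(freqs) - 1) > 1e-6) stop_data("freqs must sum to 1")
  if (min_length > max_length) stop_data("min_length must be <= max_length")
  structure(list(flavor = flavor, freqs = freqs / sum(freqs),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 proline_mode = match.arg(proline_mode),
                 cluster_gap = as.integer(cluster_gap)),
            class = "prd_generator_spec")
}

#' Composition of a named generator flavor
#'
#' The `"core"` flavor sharpens the training composition `f` by tilting
#' with the square root of the odds ratio (`f * odds^0.5`, renormalised),
#' yielding the Q/N-rich composition typical of validated prion-domain
#' cores while keeping the same residue ordering of propensities.
#'
#' @param flavor `"prd"`, `"core"` or `"background"`.
#' @return Named frequency vector over the 20 standard amino acids.
#' @export
flavor_frequencies <- function(flavor = c("background", "prd", "core")) {
  flavor <- match.arg(flavor)
  if (flavor == "background") return(background_frequencies())
  tab <- builtin_propensity_table()
  f <- stats::setNames(tab$f, tab$residue)
  if (flavor == "prd") return(f)
  tilt <- f * stats::setNames(tab$odds, tab$residue)^0.5
  tilt / sum(tilt)
}

#' Sample synthetic protein sequences
#'
#' Residues are drawn i.i.d. from the spec's composition; in clustered
#' proline mode, a proline-free backbone is sampled from the renormalised
#' non-proline composition and the expected number of prolines is planted
#' in clusters whose members are at most `cluster_gap` residues apart.
#' Output is a pure function of `(spec, n, seed)`.
#'
#' @param spec a [generator_spec()].
#' @param n number of sequences.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param id_prefix prefix for generated record ids.
#' @return A record collection (see [sequence_records()]).
#' @examples
#' sample_sequences(generator_spec("background", min_length = 80,
#'                                 max_length = 120), 3, seed = 1)
#' @export
sample_sequences <- function(spec, n, seed = NULL, id_prefix = "syn") {
  stopifnot(inherits(spec, "prd_generator_spec"))
  if (n < 1) stop_data("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- if (spec$min_length == spec$max_length) rep(spec$min_length, n)
          else sample(spec$min_length:spec$max_length, n, replace = TRUE)
  seqs <- vapply(lens, function(len) sample_one(spec, len), character(1))
  sequence_records(seqs, id = sprintf("%s%04d", id_prefix, seq_len(n)),
                   organism = "synthetic")
}

#' @noRd
sample_one <- function(spec, len) {
  if (spec$proline_mode == "iid")
    return(paste(sample(AMINO_ACIDS, len, replace = TRUE,
                        prob = spec$freqs), collapse = ""))
  q <- spec$freqs[["P"]]
  backbone_freqs <- spec$freqs
  backbone_freqs["P"] <- 0
  backbone_freqs <- backbone_freqs / sum(backbone_freqs)
  chars <- sample(AMINO_ACIDS, len, replace = TRUE, prob = backbone_freqs)
  m <- round(q * len)
  placed <- 0L
  guard <- 0L
  while (placed < m && guard < 100L) {
    guard <- guard + 1L
    size <- min(m - placed, sample(2:4, 1))
    gaps <- if (size > 1) sample(seq_len(spec$cluster_gap), size - 1,
                                 replace = TRUE) else integer(0)
    span <- 1L + sum(gaps)
    if (span > len) next
    start <- sample.int(len - span + 1L, 1)
    at <- start + c(0L, cumsum(gaps))
    if (any(chars[at] == "P")) next
    chars[at] <- "P"
    placed <- placed + size
  }
  paste(chars, collapse = "")
}

#' Insert a composition-biased 60-mer into a host sequence
#' @noRd
spike_sequence <- function(residues, spike_freqs, spike_length = 60) {
  len <- nchar(residues)
  stopifnot(len >= spike_length)
  start <- sample.int(len - spike_length + 1L, 1)
  spike <- paste(sample(AMINO_ACIDS, spike_length, replace = TRUE,
                        prob = spike_freqs), collapse = "")
  list(residues = paste0(substring(residues, 1, start - 1), spike,
                         substring(residues, start + spike_length)),
       start = start, end = start + spike_length - 1L)
}

#' Generate labelled benchmark sequence sets
#'
#' Emulates the 18-versus-18 benchmark design: positives are background
#' sequences of 60-250 residues carrying one embedded 60-mer whose
#' composition mixes the prion-core and background compositions,
#' `f_mix = contrast * f_core + (1 - contrast) * p`; negatives are pure
#' background. At `contrast = 1` the embedded window is core-like and the
#' classes separate almost completely; at `contrast = 0` the classes are
#' indistinguishable.
#'
#' @param n_pos,n_neg class sizes.
#' @param contrast mixing weight in `[0, 1]`.
#' @param seed integer seed.
#' @param spike_length length of the embedded window.
#' @return List with `positive` and `negative` record collections and a
#'   `truth` data frame (`id`, `start`, `end`).
#' @export
make_benchmark_sets <- function(n_pos = 18, n_neg = 18, contrast = 1,
                                seed = 1, spike_length = 60) {
  if (contrast < 0 || contrast > 1) stop_data("contrast must be in [0, 1]")
  set.seed(seed)
  mix <- contrast * flavor_frequencies("core") +
    (1 - contrast) * background_frequencies()
  bg <- generator_spec("background", min_length = spike_length,
                       max_length = 250)
  pos <- sample_sequences(bg, n_pos, id_prefix = "pos")
  truth <- data.frame(id = pos$id, start = NA_integer_, end = NA_integer_)
  for (i in seq_len(n_pos)) {
    sp <- spike_sequence(pos$residues[i], mix, spike_length)
    pos$residues[i] <- sp$residues
    truth$start[i] <- sp$start
    truth$end[i] <- sp$end
  }
  neg <- sample_sequences(bg, n_neg, id_prefix = "neg")
  list(positive = pos, negative = neg, truth = truth)
}

#' Generate a synthetic proteome with planted prion domains
#'
#' Background proteins of 100-800 residues; `ceiling(prd_fraction * n)` of
#' them (chosen at random) receive one embedded core-composition 60-mer at
#' a uniform random admissible position. Organism labels are assigned
#' round-robin. The returned truth table records every planted domain.
#'
#' @param n_proteins number of proteins.
#' @param prd_fraction fraction of proteins to spike, in `[0, 1]`.
#' @param seed integer seed.
#' @param organisms organism labels cycled over the proteins.
#' @param spike_length length of the embedded domain.
#' @return List with `records` (record collection) and `truth`
#'   (data frame `protein_id`, `start`, `end`, `flavor`).
#' @export
make_proteome <- function(n_proteins = 500, prd_fraction = 0.02, seed = 1,
                          organisms = c("Synthetica primus",
                                        "Synthetica secundus"),
                          spike_length = 60) {
  if (prd_fraction < 0 || prd_fraction > 1)
    stop_data("prd_fraction must be in [0, 1]")
  set.seed(seed)
  bg <- generator_spec("background", min_length = 100, max_length = 800)
  records <- sample_sequences(bg, n_proteins, id_prefix = "prot")
  records$organism <- rep_len(organisms, n_proteins)
  n_spike <- ceiling(prd_fraction * n_proteins)
  truth <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), flavor = character(),
                      stringsAsFactors = FALSE)
  if (n_spike > 0) {
    core <- flavor_frequencies("core")
    chosen <- sort(sample.int(n_proteins, n_spike))
    for (i in chosen) {
      sp <- spike_sequence(records$residues[i], core, spike_length)
      records$residues[i] <- sp$residues
      truth <- rbind(truth, data.frame(protein_id = records$id[i],
                                       start = sp$start, end = sp$end,
                                       flavor = "core",
                                       stringsAsFactors = FALSE))
    }
  }
  list(records = records, truth = truth)
}
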