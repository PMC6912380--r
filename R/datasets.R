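# Benchmark construction: identity filtering, stratified repeated splits,
# and a seeded generator of synthetic labelled windows with the
# position-specific composition biases seen around genuine 4mC sites.

#' Hamming identity between two equal-length windows
#'
#' Fraction of positions at which the two sequences carry the same base.
#' For gap-free fixed-length windows this is the natural sequence-identity
#' measure; it differs from word-filtered global-alignment identities (as
#' computed by clustering tools such as CD-HIT) in ignoring indels, which
#' cannot occur here.
#'
#' @param a,b Sequences of equal length (single strings).
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length",
                                 call. = FALSE)
  ca <- seq_chars(a)
  mean(ca == seq_chars(b))
}

#' Greedy redundancy filtering at an identity cutoff
#'
#' Greedy incremental clustering in input order: a sample is retained iff
#' its identity to every previously retained sample is at most `cutoff`.
#'
#' @param samples A sample `data.frame`.
#' @param cutoff Identity cutoff in `(0, 1]` (e.g. 0.8 within positives, 0.6
#'   within negatives).
#' @return The retained samples, input order preserved.
#' @export
greedy_redundancy_filter <- function(samples, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  keep <- integer(0)
  for (i in seq_len(nrow(samples))) {
    redundant <- FALSE
    for (j in keep) {
      if (pairwise_identity(samples$seq[i], samples$seq[j]) > cutoff) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  samples[keep, , drop = FALSE]
}

#' Remove negatives too similar to any positive
#'
#' Drops every negative whose maximum identity to any positive exceeds
#' `cutoff` (strictly greater than; identity exactly at the cutoff is kept).
#'
#' @param negatives,positives Sample `data.frame`s.
#' @param cutoff Identity cutoff, default 0.6.
#' @return The retained negatives.
#' @export
cross_set_filter <- function(negatives, positives, cutoff = 0.6) {
  keep <- vapply(negatives$seq, function(s) {
    all(vapply(positives$seq, pairwise_identity, numeric(1), a = s) <= cutoff)
  }, logical(1))
  negatives[keep, , drop = FALSE]
}

#' Repeated stratified benchmark/independent splits
#'
#' For each repeat, `floor(frac * n)` samples per class (or the explicit
#' `n_benchmark` per class, e.g. 800 out of 980) are drawn without
#' replacement into the benchmark set; the remainder form the independent
#' set. Splits are deterministic under `seed` and differ across repeats.
#'
#' @param samples Labelled sample `data.frame` (both classes present).
#' @param frac Benchmark fraction in `(0, 1)`, default 0.8.
#' @param repeats Number of repeated splits, default 10.
#' @param seed Integer seed.
#' @param n_benchmark Optional explicit per-class benchmark count overriding
#'   `frac` (either one number or a named vector `c(pos = , neg = )`).
#' @return List of length `repeats`; each element is a list with
#'   `repeat_index`, `benchmark_ids`, `independent_ids` and `seed`.
#' @export
make_splits <- function(samples, frac = 0.8, repeats = 10, seed = 1,
                        n_benchmark = NULL) {
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)", call. = FALSE)
  labs <- samples$label
  if (any(is.na(labs))) stop("all samples must be labelled", call. = FALSE)
  by_class <- split(samples$id, labs)
  if (length(by_class) < 2) stop("both classes must be present", call. = FALSE)
  take <- vapply(names(by_class), function(cl) {
    n <- length(by_class[[cl]])
    k <- if (is.null(n_benchmark)) floor(frac * n)
         else if (!is.null(names(n_benchmark))) n_benchmark[[cl]]
         else n_benchmark[[1]]
    k <- as.integer(k)
    if (k < 1 || k >= n) stop("benchmark count out of range for class ", cl,
                              call. = FALSE)
    k
  }, integer(1))
  lapply(seq_len(repeats), function(r) {
    set.seed(seed + r - 1L)
    bench <- unlist(lapply(names(by_class), function(cl) {
      sample(by_class[[cl]], take[[cl]])
    }), use.names = FALSE)
    list(repeat_index = r,
         benchmark_ids = samples$id[samples$id %in% bench],
         independent_ids = samples$id[!samples$id %in% bench],
         seed = seed + r - 1L)
  })
}

# Motif blocks planted by the synthetic generator: positives mimic the
# C-enrichment upstream (runs at 1-3 and 15-17) and T-enrichment downstream
# (run at 28-32) observed around genuine 4mC sites; negatives carry an
# upstream A run.
SYNTH_MOTIFS <- list(
  pos = list(list(base = "C", at = 1:3), list(base = "C", at = 15:17),
             list(base = "T", at = 28:32)),
  neg = list(list(base = "A", at = 1:3))
)

#' Generate synthetic labelled 41-nt windows
#'
#' Each window is drawn from a uniform ACGT background with the centre
#' forced to `C`. With probability `effect_size`, independently per motif
#' block, class-specific runs are planted: positives get `C` at positions
#' 1-3 and 15-17 and `T` at 28-32; negatives get `A` at positions 1-3.
#' `effect_size = 0` makes the two classes identically distributed;
#' `effect_size = 1` plants every block in every window.
#'
#' @param n_per_class Windows per class.
#' @param effect_size Planting probability in `[0, 1]`; default 0.8.
#' @param seed Integer seed.
#' @return Labelled sample `data.frame` with `n_per_class` positives
#'   followed by `n_per_class` negatives.
#' @export
generate_synthetic <- function(n_per_class, effect_size = 0.8, seed = 1) {
  stopifnot(n_per_class > 0, effect_size >= 0, effect_size <= 1)
  set.seed(seed)
  one_class <- function(cl, n) {
    motifs <- SYNTH_MOTIFS[[cl]]
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(BASES, WINDOW_LEN, replace = TRUE)
      chars[CENTER_POS] <- "C"
      for (m in motifs) {
        if (stats::runif(1) < effect_size) chars[m$at] <- m$base
      }
      paste(chars, collapse = "")
    }, character(1))
    dna_samples(sprintf("%s_%04d", cl, seq_len(n)), seqs, cl)
  }
  rbind(one_class("pos", n_per_class), one_class("neg", n_per_class))
}

#' Subsample a negative pool to balance the classes
#'
#' Seeded uniform sampling without replacement.
#'
#' @param negatives Sample `data.frame`.
#' @param n Number to keep.
#' @param seed Integer seed.
#' @return `n` negatives in original relative order.
#' @export
subsample_negatives <- function(negatives, n, seed = 1) {
  stopifnot(n <= nrow(negatives))
  set.seed(seed)
  idx <- sort(sample(nrow(negatives), n))
  negatives[idx, , drop = FALSE]
}
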