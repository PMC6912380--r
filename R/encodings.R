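# Seven sequence encodings for 41-nt centered-C windows. Each maps one
# window to a fixed-dimension numeric vector; dimensions are part of the
# contract and asserted on every call.

ENCODING_ORDER <- c("Kmer", "M6AMRFS", "RFHC", "EIIP", "BPF", "DPCP", "TPCP")

ENCODING_DIMS <- c(
  Kmer = 1364L, M6AMRFS = 200L, RFHC = 164L, EIIP = 64L, BPF = 164L,
  DPCP = 240L, TPCP = 704L, DPE = 160L, LPDF = 40L, PF28 = 28L
)

# Electron-ion interaction pseudopotentials per nucleotide.
EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

# Chemical-class code: (purine, weak H-bond, amino) indicator triple.
CHEM_CODE <- rbind(
  A = c(1L, 1L, 1L),
  T = c(0L, 1L, 0L),
  G = c(1L, 0L, 0L),
  C = c(0L, 0L, 1L)
)

# 2-bit per-base code underlying the dinucleotide binary encoding; the
# unique concatenative code consistent with AT->(0,0,0,1), AA->(0,0,0,0),
# GG->(1,1,1,1), AC->(0,0,1,0).
DPE_BASE_CODE <- rbind(
  A = c(0L, 0L),
  C = c(1L, 0L),
  G = c(1L, 1L),
  T = c(0L, 1L)
)

# All k-mers over ACGT in lexicographic order (A < C < G < T), cached.
.kmer_cache <- new.env(parent = emptyenv())
kmer_levels <- function(k) {
  key <- as.character(k)
  if (is.null(.kmer_cache[[key]])) {
    .kmer_cache[[key]] <- sort(do.call(
      paste0, expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)))
  }
  .kmer_cache[[key]]
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Overlapping substrings of length k.
seq_kmers <- function(chars, k) {
  n <- length(chars)
  if (k == 1) return(chars)
  vapply(seq_len(n - k + 1),
         function(i) paste(chars[i:(i + k - 1)], collapse = ""), character(1))
}

kmer_freq <- function(chars, k) {
  lv <- kmer_levels(k)
  counts <- tabulate(factor(seq_kmers(chars, k), levels = lv),
                     nbins = length(lv))
  stats::setNames(counts / (length(chars) - k + 1), lv)
}

check_dim <- function(v, name) {
  stopifnot(length(v) == ENCODING_DIMS[[name]])
  v
}

#' k-mer composition encoding
#'
#' Concatenates, for k = 1..5, the frequencies of all 4^k substrings of
#' length k (lexicographic order within each block, count divided by the
#' number of windows `41 - k + 1`), giving 4 + 16 + 64 + 256 + 1024 = 1364
#' values. Each k-block sums to 1.
#'
#' @param seq A valid 41-nt window (a single string).
#' @return Named numeric vector of length 1364.
#' @export
encode_kmer <- function(seq) {
  chars <- seq_chars(seq)
  v <- unlist(lapply(1:5, function(k) kmer_freq(chars, k)))
  check_dim(v, "Kmer")
}

#' Binary profile encoding
#'
#' Position-wise one-hot code in the order A, T, G, C: A -> (1,0,0,0),
#' T -> (0,1,0,0), G -> (0,0,1,0), C -> (0,0,0,1); 4 x 41 = 164 bits with
#' exactly 41 ones.
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length 164.
#' @export
encode_bpf <- function(seq) {
  chars <- seq_chars(seq)
  onehot <- diag(4L)
  rownames(onehot) <- c("A", "T", "G", "C")
  v <- as.vector(t(onehot[chars, , drop = FALSE]))
  names(v) <- paste0("p", rep(seq_along(chars), each = 4), ".",
                     rep(c("A", "T", "G", "C"), length(chars)))
  check_dim(v, "BPF")
}

#' EIIP-weighted trinucleotide frequency encoding
#'
#' For each of the 64 trinucleotides `abc` (lexicographic order) the entry is
#' `(EIIP_a + EIIP_b + EIIP_c) * f_abc`, where `f_abc` is the overlapping
#' trinucleotide count divided by 39 and the per-base electron-ion
#' interaction pseudopotentials are A 0.1260, C 0.1340, G 0.0806, T 0.1335.
#'
#' @inheritParams encode_kmer
#' @param eiip Named per-base pseudopotential table (override for testing).
#' @return Named numeric vector of length 64.
#' @export
encode_eiip <- function(seq, eiip = EIIP_VALUES) {
  stopifnot(setequal(names(eiip), BASES), all(eiip > 0))
  chars <- seq_chars(seq)
  freq <- kmer_freq(chars, 3)
  tri <- names(freq)
  w <- eiip[substr(tri, 1, 1)] + eiip[substr(tri, 2, 2)] +
    eiip[substr(tri, 3, 3)]
  check_dim(stats::setNames(unname(w) * freq, tri), "EIIP")
}

#' Dinucleotide binary encoding
#'
#' Each of the 40 overlapping dinucleotides maps to 4 bits by concatenating
#' the 2-bit per-base codes A -> (0,0), C -> (1,0), G -> (1,1), T -> (0,1)
#' (so e.g. AT -> (0,0,0,1), GG -> (1,1,1,1)); 160 bits total.
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length 160.
#' @export
encode_dpe <- function(seq) {
  chars <- seq_chars(seq)
  n <- length(chars)
  left <- DPE_BASE_CODE[chars[-n], , drop = FALSE]
  right <- DPE_BASE_CODE[chars[-1], , drop = FALSE]
  v <- as.vector(t(cbind(left, right)))
  names(v) <- paste0("d", rep(seq_len(n - 1), each = 4), ".b", rep(1:4, n - 1))
  check_dim(v, "DPE")
}

#' Local position-specific dinucleotide frequency encoding
#'
#' For j = 2..41, entry `f_j` is the number of occurrences of the
#' dinucleotide ending at position j within the length-j prefix, divided by
#' j; 40 values, each in (0, 0.5].
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length 40.
#' @export
encode_lpdf <- function(seq) {
  chars <- seq_chars(seq)
  n <- length(chars)
  di <- paste0(chars[-n], chars[-1])
  v <- vapply(2:n, function(j) sum(di[seq_len(j - 1)] == di[j - 1]) / j,
              numeric(1))
  names(v) <- paste0("f", 2:n)
  check_dim(v, "LPDF")
}

#' Combined dinucleotide binary + local frequency encoding
#'
#' Concatenation of [encode_dpe()] (160 bits) and [encode_lpdf()] (40
#' frequencies): 200 values.
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length 200.
#' @export
encode_m6amrfs <- function(seq) {
  check_dim(c(encode_dpe(seq), encode_lpdf(seq)), "M6AMRFS")
}

#' Ring-function-hydrogen-chemical encoding
#'
#' Per position j, the chemical-class triple of the base (purine {A,G};
#' weak H-bond {A,T}; amino {A,C}: A -> (1,1,1), T -> (0,1,0), G -> (1,0,0),
#' C -> (0,0,1)) followed by the cumulative density `d_j` = count of that
#' base within the length-j prefix divided by j; 4 x 41 = 164 values.
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length 164.
#' @export
encode_rfhc <- function(seq) {
  chars <- seq_chars(seq)
  n <- length(chars)
  dens <- vapply(seq_len(n),
                 function(j) sum(chars[seq_len(j)] == chars[j]) / j,
                 numeric(1))
  v <- as.vector(t(cbind(CHEM_CODE[chars, , drop = FALSE], dens)))
  names(v) <- paste0("p", rep(seq_len(n), each = 4), ".",
                     rep(c("a", "b", "c", "d"), n))
  check_dim(v, "RFHC")
}

#' Dinucleotide physicochemical property encoding
#'
#' Entry (NN, i) is `table[NN, i] * f_NN` with `f_NN` the overlapping
#' dinucleotide count divided by 40; dinucleotide-major, property-minor
#' ordering. With the default 16 x 15 property table this gives 240 values.
#'
#' @inheritParams encode_kmer
#' @param table 16 x 15 numeric matrix, rownames the dinucleotides, values in
#'   `[0, 1]`; defaults to the bundled table (see [default_dinuc_table()]).
#' @return Named numeric vector of length 240.
#' @export
encode_dpcp <- function(seq, table = default_dinuc_table()) {
  check_property_table(table, 2L, 15L)
  freq <- kmer_freq(seq_chars(seq), 2)
  m <- table[names(freq), , drop = FALSE] * freq
  v <- as.vector(t(m))
  names(v) <- paste0(rep(rownames(m), each = ncol(m)), ".",
                     rep(colnames(table), nrow(m)))
  check_dim(v, "DPCP")
}

#' Trinucleotide physicochemical property encoding
#'
#' Entry (NNN, i) is `table[NNN, i] * f_NNN` with `f_NNN` the overlapping
#' trinucleotide count divided by 39; trinucleotide-major ordering. With the
#' default 64 x 11 property table this gives 704 values.
#'
#' @inheritParams encode_kmer
#' @param table 64 x 11 numeric matrix, rownames the trinucleotides, values
#'   in `[0, 1]`; defaults to the bundled table (see [default_trinuc_table()]).
#' @return Named numeric vector of length 704.
#' @export
encode_tpcp <- function(seq, table = default_trinuc_table()) {
  check_property_table(table, 3L, 11L)
  freq <- kmer_freq(seq_chars(seq), 3)
  m <- table[names(freq), , drop = FALSE] * freq
  v <- as.vector(t(m))
  names(v) <- paste0(rep(rownames(m), each = ncol(m)), ".",
                     rep(colnames(table), nrow(m)))
  check_dim(v, "TPCP")
}

check_property_table <- function(table, k, nprop) {
  oligos <- kmer_levels(k)
  if (!is.matrix(table) || ncol(table) != nprop ||
      !setequal(rownames(table), oligos)) {
    stop(sprintf("property table must be %d x %d with all %d-mers as rownames",
                 length(oligos), nprop, k), call. = FALSE)
  }
  if (any(table < 0 | table > 1)) {
    stop("property table values must lie in [0, 1]", call. = FALSE)
  }
  invisible(table)
}

#' Encode a sample set under one encoding
#'
#' @param samples A sample `data.frame` (see [dna_samples()]); sequences are
#'   validated before encoding.
#' @param encoding One of `"Kmer"`, `"M6AMRFS"`, `"RFHC"`, `"EIIP"`,
#'   `"BPF"`, `"DPCP"`, `"TPCP"` (case-insensitive).
#' @param tables Optional list with elements `dinuc` and/or `trinuc`
#'   overriding the bundled physicochemical property tables.
#' @return Numeric matrix, one row per sample (rownames the ids), with an
#'   `encoding` attribute.
#' @export
encode_matrix <- function(samples, encoding, tables = list()) {
  encoding <- match_encoding(encoding)
  bad <- !vapply(samples$seq, is_valid_window, logical(1))
  if (any(bad)) {
    stop("invalid window(s): ", paste(samples$id[bad], collapse = ", "),
         call. = FALSE)
  }
  fn <- switch(encoding,
    Kmer = encode_kmer,
    M6AMRFS = encode_m6amrfs,
    RFHC = encode_rfhc,
    EIIP = encode_eiip,
    BPF = encode_bpf,
    DPCP = function(s) encode_dpcp(s, tables$dinuc %||% default_dinuc_table()),
    TPCP = function(s) encode_tpcp(s, tables$trinuc %||% default_trinuc_table())
  )
  m <- t(vapply(samples$seq, fn, numeric(ENCODING_DIMS[[encoding]]),
                USE.NAMES = FALSE))
  if (nrow(samples) == 0) {
    m <- matrix(numeric(0), 0, ENCODING_DIMS[[encoding]])
  }
  rownames(m) <- samples$id
  colnames(m) <- paste0(encoding, ".", seq_len(ncol(m)))
  attr(m, "encoding") <- encoding
  m
}

match_encoding <- function(encoding) {
  hit <- match(tolower(encoding), tolower(ENCODING_ORDER))
  if (is.na(hit)) {
    stop("unknown encoding '", encoding, "'; expected one of ",
         paste(ENCODING_ORDER, collapse = ", "), call. = FALSE)
  }
  ENCODING_ORDER[hit]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
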