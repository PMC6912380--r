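# Physicochemical property tables for the DPCP/TPCP encodings.
#
# The encodings only require *some* fixed 16 x 15 dinucleotide and 64 x 11
# trinucleotide property matrix with values normalized to [0, 1]; the
# multiplicative structure (property value x oligomer frequency) is what the
# classifiers consume. The bundled defaults are synthetic tables (fixed,
# reproducible placeholder values; see the files' comment headers) so the
# pipeline is self-contained; analyses of real data should pass curated
# property sets via `read_property_table()`.

.table_cache <- new.env(parent = emptyenv())

#' Read a delimited physicochemical property table
#'
#' Expected layout: header row naming the properties, first column the
#' oligomer, remaining columns numeric property values. Values are min-max
#' normalized to `[0, 1]` per property column unless already within range.
#'
#' @param path Path to a tab- or comma-delimited text file (`#` comment lines
#'   are skipped).
#' @param k Oligomer length the table must cover (2 for dinucleotides, 3 for
#'   trinucleotides).
#' @return Numeric matrix with oligomer rownames, rows in lexicographic
#'   order.
#' @export
read_property_table <- function(path, k) {
  if (!file.exists(path)) stop("property table not found: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  oligos <- toupper(as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- oligos
  expected <- kmer_levels(k)
  if (!setequal(oligos, expected) || anyDuplicated(oligos)) {
    stop("property table must list every ", k, "-mer exactly once",
         call. = FALSE)
  }
  if (any(m < 0 | m > 1)) {
    m <- apply(m, 2, function(col) {
      rng <- range(col)
      if (diff(rng) == 0) rep(0.5, length(col)) else (col - rng[1]) / diff(rng)
    })
    rownames(m) <- oligos
  }
  m[expected, , drop = FALSE]
}

bundled_table <- function(file, k) {
  if (is.null(.table_cache[[file]])) {
    path <- system.file("extdata", file, package = "stack4mc")
    if (!nzchar(path)) path <- file.path("inst", "extdata", file)
    .table_cache[[file]] <- read_property_table(path, k)
  }
  .table_cache[[file]]
}

#' Bundled dinucleotide property table (synthetic placeholder)
#'
#' 16 dinucleotides x 15 properties, values in `[0, 1]`. The values are
#' synthetic (fixed pseudo-random draws, min-max normalized) rather than a
#' curated physicochemical set; substitute a curated table with
#' [read_property_table()] for biological interpretation of DPCP features.
#'
#' @return 16 x 15 numeric matrix.
#' @export
default_dinuc_table <- function() {
  bundled_table("dinucleotide_properties_synthetic.tsv", 2L)
}

#' Bundled trinucleotide property table (synthetic placeholder)
#'
#' 64 trinucleotides x 11 properties, values in `[0, 1]`; synthetic in the
#' same sense as [default_dinuc_table()].
#'
#' @return 64 x 11 numeric matrix.
#' @export
default_trinuc_table <- function() {
  bundled_table("trinucleotide_properties_synthetic.tsv", 3L)
}
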