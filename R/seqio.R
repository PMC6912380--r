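WINDOW_LEN <- 41L
CENTER_POS <- 21L
BASES <- c("A", "C", "G", "T")

#' Construct a table of fixed-length DNA samples
#'
#' A sample set is a plain `data.frame` with columns `id` (character),
#' `seq` (character, 41-nt windows over A/C/G/T with a cytosine at the
#' central position 21, 1-based) and `label` (character, `"pos"` for 4mC,
#' `"neg"` for non-4mC, or `NA` when unlabelled).
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of sequences (uppercased on construction).
#' @param label Optional character vector; `"pos"`/`"neg"`/`NA`.
#' @param validate If `TRUE` (default) every sequence must satisfy the window
#'   invariants (length 41, alphabet ACGT, `C` at position 21).
#' @return A `data.frame` with columns `id`, `seq`, `label`.
#' @export
dna_samples <- function(id, seq, label = NA_character_, validate = TRUE) {
  seq <- toupper(as.character(seq))
  out <- data.frame(
    id = as.character(id),
    seq = seq,
    label = normalize_labels(rep_len(as.character(label), length(seq))),
    stringsAsFactors = FALSE
  )
  if (validate) {
    bad <- !vapply(out$seq, is_valid_window, logical(1))
    if (any(bad)) {
      stop("invalid 41-nt centered-C window(s): ",
           paste(out$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  out
}

# Maps common label spellings onto the internal pos/neg vocabulary.
normalize_labels <- function(x) {
  x <- as.character(x)
  lx <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[lx %in% c("pos", "positive", "4mc", "1", "true")] <- "pos"
  out[lx %in% c("neg", "negative", "non-4mc", "non4mc", "0", "false")] <- "neg"
  unknown <- !is.na(x) & is.na(out) & nzchar(x)
  if (any(unknown)) {
    stop("unrecognized label value(s): ",
         paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate a 41-nt centered-cytosine window
#'
#' @param seq A single character string (already uppercased).
#' @return `TRUE` iff `seq` has length 41, uses only A/C/G/T and carries `C`
#'   at 1-based position 21.
#' @export
is_valid_window <- function(seq) {
  nchar(seq) == WINDOW_LEN &&
    !grepl("[^ACGT]", seq) &&
    substr(seq, CENTER_POS, CENTER_POS) == "C"
}

# One-line reason a window fails validation, or NA if valid.
window_violation <- function(seq) {
  if (nchar(seq) != WINDOW_LEN) {
    return(sprintf("length %d != %d", nchar(seq), WINDOW_LEN))
  }
  if (grepl("[^ACGT]", seq)) {
    return("non-ACGT character")
  }
  if (substr(seq, CENTER_POS, CENTER_POS) != "C") {
    return(sprintf("center (position %d) is not C", CENTER_POS))
  }
  NA_character_
}

#' Read 41-nt DNA windows from a FASTA file
#'
#' Headers of the form `>id|label=pos` carry an optional class label; the id
#' is the first whitespace-delimited token with any `|label=` suffix removed.
#' Lowercase letters are uppercased silently. `U` and IUPAC ambiguity codes
#' are rejected, not converted.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) any record violating the window
#'   invariants is an error naming the offending ids; if `FALSE`, offenders
#'   are dropped with a warning and returned in the `skipped` attribute.
#' @return A sample `data.frame` (see [dna_samples()]); in non-strict mode the
#'   attribute `skipped` holds a `data.frame` of dropped ids and reasons.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  first_tok <- sub("\\s.*$", "", headers)
  label <- rep(NA_character_, length(headers))
  has_lab <- grepl("\\|label=", first_tok)
  label[has_lab] <- sub("^.*\\|label=", "", first_tok[has_lab])
  id <- sub("\\|label=.*$", "", first_tok)
  seqs <- toupper(as.character(set))
  reasons <- vapply(seqs, window_violation, character(1), USE.NAMES = FALSE)
  bad <- !is.na(reasons)
  if (strict && any(bad)) {
    stop("invalid record(s) in ", path, ": ",
         paste(sprintf("%s (%s)", id[bad], reasons[bad]), collapse = "; "),
         call. = FALSE)
  }
  out <- dna_samples(id[!bad], seqs[!bad], label[!bad], validate = FALSE)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped during FASTA import", call. = FALSE)
    attr(out, "skipped") <- data.frame(id = id[bad], reason = reasons[bad],
                                       stringsAsFactors = FALSE)
  }
  out
}

#' Write DNA windows to a FASTA file
#'
#' Labels, where present, are appended to the header as `|label=pos` /
#' `|label=neg` so that [read_fasta()] round-trips them.
#'
#' @param samples A sample `data.frame` (see [dna_samples()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(samples, path) {
  headers <- ifelse(is.na(samples$label), samples$id,
                    paste0(samples$id, "|label=", samples$label))
  set <- Biostrings::BStringSet(samples$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column id/label table
#'
#' @param path TSV with columns `id` and `label` (header optional; labels may
#'   be `pos`/`neg`, `4mC`/`non-4mC`, or `1`/`0`).
#' @return Named character vector of `"pos"`/`"neg"` keyed by id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "label"))
  if (identical(tolower(tab$id[1]), "id")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(normalize_labels(tab$label), tab$id)
}

#' Attach labels from an id/label table to a sample set
#'
#' @param samples A sample `data.frame`.
#' @param labels Named `"pos"`/`"neg"` vector as returned by [read_labels()].
#' @return `samples` with its `label` column filled in.
#' @export
apply_labels <- function(samples, labels) {
  hit <- samples$id %in% names(labels)
  samples$label[hit] <- unname(labels[samples$id[hit]])
  samples
}

#' Write a feature matrix as TSV
#'
#' The file carries a header line (`id` then `<encoding>.<index>` column
#' names) and one row per sample; [read_feature_matrix()] restores it
#' losslessly to full double precision.
#'
#' @param m Numeric matrix with rownames (sample ids) and an `encoding`
#'   attribute naming the encoding.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  enc <- attr(m, "encoding")
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0(if (is.null(enc)) "f" else enc, ".",
                                    seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", cols), collapse = "\t"), con)
  if (nrow(m) > 0) {
    body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with sample ids as rownames; the `encoding`
#'   attribute is recovered from the column-name prefix.
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  enc <- unique(sub("\\.[0-9]+$", "", colnames(m)))
  if (length(enc) == 1) attr(m, "encoding") <- enc
  m
}
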