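# Peptide data model and FASTA/CSV readers and writers.

#' @import methods
#' @importFrom stats predict rnorm runif sd quantile
#' @importFrom utils read.csv write.csv head
NULL

#' PeptideSet: labelled peptide sequences
#'
#' The canonical container consumed by every pipeline stage: short peptide
#' sequences over the 20 canonical amino acids, each with an identifier, an
#' optional cancer-type label in 0..8 (`NA` when unknown) and optional
#' free-text provenance.
#'
#' @slot id Character vector of record identifiers.
#' @slot sequence Character vector of validated, uppercase sequences.
#' @slot label Integer vector of cancer-type labels in 0..8 (`NA` allowed).
#' @slot source Character vector of free-text provenance (`NA` allowed).
#'
#' @export
setClass("PeptideSet",
  representation(id = "character", sequence = "character",
                 label = "integer", source = "character"),
  validity = function(object) {
    n <- length(object@id)
    if (length(object@sequence) != n || length(object@label) != n ||
        length(object@source) != n)
      return("id, sequence, label and source must have equal length")
    for (i in seq_len(n)) {
      bad <- validateSequence(object@sequence[i], .quiet = TRUE)
      if (!is.null(attr(bad, "error"))) return(attr(bad, "error"))
    }
    lab <- object@label[!is.na(object@label)]
    if (length(lab) && (any(lab < 0L) || any(lab > 8L)))
      return("labels must lie in 0..8")
    TRUE
  })

#' Construct a PeptideSet
#'
#' Sequences are validated and uppercased; labels, when given, must lie in
#' 0..8 (the nine cancer-type classes).
#'
#' @param id Character identifiers (defaults to `pep1..pepN`).
#' @param sequence Character vector of peptide sequences.
#' @param label Optional integer labels in 0..8; `NA` for unlabelled records.
#' @param source Optional free-text provenance per record.
#' @return A [PeptideSet-class] object.
#' @examples
#' ps <- PeptideSet(sequence = c("LQENDRAT", "itfiqfrmih"), label = c(1L, 0L))
#' peptideSequences(ps)
#' @export
PeptideSet <- function(id = NULL, sequence = character(), label = NULL,
                       source = NULL) {
  n <- length(sequence)
  if (is.null(id)) id <- if (n) paste0("pep", seq_len(n)) else character()
  if (is.null(label)) label <- rep(NA_integer_, n)
  if (is.null(source)) source <- rep(NA_character_, n)
  label <- vapply(label, function(x) {
    if (is.na(x)) return(NA_integer_)
    xi <- suppressWarnings(as.integer(x))
    if (is.na(xi) || xi != as.numeric(x)) stop("label must be an integer in 0..8", call. = FALSE)
    if (xi < 0L || xi > 8L) stop(sprintf("label %d outside the 0..8 cancer-type range", xi), call. = FALSE)
    xi
  }, integer(1))
  sequence <- vapply(as.character(sequence), validateSequence, character(1), USE.NAMES = FALSE)
  new("PeptideSet", id = as.character(id), sequence = sequence,
      label = label, source = as.character(source))
}

#' @describeIn PeptideSet-class Number of peptides.
#' @param x A `PeptideSet`.
#' @export
setMethod("length", "PeptideSet", function(x) length(x@id))

#' Accessors for PeptideSet
#'
#' @param x A [PeptideSet-class].
#' @return `peptideIds`, `peptideSequences`: character vectors;
#'   `peptideLabels`: integer vector with `NA` for unlabelled records.
#' @export
peptideIds <- function(x) x@id

#' @rdname peptideIds
#' @export
peptideSequences <- function(x) x@sequence

#' @rdname peptideIds
#' @export
peptideLabels <- function(x) x@label

#' @rdname peptideIds
#' @export
peptideSources <- function(x) x@source

#' @describeIn PeptideSet-class Subset records.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
  new("PeptideSet", id = x@id[i], sequence = x@sequence[i],
      label = x@label[i], source = x@source[i])
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  cat(sprintf("PeptideSet with %d record%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    lens <- nchar(object@sequence)
    cat(sprintf("  lengths: %d-%d residues\n", min(lens), max(lens)))
    lab <- object@label[!is.na(object@label)]
    if (length(lab)) {
      tb <- table(factor(lab, levels = 0:8))
      cat("  labels: ", paste(sprintf("%s:%d", names(tb)[tb > 0], tb[tb > 0]),
                              collapse = " "), "\n", sep = "")
    } else cat("  labels: none\n")
    cat("  head: ", paste(utils::head(object@sequence, 3), collapse = ", "), "\n", sep = "")
  }
})

#' Validate a peptide sequence
#'
#' Strips whitespace, uppercases, and checks that every character is one of
#' the 20 canonical amino acids. Ambiguity codes (B, J, O, U, X, Z), digits
#' and gap characters are rejected with the offending character and its
#' position named.
#'
#' @param raw Character scalar.
#' @param .quiet Internal: return the error as an attribute instead of
#'   throwing (used by the class validity method).
#' @return The canonical uppercase sequence.
#' @examples
#' validateSequence("itfiqfrmih")
#' @export
validateSequence <- function(raw, .quiet = FALSE) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("sequence must be a single character string", call. = FALSE)
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (!nzchar(s)) {
    msg <- "sequence is empty"
    if (.quiet) return(structure(s, error = msg))
    stop(msg, call. = FALSE)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% AA_ALPHABET_20))
  if (length(bad)) {
    msg <- sprintf("non-canonical residue '%s' at position %d", ch[bad[1]], bad[1])
    if (.quiet) return(structure(s, error = msg))
    stop(msg, call. = FALSE)
  }
  s
}

#' Read peptides from FASTA or CSV
#'
#' FASTA files are parsed with Biostrings; the description after the first
#' whitespace in each header is kept as `source`. CSV files must carry a
#' header with columns `id` and `sequence` and may carry `label` (integers
#' 0..8).
#'
#' @param path File path.
#' @param format `"fasta"` or `"csv"` (default: guessed from the extension).
#' @return A [PeptideSet-class]; input order is preserved.
#' @export
readPeptides <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) "fasta" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "fasta") {
    xs <- Biostrings::readBStringSet(path)
    hdr <- names(xs)
    if (length(hdr) && any(!nzchar(hdr)))
      stop("malformed FASTA: empty header", call. = FALSE)
    id <- sub("\\s.*$", "", hdr)
    src <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
    PeptideSet(id = id, sequence = as.character(xs), source = src)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "sequence") %in% names(df)))
      stop("CSV must have header columns 'id' and 'sequence'", call. = FALSE)
    lab <- if ("label" %in% names(df)) {
      ifelse(is.na(df$label) | df$label == "", NA_integer_,
             suppressWarnings(as.integer(df$label)))
    } else NULL
    if (!is.null(lab) && any(!is.na(df$label) & df$label != "" & is.na(lab)))
      stop("non-integer label in CSV", call. = FALSE)
    PeptideSet(id = df$id, sequence = df$sequence, label = lab,
               source = if ("source" %in% names(df)) df$source else NULL)
  }
}

#' Write peptides to FASTA or CSV
#'
#' Round-trip safe with [readPeptides()] on (id, sequence, label). FASTA is
#' written unwrapped; `source`, when present, becomes the header description.
#' CSV carries columns `id,sequence,label`.
#'
#' @param x A [PeptideSet-class].
#' @param path Output path.
#' @param format `"fasta"` or `"csv"` (default: guessed from the extension).
#' @return `path`, invisibly.
#' @export
writePeptides <- function(x, path, format = c("auto", "fasta", "csv")) {
  stopifnot(is(x, "PeptideSet"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) "fasta" else "csv"
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "fasta") {
    hdr <- ifelse(is.na(x@source), x@id, paste(x@id, x@source))
    xs <- Biostrings::AAStringSet(x@sequence)
    names(xs) <- hdr
    Biostrings::writeXStringSet(xs, path, width = 10000L)
  } else {
    df <- data.frame(id = x@id, sequence = x@sequence,
                     label = ifelse(is.na(x@label), "", as.character(x@label)),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
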