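#' Read peptide sequences with optional labels
#'
#' Reads multi-record FASTA (wrapped lines tolerated; headers become ids) or
#' delimited CSV/TSV files with a header row and a named sequence column;
#' remaining delimited columns are returned as label columns.  Record order is
#' preserved.  Duplicate ids are suffix-deduplicated with a warning.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"`, `"csv"` or `"tsv"`.
#' @param seq_col Name of the sequence column for delimited input.
#' @param validate Validate sequences (non-empty, canonical 20-letter
#'   alphabet)?  Default `TRUE`.
#' @return A tibble with columns `id`, `sequence`, then any label columns.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "csv", "tsv"),
                          seq_col = "sequence", validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pep_abort(sprintf("file not found: %s", path), "pep_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , faa = , fasta = , fas = "fasta",
      csv = "csv",
      tsv = , tab = , txt = "tsv",
      pep_abort(sprintf("cannot infer format from extension '.%s'", ext),
                "pep_config_error"))
  }
  out <- switch(format,
    fasta = read_fasta_tbl(path),
    csv = read_delim_tbl(path, ",", seq_col),
    tsv = read_delim_tbl(path, "\t", seq_col))
  if (anyDuplicated(out$id)) {
    warn("duplicate sequence ids; suffix-deduplicated")
    out$id <- make.unique(out$id, sep = "_")
  }
  if (validate) {
    empty <- which(is.na(out$sequence) | !nzchar(out$sequence))
    if (length(empty) > 0) {
      pep_abort(sprintf("empty sequence at record %d (id '%s')",
                        empty[1], out$id[empty[1]]),
                "pep_input_error")
    }
    out$sequence <- validate_sequences(out$sequence)
  }
  out
}

read_fasta_tbl <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    pep_abort("reading FASTA requires the Biostrings package", "pep_io_error")
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      pep_abort(sprintf("malformed FASTA file %s: %s", path,
                        conditionMessage(e)),
                "pep_io_error", parent = e)
    })
  tibble(id = sub("\\s.*$", "", names(set)),
         sequence = as.character(unname(as.character(set))))
}

read_delim_tbl <- function(path, delim, seq_col) {
  df <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) {
      pep_abort(sprintf("malformed delimited file %s: %s", path,
                        conditionMessage(e)),
                "pep_io_error", parent = e)
    })
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    pep_abort(sprintf("parse error in %s at line %d: %s", path,
                      prob$row[1] + 1L, prob$expected[1]),
              "pep_io_error")
  }
  if (!seq_col %in% names(df)) {
    pep_abort(sprintf("no '%s' column in %s", seq_col, path),
              "pep_config_error")
  }
  ids <- if ("id" %in% names(df)) as.character(df$id) else
    as.character(seq_len(nrow(df)))
  labels <- df[, setdiff(names(df), c(seq_col, "id")), drop = FALSE]
  dplyr::bind_cols(tibble(id = ids, sequence = as.character(df[[seq_col]])),
                   labels)
}

#' Write a feature matrix with a configuration sidecar
#'
#' Writes the matrix as MatrixMarket (`.mtx`, sparse) or dense CSV, a row
#' index file mapping row numbers to sequence ids, and a JSON sidecar
#' recording the fingerprint configuration.
#'
#' @param features A `pep_features` object from [featurize()].
#' @param prefix Output path prefix; files `<prefix>.mtx`/`.csv`,
#'   `<prefix>.ids.csv` and `<prefix>.json` are written.
#' @param format `"mtx"` or `"csv"`.
#' @return The paths written, invisibly.
#' @export
write_features <- function(features, prefix, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(features, "pep_features"))
  mat_path <- paste0(prefix, ".", format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(features$matrix, "generalMatrix"), mat_path)
  } else {
    readr::write_csv(as.data.frame(as.matrix(features$matrix)), mat_path,
                     col_names = FALSE)
  }
  ids_path <- paste0(prefix, ".ids.csv")
  readr::write_csv(tibble(row = seq_along(features$ids), id = features$ids),
                   ids_path)
  cfg_path <- paste0(prefix, ".json")
  jsonlite::write_json(unclass(features$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(mat_path, ids_path, cfg_path))
}
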