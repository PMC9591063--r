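# Delimited text (CSV/TSV, auto-detected by extension or `sep`) is the
# canonical interchange format; a minimal binary container (".omx":
# magic "OMX1", int32 N, int32 M, doubles column-major, little-endian)
# is offered for large sample sizes.

#' Read a signal matrix from disk
#'
#' @param path CSV/TSV file (one channel per row or per column) or a
#'   binary `.omx` container.
#' @param orientation `"rows"` if channels are stored in rows (default),
#'   `"columns"` if each column is a channel (the matrix is transposed on
#'   read; binary containers are always channels-in-rows).
#' @param sep field separator; default inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return validated N x M matrix, channels in rows.
#' @export
read_signal_matrix <- function(path, orientation = c("rows", "columns"),
                               sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    oi_stop("orderica_data_error", "file not found: %s", path)
  if (grepl("\\.omx$", path)) {
    m <- read_matrix_bin(path)
  } else {
    if (file.size(path) == 0L)
      oi_stop("orderica_data_error", "empty file: %s", path)
    if (is.null(sep))
      sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
    nf <- count.fields(path, sep = sep)
    if (length(unique(nf)) != 1L)
      oi_stop("orderica_data_error",
              "ragged rows in %s: field counts %s", path,
              paste(unique(nf), collapse = ", "))
    df <- read.table(path, sep = sep, header = FALSE,
                     strip.white = TRUE)
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
      oi_stop("orderica_data_error",
              "non-numeric cells in %s (column(s) %s)", path,
              paste(which(bad), collapse = ", "))
    m <- as.matrix(df)
    dimnames(m) <- NULL
    if (orientation == "columns") m <- t(m)
  }
  as_signal_matrix(m, arg = path)
}

#' Write a signal matrix to disk
#'
#' @param x N x M matrix, channels in rows.
#' @param path output file; `.omx` selects the binary container, anything
#'   else delimited text.
#' @param orientation store channels in `"rows"` (default) or `"columns"`
#'   (text formats only).
#' @param sep field separator (default by extension, as in
#'   [read_signal_matrix()]).
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path, orientation = c("rows", "columns"),
                                sep = NULL) {
  orientation <- match.arg(orientation)
  if (grepl("\\.omx$", path)) {
    write_matrix_bin(x, path)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
    m <- if (orientation == "columns") t(x) else x
    write_text_matrix(m, path, sep)
  }
  invisible(path)
}

# full-precision deterministic text formatting
write_text_matrix <- function(m, path, sep) {
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(lines, path)
}

read_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "OMX1"))
    oi_stop("orderica_data_error", "%s is not an OMX1 matrix container", path)
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", dims[1L] * dims[2L], endian = "little")
  matrix(vals, dims[1L], dims[2L])
}

write_matrix_bin <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("OMX1", con, eos = NULL, useBytes = TRUE)
  writeBin(c(nrow(m), ncol(m)), con, size = 4L, endian = "little")
  writeBin(as.numeric(m), con, endian = "little")
  invisible(path)
}

#' Save / load a whitening model as a JSON sidecar
#'
#' @param model a `"whitening_model"` from [whiten()].
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_whitening_model <- function(model, path) {
  stopifnot(inherits(model, "whitening_model"))
  jsonlite::write_json(
    list(mean = model$mean,
         transform = model$transform,
         inverse_transform = model$inverse_transform),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_whitening_model
#' @export
read_whitening_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 transform = as.matrix(obj$transform),
                 inverse_transform = as.matrix(obj$inverse_transform)),
            class = "whitening_model")
}

#' Write an ordering ICA fit to a directory
#'
#' Emits deterministic, full-precision delimited text plus a JSON metadata
#' file: `W.csv` (separating matrix, whitened space), `unmixing.csv` and
#' `mixing.csv` (original signal space), `components.csv` (per-component
#' kurtosis, score and convergence count) and `meta.json` (seed, L, K,
#' eps).  Two runs with the same seed produce byte-identical files.
#'
#' @param result an [ordering_ica()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_separation_result <- function(result, dir) {
  stopifnot(inherits(result, "ordering_ica"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    oi_stop("orderica_data_error", "cannot create output directory %s", dir)
  write_text_matrix(result$w_matrix, file.path(dir, "W.csv"), ",")
  write_text_matrix(result$unmixing, file.path(dir, "unmixing.csv"), ",")
  write_text_matrix(result$mixing_estimate, file.path(dir, "mixing.csv"), ",")
  comp <- cbind(result$alphas, result$upsilons,
                result$run_meta$convergence_counts)
  writeLines(c("kurtosis,upsilon,n_converged",
               apply(comp, 1L, function(r)
                 paste(sprintf("%.17g", r), collapse = ","))),
             file.path(dir, "components.csv"))
  meta <- result$run_meta
  jsonlite::write_json(
    list(seed = meta$seed, L = meta$L, K = meta$K, eps = meta$eps,
         convergence_counts = meta$convergence_counts),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(result$whitening))
    write_whitening_model(result$whitening, file.path(dir, "whitening.json"))
  invisible(dir)
}

#' Read back a fit written by [write_separation_result()]
#'
#' Restores the fields needed for stability analysis (`w_matrix`,
#' `alphas`, `upsilons`, `run_meta`); the recovered sources are not stored
#' on disk.
#'
#' @param dir directory written by [write_separation_result()].
#' @return object of class `"ordering_ica"` (without `sources`).
#' @export
read_separation_result <- function(dir) {
  wf <- file.path(dir, "W.csv")
  if (!file.exists(wf))
    oi_stop("orderica_data_error", "%s does not contain a fit (no W.csv)", dir)
  w <- as.matrix(read.table(wf, sep = ","))
  dimnames(w) <- NULL
  comp <- read.table(file.path(dir, "components.csv"), sep = ",",
                     header = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  model <- if (file.exists(file.path(dir, "whitening.json")))
    read_whitening_model(file.path(dir, "whitening.json")) else NULL
  structure(
    list(w_matrix = w, alphas = comp$kurtosis, upsilons = comp$upsilon,
         unmixing = as.matrix(read.table(file.path(dir, "unmixing.csv"),
                                         sep = ",")),
         mixing_estimate = as.matrix(read.table(file.path(dir, "mixing.csv"),
                                                sep = ",")),
         whitening = model,
         run_meta = list(seed = meta$seed, L = meta$L, K = meta$K,
                         eps = meta$eps,
                         convergence_counts = meta$convergence_counts)),
    class = "ordering_ica")
}
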