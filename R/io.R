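#' Read a multi-page TIFF stack
#'
#' @param path TIFF file with one page per optical section.
#' @return numeric (y, x, z) array of raw sample values.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("malformed TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  array(as.numeric(unlist(pages)), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write an integer-valued stack as 16-bit multi-page TIFF
#'
#' Values are rounded and clipped to [0, 65535]; the round trip through
#' [read_stack()] is lossless for data already in that range.
#'
#' @param stack (y, x, z) array or a matrix (single page).
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(z)
    pmin(pmax(round(stack[, , z]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read a 16-bit label image
#'
#' @param labels integer matrix (0 = background, labels <= 65535).
#' @param path TIFF file.
#' @export
write_labels <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stop("malformed TIFF: ", path,
                                         " (", conditionMessage(e), ")"))
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

#' Read a CSV table with schema check
#'
#' Always parses with a period decimal separator and a mandatory header row.
#'
#' @param path CSV file.
#' @param required_cols columns that must be present.
#' @return tibble.
#' @export
read_table <- function(path, required_cols = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed CSV: ", path,
                                          " (", conditionMessage(e), ")"))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write a CSV table at full precision
#'
#' @param df data frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a frozen run-configuration snapshot
#'
#' @param config named list (must include the seed).
#' @param path JSON file.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("micromorph"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
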