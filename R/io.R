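# Readers/writers. Label masks travel as plain-text PGM (P2), a standard
# single-channel integer image format that needs no binary image library;
# tables travel as CSV with stable headers.

#' Write a label mask as plain-text PGM (P2)
#'
#' @param mask integer matrix with values in `MASK_CODES`.
#' @param path output path (conventionally `.pgm`).
#' @export
write_label_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mask), nrow(mask)), "3"), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(mask, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a label mask from plain-text PGM
#'
#' @param path path to a P2 PGM file written by [write_label_mask()].
#' @return integer matrix validated against the code set `{0, 1, 2, 3}`.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) abort_glom(paste0("no such file: ", path), "glomRPS_io")
  if (file.size(path) == 0) abort_glom(paste0("empty file: ", path), "glomRPS_io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 3 || lines[1] != "P2") {
    abort_glom(paste0("not a plain-text (P2) PGM file: ", path), "glomRPS_io")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(dims) != 2 || any(is.na(dims))) {
    abort_glom(paste0("malformed PGM header: ", path), "glomRPS_io")
  }
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2]) {
    abort_glom(paste0("PGM pixel count does not match header: ", path), "glomRPS_io")
  }
  mask <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  validate_mask(mask)
}

#' Write a cells table (cell_type, row, col) as CSV
#' @param cells data.frame with columns `cell_type`, `row`, `col` and
#'   optionally `patient_id`, `glom_id`.
#' @param path output path.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cells table written by [write_cells_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cells_csv <- function(path) {
  if (!file.exists(path)) abort_glom(paste0("no such file: ", path), "glomRPS_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "row", "col")
  if (!all(need %in% names(df))) {
    abort_glom(paste0("cells CSV must have columns: ", paste(need, collapse = ", ")),
               "glomRPS_io")
  }
  df
}

# fixed-precision numeric formatting so reruns diff clean
format_table <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "g"))
  df
}

write_table_csv <- function(df, path, digits = 6) {
  utils::write.csv(format_table(df, digits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
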