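#' Write a mutation landscape to CSV
#'
#' Writes the landscape with exactly the columns `mutation, position, aa_wt,
#' aa_mt, gap_freq, wt_freq, mt_freq, rsa, lor, rsalor`, numeric values at 6
#' significant digits, empty cells for missing values, and an optional
#' `#`-prefixed comment block echoing the run configuration. The output is
#' byte-deterministic: identical inputs and settings give identical files.
#'
#' @param landscape An `rsalor_landscape` (or any data frame with the schema
#'   columns).
#' @param path Output file path.
#' @param comments Optional character vector written as `# `-prefixed header
#'   lines before the CSV header.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path, comments = NULL) {
  cols <- c("mutation", "position", "aa_wt", "aa_mt", "gap_freq",
            "wt_freq", "mt_freq", "rsa", "lor", "rsalor")
  missing_cols <- setdiff(cols, names(landscape))
  if (length(missing_cols) > 0) {
    abort(paste0("landscape lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      out <- trimws(formatC(x, digits = 6, format = "g"))
      out[out == "-0"] <- "0"
      out[is.na(x)] <- ""
      out
    } else {
      out <- as.character(x)
      out[is.na(x)] <- ""
      out
    }
  }
  body <- vapply(landscape[cols], fmt, character(nrow(landscape)))
  if (nrow(landscape) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(
    if (length(comments) > 0) paste0("# ", comments),
    paste(cols, collapse = ","),
    apply(body, 1L, paste, collapse = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Export a position map as TSV
#'
#' Writes the structure-to-target mapping table (position, structure residue
#' key, amino acids, mismatch flag) so homolog templates can be audited.
#'
#' @param map An `rsalor_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "rsalor_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
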