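#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows distinct n_distinct
#' @import ggplot2
NULL

# Accept either a file path or literal text (single string with newlines, or a
# character vector of lines); return a character vector of lines.
input_lines <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

input_text <- function(x) paste(input_lines(x), collapse = "\n")

is_go_id <- function(x) grepl("^GO:[0-9]{7}$", x)

# Stable seed derivation: one named substream per generation stage, so adding
# stages never perturbs earlier draws.  All derived seeds stay below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

write_lines_file <- function(lines, file) {
  con <- base::file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(file)
}

# TSV writers for reports: stable column order, no quoting surprises.
write_tsv_report <- function(x, file) {
  x <- as.data.frame(x)
  for (i in seq_along(x)) if (is.list(x[[i]])) {
    x[[i]] <- vapply(x[[i]], function(v) paste(v, collapse = ","), character(1))
  }
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(file)
}

write_json_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
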