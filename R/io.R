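#' Read a metabolome matrix from TSV/CSV
#'
#' Expects a header row, `sample_id` as the first column, one metabolite per
#' remaining column, and empty cells marking missing values (the mask is
#' reconstructed from them). The delimiter follows the file extension
#' (`.csv` comma, otherwise tab); numbers are parsed with the dot decimal
#' separator regardless of locale.
#'
#' @param path File path.
#' @param design Optional design table (data frame or TSV/CSV path) with a
#'   `sample_id` column to attach.
#' @return A [metab_matrix()] on the raw scale.
#' @export
read_matrix <- function(path, design = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("Matrix file needs a header and at least one row.")
  cells <- strsplit(lines, delim, fixed = TRUE)
  # strsplit drops a single trailing empty field; restore it when the raw
  # line ends with the delimiter
  width <- length(cells[[1]])
  ends_delim <- endsWith(lines, delim)
  cells <- Map(function(x, pad) if (pad) c(x, "") else x, cells, ends_delim)
  lens <- lengths(cells)
  if (any(lens != width)) {
    bad <- which(lens != width)[1]
    abort(sprintf("Ragged row %d: %d fields, expected %d.",
                  bad, lens[bad], width))
  }
  header <- cells[[1]]
  if (header[1] != "sample_id") {
    abort("First column must be named 'sample_id'.")
  }
  ids <- vapply(cells[-1], `[[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sample_id: '%s'.", ids[duplicated(ids)][1]))
  }
  mets <- header[-1]
  n <- length(ids); p <- length(mets)
  values <- matrix(NA_real_, n, p, dimnames = list(ids, mets))
  mask <- matrix(FALSE, n, p, dimnames = list(ids, mets))
  for (i in seq_len(n)) {
    row <- cells[[i + 1]][-1]
    empty <- row == ""
    mask[i, empty] <- TRUE
    if (any(!empty)) {
      num <- suppressWarnings(as.numeric(row[!empty]))
      if (anyNA(num)) {
        bad <- which(!empty)[which(is.na(num))[1]]
        abort(sprintf("Non-numeric value '%s' at sample '%s', column '%s'.",
                      row[bad], ids[i], mets[bad]))
      }
      values[i, !empty] <- num
    }
  }
  des <- if (is.null(design)) NULL else if (is.character(design)) {
    readr::read_delim(design,
                      delim = if (grepl("\\.csv$", design, TRUE)) "," else "\t",
                      show_col_types = FALSE, progress = FALSE)
  } else design
  if (!is.null(des)) {
    des <- tibble::as_tibble(des)
    des <- des[match(ids, des$sample_id), ]
  }
  metab_matrix(values, mask = mask, design = des, scale = "raw")
}

#' Write a metabolome matrix to TSV/CSV
#'
#' Inverse of [read_matrix()]: masked cells are written as empty fields,
#' numbers with full (round-trippable) precision.
#'
#' @param matrix A [metab_matrix()].
#' @param path Output path (`.csv` switches to comma delimiter).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "metab_matrix"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- matrix$values
  chr <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  chr[matrix$mask] <- ""
  lines <- c(
    paste(c("sample_id", colnames(v)), collapse = delim),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], chr[i, ]), collapse = delim)
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Serialise ground truth to JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(true_beta = as.list(truth$true_beta),
         intercept = truth$intercept, noise_sd = truth$noise_sd,
         condition_shift = truth$condition_shift,
         missing_rates = as.list(truth$missing_rates),
         block_assignment = as.list(truth$block_assignment),
         target_r2 = truth$target_r2, seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
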