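#' Read a peak list from TSV or Sparky format
#'
#' TSV is the package's canonical interchange: a header line naming the
#' columns (`residue`, `shift_ppm`, `coupling_khz` for SLF lists;
#' `residue`, `h_ppm`, `n_ppm` for H-N lists), tab-separated values.
#' Sparky assignment lists (`Y47N-H  121.3  8.02`: one-letter code, residue
#' number, atom pair, then the w1/w2 frequencies with 15N first) are
#' supported read-only for H-N peaks.
#'
#' @param path File path.
#' @param dialect `"tsv"`, `"sparky"`, or `"auto"` (sniffed: a first line
#'   starting with an assignment-like token is Sparky).
#' @return A tibble typed by content: SLF columns or H-N columns.
#' @export
read_peaklist <- function(path, dialect = c("auto", "tsv", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty peak list: %s", path))

  if (dialect == "auto") {
    first <- trimws(lines[1])
    dialect <- if (grepl("^[A-Za-z]{1,3}\\d+[A-Za-z]*N-H", first) ||
      grepl("^Assignment", first, ignore.case = TRUE)) {
      "sparky"
    } else {
      "tsv"
    }
  }

  if (dialect == "sparky") {
    return(parse_sparky(lines, path))
  }

  df <- readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    show_col_types = FALSE, progress = FALSE
  )
  hn <- all(c("h_ppm", "n_ppm") %in% names(df))
  slf <- all(c("shift_ppm", "coupling_khz") %in% names(df))
  if (!hn && !slf) {
    abort(sprintf(
      "TSV peak list %s must have columns h_ppm/n_ppm or shift_ppm/coupling_khz",
      path
    ))
  }
  bad <- if (hn) which(!is.finite(df$h_ppm) | !is.finite(df$n_ppm)) else {
    which(!is.finite(df$shift_ppm) | !is.finite(df$coupling_khz))
  }
  if (length(bad) > 0) {
    abort(sprintf("malformed value in %s at data line %d", path, bad[1]))
  }
  for (col in c("residue", "component")) {
    if (col %in% names(df) && all(is.na(df[[col]]) | df[[col]] == round(df[[col]]))) {
      df[[col]] <- as.integer(df[[col]])
    }
  }
  as_tibble(df)
}

parse_sparky <- function(lines, path) {
  if (grepl("^Assignment", trimws(lines[1]), ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(f) < 3) {
      abort(sprintf("malformed Sparky line %d in %s: '%s'", i, path, line))
    }
    m <- regmatches(f[1], regexec("^([A-Za-z])(\\d+)N-H$", f[1]))[[1]]
    if (length(m) == 0) {
      abort(sprintf(
        "malformed Sparky assignment at line %d in %s: '%s'", i, path, f[1]
      ))
    }
    w <- suppressWarnings(as.numeric(f[2:3]))
    if (anyNA(w)) {
      abort(sprintf("malformed Sparky frequencies at line %d in %s", i, path))
    }
    tibble(
      residue = as.integer(m[3]), aa = toupper(m[2]),
      n_ppm = w[1], h_ppm = w[2]
    )
  })
  dplyr::bind_rows(rows) |> dplyr::select("residue", "aa", "h_ppm", "n_ppm")
}

#' Write a peak list as TSV
#'
#' Values are written with fixed precision (6 significant decimal digits)
#' so identical data round-trips byte-stably across platforms.
#'
#' @param peaks Data frame (H-N or SLF peak columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0) abort("`peaks` must be a non-empty data frame")
  out <- peaks
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, format = "f", digits = 6))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
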