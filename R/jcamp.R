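# Minimal JCAMP-DX support: plain AFFN "(X++(Y..Y))" and "(XY..XY)" tables
# only (no ASDF/DIFDUP compression, no compound files). Covers the simple
# exports common on EPR and FT-IR instruments; delimited CSV remains the
# primary interchange format.

#' Read a simple JCAMP-DX spectrum
#'
#' Supports single-block files whose `##XYDATA=(X++(Y..Y))` or
#' `##XYPOINTS=(XY..XY)` tables are in plain AFFN (space/comma separated
#' numbers). `XFACTOR`/`YFACTOR` and `DELTAX` are honoured.
#'
#' @param path File path.
#' @return List with `x`, `y` and `labels` (the header records).
#' @export
read_jdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labels <- list()
  data_start <- NA_integer_; data_mode <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        key <- toupper(gsub("[ -]", "", substr(ln, 3, eq - 1)))
        val <- trimws(substr(ln, eq + 1, nchar(ln)))
        if (key %in% c("XYDATA", "XYPOINTS")) {
          data_start <- i + 1L
          data_mode <- if (grepl("X\\+\\+", val)) "xpp" else "xy"
          break
        }
        labels[[key]] <- val
      }
    }
  }
  if (is.na(data_start)) stop("no ##XYDATA/##XYPOINTS record found")
  num <- function(key, default) {
    v <- labels[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  rows <- lines[seq(data_start, length(lines))]
  rows <- rows[!startsWith(trimws(rows), "##")]
  toks <- lapply(rows, function(r) {
    r <- gsub("[,;]", " ", r)
    as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1]])
  })
  toks <- toks[vapply(toks, function(t) length(t) > 0 && all(is.finite(t)), logical(1))]
  if (identical(data_mode, "xy")) {
    all_nums <- unlist(toks)
    if (length(all_nums) %% 2L != 0L) stop("odd token count in (XY..XY) table")
    x <- all_nums[c(TRUE, FALSE)] * xf
    y <- all_nums[c(FALSE, TRUE)] * yf
  } else {
    x <- c(); y <- c()
    for (t in toks) {
      x0 <- t[1]; ys <- t[-1]
      dx <- num("DELTAX", {
        npt <- num("NPOINTS", NA)
        (num("LASTX", NA) - num("FIRSTX", NA)) / (npt - 1)
      })
      x <- c(x, (x0 + dx * (seq_along(ys) - 1L)) * xf)
      y <- c(y, ys * yf)
    }
  }
  o <- order(x)
  list(x = x[o], y = y[o], labels = labels)
}

#' Write a simple JCAMP-DX spectrum
#'
#' Emits a single-block AFFN `##XYPOINTS=(XY..XY)` file readable by
#' [read_jdx()] and by common instrument software.
#'
#' @param x,y Numeric vectors of equal length.
#' @param path Output file path.
#' @param title Title record.
#' @param xunits,yunits Unit records.
#' @return The path, invisibly.
#' @export
write_jdx <- function(x, y, path, title = "radstab export",
                      xunits = "ARBITRARY", yunits = "ARBITRARY") {
  stopifnot(length(x) == length(y))
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=SPECTRUM",
    paste0("##XUNITS=", xunits),
    paste0("##YUNITS=", yunits),
    "##XFACTOR=1", "##YFACTOR=1",
    paste0("##FIRSTX=", format(x[1], digits = 12)),
    paste0("##LASTX=", format(x[length(x)], digits = 12)),
    paste0("##NPOINTS=", length(x)),
    "##XYPOINTS=(XY..XY)")
  body <- paste(format(x, digits = 10, trim = TRUE),
                format(y, digits = 10, trim = TRUE), sep = " ")
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}
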