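# Minimal FCS 3.0/3.1 support: list-mode floating-point files only, which is
# what modern acquisition software exports and what the synthetic fixture
# writer produces. Integer data ($DATATYPE I), correlated/uncorrelated
# histogram modes and keyword preservation on write are out of scope.

#' Read an FCS 3.0/3.1 file
#'
#' Parses the TEXT segment for the required keywords (`$TOT`, `$PAR`,
#' `$DATATYPE`, `$BYTEORD`, `$MODE`, `$PnN`/`$PnS`) and reads the DATA
#' segment. Only list mode (`$MODE L`) with float (`F`) or double (`D`)
#' storage is supported; other data types raise an unsupported-format
#' error. No transform is applied to the values.
#'
#' @param path path to an FCS file.
#' @return expression matrix with `$TOT` cells and `$PAR` markers; marker
#'   names are taken from `$PnS` when present, else `$PnN`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (size < 58) stop("corrupt FCS file: truncated header", call. = FALSE)
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version, call. = FALSE)
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_start <- off(11L, 18L)
  text_end   <- off(19L, 26L)
  data_start <- off(27L, 34L)
  data_end   <- off(35L, 42L)
  if (anyNA(c(text_start, text_end)) || text_start < 58 ||
      text_end <= text_start || text_end > size) {
    stop("corrupt FCS file: TEXT segment offsets inconsistent with file size",
         call. = FALSE)
  }
  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kv <- stats::setNames(parts[c(FALSE, TRUE)], toupper(parts[c(TRUE, FALSE)]))
  kw <- function(key) if (key %in% names(kv)) kv[[key]] else NULL
  need <- c("$TOT", "$PAR", "$DATATYPE", "$BYTEORD")
  missing_kw <- setdiff(need, names(kv))
  if (length(missing_kw)) {
    stop("corrupt FCS file: missing keyword(s) ",
         paste(missing_kw, collapse = ", "), call. = FALSE)
  }
  if (!is.null(kw("$MODE")) && kw("$MODE") != "L") {
    stop("unsupported FCS $MODE '", kw("$MODE"), "': only list mode is read",
         call. = FALSE)
  }
  dtype <- kw("$DATATYPE")
  if (!dtype %in% c("F", "D")) {
    stop("unsupported FCS $DATATYPE '", dtype,
         "': only floating-point data (F, D) is read", call. = FALSE)
  }
  endian <- switch(kw("$BYTEORD"),
                   "1,2,3,4" = "little",
                   "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD '", kw("$BYTEORD"), "'",
                        call. = FALSE))
  tot <- as.integer(kw("$TOT"))
  par <- as.integer(kw("$PAR"))
  if (anyNA(c(tot, par)) || tot < 1L || par < 1L) {
    stop("corrupt FCS file: invalid $TOT/$PAR", call. = FALSE)
  }
  if (is.na(data_start) || data_start == 0) {
    data_start <- suppressWarnings(as.numeric(kw("$BEGINDATA")))
    data_end <- suppressWarnings(as.numeric(kw("$ENDDATA")))
  }
  bytes <- if (dtype == "F") 4L else 8L
  expected <- as.numeric(tot) * par * bytes
  if (anyNA(c(data_start, data_end)) || data_end > size ||
      data_end - data_start + 1 != expected) {
    stop("corrupt FCS file: DATA segment offsets inconsistent with file size",
         call. = FALSE)
  }
  seek(con, data_start)
  v <- readBin(con, what = "double", n = tot * par, size = bytes,
               endian = endian)
  if (length(v) < tot * par) {
    stop("corrupt FCS file: truncated DATA segment", call. = FALSE)
  }
  markers <- vapply(seq_len(par), function(i) {
    s <- kw(sprintf("$P%dS", i))
    n <- kw(sprintf("$P%dN", i))
    if (!is.null(s) && nzchar(s)) s
    else if (!is.null(n) && nzchar(n)) n
    else sprintf("P%d", i)
  }, character(1L))
  # list mode stores parameters fastest, i.e. cell-major order
  expression_matrix(matrix(v, nrow = tot, ncol = par, byrow = TRUE), markers)
}

#' Write a minimal FCS 3.0 file
#'
#' Writes an expression matrix as a single-dataset, list-mode FCS 3.0 file
#' with 32-bit little-endian floats. Intended for fixtures and interchange
#' with the reader; acquisition keywords beyond the required set are not
#' emitted.
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path) {
  x <- expression_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  rng <- max(1, ceiling(max(abs(x))))
  kws <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
           "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
           "$BEGINDATA", "%BEGIN%", "$ENDDATA", "%END%",
           "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
           "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kws <- c(kws,
             sprintf("$P%dN", i), colnames(x)[i],
             sprintf("$P%dB", i), "32",
             sprintf("$P%dE", i), "0,0",
             sprintf("$P%dR", i), as.character(rng))
  }
  if (any(grepl("/", kws, fixed = TRUE))) {
    stop("marker names must not contain the TEXT delimiter '/'", call. = FALSE)
  }
  build_text <- function(begin, end) {
    vals <- kws
    vals[vals == "%BEGIN%"] <- sprintf("%010d", begin)
    vals[vals == "%END%"] <- sprintf("%010d", end)
    paste0("/", paste(vals, collapse = "/"), "/")
  }
  text_start <- 58L
  text0 <- build_text(0L, 0L) # fixed width: offsets do not change the length
  text_end <- text_start + nchar(text0, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  if (data_end > 99999999) {
    stop("dataset too large for the minimal FCS writer", call. = FALSE)
  }
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(build_text(data_start, data_end), con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(unclass(x))), con, size = 4L, endian = "little")
  invisible(path)
}
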