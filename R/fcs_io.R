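#' Read an FCS 3.0/3.1 list-mode file (minimal parser)
#'
#' Supports list-mode ($MODE L) files with float, double or integer data,
#' either byte order, and converts log-amplified channels to linear scale
#' using the $PnE keyword: for \code{$PnE = "d,f"} with d > 0 the stored
#' value x on a channel of range R maps to \code{f * 10^(d * x / R)}
#' (f = 0 is treated as f = 1, as the standard prescribes). No compensation
#' or gating is applied. This is intentionally a small reader for
#' interchange, not a full cytometry stack.
#'
#' @param path an FCS file.
#' @return a data.frame with one column per parameter ($PnN names).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("unsupported FCS version: %s", version)
  off <- function(i) {
    s <- substr(header, 11 + (i - 1) * 8, 10 + i * 8)
    as.numeric(trimws(s))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)

  seek(con, text_start)
  text_raw <- readBin(con, "raw", text_end - text_start + 1)
  txt <- rawToChar(text_raw)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(as.list(vals), toupper(trimws(keys)))

  get_kw <- function(k, default = NULL) {
    v <- kw[[toupper(k)]]
    if (is.null(v)) default else v
  }
  if (data_start == 0) data_start <- as.numeric(get_kw("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(get_kw("$ENDDATA"))
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  dtype <- get_kw("$DATATYPE")
  mode <- get_kw("$MODE", "L")
  if (!identical(mode, "L")) stopf("only list-mode ($MODE L) supported")
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  seek(con, data_start)
  n_values <- n_par * n_tot
  dat <- switch(dtype,
    "F" = readBin(con, "numeric", n_values, size = 4, endian = endian),
    "D" = readBin(con, "numeric", n_values, size = 8, endian = endian),
    "I" = {
      bits <- as.integer(get_kw("$P1B", "32"))
      readBin(con, "integer", n_values, size = bits / 8, endian = endian,
              signed = bits > 16)
    },
    stopf("unsupported $DATATYPE: %s", dtype))
  if (length(dat) < n_values) stopf("truncated FCS data segment")
  m <- matrix(dat, nrow = n_tot, ncol = n_par, byrow = TRUE)

  nm <- vapply(seq_len(n_par), function(i)
    get_kw(sprintf("$P%dN", i), sprintf("P%d", i)), character(1))
  colnames(m) <- nm
  # log-amplification to linear
  for (i in seq_len(n_par)) {
    pe <- get_kw(sprintf("$P%dE", i), "0,0")
    df <- as.numeric(strsplit(pe, ",")[[1]])
    if (length(df) == 2 && df[1] > 0) {
      r <- as.numeric(get_kw(sprintf("$P%dR", i), "1024"))
      f2 <- if (df[2] == 0) 1 else df[2]
      m[, i] <- f2 * 10^(df[1] * m[, i] / r)
    }
  }
  as.data.frame(m, check.names = FALSE)
}

#' Write a minimal FCS 3.0 file (testing aid)
#'
#' Emits a float32 little-endian list-mode file, optionally storing chosen
#' channels log-amplified (so that [read_fcs()]'s linearization can be
#' round-trip tested). Not a production writer.
#'
#' @param data numeric matrix or data.frame, one column per channel.
#' @param path output path.
#' @param log_channels character vector of column names to store on a log
#'   scale with \code{$PnE = "4,1"} over range \code{range}.
#' @param range channel range R used for log amplification.
#' @return \code{path}, invisibly.
#' @export
write_fcs <- function(data, path, log_channels = character(), range = 1024) {
  m <- as.matrix(data)
  n_par <- ncol(m)
  n_tot <- nrow(m)
  stored <- m
  decades <- 4
  for (ch in log_channels) {
    j <- match(ch, colnames(m))
    if (is.na(j)) stopf("log channel %s not in data", ch)
    if (any(m[, j] <= 0)) stopf("log-stored channel must be positive")
    stored[, j] <- log10(m[, j]) * range / decades
  }
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    amp <- if (colnames(m)[i] %in% log_channels)
      sprintf("%d,1", decades) else "0,0"
    kv <- c(kv,
            sprintf("$P%dN", i), colnames(m)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dR", i), as.character(range),
            sprintf("$P%dE", i), amp)
  }
  delim <- "/"
  text <- paste0(delim, paste0(kv, delim, collapse = ""))
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n_par * n_tot - 1
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0, 0)
  stopifnot(nchar(header) == 58)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(stored)), con, size = 4, endian = "little")
  invisible(path)
}
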