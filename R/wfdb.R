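# Minimal WFDB-compatible record I/O: text .hea headers, format-16 signal
# files and MIT-format annotation files. Only the subset of the format
# needed for single/dual-lead arrhythmia records is supported: signal
# format 16 (16-bit two's complement, little-endian, sample-interleaved)
# and annotation words with the SKIP and AUX pseudo-annotation types.

# annotation type codes <-> display symbols (ecgcodes subset)
.ann_codes <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L,
           16L, 28L, 34L, 35L, 38L),
  symbol = c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/",
             "Q", "~", "|", "+", "e", "x", "f"),
  stringsAsFactors = FALSE
)
.RHYTHM_CODE <- 28L
.SKIP_CODE <- 59L
.AUX_CODE <- 63L

.symbol_to_code <- function(symbol) {
  idx <- match(symbol, .ann_codes$symbol)
  if (anyNA(idx)) {
    stop("unsupported annotation symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .ann_codes$code[idx]
}

.code_to_symbol <- function(code) {
  .ann_codes$symbol[match(code, .ann_codes$code)]
}

#' Write a WFDB-style record
#'
#' Writes `<record>.hea` (text header) and `<record>.dat` (format 16,
#' 16-bit little-endian integers, sample-interleaved across leads).
#' Amplitudes are quantized with the given ADC gain (units per mV).
#'
#' @param dir Directory to write into (created if missing).
#' @param record_id Record name.
#' @param signals Numeric vector (one lead) or matrix with one column per
#'   lead, in mV.
#' @param fs Sampling frequency in Hz.
#' @param leads Character vector of lead names, one per column.
#' @param gain ADC gain (integer units per mV), default 200.
#' @return `record_id`, invisibly.
#' @export
wfdb_write_record <- function(dir, record_id, signals, fs, leads = "MLII",
                              gain = 200) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  nsig <- ncol(signals)
  if (length(leads) != nsig) stop("need one lead name per signal column")
  if (fs <= 0) stop("fs must be positive")
  n <- nrow(signals)
  if (n < 1) stop("empty signal")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adu <- round(signals * gain)
  adu[adu > 32767] <- 32767
  adu[adu < -32768] <- -32768
  datfile <- paste0(record_id, ".dat")
  hea <- c(
    paste(record_id, nsig, format(fs, scientific = FALSE), n),
    vapply(seq_len(nsig), function(j) {
      paste(datfile, "16", paste0(gain, "(0)/mV"), "16 0",
            adu[1, j], "0 0", leads[j])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record_id, ".hea")))
  con <- file(file.path(dir, datfile), "wb")
  on.exit(close(con))
  # sample-major interleave: s1L1 s1L2 s2L1 s2L2 ...
  writeBin(as.integer(t(adu)), con, size = 2, endian = "little")
  invisible(record_id)
}

#' Read a WFDB-style record header and signal
#'
#' @param dir Directory containing the record files.
#' @param record_id Record name (basename of the `.hea` file).
#' @param lead Lead name to extract; `NULL` selects the first lead.
#' @return List with `samples` (numeric, mV), `fs`, `lead_name`, `n_samples`,
#'   and `leads` (all lead names in the file).
#' @export
wfdb_read_signal <- function(dir, record_id, lead = NULL) {
  heapath <- file.path(dir, paste0(record_id, ".hea"))
  if (!file.exists(heapath)) stop("record header not found: ", heapath)
  lines <- readLines(heapath, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  n <- as.integer(head_tok[4])
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    gain <- as.numeric(sub("\\(.*$", "", tok[3]))
    list(file = tok[1], format = tok[2], gain = gain,
         lead = tok[length(tok)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  leads <- vapply(sigs, `[[`, character(1), "lead")
  if (is.null(lead)) lead <- leads[1]
  j <- match(lead, leads)
  if (is.na(j)) {
    stop("record ", record_id, " has no lead '", lead,
         "'; available leads: ", paste(leads, collapse = ", "))
  }
  if (sigs[[j]]$format != "16") stop("unsupported signal format: ", sigs[[j]]$format)
  con <- file(file.path(dir, sigs[[j]]$file), "rb")
  on.exit(close(con))
  raw16 <- readBin(con, "integer", n = n * nsig, size = 2, endian = "little",
                   signed = TRUE)
  if (length(raw16) < n * nsig) stop("truncated signal file for record ", record_id)
  samples <- raw16[seq(j, by = nsig, length.out = n)] / sigs[[j]]$gain
  list(samples = samples, fs = fs, lead_name = lead, n_samples = n, leads = leads)
}

#' Write a MIT-format annotation file
#'
#' Beat annotations and rhythm change-points share one stream, ordered by
#' sample index. Rhythm changes are written as `+` annotations with an aux
#' string `(SYMBOL`. Sample indices are 1-based in memory and 0-based on
#' disk, following the on-disk convention.
#'
#' @param dir Record directory.
#' @param record_id Record name.
#' @param annotations data.frame with columns `sample` (1-based index),
#'   `symbol`, and optionally `aux` (empty string for none).
#' @param extension Annotation file extension, default `"atr"`.
#' @return Path of the file written, invisibly.
#' @export
wfdb_write_annotations <- function(dir, record_id, annotations,
                                   extension = "atr") {
  stopifnot(all(c("sample", "symbol") %in% names(annotations)))
  ann <- annotations[order(annotations$sample), , drop = FALSE]
  if (is.null(ann$aux)) ann$aux <- ""
  if (any(ann$sample < 1)) stop("annotation sample indices must be >= 1")
  codes <- .symbol_to_code(ann$symbol)
  t_disk <- as.integer(ann$sample) - 1L
  words <- integer(0)
  bytes <- raw(0)
  flush_words <- function() {
    if (length(words)) {
      # pack unsigned 16-bit words little-endian by hand: writeBin(size = 2)
      # cannot represent values above the signed range
      lo <- as.raw(words %% 256L)
      hi <- as.raw(words %/% 256L)
      b <- as.vector(rbind(lo, hi))
      bytes <<- c(bytes, b)
      words <<- integer(0)
    }
  }
  prev <- 0L
  for (i in seq_along(codes)) {
    dt <- t_disk[i] - prev
    if (dt > 1023L || dt < 0L) {
      # SKIP word followed by a 4-byte interval (high word first)
      words <- c(words, bitwShiftL(.SKIP_CODE, 10))
      hi <- dt %/% 65536L
      lo <- dt %% 65536L
      words <- c(words, hi, lo)
      dt <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(codes[i], 10), dt))
    if (nzchar(ann$aux[i])) {
      auxb <- charToRaw(ann$aux[i])
      words <- c(words, bitwOr(bitwShiftL(.AUX_CODE, 10), length(auxb)))
      flush_words()
      if (length(auxb) %% 2 == 1) auxb <- c(auxb, as.raw(0))
      bytes <- c(bytes, auxb)
    }
    prev <- t_disk[i]
  }
  words <- c(words, 0L) # EOF
  flush_words()
  path <- file.path(dir, paste0(record_id, ".", extension))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

#' Read a MIT-format annotation file
#'
#' @param dir Record directory.
#' @param record_id Record name.
#' @param extension Annotation file extension, default `"atr"`.
#' @return data.frame with columns `sample` (1-based), `symbol`, `aux`.
#' @export
wfdb_read_annotations <- function(dir, record_id, extension = "atr") {
  path <- file.path(dir, paste0(record_id, ".", extension))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = sz)
  nw <- length(bytes) %/% 2
  if (nw * 2 != length(bytes)) {
    stop("corrupt annotation stream (odd byte count) in record ", record_id)
  }
  words <- readBin(bytes, "integer", n = nw, size = 2, endian = "little",
                   signed = FALSE)
  samples <- integer(0); symbols <- character(0); auxs <- character(0)
  t <- 0L
  i <- 1L
  pending_skip <- 0L
  while (i <= nw) {
    w <- words[i]
    typ <- bitwShiftR(w, 10)
    dat <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (typ == .SKIP_CODE) {
      if (i + 2L > nw) stop("corrupt SKIP word in record ", record_id)
      pending_skip <- words[i + 1L] * 65536L + words[i + 2L]
      i <- i + 3L
    } else if (typ == .AUX_CODE) {
      nbytes <- dat
      start <- 2L * i + 1L
      aux <- rawToChar(bytes[start:(start + nbytes - 1L)])
      if (length(samples)) auxs[length(auxs)] <- aux
      i <- i + 1L + (nbytes + nbytes %% 2L) %/% 2L
    } else {
      sym <- .code_to_symbol(typ)
      if (is.na(sym)) stop("unknown annotation code ", typ, " in record ", record_id)
      t <- t + dat + pending_skip
      pending_skip <- 0L
      samples <- c(samples, t)
      symbols <- c(symbols, sym)
      auxs <- c(auxs, "")
      i <- i + 1L
    }
  }
  data.frame(sample = samples + 1L, symbol = symbols, aux = auxs,
             stringsAsFactors = FALSE)
}
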