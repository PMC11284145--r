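# WFDB record and annotation input/output.
#
# Implements the subset of the WFDB de-facto standard needed for ECG beat
# detection work: header (.hea) parsing/writing, signal (.dat) formats 16
# (16-bit little-endian) and 212 (packed 12-bit pairs), and MIT-format
# annotation files. Annotation sample indices are 0-based throughout.

# WFDB annotation code <-> mnemonic symbol (ecgcodes convention)
WFDB_ANN_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
  "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L, "]" = 33L, "e" = 34L,
  "n" = 35L, "@" = 36L, "x" = 37L, "f" = 38L, "(" = 39L, ")" = 40L,
  "r" = 41L
)
WFDB_CODE_SYMBOLS <- local({
  v <- rep(NA_character_, 49L)
  v[WFDB_ANN_CODES] <- names(WFDB_ANN_CODES)
  v
})

# QRS-marking (beat) symbols; everything else is a non-beat annotation
# (rhythm changes, noise markers, waveform boundaries, ...)
WFDB_BEAT_SYMBOLS <- c("N", "L", "R", "B", "a", "V", "F", "J", "A", "S",
                       "E", "j", "/", "Q", "e", "n", "x", "f", "r", "?")

#' Map a WFDB beat symbol to its AAMI EC57 class
#'
#' The five AAMI classes: N (normal and bundle-branch/escape beats that do
#' not fall in the other classes), S (supraventricular ectopic), V
#' (ventricular ectopic), F (fusion of ventricular and normal), Q (paced,
#' fusion of paced and normal, or unclassifiable). Beat symbols without an
#' agreed class map to Q so that exotic records never crash scoring;
#' non-beat symbols (rhythm or noise markers) are rejected — callers must
#' filter them out first.
#'
#' @param symbol character vector of WFDB beat symbols (e.g. `"N"`, `"L"`,
#'   `"V"`, `"/"`).
#' @return character vector over `{"N","S","V","F","Q"}`.
#' @export
#' @examples
#' map_symbol_to_aami(c("N", "L", "V", "f"))
map_symbol_to_aami <- function(symbol) {
  bad <- setdiff(unique(symbol), WFDB_BEAT_SYMBOLS)
  abort_if(length(bad) > 0,
           paste0("non-beat symbol(s) passed to AAMI mapper: ",
                  paste(bad, collapse = " ")))
  out <- rep("Q", length(symbol))
  out[symbol %in% c("N", "L", "R", "e", "j")] <- "N"
  out[symbol %in% c("A", "a", "J", "S")] <- "S"
  out[symbol %in% c("V", "E")] <- "V"
  out[symbol == "F"] <- "F"
  out
}

#' Test whether WFDB symbols mark beats
#' @param symbol character vector of WFDB annotation symbols.
#' @return logical vector.
#' @export
is_beat_symbol <- function(symbol) symbol %in% WFDB_BEAT_SYMBOLS

# ---- header ----------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  abort_if(!file.exists(hea_path), paste0("header not found: ", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  abort_if(length(lines) < 1, "empty WFDB header")
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  record_id <- sub("/.*$", "", top[[1]])
  n_sig <- as.integer(top[[2]])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[[3]])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[[4]]) else NA_integer_
  abort_if(is.na(n_sig) || n_sig < 1, "header: bad signal count")
  sig <- vector("list", n_sig)
  for (i in seq_len(n_sig)) {
    tok <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    fname <- tok[[1]]
    fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", tok[[2]]))
    gain_tok <- if (length(tok) >= 3) tok[[3]] else "200"
    units <- "mV"
    if (grepl("/", gain_tok)) {
      units <- sub("^.*/", "", gain_tok)
      gain_tok <- sub("/.*$", "", gain_tok)
    }
    baseline <- NA_real_
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
      gain_tok <- sub("\\(.*$", "", gain_tok)
    }
    gain <- as.numeric(gain_tok)
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[[5]]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else paste0("lead", i)
    sig[[i]] <- list(file = fname, fmt = fmt, gain = gain,
                     baseline = baseline, units = units, desc = desc)
  }
  list(record_id = record_id, n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = sig)
}

# ---- signal data -----------------------------------------------------------

read_dat_16 <- function(path, n_sig, n_samp) {
  vals <- readBin(path, "integer", n = n_sig * n_samp, size = 2L,
                  endian = "little", signed = TRUE)
  abort_if(length(vals) < n_sig * n_samp, paste0("signal file truncated: ", path))
  matrix(vals, ncol = n_sig, byrow = TRUE)
}

read_dat_212 <- function(path, n_sig, n_samp) {
  total <- n_sig * n_samp
  n_bytes <- ceiling(total / 2) * 3
  raw <- readBin(path, "raw", n = n_bytes)
  abort_if(length(raw) < 3 * floor(total / 2), paste0("signal file truncated: ", path))
  b <- as.integer(raw)
  n_tri <- length(b) %/% 3
  b0 <- b[seq(1L, by = 3L, length.out = n_tri)]
  b1 <- b[seq(2L, by = 3L, length.out = n_tri)]
  b2 <- b[seq(3L, by = 3L, length.out = n_tri)]
  s1 <- bitwAnd(b1, 0x0FL) * 256L + b0
  s2 <- bitwAnd(b1, 0xF0L) * 16L + b2
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  vals <- as.vector(rbind(s1, s2))[seq_len(total)]
  matrix(vals, ncol = n_sig, byrow = TRUE)
}

write_dat_16 <- function(path, adc) {
  vals <- as.integer(t(adc))
  writeBin(vals, path, size = 2L, endian = "little")
}

write_dat_212 <- function(path, adc) {
  vals <- as.integer(t(adc))
  if (length(vals) %% 2L == 1L) vals <- c(vals, 0L)
  u <- ifelse(vals < 0L, vals + 4096L, vals)    # 12-bit two's complement
  s1 <- u[seq(1L, length(u), 2L)]
  s2 <- u[seq(2L, length(u), 2L)]
  b0 <- s1 %% 256L
  b1 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b2 <- s2 %% 256L
  writeBin(as.raw(as.vector(rbind(b0, b1, b2))), path)
}

# ---- MIT-format annotations ------------------------------------------------

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw)
  n_words <- length(b) %/% 2L
  lo <- b[seq(1L, by = 2L, length.out = n_words)]
  hi <- b[seq(2L, by = 2L, length.out = n_words)]
  codes <- hi %/% 4L
  intervals <- (hi %% 4L) * 256L + lo
  time <- 0L
  pending <- 0
  out_t <- integer(0); out_c <- integer(0)
  i <- 1L
  while (i <= n_words) {
    code <- codes[[i]]; interval <- intervals[[i]]
    if (code == 0L && interval == 0L) break
    if (code == 59L && interval == 0L) {           # SKIP: 32-bit interval follows
      abort_if(i + 2L > n_words, "annotation file truncated inside SKIP")
      high <- hi[[i + 1L]] * 256L + lo[[i + 1L]]
      if (high >= 32768L) high <- high - 65536L
      low <- hi[[i + 2L]] * 256L + lo[[i + 2L]]
      pending <- pending + high * 65536 + low
      i <- i + 3L
      next
    }
    if (code == 63L) {                             # AUX: skip payload
      i <- i + 1L + ceiling(interval / 2)
      next
    }
    if (code %in% c(60L, 61L, 62L)) {              # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    time <- time + interval + pending
    pending <- 0
    out_t <- c(out_t, as.integer(time))
    out_c <- c(out_c, code)
    i <- i + 1L
  }
  sym <- WFDB_CODE_SYMBOLS[out_c]
  keep <- !is.na(sym)
  tibble::tibble(sample = out_t[keep], symbol = sym[keep])
}

write_wfdb_annotations <- function(path, samples, symbols) {
  abort_if(length(samples) != length(symbols), "samples/symbols length mismatch")
  abort_if(is.unsorted(samples), "annotation samples must be sorted")
  codes <- WFDB_ANN_CODES[symbols]
  abort_if(anyNA(codes), "unknown WFDB annotation symbol")
  words <- integer(0)
  prev <- 0
  for (k in seq_along(samples)) {
    delta <- as.numeric(samples[[k]]) - prev
    prev <- as.numeric(samples[[k]])
    if (delta > 1023) {
      words <- c(words, 59L * 1024L,
                 as.integer(delta %/% 65536), as.integer(delta %% 65536))
      delta <- 0
    }
    words <- c(words, codes[[k]] * 1024L + as.integer(delta))
  }
  words <- c(words, 0L)
  b_lo <- words %% 256L
  b_hi <- words %/% 256L
  writeBin(as.raw(as.vector(rbind(b_lo, b_hi))), path)
}

# ---- public record I/O -----------------------------------------------------

#' Read a WFDB record
#'
#' Reads the header, the signal file (formats 16 and 212) and, when
#' present, the beat annotation file. Signals are converted to physical
#' units using the per-lead gain and baseline. Non-beat annotations
#' (rhythm changes, noise markers, ...) are dropped and each kept beat is
#' assigned its AAMI class. Records with more than `max_leads` leads are
#' truncated to the first `max_leads` with a warning.
#'
#' @param path path to the record, with or without the `.hea` extension.
#' @param max_leads maximum number of leads to keep (default 2, the
#'   detector's input width).
#' @param annotator annotation file extension to look for (default `"atr"`).
#' @return an [ecg_record()].
#' @export
read_record <- function(path, max_leads = 2L, annotator = "atr") {
  base <- sub("\\.hea$", "", path)
  hdr <- parse_wfdb_header(paste0(base, ".hea"))
  fmts <- vapply(hdr$signals, function(s) s$fmt, integer(1))
  files <- vapply(hdr$signals, function(s) s$file, character(1))
  abort_if(length(unique(files)) != 1L,
           "multi-file WFDB records are not supported")
  abort_if(!all(fmts[1] == fmts), "mixed signal formats are not supported")
  dat_path <- file.path(dirname(base), files[[1]])
  abort_if(!file.exists(dat_path), paste0("signal file not found: ", dat_path))
  n_samp <- hdr$n_samp
  if (is.na(n_samp) || n_samp == 0L) {
    bytes <- file.size(dat_path)
    n_samp <- if (fmts[1] == 212L) floor(bytes * 2 / 3 / hdr$n_sig)
              else floor(bytes / 2 / hdr$n_sig)
  }
  abort_if(n_samp < 1, "zero-length signal")
  adc <- switch(as.character(fmts[1]),
    "16" = read_dat_16(dat_path, hdr$n_sig, n_samp),
    "212" = read_dat_212(dat_path, hdr$n_sig, n_samp),
    stop("unsupported WFDB signal format: ", fmts[1], call. = FALSE))
  phys <- adc
  for (i in seq_len(hdr$n_sig)) {
    phys[, i] <- (adc[, i] - hdr$signals[[i]]$baseline) / hdr$signals[[i]]$gain
  }
  lead_names <- vapply(hdr$signals, function(s) s$desc, character(1))
  if (hdr$n_sig > max_leads) {
    warning(sprintf("record '%s' has %d leads; keeping the first %d",
                    hdr$record_id, hdr$n_sig, max_leads), call. = FALSE)
    phys <- phys[, seq_len(max_leads), drop = FALSE]
    lead_names <- lead_names[seq_len(max_leads)]
  }
  ann <- NULL
  atr_path <- paste0(base, ".", annotator)
  if (file.exists(atr_path)) {
    raw_ann <- read_wfdb_annotations(atr_path)
    raw_ann <- raw_ann[is_beat_symbol(raw_ann$symbol), , drop = FALSE]
    raw_ann <- raw_ann[raw_ann$sample >= 0 & raw_ann$sample < n_samp, , drop = FALSE]
    if (nrow(raw_ann) > 0) {
      ann <- tibble::tibble(sample = raw_ann$sample, symbol = raw_ann$symbol,
                            aami = map_symbol_to_aami(raw_ann$symbol))
    }
  }
  ecg_record(phys, fs = hdr$fs, lead_names = lead_names, annotations = ann,
             record_id = basename(hdr$record_id))
}

#' Write an ECG record as WFDB files
#'
#' Writes `<record_id>.hea`, `<record_id>.dat` (format 16 or 212) and, when
#' the record carries beat annotations, `<record_id>.atr` in MIT format.
#'
#' @param rec an [ecg_record()].
#' @param dir output directory (created if missing).
#' @param fmt WFDB signal format, 16 (default) or 212.
#' @param gain ADC units per millivolt (default 200).
#' @return the header path, invisibly.
#' @export
write_record <- function(rec, dir, fmt = 16L, gain = 200) {
  abort_if(!inherits(rec, "ecg_record"), "rec must be an ecg_record")
  abort_if(!fmt %in% c(16L, 212L), "fmt must be 16 or 212")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adc <- round(rec$signal * gain)
  lim <- if (fmt == 212L) 2047 else 32767
  abort_if(max(abs(adc)) > lim, "signal exceeds ADC range at this gain/format")
  base <- file.path(dir, rec$record_id)
  n <- nrow(adc); n_sig <- ncol(adc)
  hea <- c(sprintf("%s %d %g %d", rec$record_id, n_sig, rec$fs, n))
  for (i in seq_len(n_sig)) {
    cks <- sum(adc[, i]) %% 65536
    if (cks >= 32768) cks <- cks - 65536
    hea <- c(hea, sprintf("%s.dat %d %g(0)/mV %d 0 %d %d 0 %s",
                          rec$record_id, fmt, gain,
                          if (fmt == 212L) 12L else 16L,
                          as.integer(adc[1, i]), as.integer(cks),
                          rec$lead_names[[i]]))
  }
  writeLines(hea, paste0(base, ".hea"))
  if (fmt == 212L) write_dat_212(paste0(base, ".dat"), adc)
  else write_dat_16(paste0(base, ".dat"), adc)
  if (nrow(rec$annotations) > 0) {
    write_wfdb_annotations(paste0(base, ".atr"),
                           rec$annotations$sample, rec$annotations$symbol)
  }
  invisible(paste0(base, ".hea"))
}

# ---- detection serialization ----------------------------------------------

#' Write detections to CSV
#'
#' One row per detected QRS complex: `record_id`, `sample` (0-based, at the
#' record's native rate), `time_s`, `probability`.
#'
#' @param det a `qrs_detections` tibble from [detect_record()] or [nms()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(det, path) {
  abort_if(is.unsorted(det$sample), "detections must be sorted by sample")
  fs <- attr(det, "fs") %||% NA_real_
  df <- data.frame(
    record_id = rep(attr(det, "record_id") %||% "record", length(det$sample)),
    sample = det$sample,
    time_s = det$sample / fs,
    probability = det$prob
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV
#' @param path CSV written by [write_detections()].
#' @return a `qrs_detections` tibble with `sample` and `prob` columns and
#'   `fs`/`record_id` attributes when recoverable.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fs <- if (nrow(df) > 0 && all(is.finite(df$time_s)) && any(df$sample > 0)) {
    i <- which(df$sample > 0)[1]
    df$sample[i] / df$time_s[i]
  } else NA_real_
  new_detections(df$sample, df$probability, fs = fs,
                 record_id = if (nrow(df) > 0) df$record_id[[1]] else "record")
}

#' Write detections as a WFDB annotation file
#'
#' Detections are stored with beat symbol `"N"` so that any WFDB-aware
#' tool can overlay them.
#'
#' @param det a `qrs_detections` tibble.
#' @param path output annotation file path.
#' @return `path`, invisibly.
#' @export
write_detections_wfdb <- function(det, path) {
  write_wfdb_annotations(path, det$sample, rep("N", length(det$sample)))
  invisible(path)
}
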