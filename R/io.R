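#' Read an ECG segment from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{One or two numeric comma-separated columns (amplitude, or
#'     time + amplitude). Optional `#`-prefixed header comments of the form
#'     `# key=value` carry `fs`, `label` and `subject_id`. When no `fs`
#'     header is present, a two-column file has its rate inferred from the
#'     median time step; a one-column file requires the `fs` argument.}
#'   \item{`wfdb`}{A WFDB record (`.hea` header plus `.dat` signal file,
#'     formats 16 and 212). Only the first channel is read; the ADC gain
#'     and baseline from the header are applied.}
#' }
#'
#' @param path Path to the file (for `wfdb`, the `.hea` file or the record
#'   name without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param fs Sampling rate override in Hz; required for headerless
#'   single-column CSV files.
#' @return An [ecg_segment()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), fs = NULL) {
  format <- match.arg(format)
  switch(format,
         csv = read_ecg_csv(path, fs = fs),
         wfdb = read_ecg_wfdb(path))
}

read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  header <- grepl("^\\s*#", lines)
  for (h in lines[header]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  data_idx <- which(!header & nzchar(trimws(lines)))
  if (!length(data_idx)) stop("no samples in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "\\s*,\\s*")
  ncol <- length(fields[[1]])
  if (!ncol %in% c(1L, 2L)) {
    stop("CSV must have 1 or 2 columns, found ", ncol)
  }
  vals <- matrix(NA_real_, nrow = length(fields), ncol = ncol)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != ncol) {
      stop(sprintf("line %d: expected %d columns", data_idx[i], ncol))
    }
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v))) {
      stop(sprintf("line %d: non-numeric value '%s'", data_idx[i],
                   lines[data_idx[i]]))
    }
    vals[i, ] <- v
  }
  if (ncol == 2L) {
    tm <- vals[, 1]
    samples <- vals[, 2]
    if (is.null(fs) && !is.null(meta$fs)) fs <- as.numeric(meta$fs)
    if (is.null(fs)) {
      dt <- stats::median(diff(tm))
      if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from time column")
      fs <- 1 / dt
    }
  } else {
    samples <- vals[, 1]
    if (is.null(fs) && !is.null(meta$fs)) fs <- as.numeric(meta$fs)
    if (is.null(fs)) {
      stop("sampling rate unknown: no '# fs=' header in ", path,
           " and no 'fs' argument given")
    }
  }
  ecg_segment(samples, fs = fs, label = meta$label,
              subject_id = meta$subject_id)
}

#' Write an ECG segment to a CSV file
#'
#' Writes the self-describing CSV dialect read by [read_ecg()]: header
#' comments (`# fs=...`, and `# label=` / `# subject_id=` when present)
#' followed by one amplitude per line at full double precision, so that a
#' read/write round trip is lossless.
#'
#' @param segment An [ecg_segment()].
#' @param path Output path.
#' @param format Only `"csv"` is supported for writing.
#' @return Invisibly, `path`.
#' @export
write_ecg <- function(segment, path, format = "csv") {
  stopifnot(is_ecg_segment(segment))
  format <- match.arg(format, "csv")
  hdr <- sprintf("# fs=%.17g", segment$fs)
  if (!is.null(segment$label)) hdr <- c(hdr, paste0("# label=", segment$label))
  if (!is.null(segment$subject_id)) {
    hdr <- c(hdr, paste0("# subject_id=", segment$subject_id))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(hdr, sprintf("%.17g", segment$samples)), con)
  invisible(path)
}

# Minimal WFDB reader: .hea header plus .dat in format 16 (16-bit
# little-endian, channel-interleaved) or 212 (two 12-bit samples packed in
# 3 bytes). First channel only; physical units = (adc - baseline) / gain.
read_ecg_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  if (is.na(nsig) || nsig < 1L) stop("WFDB record has no signal channels")
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  datfile <- file.path(dirname(hea), sig[1])
  fmt <- sub("x.*|:.*|\\+.*", "", sig[2])
  gain_field <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_field)) {
    as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field))
  } else if (length(sig) >= 5) as.numeric(sig[5]) else 0
  if (!is.finite(baseline)) baseline <- 0
  if (nsig > 1L) {
    message("WFDB record has ", nsig, " channels; reading channel 1 only")
  }
  if (!file.exists(datfile)) stop("file not found: ", datfile)
  raw <- readBin(datfile, "raw", n = file.info(datfile)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   endian = "little", signed = TRUE)
      matrix(v, nrow = nsig)[1, ]
    },
    "212" = {
      n3 <- (length(raw) %/% 3) * 3
      b <- as.integer(raw[seq_len(n3)])
      b1 <- b[seq(1, n3, by = 3)]; b2 <- b[seq(2, n3, by = 3)]
      b3 <- b[seq(3, n3, by = 3)]
      s1 <- bitwAnd(b2, 15L) * 256L + b1
      s2 <- bitwAnd(b2, 240L) %/% 16L * 256L + b3
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      v <- as.vector(rbind(s1, s2))
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)[1, ]
    },
    stop("unsupported WFDB format: ", fmt)
  )
  if (is.finite(nsamp) && nsamp > 0 && nsamp <= length(adc)) {
    adc <- adc[seq_len(nsamp)]
  }
  ecg_segment((adc - baseline) / gain, fs = fs,
              subject_id = sub("\\.hea$", "", basename(hea)))
}

#' Resample an ECG segment to a new rate
#'
#' Polyphase, anti-aliased rate conversion (via [signal::resample()]).
#' Content below the smaller of the two Nyquist frequencies is preserved;
#' the output has exactly `round(n * target_fs / fs)` samples.
#'
#' @param segment An [ecg_segment()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return An [ecg_segment()] at `target_fs`.
#' @export
resample_ecg <- function(segment, target_fs) {
  stopifnot(is_ecg_segment(segment))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0) {
    stop("'target_fs' must be > 0")
  }
  n_out <- round(length(segment$samples) * target_fs / segment$fs)
  if (isTRUE(all.equal(target_fs, segment$fs))) {
    out <- segment
    out$fs <- target_fs
    return(out)
  }
  pq <- rational_approx(target_fs / segment$fs)
  y <- signal::resample(segment$samples, pq[1], pq[2])
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, rep(y[length(y)], n_out - length(y)))
  ecg_segment(y, fs = target_fs, label = segment$label,
              subject_id = segment$subject_id)
}

# Best rational p/q approximation to x with q <= qmax.
rational_approx <- function(x, qmax = 1000L, tol = 1e-9) {
  for (q in seq_len(qmax)) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < tol * x) return(c(p, q))
  }
  q <- qmax
  c(max(1, round(x * q)), q)
}
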