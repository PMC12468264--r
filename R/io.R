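#' Label rule for two-column signal-pair filenames
#'
#' Infers the class from the customary filename prefix convention of
#' paired intracranial recordings: a `F` component (e.g. `Data_F_50.txt`)
#' marks a focal pair, `N` a non-focal pair. Returns `NA` when neither
#' matches.
#'
#' @param filename file name or path.
#' @return `"focal"`, `"non-focal"` or `NA`.
#' @export
pairLabelFromFilename <- function(filename) {
  base <- basename(filename)
  if (grepl("(^|[._-])F([._-]|$)", base, ignore.case = FALSE)) return("focal")
  if (grepl("(^|[._-])N([._-]|$)", base, ignore.case = FALSE))
    return("non-focal")
  NA_character_
}

#' Read a two-column ASCII signal pair
#'
#' Parses one record file holding an aligned signal pair (columns x and
#' y), comma- or whitespace-delimited (auto-detected). Ragged rows or
#' non-numeric cells are rejected with the offending line number.
#'
#' @param path file path.
#' @param fs sampling rate to attach (the paired iEEG database is
#'   recorded at 512 Hz).
#' @param labelRule function mapping the filename to a class label.
#' @return a list of class `"PairRecord"` with `x`, `y`, `fs`, `label`,
#'   `source`.
#' @export
readPairText <- function(path, fs = 512, labelRule = pairLabelFromFilename) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal-pair file: ", path)
  delim <- if (any(grepl(",", lines))) "," else "[[:space:]]+"
  parts <- strsplit(trimws(lines), delim)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("ragged row in %s: line %d has %d field(s), expected 2",
                 path, which(nf != 2L)[1L], nf[nf != 2L][1L]))
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(2L)))
  if (anyNA(vals))
    stop(sprintf("non-numeric cell in %s: line %d", path,
                 which(colSums(is.na(vals)) > 0)[1L]))
  structure(list(x = vals[1L, ], y = vals[2L, ], fs = fs,
                 label = labelRule(path), source = path),
            class = "PairRecord")
}

#' Write a two-column ASCII signal pair
#'
#' @param x,y aligned numeric series of equal length.
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
writePairText <- function(x, y, path, sep = ",") {
  stopifnot(length(x) == length(y))
  writeLines(paste(format(x, trim = TRUE, digits = 10),
                   format(y, trim = TRUE, digits = 10), sep = sep), path)
  invisible(path)
}

#' Convert a pair record to a two-channel signal
#'
#' @param record a `PairRecord` from [readPairText()].
#' @return a [MultichannelSignal-class] with channels `x` and `y`.
#' @export
pairToSignal <- function(record) {
  stopifnot(inherits(record, "PairRecord"))
  multichannelSignal(rbind(record$x, record$y), record$fs, c("x", "y"))
}

#' Read / write multi-column plain-text signals
#'
#' Tab-delimited matrix, one column per channel, with a header row of
#' channel names. This is the EDF-free plain format the fixture
#' generator emits for recordings with more than two channels.
#'
#' @param path file path.
#' @param fs sampling rate to attach.
#' @param signal a [MultichannelSignal-class].
#' @return `readSignalText` returns a [MultichannelSignal-class];
#'   `writeSignalText` returns `path` invisibly.
#' @export
readSignalText <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  multichannelSignal(t(as.matrix(m)), fs, colnames(m))
}

#' @rdname readSignalText
#' @export
writeSignalText <- function(signal, path) {
  m <- t(samples(signal))
  colnames(m) <- channelNames(signal)
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- minimal EDF support ---------------------------------------------------

padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a signal as an EDF file
#'
#' Minimal continuous EDF writer: one data record spanning the whole
#' signal, 16-bit samples scaled symmetrically to each channel's peak
#' amplitude. Intended for building test recordings and fixtures; the
#' quantization step is `max(|x|)/32767` per channel.
#'
#' @param signal a [MultichannelSignal-class].
#' @param path output path.
#' @param physicalDim unit string stored per channel.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(signal, path, physicalDim = "uV") {
  stopifnot(is(signal, "MultichannelSignal"))
  x <- samples(signal)
  ns <- nrow(x)
  N <- ncol(x)
  dur <- N / samplingRate(signal)
  pm <- apply(abs(x), 1L, max)
  pm[pm == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8L), padField("synthetic", 80L),
    padField("mvmdnet test recording", 80L),
    padField("01.01.26", 8L), padField("00.00.00", 8L),
    padField(256L * (ns + 1L), 8L), padField("", 44L),
    padField(1L, 8L), padField(format(dur, digits = 8), 8L),
    padField(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(channelNames(signal), 16L),
    list(rep("synthetic", ns), 80L),
    list(rep(physicalDim, ns), 8L),
    list(format(-pm, digits = 8), 8L),
    list(format(pm, digits = 8), 8L),
    list(rep("-32767", ns), 8L),
    list(rep("32767", ns), 8L),
    list(rep("none", ns), 80L),
    list(rep(N, ns), 8L),
    list(rep("", ns), 32L))
  for (f in fields)
    writeChar(paste(vapply(f[[1L]], padField, "", width = f[[2L]]),
                    collapse = ""), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- as.integer(round(x[i, ] / pm[i] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

readEDFHeader <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8L); patient <- rd(80L); recording <- rd(80L)
  startDate <- rd(8L); startTime <- rd(8L)
  headerBytes <- as.integer(rd(8L)); reserved <- rd(44L)
  nRecords <- as.integer(rd(8L)); recDuration <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  fieldBlock <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fieldBlock(16L); transducer <- fieldBlock(80L)
  dims <- fieldBlock(8L)
  physMin <- as.numeric(fieldBlock(8L)); physMax <- as.numeric(fieldBlock(8L))
  digMin <- as.numeric(fieldBlock(8L)); digMax <- as.numeric(fieldBlock(8L))
  prefilter <- fieldBlock(80L)
  spr <- as.integer(fieldBlock(8L)); fieldBlock(32L)
  list(ns = ns, nRecords = nRecords, recDuration = recDuration,
       labels = labels, physMin = physMin, physMax = physMax,
       digMin = digMin, digMax = digMax, spr = spr,
       headerBytes = headerBytes)
}

#' Read selected channels from an EDF recording
#'
#' Extracts the requested channels, in the requested order, at their
#' native sampling rate. Matching is case-insensitive and tolerant of
#' montage decorations (`EEG FP1-REF` resolves `FP1`). If `expectedFs`
#' is supplied, a sampling-rate mismatch raises an error — there is no
#' silent resampling.
#'
#' @param path EDF file path.
#' @param labels channel labels to extract.
#' @param expectedFs optional sampling rate the caller requires, Hz.
#' @return a [MultichannelSignal-class].
#' @export
readEDFChannels <- function(path, labels, expectedFs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEDFHeader(con)
  have <- normalizeChannelLabel(h$labels)
  want <- normalizeChannelLabel(labels)
  idx <- match(want, have)
  if (anyNA(idx))
    stop("channel label(s) not present in EDF: ",
         paste(labels[is.na(idx)], collapse = ", "))
  spr <- h$spr[idx]
  if (length(unique(spr)) != 1L)
    stop("requested channels have differing sampling rates")
  fs <- spr[1L] / h$recDuration
  if (!is.null(expectedFs) && abs(fs - expectedFs) > 1e-9)
    stop(sprintf("sampling rate mismatch: file has %g Hz, config expects %g Hz (no resampling is applied)",
                 fs, expectedFs))
  perRecord <- sum(h$spr)
  raw <- readBin(con, "integer", n = perRecord * h$nRecords, size = 2L,
                 signed = TRUE, endian = "little")
  offsets <- c(0L, cumsum(h$spr))
  out <- matrix(0, length(idx), spr[1L] * h$nRecords)
  for (r in seq_len(h$nRecords)) {
    base <- (r - 1L) * perRecord
    for (j in seq_along(idx)) {
      ch <- idx[j]
      dig <- raw[(base + offsets[ch] + 1L):(base + offsets[ch] + h$spr[ch])]
      phys <- h$physMin[ch] + (dig - h$digMin[ch]) *
        (h$physMax[ch] - h$physMin[ch]) / (h$digMax[ch] - h$digMin[ch])
      out[j, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <- phys
    }
  }
  multichannelSignal(out, fs, labels)
}

## ---- run configuration and logs -------------------------------------------

#' Read / write a run configuration
#'
#' Key-value YAML holding the preprocessing, decomposition, STFT, model
#' and training settings of a run. Command-line flags mirror these keys;
#' a flag given on the command line overrides the file value.
#'
#' @param path file path.
#' @param cfg named list to write.
#' @return `readRunConfig` returns a named list; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a reproducibility log
#'
#' Records everything needed to reproduce a run bit for bit: timestamp,
#' R and package versions, every seed, and the full configuration.
#'
#' @param path log file path.
#' @param config named list of settings (must include the seeds used).
#' @return `path`, invisibly.
#' @export
writeRunLog <- function(path, config) {
  info <- list(timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               r_version = R.version.string,
               package = "mvmdnet",
               package_version =
                 as.character(utils::packageVersion("mvmdnet")),
               config = config)
  yaml::write_yaml(info, path)
  invisible(path)
}
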