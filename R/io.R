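#' Write a waveform channel to CSV
#'
#' One channel per file, columns `time_s,value` with header.
#'
#' @param wave a `waveform_channel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(wave, path) {
  stopifnot(inherits(wave, "waveform_channel"))
  utils::write.csv(
    data.frame(time_s = wf_times(wave), value = wave$values),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a waveform channel from CSV
#'
#' Expects columns `time_s,value`. The sampling rate is inferred from the
#' time column (which must start near 0, be strictly increasing and
#' uniform to within 1e-6 relative jitter) unless `fs` is supplied.
#'
#' @param path CSV file.
#' @param fs optional sampling rate override, Hz.
#' @param role channel role label.
#' @return a `waveform_channel`.
#' @export
read_channel_csv <- function(path, fs = NULL,
                             role = c("generic", "ecg", "thoracic", "abdominal")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_trancehrv("file not found: %s", path)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop_trancehrv("%s: expected columns `time_s,value`", path)
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop_trancehrv("%s: time column must be strictly increasing", path)
  if (is.null(fs)) {
    step <- stats::median(dt)
    if (max(abs(dt - step)) > 1e-6 * max(step, 1)) {
      stop_trancehrv("%s: time column is not uniformly sampled and no `fs` given", path)
    }
    fs <- 1 / step
  }
  waveform_channel(d$value, fs, role = role)
}

# --- Minimal EDF (European Data Format) support ------------------------------
# EDF is a fixed-layout format: a 256-byte ASCII global header, 256 ASCII
# bytes per channel of channel headers, then data records of little-endian
# 16-bit integers mapped linearly from digital to physical range. Only
# continuous multi-channel records with a common record duration are handled,
# which covers polygraph exports of ECG + belt channels.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write waveform channels to an EDF file
#'
#' Minimal EDF writer: all channels must share the same sampling rate and
#' duration; samples are scaled to the int16 digital range per channel.
#'
#' @param waves named list of `waveform_channel`s (names become EDF labels).
#' @param path output file.
#' @param record_s data-record duration, s.
#' @return `path`, invisibly.
#' @export
write_edf <- function(waves, path, record_s = 1) {
  stopifnot(length(waves) >= 1, !is.null(names(waves)))
  fs <- unique(vapply(waves, function(w) w$fs, numeric(1)))
  if (length(fs) != 1L) stop_trancehrv("EDF export requires a common sampling rate")
  ns <- unique(vapply(waves, function(w) length(w$values), numeric(1)))
  if (length(ns) != 1L) stop_trancehrv("EDF export requires equal channel lengths")
  spr <- round(fs * record_s)
  n_rec <- floor(ns / spr)
  nch <- length(waves)

  phys_min <- vapply(waves, function(w) min(w$values), numeric(1))
  phys_max <- vapply(waves, function(w) max(w$values), numeric(1))
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("synthetic cohort", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nch), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_s), 8), edf_pad(nch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(names(waves), 16)                      # label
  field(rep("", nch), 80)                      # transducer
  field(rep("au", nch), 8)                     # physical dimension
  field(sprintf("%.6g", phys_min), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep("-32768", nch), 8)
  field(rep("32767", nch), 8)
  field(rep("", nch), 80)                      # prefiltering
  field(rep(spr, nch), 8)
  field(rep("", nch), 32)                      # reserved

  dig <- lapply(seq_len(nch), function(i) {
    w <- waves[[i]]$values[seq_len(n_rec * spr)]
    g <- (w - phys_min[i]) / (phys_max[i] - phys_min[i])
    as.integer(round(g * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nch)) {
      writeBin(dig[[i]][sel], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into waveform channels
#'
#' Minimal EDF reader matching [write_edf()]: continuous records, common
#' record duration, int16 samples mapped back to physical units.
#'
#' @param path EDF file.
#' @return named list of `waveform_channel`s (names from EDF labels,
#'   whitespace-trimmed).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_trancehrv("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  gh <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(gh, 237, 244))
  record_s <- as.numeric(substr(gh, 245, 252))
  nch <- as.integer(substr(gh, 253, 256))
  if (is.na(nch) || nch < 1L) stop_trancehrv("%s: not a readable EDF header", path)
  ch_hdr <- readChar(con, 256 * nch, useBytes = TRUE)
  take <- function(offset, width) {
    vapply(seq_len(nch), function(i) {
      trimws(substr(ch_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, "")
  }
  labels <- take(0, 16)
  pos <- 16 * nch + 80 * nch + 8 * nch
  phys_min <- as.numeric(take(pos, 8)); pos <- pos + 8 * nch
  phys_max <- as.numeric(take(pos, 8)); pos <- pos + 8 * nch
  dig_min <- as.numeric(take(pos, 8)); pos <- pos + 8 * nch
  dig_max <- as.numeric(take(pos, 8)); pos <- pos + 8 * nch + 80 * nch
  spr <- as.integer(take(pos, 8))

  out <- lapply(seq_len(nch), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      g <- (d - dig_min[i]) / (dig_max[i] - dig_min[i])
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        phys_min[i] + g * (phys_max[i] - phys_min[i])
    }
  }
  stats::setNames(
    lapply(seq_len(nch), function(i) {
      waveform_channel(out[[i]], spr[i] / record_s)
    }),
    labels
  )
}

#' Read one subject-condition recording
#'
#' Loads the three channels of a recording either from three per-channel CSV
#' files or from a single EDF file whose channel labels are mapped to roles
#' by the regular expressions in `role_patterns`.
#'
#' @param paths for CSV: named character vector/list with entries `ecg`,
#'   `thoracic`, `abdominal`; for EDF: a single file path.
#' @param format `"csv"` or `"edf"`.
#' @param fs sampling rate override for CSV input, Hz.
#' @param role_patterns named list of regexes mapping EDF labels to roles.
#' @return list with `ecg`, `thoracic`, `abdominal` waveform channels.
#' @export
read_recording <- function(paths, format = c("csv", "edf"), fs = NULL,
                           role_patterns = list(ecg = "(?i)ecg|ekg",
                                                thoracic = "(?i)thor|chest",
                                                abdominal = "(?i)abdo|belly")) {
  format <- match.arg(format)
  if (format == "csv") {
    need <- c("ecg", "thoracic", "abdominal")
    if (!all(need %in% names(paths))) {
      stop_trancehrv("CSV recording needs named paths: ecg, thoracic, abdominal")
    }
    return(list(
      ecg = read_channel_csv(paths[["ecg"]], fs = fs, role = "ecg"),
      thoracic = read_channel_csv(paths[["thoracic"]], fs = fs, role = "thoracic"),
      abdominal = read_channel_csv(paths[["abdominal"]], fs = fs, role = "abdominal")
    ))
  }
  chans <- read_edf(if (is.list(paths)) paths[[1]] else paths[1])
  find_role <- function(role) {
    hit <- grep(role_patterns[[role]], names(chans), perl = TRUE)
    if (length(hit) != 1L) {
      stop_trancehrv("EDF: expected exactly one channel matching role `%s`", role)
    }
    w <- chans[[hit]]
    w$role <- role
    w
  }
  list(ecg = find_role("ecg"), thoracic = find_role("thoracic"),
       abdominal = find_role("abdominal"))
}

#' Write a synthetic cohort to disk
#'
#' One CSV per channel (`<subject>_<condition>_<role>.csv`), a manifest CSV
#' listing every recording with its file paths and seed, and a ground-truth
#' JSON with true beat and breath times per recording.
#'
#' @param cohort a `synthetic_cohort` (with waveforms).
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth <- list()
  for (rec in cohort$recordings) {
    if (is.null(rec$ecg)) stop_trancehrv("cohort was generated without waveforms")
    stem <- sprintf("%s_%s", rec$subject_id, rec$condition)
    p <- c(ecg = file.path(dir, paste0(stem, "_ecg.csv")),
           thoracic = file.path(dir, paste0(stem, "_thoracic.csv")),
           abdominal = file.path(dir, paste0(stem, "_abdominal.csv")))
    write_channel_csv(rec$ecg, p[["ecg"]])
    write_channel_csv(rec$thoracic, p[["thoracic"]])
    write_channel_csv(rec$abdominal, p[["abdominal"]])
    mrow <- cohort$manifest[cohort$manifest$subject_id == rec$subject_id &
                             cohort$manifest$condition == rec$condition, ]
    rows[[stem]] <- cbind(
      mrow[, c("subject_id", "condition", "fs", "duration_s",
               "induction_end_s", "trance_intensity", "seed")],
      data.frame(ecg_path = p[["ecg"]], thoracic_path = p[["thoracic"]],
                 abdominal_path = p[["abdominal"]], stringsAsFactors = FALSE)
    )
    truth[[stem]] <- list(
      subject_id = rec$subject_id, condition = rec$condition,
      r_times = rec$truth_r_times, breath_times = rec$truth_breath_times
    )
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read and validate a cohort manifest
#'
#' @param path manifest CSV (as written by [write_cohort()]).
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_trancehrv("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "ecg_path", "thoracic_path",
            "abdominal_path", "fs", "induction_end_s")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop_trancehrv("manifest missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(m[, c("subject_id", "condition")])) {
    stop_trancehrv("manifest has duplicate (subject_id, condition) rows")
  }
  for (col in c("ecg_path", "thoracic_path", "abdominal_path")) {
    gone <- !file.exists(m[[col]])
    if (any(gone)) stop_trancehrv("manifest references missing files: %s",
                                  paste(m[[col]][gone], collapse = ", "))
  }
  if ("trance_intensity" %in% names(m)) {
    ti <- m$trance_intensity
    if (any(!is.na(ti) & (ti < 0 | ti > 10))) {
      stop_trancehrv("trance_intensity must lie in [0, 10]")
    }
  }
  m
}
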