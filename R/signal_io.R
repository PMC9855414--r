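#' Read a single-lead ECG record
#'
#' Supports a one-column CSV (`voltage_mv`, optionally alongside other
#' columns) and a minimal WFDB record (format-16 `.hea`/`.dat` pair, single
#' signal; samples are converted to mV using the header gain and baseline).
#' The sampling rate is verified against the configuration: the pipeline
#' operates at 125 Hz and does not resample.
#'
#' @param path File path. For WFDB, either the `.hea` file or the record name
#'   without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @param cfg A [pipeline_config()].
#' @param sampling_rate_hz Sampling rate of a CSV file (CSV carries none);
#'   defaults to the configured rate.
#' @param subject_id Identifier for the returned record.
#' @return An [ecg_record()].
#' @seealso [write_ecg()]
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), cfg = pipeline_config(),
                     sampling_rate_hz = cfg$sampling_rate_hz,
                     subject_id = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) {
      abort(sprintf("ECG file not found: %s", path), class = "ecgdys_data_error")
    }
    df <- read.csv(path)
    if (!"voltage_mv" %in% names(df)) {
      abort("CSV ECG file must have a 'voltage_mv' column",
            class = "ecgdys_data_error")
    }
    fs <- sampling_rate_hz
    samples <- df$voltage_mv
    id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  } else {
    hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
    if (!file.exists(hea)) {
      abort(sprintf("WFDB header not found: %s", hea), class = "ecgdys_data_error")
    }
    h <- read_wfdb_header(hea)
    dat <- file.path(dirname(hea), h$dat_file)
    if (!file.exists(dat)) {
      abort(sprintf("WFDB signal file not found: %s", dat),
            class = "ecgdys_data_error")
    }
    raw <- readBin(dat, "integer", n = h$n_samples, size = 2, endian = "little")
    if (length(raw) != h$n_samples) {
      abort(sprintf("WFDB signal file %s is truncated (%d of %d samples)",
                    dat, length(raw), h$n_samples), class = "ecgdys_data_error")
    }
    samples <- (raw - h$baseline) / h$gain
    fs <- h$fs
    id <- subject_id %||% h$record
  }
  if (fs != cfg$sampling_rate_hz) {
    abort(sprintf(
      "unsupported sampling rate: %g Hz (pipeline requires %d Hz; resampling is out of scope)",
      fs, cfg$sampling_rate_hz), class = "ecgdys_data_error")
  }
  ecg_record(samples, fs, 0, id)
}

read_wfdb_header <- function(hea) {
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) {
    abort(sprintf("malformed WFDB header: %s", hea), class = "ecgdys_data_error")
  }
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fmt <- sig[2]
  if (!startsWith(fmt, "16")) {
    abort(sprintf("unsupported WFDB signal format '%s' (only 16)", fmt),
          class = "ecgdys_data_error")
  }
  gain_spec <- sig[3]
  baseline <- 0
  m <- regmatches(gain_spec, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/(.*))?$",
                                     gain_spec))[[1]]
  gain <- as.numeric(m[2])
  if (nzchar(m[4])) baseline <- as.numeric(m[4])
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
  list(record = top[1], n_sig = as.integer(top[2]), fs = as.numeric(top[3]),
       n_samples = as.integer(top[4]), dat_file = sig[1], gain = gain,
       baseline = baseline)
}

#' Write a single-lead ECG record
#'
#' WFDB output uses format 16 with a gain of 1000 adu/mV (1 uV amplitude
#' resolution, matching the generator's quantization, so write-then-read
#' round-trips exactly); CSV output is a single `voltage_mv` column.
#'
#' @param record An [ecg_record()].
#' @param path Output path: record name (without extension) for WFDB, file
#'   path for CSV.
#' @param format `"csv"` or `"wfdb"`.
#' @return The header/file path, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    write.csv(data.frame(voltage_mv = record$samples), path, row.names = FALSE)
    return(invisible(path))
  }
  gain <- 1000
  name <- sub("\\.hea$", "", path)
  rec <- basename(name)
  raw <- as.integer(round(record$samples * gain))
  if (any(abs(raw) > 32767)) {
    warn("write_ecg: samples exceed the int16 range at gain 1000 and were clipped")
    raw <- pmin(pmax(raw, -32767L), 32767L)
  }
  writeLines(c(sprintf("%s 1 %g %d", rec, record$sampling_rate_hz, length(raw)),
               sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 II", rec, gain, raw[1])),
             paste0(name, ".hea"))
  writeBin(raw, paste0(name, ".dat"), size = 2, endian = "little")
  invisible(paste0(name, ".hea"))
}

glycemic_levels <- function() c("euglycemia", "dysglycemia", "excluded")

#' Label blood glucose values by glycemic state
#'
#' Dysglycemia is strictly above `bg_hyper_mgdl` (200) or strictly below
#' `bg_hypo_mgdl` (70); euglycemia is the inclusive band
#' `[bg_eu_low_mgdl, bg_eu_high_mgdl]` (80-180). The two buffer bands between
#' them — 70-80 and 180-200 mg/dL, boundaries included — are labelled
#' `excluded` so that no consecutive heartbeats can be assigned to both a
#' normal and an abnormal class.
#'
#' @param glucose_mgdl Numeric vector of BG values (mg/dL); values outside the
#'   sanity band (10, 1500) are a data error.
#' @param cfg A [pipeline_config()].
#' @return A factor with levels `euglycemia`, `dysglycemia`, `excluded`.
#' @examples
#' label_bg(c(65, 120, 250, 75, 190))
#' @export
label_bg <- function(glucose_mgdl, cfg = pipeline_config()) {
  bad <- !is.finite(glucose_mgdl) | glucose_mgdl <= 10 | glucose_mgdl >= 1500
  if (any(bad)) {
    abort(sprintf("blood glucose outside the sanity band (10, 1500) mg/dL: %s",
                  paste(format(glucose_mgdl[bad]), collapse = ", ")),
          class = "ecgdys_data_error")
  }
  out <- ifelse(glucose_mgdl > cfg$bg_hyper_mgdl |
                  glucose_mgdl < cfg$bg_hypo_mgdl, "dysglycemia",
         ifelse(glucose_mgdl >= cfg$bg_eu_low_mgdl &
                  glucose_mgdl <= cfg$bg_eu_high_mgdl, "euglycemia",
                "excluded"))
  factor(out, levels = glycemic_levels())
}

#' Match blood-glucose records to ECG strips
#'
#' Each BG record claims the `bg_corr_window_s` (10 min) of signal in the
#' half-open window `[t - 600, t)` immediately preceding its storage time
#' `t`. BG records whose window extends before the start of the record are
#' dropped with a message; `excluded`-label strips are retained for audit but
#' flagged non-usable.
#'
#' @param record An [ecg_record()].
#' @param bg A data frame with `time_s` (ascending) and `glucose_mgdl`.
#' @param cfg A [pipeline_config()].
#' @return A tibble of strips: `strip_id`, `bg_time_s`, `glucose_mgdl`,
#'   `label`, `start_s`, `end_s`, `usable`.
#' @export
match_ecg_to_bg <- function(record, bg, cfg = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"), is.data.frame(bg))
  if (is.unsorted(bg$time_s, strictly = FALSE)) {
    abort("BG times must be sorted ascending", class = "ecgdys_data_error")
  }
  win <- cfg$bg_corr_window_s
  rec_start <- record$start_time_s
  rec_end <- rec_start + length(record$samples) / record$sampling_rate_hz
  strips <- tibble(
    strip_id = seq_len(nrow(bg)),
    bg_time_s = bg$time_s,
    glucose_mgdl = bg$glucose_mgdl,
    label = label_bg(bg$glucose_mgdl, cfg),
    start_s = bg$time_s - win,
    end_s = bg$time_s)
  dropped <- strips$start_s < rec_start | strips$end_s > rec_end
  if (any(dropped)) {
    rlang::inform(sprintf(
      "match_ecg_to_bg: dropped %d BG record(s) whose 10-min window falls outside the ECG record",
      sum(dropped)))
  }
  strips <- strips[!dropped, , drop = FALSE]
  strips$usable <- strips$label != "excluded"
  strips
}

#' Apply the cohort inclusion filters
#'
#' A subject is retained when it has at least `min_bg_records` BG records, at
#' least `min_dys_records` dysglycemic records, enough euglycemic records for
#' the train/validation split, and no atrial-fibrillation/pacemaker flag.
#'
#' @param subjects A data frame with one row per subject and columns `n_bg`,
#'   `n_dys`, `n_eu`, and optionally `af_or_pacemaker` (logical).
#' @param cfg A [pipeline_config()].
#' @return The input tibble with a logical `retained` column.
#' @export
filter_subjects <- function(subjects, cfg = pipeline_config()) {
  stopifnot(is.data.frame(subjects))
  need <- c("n_bg", "n_dys", "n_eu")
  missing <- setdiff(need, names(subjects))
  if (length(missing)) {
    abort(sprintf("filter_subjects: missing column(s) %s",
                  paste(missing, collapse = ", ")), class = "ecgdys_data_error")
  }
  af <- if ("af_or_pacemaker" %in% names(subjects)) {
    isTRUE_v(subjects$af_or_pacemaker)
  } else rep(FALSE, nrow(subjects))
  as_tibble(subjects) |>
    mutate(retained = .data$n_bg >= cfg$min_bg_records &
             .data$n_dys >= cfg$min_dys_records &
             .data$n_eu >= cfg$n_train_eu + cfg$n_val_eu &
             !af)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Split strips into training and validation sets
#'
#' Randomly selects `n_train_eu` (10) euglycemic strips for one-class
#' training, then `n_val_eu` (5) euglycemic and `n_val_dys` (5) dysglycemic
#' strips from the remainder for validation; sampling is without replacement
#' and seeded. Excluded-label strips are never eligible.
#'
#' @param strips A strips tibble from [match_ecg_to_bg()].
#' @param seed Integer seed.
#' @param cfg A [pipeline_config()].
#' @return `strips` with a `split` column (`train`, `val`, `none`).
#' @export
split_records <- function(strips, seed, cfg = pipeline_config()) {
  eu_ids <- strips$strip_id[strips$label == "euglycemia"]
  dys_ids <- strips$strip_id[strips$label == "dysglycemia"]
  need_eu <- cfg$n_train_eu + cfg$n_val_eu
  if (length(eu_ids) < need_eu || length(dys_ids) < cfg$n_val_dys) {
    deficit <- c(
      if (length(eu_ids) < need_eu)
        sprintf("euglycemia: have %d, need %d", length(eu_ids), need_eu),
      if (length(dys_ids) < cfg$n_val_dys)
        sprintf("dysglycemia: have %d, need %d", length(dys_ids), cfg$n_val_dys))
    abort(paste0("insufficient strips for the split (",
                 paste(deficit, collapse = "; "), ")"),
          class = "ecgdys_split_error")
  }
  withr::with_seed(seed, {
    train <- sample(eu_ids, cfg$n_train_eu)
    val_eu <- sample(setdiff(eu_ids, train), cfg$n_val_eu)
    val_dys <- sample(dys_ids, cfg$n_val_dys)
  })
  strips |>
    mutate(split = case_when(
      .data$strip_id %in% train ~ "train",
      .data$strip_id %in% c(val_eu, val_dys) ~ "val",
      TRUE ~ "none"))
}

#' Write a synthetic subject's data files
#'
#' Emits the ECG (WFDB or CSV) and the BG table (`time_s,glucose_mgdl` CSV),
#' the on-disk interface of the pipeline.
#'
#' @param subject A `synthetic_subject`.
#' @param dir Output directory (created if needed).
#' @param format ECG format, `"wfdb"` or `"csv"`.
#' @return The directory, invisibly.
#' @export
write_subject_data <- function(subject, dir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(subject, "synthetic_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, subject$subject_id)
  if (format == "wfdb") write_ecg(subject$record, base, "wfdb")
  else write_ecg(subject$record, paste0(base, ".csv"), "csv")
  write.csv(subject$bg[c("time_s", "glucose_mgdl")],
            paste0(base, "_bg.csv"), row.names = FALSE)
  invisible(dir)
}
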