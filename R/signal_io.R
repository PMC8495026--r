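STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a multi-lead ECG record
#'
#' An `ecg_record` holds a short multi-lead voltage recording together with
#' the metadata needed downstream: sampling rate, subject identity, sex and
#' age. Voltages are always stored in millivolts so that attractor measures
#' are comparable across records and sources.
#'
#' @param record_id Character scalar identifying the recording.
#' @param subject_id Character scalar identifying the subject (defaults to
#'   `record_id`).
#' @param samples Numeric matrix, one column per lead, in mV.
#' @param lead_names Character vector of lead labels, drawn from the standard
#'   12-lead set (I, II, III, aVR, aVL, aVF, V1-V6), no duplicates.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param age Age in years, or `NA` if missing.
#' @param order_key Optional ordering key (e.g. acquisition date or sequence
#'   number) used when deduplicating multiple recordings per subject.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, lead_names, sampling_rate,
                       subject_id = record_id, sex = "unknown", age = NA_real_,
                       order_key = record_id) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.character(lead_names) || anyDuplicated(lead_names))
    stop("lead_names must be unique character labels")
  if (!all(lead_names %in% STANDARD_LEADS))
    stop("unknown lead label(s): ",
         paste(setdiff(lead_names, STANDARD_LEADS), collapse = ", "))
  if (ncol(samples) != length(lead_names))
    stop("samples has ", ncol(samples), " columns but ", length(lead_names),
         " lead names were given")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  sex <- match.arg(sex, c("female", "male", "unknown"))
  colnames(samples) <- lead_names
  structure(list(
    record_id = as.character(record_id),
    subject_id = as.character(subject_id),
    lead_names = lead_names,
    samples = samples,
    sampling_rate = as.numeric(sampling_rate),
    duration = nrow(samples) / sampling_rate,
    sex = sex,
    age = as.numeric(age),
    order_key = as.character(order_key)
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> %d leads x %d samples @ %g Hz (%.2f s), sex=%s, age=%s\n",
              x$record_id, length(x$lead_names), nrow(x$samples),
              x$sampling_rate, x$duration, x$sex,
              ifelse(is.na(x$age), "NA", format(x$age))))
  invisible(x)
}

#' Extract one lead of an ECG record
#'
#' @param record An `ecg_record`.
#' @param lead Lead label.
#' @return Numeric vector of samples in mV.
#' @export
record_lead <- function(record, lead) {
  if (!lead %in% record$lead_names)
    stop("record ", record$record_id, " has no lead ", lead)
  record$samples[, lead]
}

#' Construct a cohort of ECG records
#'
#' @param records List of `ecg_record` objects.
#' @param provenance Character vector (recycled) tagging the source of each
#'   record.
#' @return An object of class `ecg_cohort`.
#' @export
ecg_cohort <- function(records, provenance = "unknown") {
  if (!all(vapply(records, inherits, logical(1), "ecg_record")))
    stop("all elements must be ecg_record objects")
  provenance <- rep_len(as.character(provenance), length(records))
  structure(list(records = records, provenance = provenance),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  sexes <- vapply(x$records, `[[`, character(1), "sex")
  cat(sprintf("<ecg_cohort> %d records (%d female, %d male, %d unknown)\n",
              length(x$records), sum(sexes == "female"),
              sum(sexes == "male"), sum(sexes == "unknown")))
  invisible(x)
}

#' @export
length.ecg_cohort <- function(x) length(x$records)

#' Cohort metadata table
#'
#' @param cohort An `ecg_cohort`.
#' @return A data.frame with one row per record: record_id, subject_id, sex,
#'   age, provenance.
#' @export
cohort_metadata <- function(cohort) {
  data.frame(
    record_id = vapply(cohort$records, `[[`, character(1), "record_id"),
    subject_id = vapply(cohort$records, `[[`, character(1), "subject_id"),
    sex = vapply(cohort$records, `[[`, character(1), "sex"),
    age = vapply(cohort$records, `[[`, numeric(1), "age"),
    provenance = cohort$provenance,
    stringsAsFactors = FALSE
  )
}

#' Keep only the first recording per subject
#'
#' When a subject contributed several recordings, all but the earliest are
#' dropped. "Earliest" is decided by each record's `order_key` (acquisition
#' date where available, else the record id), with the record id as a
#' deterministic tie-break.
#'
#' @param cohort An `ecg_cohort`.
#' @return An `ecg_cohort` with exactly one record per `subject_id`. The
#'   operation is idempotent.
#' @export
dedupe_first_record <- function(cohort) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  if (length(cohort$records) == 0) return(cohort)
  subj <- vapply(cohort$records, `[[`, character(1), "subject_id")
  key <- vapply(cohort$records, `[[`, character(1), "order_key")
  rid <- vapply(cohort$records, `[[`, character(1), "record_id")
  ord <- order(subj, key, rid)
  keep_sorted <- !duplicated(subj[ord])
  keep <- sort(ord[keep_sorted])
  ecg_cohort(cohort$records[keep], cohort$provenance[keep])
}

# ---------------------------------------------------------------------------
# WFDB (PhysioNet) header + 16-bit signal files. Only the subset used by the
# 10 s resting ECG databases is supported: format 16, one .dat for all leads,
# gain in adu/mV, optional baseline, '# key: value' comment metadata.
# ---------------------------------------------------------------------------

#' Read a WFDB record (format 16)
#'
#' Parses a PhysioNet WFDB header (`.hea`) plus its interleaved 16-bit
#' little-endian signal file and returns the voltages converted to mV via
#' each signal's gain and baseline. Sex and age are taken from `# sex:` /
#' `# age:` comment lines when present, else left unknown/missing.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @return An `ecg_record`.
#' @export
read_wfdb_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- lines[startsWith(trimws(lines), "#")]
  lines <- lines[!startsWith(trimws(lines), "#")]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 4)
    stop("malformed WFDB header line: ", lines[1])
  record_id <- sub("/.*", "", head_tok[1])
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(sub("/.*", "", head_tok[3]))
  nsamp <- as.integer(head_tok[4])
  sig_lines <- lines[-1]
  if (length(sig_lines) != nsig)
    stop("WFDB header declares ", nsig, " signals but lists ",
         length(sig_lines))
  parse_sig <- function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x.*|:.*|\\+.*", "", tok[2])
    gain_tok <- tok[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_tok)))
    baseline <- if (grepl("\\(", gain_tok))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_tok)) else 0
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else NA_character_
    list(file = tok[1], fmt = fmt, gain = gain, baseline = baseline,
         desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  if (any(vapply(sigs, `[[`, character(1), "fmt") != "16"))
    stop("only WFDB format 16 is supported")
  dat_files <- unique(vapply(sigs, `[[`, character(1), "file"))
  if (length(dat_files) != 1)
    stop("multi-file WFDB records are not supported")
  dat_path <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, integer(), n = nsig * nsamp, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp)
    stop("WFDB signal file shorter than declared: ", dat_path)
  adc <- matrix(raw, nrow = nsamp, ncol = nsig, byrow = TRUE)
  gains <- vapply(sigs, `[[`, numeric(1), "gain")
  gains[!is.finite(gains) | gains == 0] <- 200  # WFDB default gain adu/mV
  basel <- vapply(sigs, `[[`, numeric(1), "baseline")
  mv <- sweep(sweep(adc, 2, basel, "-"), 2, gains, "/")
  leads <- vapply(sigs, `[[`, character(1), "desc")
  if (anyNA(leads)) leads <- STANDARD_LEADS[seq_len(nsig)]
  meta <- parse_wfdb_comments(comments)
  ecg_record(record_id, mv, leads, fs,
             subject_id = meta$subject_id %||% record_id,
             sex = meta$sex, age = meta$age,
             order_key = meta$order_key %||% record_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_wfdb_comments <- function(comments) {
  out <- list(sex = "unknown", age = NA_real_, subject_id = NULL,
              order_key = NULL)
  for (cm in comments) {
    body <- trimws(sub("^\\s*#", "", cm))
    kv <- regmatches(body, regexec("^([A-Za-z_ ]+):\\s*(.*)$", body))[[1]]
    if (length(kv) != 3) next
    key <- tolower(trimws(kv[2])); val <- trimws(kv[3])
    if (key == "sex") {
      out$sex <- switch(tolower(substr(val, 1, 1)),
                        "f" = "female", "m" = "male", "unknown")
    } else if (key == "age") {
      a <- suppressWarnings(as.numeric(val))
      out$age <- if (is.finite(a)) a else NA_real_
    } else if (key %in% c("subject", "subject_id", "subject id")) {
      out$subject_id <- val
    } else if (key %in% c("date", "order", "order_key")) {
      out$order_key <- val
    }
  }
  out
}

#' Write an ECG record in WFDB format 16
#'
#' Millivolt samples are quantised with the given gain (adu/mV) into 16-bit
#' integers; sex, age and subject id are stored as header comments so a
#' round-trip through [read_wfdb_record()] preserves the metadata.
#'
#' @param record An `ecg_record`.
#' @param path Output path without extension; `.hea` and `.dat` are written.
#' @param gain ADC units per mV (default 1000).
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(record, path, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  nsamp <- nrow(record$samples)
  nsig <- ncol(record$samples)
  base <- basename(path)
  adc <- round(record$samples * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  header <- c(
    sprintf("%s %d %g %d", base, nsig, record$sampling_rate, nsamp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
            base, gain, record$lead_names),
    sprintf("# age: %s", ifelse(is.na(record$age), "NaN", record$age)),
    sprintf("# sex: %s", switch(record$sex, female = "F", male = "M", "?")),
    sprintf("# subject_id: %s", record$subject_id),
    sprintf("# order_key: %s", record$order_key)
  )
  writeLines(header, paste0(path, ".hea"))
  interleaved <- as.integer(t(adc))
  writeBin(interleaved, paste0(path, ".dat"), size = 2, endian = "little")
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Expects one column per lead with a header row of lead names (or supply
#' `lead_names` to override). Values are taken to be in mV.
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate in Hz.
#' @param lead_names Optional lead labels; default taken from the header row.
#' @param record_id Record identifier (default: file name without extension).
#' @inheritParams ecg_record
#' @return An `ecg_record`.
#' @export
read_csv_record <- function(path, sampling_rate, lead_names = NULL,
                            record_id = sub("\\.[^.]*$", "", basename(path)),
                            sex = "unknown", age = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty CSV record: ", path)
  if (is.null(lead_names)) lead_names <- colnames(df)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[j]])))))
      stop("non-numeric value in column ", colnames(df)[j],
           " at data row ", bad[1])
    }
  }
  ecg_record(record_id, as.matrix(df), lead_names, sampling_rate,
             sex = sex, age = age)
}

#' Write an ECG record to CSV
#'
#' @param record An `ecg_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  df <- as.data.frame(record$samples)
  colnames(df) <- record$lead_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns record_id, subject_id, sex, age and
#'   optionally label / order_key.
#' @return data.frame.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "subject_id", "sex", "age")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("metadata table missing column(s): ", paste(missing, collapse = ", "))
  df$sex <- ifelse(tolower(substr(df$sex, 1, 1)) == "f", "female",
                   ifelse(tolower(substr(df$sex, 1, 1)) == "m", "male",
                          "unknown"))
  df
}
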