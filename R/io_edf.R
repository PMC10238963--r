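# EDF+ annotation-file I/O.
#
# Only the annotation channel ("EDF Annotations" signal, TAL-encoded) is
# supported: hypnograms live entirely in annotations, so no waveform signals
# are read or written (record duration 0, as the EDF+ standard permits for
# annotation-only files).  Onsets are seconds relative to the header start
# time; 1-s precision.
#
# Stage annotation texts follow the AASM standard spelling:
#   "Sleep stage W", "Sleep stage N1", "Sleep stage N2", "Sleep stage N3",
#   "Sleep stage R"
# For the 4-stage device vocabulary the merged light class has no standard
# text; we use the dedicated text "Sleep stage L" and tag the vocabulary in
# the recording-identification header field so the round trip is lossless
# (writing "Sleep stage N2" would pretend N1/N2 detail exists).

TAL_ONSET_SEP <- "\x14"   # separates onset[/duration] from annotation texts
TAL_DUR_SEP   <- "\x15"   # separates onset from duration

DEFAULT_LIGHTS_OFF_TEXTS <- c("Lights off", "Lights Off", "lights off", "LIGHTS OFF")
DEFAULT_LIGHTS_ON_TEXTS  <- c("Lights on", "Lights On", "lights on", "LIGHTS ON")

stage_text_for <- function(stage, vocabulary) {
  if (vocabulary == "AASM5") {
    switch(stage,
      W = "Sleep stage W", N1 = "Sleep stage N1", N2 = "Sleep stage N2",
      N3 = "Sleep stage N3", REM = "Sleep stage R",
      UNSCORED = "Sleep stage ?")
  } else {
    switch(stage,
      WAKE = "Sleep stage W", LIGHT = "Sleep stage L",
      DEEP = "Sleep stage N3", REM = "Sleep stage R",
      UNSCORED = "Sleep stage ?")
  }
}

stage_from_text <- function(text, vocabulary) {
  code <- sub("^Sleep stage ", "", text)
  if (vocabulary == "AASM5") {
    switch(code, W = "W", N1 = "N1", N2 = "N2", N3 = "N3",
           R = "REM", REM = "REM", "?" = UNSCORED, NA_character_)
  } else {
    switch(code, W = "WAKE", L = "LIGHT", N3 = "DEEP",
           R = "REM", REM = "REM", "?" = UNSCORED, NA_character_)
  }
}

is_stage_text <- function(text) startsWith(text, "Sleep stage ")

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a hypnogram to an EDF+ annotation file
#'
#' Emits an annotation-only EDF+ file (EDF+C, record duration 0) holding one
#' stage annotation per epoch plus `Lights off` / `Lights on` marker
#' annotations. Stage texts follow the AASM standard spelling; the device
#' vocabulary's merged light class is written as the dedicated text
#' `"Sleep stage L"` and the vocabulary is tagged in the
#' recording-identification header field, so [read_edfplus_hypnogram()]
#' inverts the file exactly.
#'
#' @param hyp A nonempty [hypnogram()].
#' @param markers [recording_markers()]; the header start time is
#'   `markers$start_time`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edfplus_hypnogram <- function(hyp, markers, path) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(markers, "recording_markers"))
  if (length(hyp$stages) == 0L)
    stop("cannot write an empty hypnogram", call. = FALSE)
  if (hyp$start < markers$start_time)
    stop("hypnogram starts before markers$start_time", call. = FALSE)

  t0 <- markers$start_time
  rel <- function(t) as.numeric(difftime(t, t0, units = "secs"))

  onsets <- rel(epoch_onsets(hyp))
  tals <- c(
    make_tal(rel(markers$lights_off), NULL, "Lights off"),
    make_tal(rel(markers$lights_on), NULL, "Lights on"),
    vapply(seq_along(hyp$stages), function(i) {
      make_tal(onsets[i], hyp$epoch_s, stage_text_for(hyp$stages[i], hyp$vocabulary))
    }, character(1))
  )

  # chunk TALs into data records; each record opens with a timekeeping TAL.
  # TALs are NUL-terminated, so records are assembled as raw vectors.
  chunk_size <- 120L
  idx <- split(seq_along(tals), ceiling(seq_along(tals) / chunk_size))
  records <- lapply(idx, function(i) {
    onset0 <- tal_onset(tals[[i[1]]])
    chunk <- c(make_timekeeping_tal(onset0), tals[i])
    do.call(c, lapply(chunk, function(s) c(charToRaw(s), as.raw(0L))))
  })
  rec_bytes <- lengths(records)
  # all records share one samples-per-record; 2 bytes per sample
  ns_per_rec <- as.integer(ceiling(max(rec_bytes) / 2) + 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  n_rec <- length(records)
  header <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(paste0("Startdate ", toupper(format(t0, "%d-%b-%Y")),
                     " X X hypnoval_", hyp$vocabulary), 80),
    pad_field(format(t0, "%d.%m.%y"), 8),
    pad_field(format(t0, "%H.%M.%S"), 8),
    pad_field(256L * 2L, 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field("0", 8),
    pad_field(1L, 4),
    # signal header for the single annotation signal
    pad_field("EDF Annotations", 16),
    pad_field("", 80),
    pad_field("", 8),
    pad_field("-1", 8),
    pad_field("1", 8),
    pad_field("-32768", 8),
    pad_field("32767", 8),
    pad_field("", 80),
    pad_field(ns_per_rec, 8),
    pad_field("", 32)
  )
  writeBin(charToRaw(header), con)
  for (r in records) {
    writeBin(c(r, raw(2L * ns_per_rec - length(r))), con)
  }
  invisible(path)
}

make_tal <- function(onset, duration, text) {
  paste0(if (onset >= 0) "+" else "", format_edf_num(onset),
         if (!is.null(duration)) paste0(TAL_DUR_SEP, format_edf_num(duration)),
         TAL_ONSET_SEP, text, TAL_ONSET_SEP)
}

make_timekeeping_tal <- function(onset) {
  paste0(if (onset >= 0) "+" else "", format_edf_num(onset),
         TAL_ONSET_SEP, TAL_ONSET_SEP)
}

format_edf_num <- function(x) {
  if (x == round(x)) sprintf("%d", as.integer(round(x)))
  else sub("0+$", "", sprintf("%.3f", x))
}

tal_onset <- function(tal) {
  head_part <- strsplit(tal, TAL_ONSET_SEP, fixed = TRUE)[[1]][1]
  as.numeric(strsplit(head_part, TAL_DUR_SEP, fixed = TRUE)[[1]][1])
}

#' Read a hypnogram from an EDF+ annotation file
#'
#' Parses the annotation channel of an EDF+ file, extracts `Sleep stage *`
#' annotations and tiles them onto a regular epoch grid. The epoch duration
#' is implied by the annotations (greatest common divisor of stage-annotation
#' durations); annotations spanning several epochs are expanded, and gaps
#' between annotations become `UNSCORED` epochs. Lights-off/lights-on marker
#' annotations populate the returned [recording_markers()]; when absent they
#' default to the recording start / end of the last annotation, with a
#' warning.
#'
#' @param path Path to an EDF+ file.
#' @param lights_off_texts,lights_on_texts Accepted marker annotation texts.
#' @return A list with elements `hypnogram` and `markers`.
#' @export
read_edfplus_hypnogram <- function(path,
                                   lights_off_texts = DEFAULT_LIGHTS_OFF_TEXTS,
                                   lights_on_texts = DEFAULT_LIGHTS_ON_TEXTS) {
  hdr <- read_edf_header(path)
  anns <- read_edf_annotations(path, hdr)

  vocabulary <- if (grepl("hypnoval_DEV4", hdr$recording_id, fixed = TRUE))
    "DEV4" else "AASM5"

  stage_rows <- anns[is_stage_text(anns$text), , drop = FALSE]
  if (nrow(stage_rows) == 0L)
    stop("no sleep-stage annotations found in ", path, call. = FALSE)
  stage_rows <- stage_rows[order(stage_rows$onset), , drop = FALSE]
  stage_rows$stage <- vapply(stage_rows$text, stage_from_text, character(1),
                             vocabulary = vocabulary)
  if (anyNA(stage_rows$stage))
    stop("unrecognised stage text: ",
         stage_rows$text[is.na(stage_rows$stage)][1], call. = FALSE)
  if (any(is.na(stage_rows$duration) | stage_rows$duration <= 0))
    stop("stage annotation without a positive duration", call. = FALSE)

  # overlapping stage annotations are a consistency error
  ends <- stage_rows$onset + stage_rows$duration
  if (nrow(stage_rows) > 1L) {
    ov <- which(stage_rows$onset[-1] < ends[-nrow(stage_rows)] - 1e-9)
    if (length(ov))
      stop(sprintf("overlapping stage annotations at %.0f-%.0f s and %.0f s",
                   stage_rows$onset[ov[1]], ends[ov[1]],
                   stage_rows$onset[ov[1] + 1L]), call. = FALSE)
  }

  epoch_s <- Reduce(gcd_int, as.integer(round(stage_rows$duration)))
  gaps <- stage_rows$onset[-1] - ends[-nrow(stage_rows)]
  if (any(abs(gaps - round(gaps / epoch_s) * epoch_s) > 1e-6))
    stop("annotation gap is not a multiple of the epoch duration (",
         epoch_s, " s)", call. = FALSE)

  first_onset <- stage_rows$onset[1]
  n_epochs <- as.integer(round((max(ends) - first_onset) / epoch_s))
  stages <- rep(UNSCORED, n_epochs)
  for (i in seq_len(nrow(stage_rows))) {
    from <- as.integer(round((stage_rows$onset[i] - first_onset) / epoch_s))
    len <- as.integer(round(stage_rows$duration[i] / epoch_s))
    stages[from + seq_len(len)] <- stage_rows$stage[i]
  }

  hyp <- hypnogram(stages, hdr$start + first_onset, epoch_s, vocabulary)

  off_rows <- anns$onset[anns$text %in% lights_off_texts]
  on_rows  <- anns$onset[anns$text %in% lights_on_texts]
  if (length(off_rows) == 0L || length(on_rows) == 0L) {
    warning("lights off/on markers absent in ", basename(path),
            "; defaulting to recording span", call. = FALSE)
  }
  lights_off <- if (length(off_rows)) hdr$start + off_rows[1] else hdr$start
  lights_on  <- if (length(on_rows)) hdr$start + on_rows[1] else hypnogram_end(hyp)

  list(
    hypnogram = hyp,
    markers = recording_markers(
      lights_off = lights_off, lights_on = lights_on,
      start_time = min(hdr$start, lights_off),
      end_time = max(hypnogram_end(hyp), lights_on)
    )
  )
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256L)
  if (length(fixed) < 256L) stop("malformed EDF header: file too short", call. = FALSE)
  fld <- function(raw, from, len) trimws(rawToChar(raw[from:(from + len - 1L)]))
  version <- fld(fixed, 1L, 8L)
  if (version != "0") stop("malformed EDF header: bad version field", call. = FALSE)
  reserved <- fld(fixed, 193L, 44L)
  if (!startsWith(reserved, "EDF+"))
    stop("not an EDF+ file (reserved field: '", reserved, "')", call. = FALSE)
  startdate <- fld(fixed, 169L, 8L)
  starttime <- fld(fixed, 177L, 8L)
  start <- as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")
  if (is.na(start)) stop("malformed EDF header: bad start date/time", call. = FALSE)
  n_rec <- suppressWarnings(as.integer(fld(fixed, 237L, 8L)))
  ns <- suppressWarnings(as.integer(fld(fixed, 253L, 4L)))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count", call. = FALSE)
  sig <- readBin(con, "raw", 256L * ns)
  if (length(sig) < 256L * ns) stop("malformed EDF header: truncated signal headers",
                                    call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) {
    fld(sig, (i - 1L) * 16L + 1L, 16L)
  }, character(1))
  spr_off <- ns * (16L + 80L + 8L + 8L + 8L + 8L + 8L + 80L)
  samples_per_rec <- vapply(seq_len(ns), function(i) {
    as.integer(fld(sig, spr_off + (i - 1L) * 8L + 1L, 8L))
  }, integer(1))
  list(
    recording_id = fld(fixed, 89L, 80L),
    start = start, n_records = n_rec, ns = ns,
    labels = labels, samples_per_record = samples_per_rec,
    header_bytes = 256L * (ns + 1L)
  )
}

read_edf_annotations <- function(path, hdr = read_edf_header(path)) {
  ann_idx <- which(hdr$labels == "EDF Annotations")
  if (length(ann_idx) == 0L)
    stop("no 'EDF Annotations' signal in ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", hdr$header_bytes))
  rec_samp <- hdr$samples_per_record
  out <- list()
  for (r in seq_len(max(hdr$n_records, 0L))) {
    for (s in seq_len(hdr$ns)) {
      chunk <- readBin(con, "raw", 2L * rec_samp[s])
      if (length(chunk) == 0L) break
      if (s %in% ann_idx) out[[length(out) + 1L]] <- chunk
    }
  }
  tals <- unlist(lapply(out, split_on_nul))
  tals <- tals[nzchar(tals)]
  parsed <- lapply(tals, parse_tal)
  parsed <- do.call(rbind, parsed)
  if (is.null(parsed))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      text = character(0), stringsAsFactors = FALSE))
  parsed[!is.na(parsed$text) & nzchar(parsed$text), , drop = FALSE]
}

parse_tal <- function(tal) {
  parts <- strsplit(tal, TAL_ONSET_SEP, fixed = TRUE)[[1]]
  if (length(parts) == 0L) return(NULL)
  head_part <- strsplit(parts[1], TAL_DUR_SEP, fixed = TRUE)[[1]]
  onset <- suppressWarnings(as.numeric(head_part[1]))
  if (is.na(onset)) return(NULL)
  duration <- if (length(head_part) > 1L)
    suppressWarnings(as.numeric(head_part[2])) else NA_real_
  texts <- parts[-1]
  texts <- texts[nzchar(texts)]
  if (length(texts) == 0L) return(NULL)  # timekeeping TAL
  data.frame(onset = onset, duration = duration, text = texts,
             stringsAsFactors = FALSE)
}

split_on_nul <- function(chunk) {
  zero <- which(chunk == as.raw(0L))
  starts <- c(1L, zero + 1L)
  ends <- c(zero - 1L, length(chunk))
  segs <- mapply(function(s, e) {
    if (s <= e) rawToChar(chunk[s:e]) else ""
  }, starts, ends, USE.NAMES = FALSE)
  segs[nzchar(segs)]
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)
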