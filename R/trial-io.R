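#' @section Trial tables:
#' Throughout the package a *trial table* is a tibble with one row per
#' trial and columns `subject`, `session` (integer 1..5), `trial`
#' (within-session index), `label` (factor left/right), `sampling_rate`
#' and `data` (list-column of 3 x samples matrices with rows C3, Cz, C4).
#' Trials are epoched to `[0, 8)` s relative to trial start with the cue
#' at 3 s, so the imagery interval 3--7 s is anchored at samples
#' `3*fs .. 7*fs` (0-based, half-open).
#' @name trial-table
#' @keywords internal
NULL

trial_cols <- c("subject", "session", "trial", "label", "sampling_rate", "data")

check_trial_table <- function(trials, what = "trials") {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing))
    stopf("midecoder_error_format", "%s is missing column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(trials)
}

#' Write a trial table as a plain-text fixture
#'
#' One signals CSV and one JSON manifest per subject. The CSV holds the
#' raw samples in long form (`session`, `trial`, `sample`, `C3`, `Cz`,
#' `C4`); the manifest records labels, sampling rate and sample counts.
#' Values round-trip through [read_trials()] at full double precision.
#'
#' @param trials A trial table (see [generate_dataset()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  check_trial_table(trials)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subj in unique(trials$subject)) {
    sub <- trials[trials$subject == subj, ]
    sig <- purrr::pmap(list(sub$session, sub$trial, sub$data),
      function(session, trial, data) {
        tibble::tibble(session = session, trial = trial,
                       sample = seq_len(ncol(data)) - 1L,
                       C3 = data[1, ], Cz = data[2, ], C4 = data[3, ])
      })
    readr::write_csv(dplyr::bind_rows(sig),
                     file.path(dir, paste0(subj, "_signals.csv")))
    manifest <- list(
      format = "midecoder-fixture", version = 1L, subject = subj,
      sampling_rate = sub$sampling_rate[[1]],
      n_samples = ncol(sub$data[[1]]),
      trials = purrr::pmap(list(sub$session, sub$trial, as.character(sub$label)),
                           function(session, trial, label)
                             list(session = session, trial = trial, label = label))
    )
    jsonlite::write_json(manifest, file.path(dir, paste0(subj, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read trials from disk
#'
#' @param path Directory containing per-subject fixture files (dialect
#'   `"fixture"`), or a directory/file of GDF recordings (dialect `"gdf"`).
#' @param dialect `"fixture"` for the package's plain-text format written
#'   by [write_trials()]; `"gdf"` for BCI Competition IV-2b style GDF
#'   recordings. The GDF path requires a `python` interpreter with the
#'   `mne` library on the PATH: files are converted to the fixture format
#'   by the bundled `inst/python/gdf2fixture.py` and then read back.
#' @return A trial table.
#' @export
read_trials <- function(path, dialect = c("fixture", "gdf")) {
  dialect <- match.arg(dialect)
  if (dialect == "gdf") return(read_trials_gdf(path))
  manifests <- sort(list.files(path, pattern = "_manifest\\.json$",
                               full.names = TRUE))
  if (!length(manifests))
    stopf("midecoder_error_format", "no fixture manifests found under %s", path)
  rows <- lapply(manifests, function(mf) {
    man <- jsonlite::read_json(mf, simplifyVector = FALSE)
    if (!identical(man$format, "midecoder-fixture"))
      stopf("midecoder_error_format", "%s is not a midecoder fixture manifest", mf)
    sig <- readr::read_csv(sub("_manifest\\.json$", "_signals.csv", mf),
                           show_col_types = FALSE)
    if (!all(c("C3", "Cz", "C4") %in% names(sig)))
      stopf("midecoder_error_format", "fixture for %s lacks the 3 channels",
            man$subject)
    meta <- dplyr::bind_rows(lapply(man$trials, tibble::as_tibble))
    dat <- lapply(seq_len(nrow(meta)), function(i) {
      block <- sig[sig$session == meta$session[i] & sig$trial == meta$trial[i], ]
      block <- block[order(block$sample), ]
      if (nrow(block) != man$n_samples)
        stopf("midecoder_error_format",
              "subject %s session %d trial %d: %d samples on disk, manifest says %d",
              man$subject, meta$session[i], meta$trial[i], nrow(block),
              man$n_samples)
      t(`colnames<-`(as.matrix(block[, c("C3", "Cz", "C4")]), NULL))
    })
    dat <- lapply(dat, function(m) { rownames(m) <- c("C3", "Cz", "C4"); m })
    tibble::tibble(subject = man$subject,
                   session = as.integer(meta$session),
                   trial = as.integer(meta$trial),
                   label = factor(meta$label, levels = c("left", "right")),
                   sampling_rate = man$sampling_rate, data = dat)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$session, .data$trial)
}

read_trials_gdf <- function(path) {
  py <- Sys.which("python")
  if (py == "")
    stopf("midecoder_error_gdf",
          "reading GDF requires a python interpreter with mne on the PATH")
  script <- system.file("python", "gdf2fixture.py", package = "midecoder")
  out <- tempfile("gdf_fixture_")
  status <- system2(py, c(script, shQuote(path), shQuote(out)))
  if (status != 0)
    stopf("midecoder_error_gdf",
          "GDF conversion failed (exit %d); is the mne library installed?",
          status)
  read_trials(out, dialect = "fixture")
}

#' Intra-subject (within-subject) train/test split
#'
#' Training data are sessions 1--3 of the subject, test data sessions
#' 4--5, mirroring the calibration/evaluation session structure of cue-
#' paradigm BCI recordings. No shuffling happens at this layer.
#'
#' @param trials A trial table containing all 5 sessions of `subject`.
#' @param subject Subject id to split.
#' @return A list with trial tables `train` and `test`.
#' @export
split_intra_subject <- function(trials, subject) {
  check_trial_table(trials)
  sub <- trials[trials$subject == subject, ]
  if (!nrow(sub))
    stopf("midecoder_error_split", "subject %s not present", subject)
  missing <- setdiff(1:5, unique(sub$session))
  if (length(missing))
    stopf("midecoder_error_split", "subject %s is missing session(s) %s",
          subject, paste(missing, collapse = ", "))
  list(train = sub[sub$session %in% 1:3, ],
       test = sub[sub$session %in% 4:5, ])
}

#' Leave-one-subject-out (inter-subject) split
#'
#' Training data are *all* sessions (1--5) of every subject except the
#' held-out one; test data are the held-out subject's evaluation sessions
#' 4--5. This is the transfer-learning protocol: the decoder never sees
#' any data from the subject it is evaluated on.
#'
#' @param trials A trial table with at least two subjects.
#' @param held_out Subject id to hold out.
#' @return A list with trial tables `train` and `test`.
#' @export
assemble_inter_subject <- function(trials, held_out) {
  check_trial_table(trials)
  subjects <- unique(trials$subject)
  if (length(subjects) < 2)
    stopf("midecoder_error_split", "need >= 2 subjects for leave-one-out")
  if (!held_out %in% subjects)
    stopf("midecoder_error_split", "held-out subject %s not present", held_out)
  list(train = trials[trials$subject != held_out, ],
       test = trials[trials$subject == held_out & trials$session %in% 4:5, ])
}
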