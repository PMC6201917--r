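#' Describe the column layout of a gaze CSV file
#'
#' Raw gaze recordings are plain CSV sample streams with one row per tracker
#' sample: a timestamp in milliseconds, screen coordinates in pixels (origin
#' top-left, x rightward, y downward), and a validity flag. Different
#' eye-tracker exports name these columns differently; a dialect maps the
#' package's canonical names onto the file's header.
#'
#' @param t,x,y Column names holding the timestamp (ms) and the horizontal /
#'   vertical gaze position (px).
#' @param valid Column name of the validity flag (logical or 0/1), or `NULL`
#'   if the file has no such column (all rows are then taken as valid).
#' @return A named list of class `gaze_dialect`.
#' @examples
#' gaze_dialect(t = "time", x = "gx", y = "gy", valid = NULL)
#' @export
gaze_dialect <- function(t = "t_ms", x = "x_px", y = "y_px", valid = "valid") {
  structure(list(t = t, x = x, y = y, valid = valid), class = "gaze_dialect")
}

#' Read a raw gaze sample stream from CSV
#'
#' Reads one participant-by-text recording. Rows are returned sorted by
#' timestamp; rows whose validity flag is false are retained but marked
#' invalid (they are ignored later by event detection). Rows with
#' non-numeric timestamp or coordinates despite being flagged valid are
#' dropped, with an error if they exceed `max_bad_fraction` of the file.
#'
#' @param path Path to a CSV file with a header.
#' @param dialect A [gaze_dialect()] mapping canonical column names onto the
#'   file's header.
#' @param max_bad_fraction Largest tolerated fraction of malformed valid
#'   rows before the whole file is rejected.
#' @return A tibble with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @seealso [write_gaze_csv()], [detect_fixations()]
#' @export
read_gaze_csv <- function(path, dialect = gaze_dialect(), max_bad_fraction = 0.05) {
  if (!file.exists(path)) {
    abort(paste0("gaze file not found: ", path), class = "gazeread_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c(t = dialect$t, x = dialect$x, y = dialect$y)
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("gaze file ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazeread_format_error")
  }
  valid <- if (!is.null(dialect$valid) && dialect$valid %in% names(raw)) {
    v <- toupper(trimws(raw[[dialect$valid]]))
    !(v %in% c("FALSE", "F", "0", "NO"))
  } else {
    rep(TRUE, nrow(raw))
  }
  t <- suppressWarnings(as.numeric(raw[[dialect$t]]))
  x <- suppressWarnings(as.numeric(raw[[dialect$x]]))
  y <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  bad <- valid & (!is.finite(t) | is.na(x) | is.na(y))
  if (nrow(raw) > 0 && sum(bad) / nrow(raw) > max_bad_fraction) {
    abort(paste0("gaze file ", path, ": ", sum(bad), " of ", nrow(raw),
                 " valid rows are malformed (limit ",
                 format(max_bad_fraction), ")"),
          class = "gazeread_format_error")
  }
  if (any(bad)) {
    inform(paste0("read_gaze_csv: dropped ", sum(bad), " malformed row(s) from ", path))
  }
  out <- tibble::tibble(t_ms = t, x_px = x, y_px = y, valid = valid)[!bad, ]
  out <- out[is.finite(out$t_ms), , drop = FALSE]
  out[order(out$t_ms), ]
}

#' Write a gaze sample stream to CSV
#'
#' @param samples A tibble with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(samples, path) {
  stopifnot(all(c("t_ms", "x_px", "y_px") %in% names(samples)))
  if (is.null(samples$valid)) samples$valid <- TRUE
  readr::write_csv(samples[, c("t_ms", "x_px", "y_px", "valid")], path, progress = FALSE)
  invisible(path)
}

#' Read a session manifest
#'
#' A session manifest links participants and texts: which texts each
#' participant read, the character count of each text, the self-rated
#' understanding (1-5, where 1 means the text was aborted) and the
#' correctness of the one comprehension question per text. Texts rated 1 are
#' flagged `excluded` and never enter feature averages, answer scores or the
#' prediction target. The manifest is a YAML document with a required
#' `schema_version` field, `texts:` (text_id, n_chars, optional level) and
#' `participants:` (participant_id plus per-text `rating`, `answer_correct`
#' and optional `gaze_file`).
#'
#' @param path Path to a YAML manifest.
#' @return An object of class `gaze_manifest`: a list with tibbles `texts`
#'   (`text_id`, `n_chars`, `level`), `outcomes` (`participant_id`,
#'   `text_id`, `rating`, `answer_correct`, `excluded`) and `files`
#'   (`participant_id`, `text_id`, `gaze_file`).
#' @seealso [write_manifest()], [simulate_cohort()]
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "gazeread_io_error")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version)) {
    abort("manifest is missing the schema_version field",
          class = "gazeread_format_error")
  }
  if (is.null(doc$texts) || is.null(doc$participants)) {
    abort("manifest must contain both 'texts' and 'participants'",
          class = "gazeread_format_error")
  }
  texts <- purrr::map_dfr(doc$texts, function(tx) {
    tibble::tibble(
      text_id = as.character(tx$text_id),
      n_chars = as.integer(tx$n_chars),
      level = as.character(tx$level %||% NA_character_)
    )
  })
  if (any(is.na(texts$n_chars)) || any(texts$n_chars < 1)) {
    abort("every text needs n_chars >= 1", class = "gazeread_validation_error")
  }
  if (anyDuplicated(texts$text_id)) {
    abort("duplicate text_id in manifest texts", class = "gazeread_validation_error")
  }
  rows <- purrr::map_dfr(doc$participants, function(pp) {
    purrr::map_dfr(pp$texts, function(tx) {
      tibble::tibble(
        participant_id = as.character(pp$participant_id),
        text_id = as.character(tx$text_id),
        rating = as.integer(tx$rating),
        answer_correct = as.integer(tx$answer_correct),
        gaze_file = as.character(tx$gaze_file %||% NA_character_)
      )
    })
  })
  if (any(is.na(rows$rating)) || any(!rows$rating %in% 1:5)) {
    offending <- rows$rating[is.na(rows$rating) | !rows$rating %in% 1:5]
    abort(paste0("self-rated understanding must be an integer in 1..5, got: ",
                 paste(unique(offending), collapse = ", ")),
          class = "gazeread_validation_error")
  }
  if (any(!rows$answer_correct %in% c(0L, 1L))) {
    abort("answer_correct must be 0 or 1", class = "gazeread_validation_error")
  }
  dangling <- setdiff(rows$text_id, texts$text_id)
  if (length(dangling) > 0) {
    abort(paste0("manifest references unknown text_id(s): ",
                 paste(dangling, collapse = ", ")),
          class = "gazeread_reference_error")
  }
  dup <- rows |>
    dplyr::count(.data$participant_id, .data$text_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate (participant_id, text_id) pair in manifest",
          class = "gazeread_validation_error")
  }
  paths <- rows$gaze_file[!is.na(rows$gaze_file)]
  if (anyDuplicated(paths)) {
    abort("gaze file paths in a manifest must be unique",
          class = "gazeread_validation_error")
  }
  outcomes <- rows |>
    dplyr::mutate(excluded = .data$rating == 1L) |>
    dplyr::select("participant_id", "text_id", "rating", "answer_correct", "excluded")
  files <- rows |> dplyr::select("participant_id", "text_id", "gaze_file")
  structure(
    list(schema_version = doc$schema_version, texts = texts,
         outcomes = outcomes, files = files),
    class = "gaze_manifest"
  )
}

#' Write a session manifest
#'
#' @param texts Tibble with `text_id`, `n_chars` and optionally `level`.
#' @param outcomes Tibble with `participant_id`, `text_id`, `rating`,
#'   `answer_correct` and optionally `gaze_file`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(texts, outcomes, path) {
  if (!"gaze_file" %in% names(outcomes)) outcomes$gaze_file <- NA_character_
  if (!"level" %in% names(texts)) texts$level <- NA_character_
  doc <- list(
    schema_version = 1L,
    texts = purrr::pmap(
      list(texts$text_id, texts$n_chars, texts$level),
      function(id, nc, lv) {
        out <- list(text_id = id, n_chars = as.integer(nc))
        if (!is.na(lv)) out$level <- lv
        out
      }
    ),
    participants = lapply(split(outcomes, outcomes$participant_id), function(df) {
      list(
        participant_id = df$participant_id[1],
        texts = purrr::pmap(
          list(df$text_id, df$rating, df$answer_correct, df$gaze_file),
          function(id, r, a, g) {
            out <- list(text_id = id, rating = as.integer(r),
                        answer_correct = as.integer(a))
            if (!is.na(g)) out$gaze_file <- g
            out
          }
        )
      )
    })
  )
  names(doc$participants) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.gaze_manifest <- function(x, ...) {
  cat("<gaze_manifest> schema_version", x$schema_version, "\n")
  cat("  texts:       ", nrow(x$texts), "\n")
  cat("  participants:", dplyr::n_distinct(x$outcomes$participant_id), "\n")
  cat("  recordings:  ", nrow(x$outcomes),
      sprintf("(%d excluded as aborted)\n", sum(x$outcomes$excluded)))
  invisible(x)
}

#' Write / read per-recording feature vectors as TSV
#'
#' Lossless round-trip of the four normalized features per
#' (participant, text) recording. Floats are serialized at full double
#' precision; duplicate keys are rejected in both directions.
#'
#' @param features Tibble with columns `participant_id`, `text_id`,
#'   `f1`, `f2`, `f3`, `f4`.
#' @param path TSV path.
#' @return `write_features_tsv()` returns `path` invisibly;
#'   `read_features_tsv()` returns the features tibble.
#' @export
write_features_tsv <- function(features, path) {
  cols <- c("participant_id", "text_id", "f1", "f2", "f3", "f4")
  stopifnot(all(cols %in% names(features)))
  if (anyDuplicated(features[, c("participant_id", "text_id")])) {
    abort("duplicate (participant_id, text_id) key in features",
          class = "gazeread_validation_error")
  }
  df <- features[, cols]
  # 17 significant digits round-trip any double exactly
  df <- dplyr::mutate(df, dplyr::across(c("f1", "f2", "f3", "f4"),
                                        ~ sprintf("%.17g", .x)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in setdiff(names(out), c("participant_id", "text_id"))) {
    out[[col]] <- as.numeric(out[[col]]) # strtod: correctly rounded
  }
  cols <- c("participant_id", "text_id", "f1", "f2", "f3", "f4")
  missing_cols <- setdiff(cols, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("features file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazeread_format_error")
  }
  if (anyDuplicated(out[, c("participant_id", "text_id")])) {
    abort("duplicate (participant_id, text_id) key in features file",
          class = "gazeread_validation_error")
  }
  out[, cols]
}
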