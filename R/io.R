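# Readers and writers for landmark and cohort files. CSV dialect:
# comma-separated, UTF-8, mandatory header, "." decimal separator; full
# precision on write (display rounding happens only in human-readable
# tables).

landmark_csv_required <- c("patient_id", "side", "t_x", "t_y",
                           "mid_base_x", "mid_base_y", "mid_apex_x",
                           "mid_apex_y", "occlusion", "a1_status",
                           "acoa_patent", "contralateral")

#' Read per-patient landmark files (CSV or JSON)
#'
#' CSV schema: one row per patient-measurement with columns `patient_id`,
#' `side`, `t_x`, `t_y`, `mid_base_x`, `mid_base_y`, `mid_apex_x`,
#' `mid_apex_y`, `occlusion`, `a1_status`, `acoa_patent`, `contralateral`,
#' then repeated `term_x_1`, `term_y_1`, `term_x_2`, ... candidate columns
#' (blank cells allowed for unused candidates); an optional `rater` column is
#' accepted for reliability input. JSON schema: an array of objects with the
#' same scalar fields plus a `terminal_candidates` array of `[x, y]` pairs.
#' Schema violations are reported with the offending row and field.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A list of [angio_landmarks()] objects; any `rater` value is kept
#'   as attribute `rater` on each element.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(seq_along(recs), function(i) landmarks_from_record(recs[[i]], i)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(landmark_csv_required, names(df))
  if (length(missing_cols)) {
    stop("landmark CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  term_x <- sort(grep("^term_x_[0-9]+$", names(df), value = TRUE))
  term_y <- sort(grep("^term_y_[0-9]+$", names(df), value = TRUE))
  if (length(term_x) != length(term_y)) {
    stop("landmark CSV: unpaired term_x_i / term_y_i columns", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tc <- NULL
    if (length(term_x)) {
      xs <- suppressWarnings(as.numeric(unlist(row[term_x])))
      ys <- suppressWarnings(as.numeric(unlist(row[term_y])))
      ok <- !is.na(xs) & !is.na(ys)
      if (any(xs[!ok] != ys[!ok], na.rm = TRUE) || any(is.na(xs) != is.na(ys))) {
        stop("row ", i, ": terminal candidate with only one coordinate", call. = FALSE)
      }
      if (any(ok)) tc <- cbind(xs[ok], ys[ok])
    }
    rec <- list(patient_id = row$patient_id, side = row$side,
                t_point = c(row$t_x, row$t_y),
                mid_base = c(row$mid_base_x, row$mid_base_y),
                mid_apex = c(row$mid_apex_x, row$mid_apex_y),
                terminal_candidates = tc,
                occlusion = row$occlusion, a1_status = row$a1_status,
                acoa_patent = parse_flag(row$acoa_patent, i, "acoa_patent"),
                measured_from_contralateral =
                  parse_flag(row$contralateral, i, "contralateral"))
    lm <- landmarks_validate(rec, i)
    if ("rater" %in% names(df)) attr(lm, "rater") <- row$rater
    lm
  })
}

parse_flag <- function(x, row, field) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  stop("row ", row, ": field '", field, "' has non-boolean value '", x, "'",
       call. = FALSE)
}

landmarks_from_record <- function(rec, i) {
  need <- c("patient_id", "side", "t_point", "mid_base", "mid_apex",
            "occlusion", "a1_status", "acoa_patent",
            "measured_from_contralateral")
  missing_f <- setdiff(need, names(rec))
  if (length(missing_f)) {
    stop("record ", i, ": missing field(s) ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  tc <- NULL
  if (!is.null(rec$terminal_candidates) && length(rec$terminal_candidates)) {
    tc <- do.call(rbind, lapply(rec$terminal_candidates, function(p)
      as.numeric(unlist(p))))
  }
  rec2 <- list(patient_id = rec$patient_id, side = rec$side,
               t_point = as.numeric(unlist(rec$t_point)),
               mid_base = as.numeric(unlist(rec$mid_base)),
               mid_apex = as.numeric(unlist(rec$mid_apex)),
               terminal_candidates = tc,
               occlusion = rec$occlusion, a1_status = rec$a1_status,
               acoa_patent = isTRUE(rec$acoa_patent),
               measured_from_contralateral =
                 isTRUE(rec$measured_from_contralateral))
  lm <- landmarks_validate(rec2, i)
  if (!is.null(rec$rater)) attr(lm, "rater") <- rec$rater
  lm
}

landmarks_validate <- function(rec, i) {
  tryCatch(
    angio_landmarks(patient_id = rec$patient_id, side = rec$side,
                    t_point = rec$t_point, mid_base = rec$mid_base,
                    mid_apex = rec$mid_apex,
                    terminal_candidates = rec$terminal_candidates,
                    occlusion = rec$occlusion, a1_status = rec$a1_status,
                    acoa_patent = rec$acoa_patent,
                    measured_from_contralateral =
                      rec$measured_from_contralateral),
    error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
}

#' Write landmark sets to CSV or JSON
#'
#' Inverse of [read_landmarks()]; numeric coordinates are serialized at full
#' precision so that write-then-read is an identity.
#'
#' @param landmark_list List of [angio_landmarks()] objects.
#' @param path Destination path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmark_list, path) {
  stopifnot(is.list(landmark_list),
            all(vapply(landmark_list, inherits, TRUE, "angio_landmarks")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(landmark_list, function(lm) {
      r <- list(patient_id = lm$patient_id, side = lm$side,
                t_point = lm$t_point, mid_base = lm$mid_base,
                mid_apex = lm$mid_apex,
                terminal_candidates = unname(apply(lm$terminal_candidates, 1L,
                                                   identity, simplify = FALSE)),
                occlusion = lm$occlusion, a1_status = lm$a1_status,
                acoa_patent = lm$acoa_patent,
                measured_from_contralateral = lm$measured_from_contralateral)
      if (!is.null(attr(lm, "rater"))) r$rater <- attr(lm, "rater")
      r
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  kmax <- max(vapply(landmark_list, function(lm) nrow(lm$terminal_candidates), 0L))
  rows <- lapply(landmark_list, function(lm) {
    base <- data.frame(patient_id = lm$patient_id, side = lm$side,
                       t_x = lm$t_point[1], t_y = lm$t_point[2],
                       mid_base_x = lm$mid_base[1], mid_base_y = lm$mid_base[2],
                       mid_apex_x = lm$mid_apex[1], mid_apex_y = lm$mid_apex[2],
                       occlusion = lm$occlusion, a1_status = lm$a1_status,
                       acoa_patent = lm$acoa_patent,
                       contralateral = lm$measured_from_contralateral,
                       stringsAsFactors = FALSE)
    for (k in seq_len(kmax)) {
      tc <- lm$terminal_candidates
      base[[paste0("term_x_", k)]] <- if (k <= nrow(tc)) tc[k, 1] else NA_real_
      base[[paste0("term_y_", k)]] <- if (k <= nrow(tc)) tc[k, 2] else NA_real_
    }
    if (!is.null(attr(lm, "rater"))) base$rater <- attr(lm, "rater")
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the clinical columns it recognizes: `mrs_90` in 0..6, grade
#' columns in 0..4, `age` positive, `abza_deg` in [0, 90].
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty cohort table: ", path, call. = FALSE)
  check_range <- function(col, lo, hi) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
      if (length(bad)) {
        stop("cohort column '", col, "' out of [", lo, ", ", hi, "] at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  check_range("mrs_90", 0, 6)
  check_range("abza_grade", 0, 4)
  check_range("asitn_grade", 0, 4)
  check_range("abza_deg", 0, 90)
  if ("age" %in% names(df) && any(df$age <= 0, na.rm = TRUE)) {
    stop("cohort column 'age' must be positive", call. = FALSE)
  }
  df
}

#' Write a cohort table to CSV at full precision
#'
#' @param cohort A data.frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
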