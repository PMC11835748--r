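#' Construct a multi-subject ROI time-series cohort
#'
#' A `CohortSeries` bundles one volumes-by-regions signal matrix per subject
#' together with the repetition time, region identifiers and a two-level group
#' label per subject (level `"A"` is the melancholic group by convention, `"B"`
#' the non-melancholic group). All subjects must share the same region set,
#' region ordering and volume count.
#'
#' @param data named list of numeric matrices, one per subject
#'   (rows = volumes, columns = regions).
#' @param tr_seconds repetition time between volumes in seconds.
#' @param group_labels character/factor of group labels, one per subject,
#'   named by subject id or in the order of `data`.
#' @param region_ids region identifiers; defaults to the column names of the
#'   first matrix.
#' @return an object of class `CohortSeries`.
#' @export
cohort_series <- function(data, tr_seconds, group_labels, region_ids = NULL) {
  stopifnot(is.list(data), length(data) >= 1L, is.numeric(tr_seconds),
            tr_seconds > 0)
  subject_ids <- names(data)
  if (is.null(subject_ids) || anyDuplicated(subject_ids))
    stop("subject matrices must be uniquely named by subject id")
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(region_ids)) region_ids <- colnames(data[[1L]])
  if (is.null(region_ids)) region_ids <- paste0("r", seq_len(ncol(data[[1L]])))
  nv <- vapply(data, nrow, 0L)
  nr <- vapply(data, ncol, 0L)
  if (length(unique(nv)) != 1L)
    stop("all subjects must have the same number of volumes; got ",
         paste(unique(nv), collapse = ", "))
  if (any(nr != length(region_ids)))
    stop("all subjects must have ", length(region_ids), " regions")
  if (any(vapply(data, function(m) anyNA(m) || any(!is.finite(m)), TRUE)))
    stop("cohort data must be finite with no missing values")
  if (!is.null(names(group_labels))) group_labels <- group_labels[subject_ids]
  group_labels <- as.character(group_labels)
  if (length(group_labels) != length(data) || anyNA(group_labels))
    stop("one group label required per subject; missing label for: ",
         paste(subject_ids[is.na(group_labels)], collapse = ", "))
  for (i in seq_along(data)) {
    dimnames(data[[i]]) <- list(NULL, region_ids)
  }
  structure(
    list(data = data, tr_seconds = as.numeric(tr_seconds),
         subject_ids = subject_ids, region_ids = as.character(region_ids),
         group_labels = stats::setNames(group_labels, subject_ids)),
    class = "CohortSeries")
}

#' @export
print.CohortSeries <- function(x, ...) {
  cat(sprintf("CohortSeries: %d subjects x %d volumes x %d regions (TR %.3g s)\n",
              length(x$subject_ids), nrow(x$data[[1L]]), length(x$region_ids),
              x$tr_seconds))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group_labels)),
                               table(x$group_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of volumes per subject in a cohort
#' @param cohort a `CohortSeries`.
#' @return integer volume count.
#' @export
n_volumes <- function(cohort) nrow(cohort$data[[1L]])

#' Read per-subject ROI time-series tables into a cohort
#'
#' Each file is a CSV/TSV with a header row of region identifiers and one row
#' per fMRI volume. Region columns are harmonised to the ordering of the first
#' file; subjects whose region set differs are rejected. Any cell that does not
#' parse as a finite number raises an error naming the file, row and column.
#'
#' @param paths character vector of file paths, named by subject id (unnamed
#'   paths use the file base name without extension).
#' @param labels named character vector mapping subject id to group label.
#' @param tr_seconds repetition time in seconds (default 0.81, the study
#'   acquisition).
#' @return a [cohort_series()] object.
#' @export
read_roi_timeseries <- function(paths, labels, tr_seconds = 0.81) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("\\.[^.]+$", "", basename(paths))
  missing_lab <- setdiff(names(paths), names(labels))
  if (length(missing_lab))
    stop("no group label supplied for subject(s): ",
         paste(missing_lab, collapse = ", "))
  canonical <- NULL
  data <- lapply(names(paths), function(sid) {
    m <- read_numeric_table(paths[[sid]])
    if (is.null(canonical)) canonical <<- colnames(m)
    if (!setequal(colnames(m), canonical))
      stop("subject ", sid, " has a mismatched region set (",
           paths[[sid]], ")")
    m[, canonical, drop = FALSE]
  })
  names(data) <- names(paths)
  cohort_series(data, tr_seconds = tr_seconds,
                group_labels = labels[names(paths)], region_ids = canonical)
}

# Strict numeric table reader: delimiter sniffed from the header line,
# non-numeric cells reported with file/row/column coordinates.
read_numeric_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  m <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(is.na(m) & !is.na(as.matrix(df)) | is.na(as.matrix(df)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell in %s at row %d, column '%s' (value '%s')",
                 path, bad[1L, 1L], colnames(m)[bad[1L, 2L]],
                 as.matrix(df)[bad[1L, 1L], bad[1L, 2L]]))
  }
  colnames(m) <- names(df)
  m
}

#' Read a cohort from a YAML manifest
#'
#' The manifest maps subject ids to time-series files and group labels:
#' ```yaml
#' tr_seconds: 0.81
#' subjects:
#'   - {id: sub01, file: sub01.csv, group: A}
#' ```
#' Relative file paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return a [cohort_series()] object.
#' @export
read_cohort_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$subjects) || !length(man$subjects))
    stop("manifest has no subjects")
  ids <- vapply(man$subjects, function(s) as.character(s$id), "")
  files <- vapply(man$subjects, function(s) as.character(s$file), "")
  groups <- vapply(man$subjects, function(s) as.character(s$group), "")
  rel <- !grepl("^(/|[A-Za-z]:)", files)
  files[rel] <- file.path(dirname(path), files[rel])
  tr <- if (is.null(man$tr_seconds)) 0.81 else as.numeric(man$tr_seconds)
  read_roi_timeseries(stats::setNames(files, ids),
                      stats::setNames(groups, ids), tr_seconds = tr)
}

#' Write a cohort as per-subject CSVs plus a YAML manifest
#'
#' Produces the same on-disk layout that [read_cohort_manifest()] consumes, so
#' simulated cohorts exercise the real readers.
#'
#' @param cohort a `CohortSeries`.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in cohort$subject_ids) {
    m <- cohort$data[[sid]]
    # 17 significant digits so values survive the text round-trip exactly
    ch <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m))
    df <- as.data.frame(ch, stringsAsFactors = FALSE)
    names(df) <- colnames(m)
    utils::write.csv(df, file.path(dir, paste0(sid, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  man <- list(
    tr_seconds = cohort$tr_seconds,
    subjects = lapply(cohort$subject_ids, function(sid)
      list(id = sid, file = paste0(sid, ".csv"),
           group = unname(cohort$group_labels[[sid]]))))
  path <- file.path(dir, "cohort.yaml")
  yaml::write_yaml(man, path, precision = 17L)
  invisible(path)
}

#' Trim, demean and scale ROI time series
#'
#' Applies the study's final preprocessing step to extracted ROI traces:
#' drop the first `trim_start` and last `trim_end` volumes (periods when the
#' movie was not playing), then standardise each subject-by-region trace to
#' mean 0, SD 1 over the retained volumes. Standardisation is per trace by
#' default; `scale = "pooled"` centres and scales each region on the
#' concatenated cohort instead.
#'
#' @param raw a `CohortSeries`.
#' @param trim_start,trim_end volumes dropped at the start/end (defaults 10
#'   and 35).
#' @param scale `"per_subject"` (default) or `"pooled"`.
#' @return a preprocessed `CohortSeries`.
#' @export
preprocess_series <- function(raw, trim_start = 10L, trim_end = 35L,
                              scale = c("per_subject", "pooled")) {
  scale <- match.arg(scale)
  nv <- n_volumes(raw)
  if (nv <= trim_start + trim_end)
    stop("cohort has ", nv, " volumes; cannot trim ", trim_start, " + ",
         trim_end)
  keep <- seq.int(trim_start + 1L, nv - trim_end)
  trimmed <- lapply(raw$data, function(m) m[keep, , drop = FALSE])
  if (scale == "per_subject") {
    out <- lapply(names(trimmed), function(sid) {
      m <- trimmed[[sid]]
      sds <- apply(m, 2L, stats::sd)
      if (any(sds == 0))
        stop("degenerate (constant) signal for subject ", sid, ", region ",
             raw$region_ids[which(sds == 0)[1L]])
      scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
    })
    names(out) <- names(trimmed)
  } else {
    pooled <- do.call(rbind, trimmed)
    mu <- colMeans(pooled)
    sds <- apply(pooled, 2L, stats::sd)
    if (any(sds == 0))
      stop("degenerate (constant) pooled signal in region ",
           raw$region_ids[which(sds == 0)[1L]])
    out <- lapply(trimmed, function(m)
      sweep(sweep(m, 2L, mu), 2L, sds, "/"))
  }
  out <- lapply(out, function(m) {
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    m
  })
  cohort_series(out, tr_seconds = raw$tr_seconds,
                group_labels = raw$group_labels, region_ids = raw$region_ids)
}

#' Read a scene annotation table
#'
#' Expects columns `onset_s`, `duration_s`, `valence` and optionally
#' `description`. Intervals must be non-overlapping once sorted by onset.
#'
#' @param path CSV file path.
#' @return a `data.frame` sorted by onset, class `SceneTable`.
#' @export
read_scene_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scene_table(df)
}

#' Validate a scene annotation data frame
#' @param df data frame with `onset_s`, `duration_s`, `valence` columns.
#' @return the sorted, validated data frame with class `SceneTable`.
#' @export
scene_table <- function(df) {
  need <- c("onset_s", "duration_s", "valence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"description" %in% names(df))
    df$description <- character(nrow(df))
  if (nrow(df)) {
    if (any(df$onset_s < 0) || any(df$duration_s <= 0))
      stop("scene onsets must be >= 0 and durations > 0")
    df <- df[order(df$onset_s), , drop = FALSE]
    ends <- df$onset_s + df$duration_s
    if (nrow(df) > 1L && any(df$onset_s[-1L] < ends[-nrow(df)]))
      stop("scene intervals overlap after sorting by onset")
  }
  rownames(df) <- NULL
  class(df) <- c("SceneTable", "data.frame")
  df
}

#' Convert scene annotations to a per-volume epoch mask
#'
#' Volume `v` (0-based index in post-trim space) is marked `TRUE` when its
#' acquisition onset `(v + trim_start) * tr_seconds` falls inside some
#' half-open scene interval `[onset, onset + duration)`. Scene times are
#' absolute movie time; the movie starts playing at volume `trim_start`.
#'
#' @param scenes a `SceneTable` (or conforming data frame).
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes number of post-trim volumes.
#' @param trim_start number of volumes trimmed from the start (time origin).
#' @return logical vector of length `n_volumes` with attribute `tr_seconds`.
#' @export
scenes_to_mask <- function(scenes, tr_seconds, n_volumes, trim_start = 10L) {
  stopifnot(tr_seconds > 0, n_volumes >= 1)
  scenes <- scene_table(as.data.frame(scenes))
  movie_end <- (trim_start + n_volumes) * tr_seconds
  if (nrow(scenes) && any(scenes$onset_s + scenes$duration_s >
                          movie_end + 1e-9))
    stop("scene extends beyond the movie end (",
         signif(movie_end, 6), " s)")
  times <- (seq_len(n_volumes) - 1L + trim_start) * tr_seconds
  mask <- rep(FALSE, n_volumes)
  for (i in seq_len(nrow(scenes))) {
    mask <- mask | (times >= scenes$onset_s[i] - 1e-9 &
                    times < scenes$onset_s[i] + scenes$duration_s[i] - 1e-9)
  }
  attr(mask, "tr_seconds") <- tr_seconds
  mask
}

# OpenFace intensity column names for the 16 emotion-relevant action units.
AU_ANALYSIS_SET <- c("AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09",
                     "AU10", "AU12", "AU14", "AU15", "AU17", "AU20", "AU23",
                     "AU25", "AU26")
AU_SMILE_SET <- c("AU06", "AU07", "AU09", "AU12", "AU14", "AU25")

#' Read an OpenFace action-unit intensity CSV
#'
#' Parses the OpenFace `_r` (intensity) columns for the 16 emotion-relevant
#' action units. AU45 (blink) is parsed when present but returned separately
#' and flagged excluded, since blinking is not analysed. Frames with
#' `success == 0` are marked missing (`NA`), never zero.
#'
#' @param path OpenFace CSV path.
#' @return list with `intensities` (frames x 16 matrix, columns named by AU),
#'   `au45` (numeric vector or `NULL`), `excluded` (character, always
#'   contains `"AU45"` when present), `fps` (frames per second inferred from
#'   the `timestamp` column, default 10), and `n_missing` frames.
#' @export
read_openface_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  want <- paste0(AU_ANALYSIS_SET, "_r")
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop("OpenFace file ", path, " is missing AU intensity column(s): ",
         paste(sub("_r$", "", miss), collapse = ", "))
  m <- as.matrix(df[, want])
  colnames(m) <- AU_ANALYSIS_SET
  au45 <- if ("AU45_r" %in% names(df)) df[["AU45_r"]] else NULL
  bad <- if ("success" %in% names(df)) df$success == 0 else rep(FALSE, nrow(df))
  m[bad, ] <- NA_real_
  if (!is.null(au45)) au45[bad] <- NA_real_
  fps <- 10
  if ("timestamp" %in% names(df) && nrow(df) > 1L) {
    dt <- stats::median(diff(df$timestamp))
    if (is.finite(dt) && dt > 0) fps <- 1 / dt
  }
  list(intensities = m, au45 = au45,
       excluded = if (is.null(au45)) character() else "AU45",
       fps = fps, n_missing = sum(bad))
}
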