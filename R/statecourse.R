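#' Construct a discrete state time course
#'
#' A state time course assigns every sample of a recording to exactly one of
#' `K` mutually exclusive network states (for example the most-probable path
#' of a hidden Markov model). All downstream interval statistics operate on
#' this container.
#'
#' @param labels Integer vector of state labels, values in `1..K`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param K Number of states; defaults to `max(labels)`.
#' @param subject_id Identifier carried through to outputs.
#' @param segments Optional integer matrix with columns `start`, `end`
#'   giving disjoint, sorted, half-open `[start, end)` sample ranges
#'   (0-based) marking valid epochs. Intervals not fully contained in one
#'   segment are discarded by [extract_intervals()].
#' @return An object of class `state_tc`.
#' @export
state_tc <- function(labels, fs, K = max(labels), subject_id = "subject",
                     segments = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("state time course must have at least 1 sample")
  if (anyNA(labels)) stop("labels contain NA")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  K <- as.integer(K)
  if (K < 1L || any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K (K = ", K, ")")
  if (!is.null(segments)) {
    segments <- matrix(as.integer(segments), ncol = 2L,
                       dimnames = list(NULL, c("start", "end")))
    if (any(segments[, 2L] <= segments[, 1L])) stop("segment end must exceed start")
    if (any(segments < 0L) || any(segments[, 2L] > length(labels)))
      stop("segments must lie within [0, T)")
    o <- order(segments[, 1L])
    segments <- segments[o, , drop = FALSE]
    if (nrow(segments) > 1L &&
        any(segments[-1L, 1L] < segments[-nrow(segments), 2L]))
      stop("segments must be disjoint")
  }
  structure(list(labels = labels, fs = fs, K = K,
                 subject_id = as.character(subject_id), segments = segments),
            class = "state_tc")
}

#' @export
print.state_tc <- function(x, ...) {
  cat(sprintf("State time course '%s': T = %d samples (%.1f s at %g Hz), K = %d states\n",
              x$subject_id, length(x$labels), length(x$labels) / x$fs, x$fs, x$K))
  fo <- fractional_occupancy(x)
  cat("Fractional occupancy:", paste(sprintf("%.3f", fo), collapse = " "), "\n")
  invisible(x)
}

#' Bundle subjects into a cohort
#'
#' @param subjects List of [state_tc()] objects sharing `K` and `fs`.
#' @return Object of class `state_cohort` (a list of `state_tc`).
#' @export
state_cohort <- function(subjects) {
  if (length(subjects) < 1L) stop("cohort must contain at least one subject")
  if (!all(vapply(subjects, inherits, logical(1L), "state_tc")))
    stop("all subjects must be state_tc objects")
  Ks <- vapply(subjects, `[[`, integer(1L), "K")
  fss <- vapply(subjects, `[[`, numeric(1L), "fs")
  if (length(unique(Ks)) != 1L) stop("all subjects must share K")
  if (length(unique(fss)) != 1L) stop("all subjects must share fs")
  structure(subjects, class = "state_cohort")
}

#' @export
print.state_cohort <- function(x, ...) {
  cat(sprintf("State cohort: %d subjects, K = %d, fs = %g Hz\n",
              length(x), x[[1L]]$K, x[[1L]]$fs))
  invisible(x)
}

#' Read a state time course from delimited text
#'
#' Two dialects are supported: `"labels"` (one integer state label per row)
#' and `"posteriors"` (a T x K matrix of nonnegative reals, reduced by
#' per-row argmax with ties broken toward the lowest state index).
#'
#' @param path File path (CSV/TSV; delimiter auto-detected from the first
#'   line, whitespace otherwise).
#' @param dialect `"labels"` or `"posteriors"`.
#' @param fs Sampling rate in Hz.
#' @param label_base 0 or 1: base of on-disk labels (stored 1-based).
#' @param K Number of states; inferred if `NULL` (max label, or column count).
#' @param subject_id Identifier; defaults to the file name.
#' @return A [state_tc()] object.
#' @export
read_state_time_course <- function(path, dialect = c("labels", "posteriors"),
                                   fs, label_base = 1L, K = NULL,
                                   subject_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
    if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  mat <- tryCatch(
    as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                colClasses = "numeric")),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (nrow(mat) == 0L) stop("empty file: ", path)
  if (dialect == "labels") {
    if (ncol(mat) != 1L) stop("labels dialect expects one value per row, got ",
                              ncol(mat), " columns in ", path)
    v <- mat[, 1L]
    bad <- which(v != round(v))
    if (length(bad)) stop("non-integer label at row ", bad[1L], " of ", path)
    labels <- as.integer(v) - as.integer(label_base) + 1L
    Kk <- if (is.null(K)) max(labels) else as.integer(K)
    bad <- which(labels < 1L | labels > Kk)
    if (length(bad)) stop("label outside 1..", Kk, " at row ", bad[1L], " of ", path)
  } else {
    if (any(mat < 0)) {
      bad <- which(apply(mat, 1L, function(r) any(r < 0)))
      stop("negative posterior at row ", bad[1L], " of ", path)
    }
    # ties break to the lowest state index: which.max does exactly this
    labels <- apply(mat, 1L, which.max)
    Kk <- if (is.null(K)) ncol(mat) else as.integer(K)
  }
  state_tc(labels, fs = fs, K = Kk, subject_id = subject_id)
}

#' Read a cohort manifest (YAML or JSON)
#'
#' The manifest lists one entry per subject with fields `subject_id`, `path`,
#' `dialect` and optionally `label_base`; `fs` and `K` may be given at the
#' top level or per subject. Relative paths resolve against the manifest's
#' directory.
#'
#' @param manifest_path Path to a `.yaml`/`.yml` or `.json` manifest.
#' @return A [state_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE))
    yaml::read_yaml(manifest_path)
  else jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$subjects)) stop("manifest has no 'subjects' list")
  root <- dirname(manifest_path)
  subs <- lapply(man$subjects, function(s) {
    p <- s$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(root, p)
    read_state_time_course(
      p,
      dialect = if (is.null(s$dialect)) "labels" else s$dialect,
      fs = if (is.null(s$fs)) man$fs else s$fs,
      label_base = if (is.null(s$label_base)) 1L else s$label_base,
      K = if (is.null(s$K)) man$K else s$K,
      subject_id = if (is.null(s$subject_id)) basename(p) else s$subject_id)
  })
  state_cohort(subs)
}

#' Write a cohort as per-subject label files plus a manifest
#'
#' @param cohort A [state_cohort()].
#' @param dir Output directory (created if needed).
#' @param config Optional list echoed into the manifest for provenance.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(s) {
    fn <- paste0(s$subject_id, ".csv")
    utils::write.table(s$labels, file.path(dir, fn), row.names = FALSE,
                       col.names = FALSE)
    list(subject_id = s$subject_id, path = fn, dialect = "labels",
         fs = s$fs, K = s$K)
  })
  man <- list(fs = cohort[[1L]]$fs, K = cohort[[1L]]$K, subjects = entries)
  if (!is.null(config)) man$config <- config
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, mp)
  invisible(mp)
}

#' Run-length encode a state time course into visits
#'
#' A visit is a maximal run of one state. Visits partition `[0, T)` with
#' 0-based half-open `[onset, offset)` coordinates.
#'
#' @param stc A [state_tc()].
#' @return Data frame with columns `state`, `onset`, `offset`,
#'   `duration_samples`, `duration_ms`.
#' @export
extract_visits <- function(stc) {
  stopifnot(inherits(stc, "state_tc"))
  r <- rle(stc$labels)
  offset <- cumsum(r$lengths)
  onset <- offset - r$lengths
  data.frame(state = r$values, onset = onset, offset = offset,
             duration_samples = r$lengths,
             duration_ms = r$lengths / stc$fs * 1000)
}

#' Extract inter-visit intervals of a reference state
#'
#' For each consecutive pair of visits of `reference_state`, the interval is
#' the half-open span of samples strictly between them: from the offset of
#' one visit to the onset of the next. Samples before the first visit and
#' after the last belong to no interval. When the time course carries a
#' segment mask, intervals not fully contained in one segment are discarded.
#'
#' @param stc A [state_tc()].
#' @param reference_state State whose reactivations delimit the intervals.
#' @return Object of class `interval_set`: a data frame with columns
#'   `start`, `end` (0-based half-open), `duration_samples`, `duration_ms`,
#'   plus attributes `reference_state`, `fs`. A state visited fewer than
#'   twice yields zero rows (not an error).
#' @export
extract_intervals <- function(stc, reference_state) {
  stopifnot(inherits(stc, "state_tc"))
  reference_state <- as.integer(reference_state)
  if (reference_state < 1L || reference_state > stc$K)
    stop("reference_state must be in 1..K")
  v <- extract_visits(stc)
  v <- v[v$state == reference_state, , drop = FALSE]
  if (nrow(v) < 2L) {
    iv <- data.frame(start = integer(0), end = integer(0),
                     duration_samples = integer(0), duration_ms = numeric(0))
  } else {
    start <- v$offset[-nrow(v)]
    end <- v$onset[-1L]
    dur <- end - start
    iv <- data.frame(start = start, end = end, duration_samples = dur,
                     duration_ms = dur / stc$fs * 1000)
    if (!is.null(stc$segments)) {
      keep <- vapply(seq_len(nrow(iv)), function(i) {
        any(stc$segments[, 1L] <= iv$start[i] & iv$end[i] <= stc$segments[, 2L])
      }, logical(1L))
      iv <- iv[keep, , drop = FALSE]
      rownames(iv) <- NULL
    }
  }
  structure(iv, reference_state = reference_state, fs = stc$fs,
            class = c("interval_set", "data.frame"))
}

#' Fractional occupancy per state
#'
#' @param stc A [state_tc()].
#' @return Numeric vector of length `K`: proportion of samples in each state
#'   (sums to 1).
#' @export
fractional_occupancy <- function(stc) {
  stopifnot(inherits(stc, "state_tc"))
  tabulate(stc$labels, nbins = stc$K) / length(stc$labels)
}

#' Mean state lifetimes
#'
#' Mean visit duration per state and the grand mean over all visits,
#' reported in both samples and milliseconds. States never visited get `NA`
#' with a warning.
#'
#' @param stc A [state_tc()].
#' @return List with `per_state_samples`, `per_state_ms` (length-`K`
#'   vectors), `grand_mean_samples`, `grand_mean_ms`.
#' @export
mean_lifetimes <- function(stc) {
  stopifnot(inherits(stc, "state_tc"))
  v <- extract_visits(stc)
  per <- rep(NA_real_, stc$K)
  agg <- tapply(v$duration_samples, factor(v$state, levels = seq_len(stc$K)),
                mean)
  per[] <- as.numeric(agg)
  if (anyNA(per))
    warning("state(s) never visited: ",
            paste(which(is.na(per)), collapse = ", "))
  gm <- mean(v$duration_samples)
  list(per_state_samples = per, per_state_ms = per / stc$fs * 1000,
       grand_mean_samples = gm, grand_mean_ms = gm / stc$fs * 1000)
}
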