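#' Segment an MFCC matrix into fixed-length feature blocks
#'
#' Splits the frame sequence into consecutive non-overlapping blocks of
#' `frames_per_segment` rows; a trailing remainder shorter than one block is
#' dropped. Every segment inherits the participant's label. A matrix shorter
#' than one segment yields an empty list with a warning.
#'
#' @param m A `mfcc_matrix` from [extract_mfcc].
#' @param frames_per_segment Rows per segment, >= 1 (default 100, about
#'   1.16 s at 44.1 kHz with hop 512).
#' @param label Binary class label (0 control, 1 mTBI).
#' @return A list of `feature_segment` objects, each with `features`
#'   (`frames_per_segment x n_coefficients`), `label`, `participant_id`.
#' @export
segment_mfcc <- function(m, frames_per_segment = 100L, label) {
  stopifnot(inherits(m, "mfcc_matrix"))
  frames_per_segment <- as.integer(frames_per_segment)
  if (frames_per_segment < 1L) {
    stop("segment_mfcc: frames_per_segment must be >= 1")
  }
  label <- as.integer(label)
  stopifnot(label %in% c(0L, 1L))
  n <- nrow(m$coefficients)
  k <- n %/% frames_per_segment
  if (k == 0L) {
    warning("segment_mfcc: ", n, " frames is shorter than one segment (",
            frames_per_segment, "); returning no segments")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    rows <- ((i - 1L) * frames_per_segment + 1L):(i * frames_per_segment)
    structure(
      list(features = m$coefficients[rows, , drop = FALSE],
           label = label, participant_id = m$source_id),
      class = "feature_segment"
    )
  })
}

#' Assemble a feature dataset
#'
#' @param segments List of `feature_segment` objects sharing one shape.
#' @param label_names Ordered class names; index 1 is label 0.
#' @param extraction_params The [mfcc_dialect] (plus segmentation settings)
#'   the features were produced with.
#' @return A `feature_dataset`.
#' @export
feature_dataset <- function(segments,
                            label_names = c("control", "mtbi"),
                            extraction_params = mfcc_dialect()) {
  if (length(segments) == 0L) stop("feature_dataset: no segments")
  shapes <- vapply(segments, function(s) paste(dim(s$features), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("feature_dataset: segments have inconsistent shapes: ",
         paste(unique(shapes), collapse = ", "))
  }
  labs <- vapply(segments, function(s) s$label, integer(1))
  if (!all(labs %in% (seq_along(label_names) - 1L))) {
    stop("feature_dataset: segment label outside label_names")
  }
  structure(
    list(segments = segments, label_names = label_names,
         extraction_params = extraction_params),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  d <- dim(x$segments[[1L]]$features)
  labs <- table(factor(vapply(x$segments, `[[`, integer(1), "label"),
                       levels = seq_along(x$label_names) - 1L,
                       labels = x$label_names))
  cat(sprintf("<feature_dataset> %d segments of %d x %d (%s)\n",
              length(x$segments), d[1L], d[2L],
              paste(names(labs), labs, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Stack a feature dataset into an array
#' @param ds A `feature_dataset`.
#' @return List with `x` (`n x frames x coefs` array), `y` (integer labels),
#'   `participant_id` (character).
#' @export
dataset_arrays <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  d <- dim(ds$segments[[1L]]$features)
  n <- length(ds$segments)
  x <- array(0, dim = c(n, d[1L], d[2L]))
  for (i in seq_len(n)) x[i, , ] <- ds$segments[[i]]$features
  list(x = x,
       y = vapply(ds$segments, `[[`, integer(1), "label"),
       participant_id = vapply(ds$segments, `[[`, character(1),
                               "participant_id"))
}

#' Serialise a feature dataset to the JSON feature file
#'
#' Schema: `{"extraction_params": {...}, "label_names": [...],
#' "participant_ids": [...], "labels": [...], "mfcc": [[[...]]]}` where
#' `mfcc` is `n_segments x frames_per_segment x n_coefficients`. Numbers are
#' written at full double precision so the round trip is lossless.
#'
#' @param ds A `feature_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_json <- function(ds, path) {
  stopifnot(inherits(ds, "feature_dataset"))
  obj <- list(
    extraction_params = unclass(ds$extraction_params),
    label_names = ds$label_names,
    participant_ids = vapply(ds$segments, `[[`, character(1),
                             "participant_id"),
    labels = vapply(ds$segments, `[[`, integer(1), "label"),
    mfcc = lapply(ds$segments, function(s) unname(s$features))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a feature dataset back from JSON
#' @param path Path written by [write_feature_json].
#' @return A `feature_dataset`.
#' @export
read_feature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("extraction_params", "label_names", "participant_ids", "labels",
            "mfcc")
  if (!all(need %in% names(obj))) {
    stop("read_feature_json: malformed feature file (missing keys)")
  }
  labels <- as.integer(obj$labels)
  if (!all(labels %in% (seq_along(obj$label_names) - 1L))) {
    stop("read_feature_json: label outside label_names")
  }
  mfcc <- obj$mfcc
  if (is.array(mfcc) && length(dim(mfcc)) == 3L) {
    mats <- lapply(seq_len(dim(mfcc)[1L]), function(i) mfcc[i, , ])
  } else {
    mats <- lapply(mfcc, function(m) {
      if (is.list(m)) m <- do.call(rbind, m)
      as.matrix(m)
    })
  }
  segments <- mapply(function(feat, lab, pid) {
    structure(list(features = feat, label = lab, participant_id = pid),
              class = "feature_segment")
  }, mats, labels, as.character(obj$participant_ids), SIMPLIFY = FALSE)
  ep <- obj$extraction_params
  dialect <- do.call(
    mfcc_dialect,
    ep[intersect(names(ep), names(formals(mfcc_dialect)))]
  )
  feature_dataset(segments, obj$label_names, dialect)
}

#' Extract, segment and collect features for a whole manifest
#'
#' @param manifest Participant manifest data.frame (see [read_manifest]).
#' @param dialect An [mfcc_dialect].
#' @param frames_per_segment Segment length in frames.
#' @param base_dir Directory `clip_path` entries are relative to ("" = as-is).
#' @return A `feature_dataset` covering every participant with at least one
#'   full segment.
#' @export
extract_dataset <- function(manifest, dialect = mfcc_dialect(),
                            frames_per_segment = 100L, base_dir = "") {
  manifest <- validate_manifest(manifest)
  segs <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$clip_path[i]
    if (nzchar(base_dir)) p <- file.path(base_dir, p)
    clip <- read_wav(p, source_id = manifest$participant_id[i])
    m <- extract_mfcc(clip, dialect)
    segs <- c(segs, segment_mfcc(m, frames_per_segment, manifest$label[i]))
  }
  feature_dataset(segs, extraction_params = dialect)
}
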