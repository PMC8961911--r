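#' Read a counts file into an observation set
#'
#' The counts file is tidy comma-separated text with a header and
#' columns `series_id` (string), `time_index` (integer, 0..n_k without
#' gaps or duplicates within a series) and `count` (non-negative
#' integer).  The observation lag is an experiment constant and is
#' supplied separately, not stored in the file.
#'
#' @param path file path.
#' @param delta observation lag attached to every series.
#' @return an `"observation_set"`; series ordered by first appearance.
#' @export
read_counts <- function(path, delta = 1) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "time_index", "count")
  if (!all(need %in% names(df)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  for (col in c("time_index", "count")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop("series '", df$series_id[bad[1L]], "', row ", bad[1L],
           ": column '", col, "' must be a non-negative integer (got ",
           v[bad[1L]], ")")
  }
  ids <- unique(df$series_id)
  series <- lapply(ids, function(id) {
    rows <- df[df$series_id == id, ]
    rows <- rows[order(rows$time_index), ]
    n_k <- nrow(rows) - 1L
    if (!identical(as.integer(rows$time_index), 0:n_k)) {
      expected <- 0:n_k
      off <- which(as.integer(rows$time_index) != expected)[1L]
      stop("series '", id, "': time_index has a gap or duplicate at ",
           "position ", off, " (found ", rows$time_index[off],
           ", expected ", expected[off], ")")
    }
    structure(list(counts = as.integer(rows$count), delta = delta,
                   series_id = id), class = "count_series")
  })
  structure(list(series = series, delta = delta),
            class = "observation_set")
}

#' Write an observation set to a counts file
#'
#' Inverse of [read_counts()]; rows are ordered deterministically by
#' series then time index.
#'
#' @param data an `"observation_set"`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_counts <- function(data, path) {
  stopifnot(inherits(data, "observation_set"))
  df <- do.call(rbind, lapply(data$series, function(s)
    data.frame(series_id = s$series_id,
               time_index = seq_along(s$counts) - 1L,
               count = s$counts)))
  if (is.null(df))
    df <- data.frame(series_id = character(0), time_index = integer(0),
                     count = integer(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble an observation set from in-memory count vectors
#'
#' @param counts a list of non-negative integer vectors (one series
#'   each) or a single vector.
#' @param delta common observation lag.
#' @return an `"observation_set"`.
#' @export
as_observation_set <- function(counts, delta = 1) {
  if (!is.list(counts)) counts <- list(counts)
  series <- lapply(seq_along(counts), function(k) {
    v <- counts[[k]]
    if (any(v < 0 | v != floor(v)))
      stop("series ", k, ": counts must be non-negative integers")
    structure(list(counts = as.integer(v), delta = delta,
                   series_id = sprintf("s%04d", k)),
              class = "count_series")
  })
  structure(list(series = series, delta = delta),
            class = "observation_set")
}
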