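#' Construct a parcellated time series object
#'
#' One run's time x region matrix together with region and network labels
#' and identifying metadata. Regions keep a fixed order for a cohort so
#' edge vectors are comparable across subjects.
#'
#' @param values numeric time x region matrix, no missing values.
#' @param region_ids character vector of region identifiers (default
#'   `"R001"...`).
#' @param network_labels character vector mapping each region to a network.
#' @param subject_id,run_id,visit_id identifiers.
#' @param sampling_interval sampling interval in seconds (default 3.0).
#' @return object of class `parcel_ts`.
#' @export
parcel_time_series <- function(values, region_ids = NULL,
                               network_labels = NULL,
                               subject_id = "S1", run_id = "run1",
                               visit_id = "visit1",
                               sampling_interval = 3.0) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("time series contains missing values")
  if (ncol(values) < 2) stopf("need at least 2 regions")
  if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(ncol(values)))
  if (length(region_ids) != ncol(values))
    stopf("region_ids length (%d) != number of regions (%d)",
          length(region_ids), ncol(values))
  if (is.null(network_labels)) network_labels <- rep("net1", ncol(values))
  structure(
    list(values = unname(values), region_ids = as.character(region_ids),
         network_labels = as.character(network_labels),
         subject_id = subject_id, run_id = run_id, visit_id = visit_id,
         sampling_interval = sampling_interval),
    class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject %s, %s/%s: %d time points x %d regions (%d networks)\n",
              x$subject_id, x$visit_id, x$run_id, nrow(x$values),
              ncol(x$values), length(unique(x$network_labels))))
  invisible(x)
}

#' Sliding-window correlation stack
#'
#' Computes, for each rectangular (untapered) window of `width` consecutive
#' time points advanced by `stride`, the Pearson correlation of every region
#' pair, Fisher z-transformed. A 120-time-point run with width 11 and stride
#' 1 yields 110 windows; with a 3 s sampling interval the default width
#' spans 33 s.
#'
#' @param ts a [parcel_time_series()] object.
#' @param width window width in time points (default 11), `3 <= width <= T`.
#' @param stride advance in time points between consecutive windows
#'   (default 1).
#' @return object of class `windowed_fc` holding `z_edges` (window x edge
#'   matrix in the canonical edge ordering), window geometry, and region
#'   metadata carried over from `ts`.
#' @export
sliding_window_correlations <- function(ts, width = 11L, stride = 1L) {
  stopifnot(inherits(ts, "parcel_ts"))
  tt <- nrow(ts$values)
  if (!is_count(width) || width < 3) stopf("width must be an integer >= 3")
  if (!is_count(stride) || stride < 1) stopf("stride must be an integer >= 1")
  if (tt < width) stopf("run has %d time points < window width %d", tt, width)
  starts <- seq.int(1L, tt - width + 1L, by = stride)
  n_reg <- ncol(ts$values)
  n_edge <- n_reg * (n_reg - 1L) / 2L
  z <- matrix(NA_real_, length(starts), n_edge)
  lt <- lower.tri(matrix(0, n_reg, n_reg))
  for (w in seq_along(starts)) {
    seg <- ts$values[starts[w]:(starts[w] + width - 1L), , drop = FALSE]
    cs <- .colMeans(seg, width, n_reg)
    sds <- sqrt(.colMeans(seg^2, width, n_reg) - cs^2)
    if (any(sds < 1e-12))
      stopf("zero variance in window %d (start %d) for region(s) %s",
            w, starts[w],
            paste(ts$region_ids[sds < 1e-12], collapse = ", "))
    z[w, ] <- fisher_z(stats::cor(seg)[lt])
  }
  structure(
    list(z_edges = z, window_width = as.integer(width),
         stride = as.integer(stride), window_start_indices = starts,
         region_ids = ts$region_ids, network_labels = ts$network_labels,
         subject_id = ts$subject_id, run_id = ts$run_id,
         visit_id = ts$visit_id),
    class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("<windowed_fc> %s/%s/%s: %d windows (width %d, stride %d), %d edges\n",
              x$subject_id, x$visit_id, x$run_id, nrow(x$z_edges),
              x$window_width, x$stride, ncol(x$z_edges)))
  invisible(x)
}

#' Number of windows for a given run length
#'
#' `floor((T - width) / stride) + 1`.
#'
#' @param n_timepoints run length T.
#' @param width,stride window geometry.
#' @export
window_count <- function(n_timepoints, width = 11L, stride = 1L) {
  if (n_timepoints < width) stopf("T < width")
  as.integer(floor((n_timepoints - width) / stride) + 1L)
}

#' Subsample windows before pooled clustering
#'
#' Reduces redundancy across heavily overlapping windows. `stride` mode
#' keeps every ceiling(1/rate)-th window starting at the first (the default
#' 1/10 subsampling keeps 11 of 110 windows). `variance_maxima` mode ranks
#' windows whose across-edge variance is a strict local maximum in window
#' index, keeping the requested count largest-variance first and padding
#' from the remaining windows (again by variance) if there are too few
#' maxima.
#'
#' @param wc a `windowed_fc` object.
#' @param mode `"stride"` or `"variance_maxima"`.
#' @param rate fraction of windows to keep, in (0, 1].
#' @return a `windowed_fc` restricted to the selected windows.
#' @export
subsample_windows <- function(wc, mode = c("stride", "variance_maxima"),
                              rate = 0.1) {
  stopifnot(inherits(wc, "windowed_fc"))
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate <= 0 || rate > 1)
    stopf("rate must be in (0, 1]")
  n <- nrow(wc$z_edges)
  if (mode == "stride") {
    keep <- seq.int(1L, n, by = as.integer(ceiling(1 / rate)))
  } else {
    v <- apply(wc$z_edges, 1L, stats::var)
    target <- max(1L, as.integer(floor(rate * n)))
    is_max <- vapply(seq_len(n), function(w) {
      left <- if (w > 1L) v[w] > v[w - 1L] else TRUE
      right <- if (w < n) v[w] > v[w + 1L] else TRUE
      left && right
    }, logical(1))
    maxima <- which(is_max)
    maxima <- maxima[order(v[maxima], decreasing = TRUE)]
    if (length(maxima) >= target) {
      keep <- maxima[seq_len(target)]
    } else {
      rest <- setdiff(order(v, decreasing = TRUE), maxima)
      keep <- c(maxima, rest[seq_len(target - length(maxima))])
    }
    keep <- sort(keep)
  }
  if (length(keep) == 0L) stopf("window subsampling selected no windows")
  out <- wc
  out$z_edges <- wc$z_edges[keep, , drop = FALSE]
  out$window_start_indices <- wc$window_start_indices[keep]
  out
}

#' Strict local maxima of a numeric profile
#'
#' Helper exposed for testing the `variance_maxima` selection rule:
#' interior points strictly above both neighbours; endpoints qualify when
#' strictly above their single neighbour.
#'
#' @param v numeric vector.
#' @return integer indices of strict local maxima.
#' @keywords internal
#' @export
local_maxima <- function(v) {
  n <- length(v)
  which(vapply(seq_len(n), function(w) {
    (w == 1L || v[w] > v[w - 1L]) && (w == n || v[w] > v[w + 1L])
  }, logical(1)))
}

#' Read / write parcel time series as TSV
#'
#' One file per run: header row of region identifiers, one row per time
#' point, tab-separated.
#'
#' @param ts a `parcel_ts` object.
#' @param path file path.
#' @export
write_parcel_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  df <- as.data.frame(ts$values)
  names(df) <- ts$region_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_tsv
#' @param network_labels,subject_id,run_id,visit_id,sampling_interval
#'   metadata not stored in the TSV itself.
#' @export
read_parcel_tsv <- function(path, network_labels = NULL, subject_id = "S1",
                            run_id = "run1", visit_id = "visit1",
                            sampling_interval = 3.0) {
  df <- utils::read.delim(path, check.names = FALSE)
  parcel_time_series(as.matrix(df), region_ids = names(df),
                     network_labels = network_labels,
                     subject_id = subject_id, run_id = run_id,
                     visit_id = visit_id,
                     sampling_interval = sampling_interval)
}
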