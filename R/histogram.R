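#' Uniform TCSPC time grid
#'
#' A uniformly binned arrival-time axis shared by decay, buffer and IRF
#' histograms.  Times are in nanoseconds; `origin` is the time of the first
#' bin *center*.
#'
#' @param bin_width Bin width in ns (> 0).
#' @param n_bins Number of bins (>= 2).
#' @param origin Time of the first bin center in ns; defaults to
#'   `bin_width / 2` so that bin edges start at t = 0.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(0.025, 4096)
#' head(bin_centers(g))
#' @export
time_grid <- function(bin_width = 0.025, n_bins = 4096L, origin = bin_width / 2) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 2,
            is.numeric(origin), length(origin) == 1L, is.finite(origin))
  structure(
    list(bin_width = as.double(bin_width), n_bins = as.integer(n_bins),
         origin = as.double(origin)),
    class = "time_grid"
  )
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
bin_centers <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$origin + (seq_len(grid$n_bins) - 1L) * grid$bin_width
}

## identity string used for cache keys
.grid_id <- function(grid) {
  sprintf("%.12g/%d/%.12g", grid$bin_width, grid$n_bins, grid$origin)
}

.same_grid <- function(a, b) {
  a$n_bins == b$n_bins &&
    abs(a$bin_width - b$bin_width) <= 1e-9 * a$bin_width &&
    abs(a$origin - b$origin) <= 1e-9 * max(a$bin_width, abs(a$origin))
}

#' Photon-count histogram
#'
#' A per-bin photon-count record on a [time_grid()].  Counts are integers for
#' measured or simulated data and may be real-valued for model predictions.
#'
#' @param grid A [time_grid()].
#' @param counts Numeric vector of per-bin counts, length `grid$n_bins`,
#'   all non-negative.
#' @param role One of `"decay"`, `"buffer"`, `"irf"`.
#' @param acquisition_duration Acquisition time in seconds.  Required
#'   (positive) for `"decay"` and `"buffer"` roles, where it fixes the
#'   buffer-scaling parameter `f_B`.
#' @param condition Free-text condition label (e.g. a ligand concentration).
#' @return An object of class `tcspc_histogram`.
#' @export
histogram <- function(grid, counts, role = c("decay", "buffer", "irf"),
                      acquisition_duration = NA_real_,
                      condition = NA_character_) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "time_grid"))
  if (length(counts) != grid$n_bins)
    stop("`counts` length (", length(counts), ") does not match grid n_bins (",
         grid$n_bins, ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be finite and >= 0")
  if (role %in% c("decay", "buffer") && !is.na(acquisition_duration) &&
      acquisition_duration <= 0)
    stop("acquisition_duration must be > 0 for decay/buffer histograms")
  structure(
    list(grid = grid, counts = as.double(counts), role = role,
         acquisition_duration = as.double(acquisition_duration),
         condition = as.character(condition)),
    class = "tcspc_histogram"
  )
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("<tcspc_histogram> role=%s  %d bins x %.4g ns  total=%.4g counts\n",
              x$role, x$grid$n_bins, x$grid$bin_width, sum(x$counts)))
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.na(x$acquisition_duration))
    cat("  acquisition:", x$acquisition_duration, "s\n")
  invisible(x)
}

#' Intensity-weighted mean photon arrival time
#'
#' A model-free summary of how fast a decay is: the count-weighted mean of
#' the bin-center times.  Useful as a monotonic FRET indicator (more FRET,
#' earlier mean arrival) and for initializing distance estimates.
#'
#' @param x A `tcspc_histogram` or a numeric vector of per-bin intensities.
#' @param grid Required when `x` is a bare numeric vector.
#' @return Mean arrival time in ns.
#' @export
mean_arrival_time <- function(x, grid = NULL) {
  if (inherits(x, "tcspc_histogram")) {
    grid <- x$grid
    x <- x$counts
  }
  stopifnot(inherits(grid, "time_grid"), length(x) == grid$n_bins)
  s <- sum(x)
  if (s <= 0) stop("cannot compute mean arrival time of an all-zero signal")
  sum(bin_centers(grid) * x) / s
}
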