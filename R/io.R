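#' Read / write TCSPC histograms as delimited text
#'
#' Histograms are stored as two-column delimited text (time in ns, counts)
#' with `#`-prefixed header lines carrying the role and acquisition
#' metadata.  Both CSV and TSV are accepted; the delimiter is detected from
#' the column-header line.  Uniform binning is enforced to within 1e-9
#' relative.
#'
#' @param path File path.
#' @return For `read_histogram()`, a `tcspc_histogram`.
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  if (length(meta_idx) && !identical(meta_idx, seq_along(meta_idx)))
    stop(path, ": '#' metadata lines must precede the data")
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 3L) stop(path, ": too few data rows")
  sep <- if (grepl("\t", body[1])) "\t" else ","
  header <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (length(header) != 2L)
    stop(path, ": expected two columns (time, counts), found ",
         length(header))
  first_data_line <- length(meta_idx) + 2L
  rows <- strsplit(body[-1L], sep, fixed = TRUE)
  bad <- which(lengths(rows) != 2L)
  if (length(bad))
    stop(path, ": malformed row at line ", first_data_line + bad[1] - 1L)
  tm <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1L)))
  ct <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  if (anyNA(tm) || anyNA(ct)) {
    i <- which(is.na(tm) | is.na(ct))[1]
    stop(path, ": non-numeric value at line ", first_data_line + i - 1L)
  }
  neg <- which(ct < 0)
  if (length(neg))
    stop(path, ": negative count at line ", first_data_line + neg[1] - 1L)
  dts <- diff(tm)
  bw <- dts[1]
  if (bw <= 0 || any(abs(dts - bw) > 1e-9 * bw)) {
    i <- which(abs(dts - bw) > 1e-9 * bw)[1]
    stop(path, ": non-uniform binning near line ",
         first_data_line + i)
  }
  role <- meta[["role"]]
  if (is.null(role))
    stop(path, ": missing required '# role:' metadata line")
  acq <- if (!is.null(meta[["acquisition_duration_s"]]))
    as.numeric(meta[["acquisition_duration_s"]]) else NA_real_
  cond <- meta[["condition"]] %||% NA_character_
  histogram(time_grid(bw, length(tm), origin = tm[1]), ct, role = role,
            acquisition_duration = acq, condition = cond)
}

#' @rdname read_histogram
#' @param h A `tcspc_histogram`.
#' @param sep Field delimiter: `","` (CSV, default) or `"\t"` (TSV).
#' @export
write_histogram <- function(h, path, sep = ",") {
  stopifnot(inherits(h, "tcspc_histogram"), sep %in% c(",", "\t"))
  meta <- c(
    "# tdfret-histogram: 1",
    paste0("# role: ", h$role),
    if (!is.na(h$acquisition_duration))
      paste0("# acquisition_duration_s: ",
             format(h$acquisition_duration, digits = 15)),
    if (!is.na(h$condition)) paste0("# condition: ", h$condition)
  )
  tm <- format(bin_centers(h$grid), digits = 15, trim = TRUE,
               scientific = FALSE)
  ct <- format(h$counts, digits = 15, trim = TRUE, scientific = FALSE)
  writeLines(c(meta, paste0("time_ns", sep, "counts"),
               paste0(tm, sep, ct)), path)
  invisible(path)
}

#' Write a synthetic scenario bundle to disk
#'
#' Writes the IRF, buffer and per-condition decay histograms plus a
#' versioned YAML manifest that records file roles, acquisition durations,
#' the fitting protocol (donor parameters, `R0`, fixed flags, sharing
#' groups, the intersubunit `rho2` block when present) and the generating
#' ground truth.  The bundle is self-describing: [read_bundle()] returns
#' everything needed to re-fit it.
#'
#' @param scen A `fret_scenario` from [make_scenario()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scenario_bundle <- function(scen, dir) {
  stopifnot(inherits(scen, "fret_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_histogram(scen$irf, file.path(dir, "irf.csv"))
  write_histogram(scen$buffer$histogram, file.path(dir, "buffer.csv"))
  decays <- list()
  for (d in scen$datasets) {
    fn <- paste0("decay_", gsub("[^A-Za-z0-9._-]", "_", d$condition), ".csv")
    write_histogram(d$decay, file.path(dir, fn))
    decays[[length(decays) + 1L]] <- list(
      file = fn, condition = d$condition,
      f_A2_true = d$f_A2_true,
      truth = as.list(d$truth$values)
    )
  }
  cfg <- scen$config
  donor_only <- is.null(cfg$rho)
  manifest <- list(
    tdfret_manifest = 1L,
    scenario = scen$name,
    seed = scen$seed,
    files = list(irf = "irf.csv", buffer = "buffer.csv", decays = decays),
    params = c(
      list(R0 = cfg$R0,
           tau_D1 = cfg$donor$lifetimes[1],
           alpha_D1 = cfg$donor$fractions[1],
           tau_D2 = if (length(cfg$donor$lifetimes) > 1)
             cfg$donor$lifetimes[2] else 4.73),
      if (!donor_only) list(rbar_1 = cfg$rho$rbar[1],
                            sigma_1 = cfg$rho$sigma[1],
                            rbar_2 = cfg$rho$rbar[2],
                            sigma_2 = cfg$rho$sigma[2])
    ),
    fixed = c("tau_D1", "alpha_D1", "tau_D2", "R0", "f_B", "bkgr_irf"),
    sharing = if (!donor_only)
      c("rbar_1", "sigma_1", "rbar_2", "sigma_2") else character(),
    rho2 = if (!is.null(cfg$rho2))
      list(rbar = cfg$rho2$rbar, sigma = cfg$rho2$sigma, tied = TRUE),
    energetics = list(temperature = 298.15),
    donor_only = donor_only
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a dataset bundle from its manifest
#'
#' @param path A bundle directory or a manifest file path.
#' @return A list with the parsed `manifest`, the `irf` and `buffer`
#'   histograms, the list of `decays`, a `params` template (a
#'   [fret_params()] with the manifest's initial values, fixed flags and
#'   `rho2` block) and the `sharing` group.
#' @export
read_bundle <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.yaml")
  else path
  if (!file.exists(manifest_path)) stop("no manifest at ", manifest_path)
  dir <- dirname(manifest_path)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$tdfret_manifest))
    stop(manifest_path, ": not a tdfret manifest")
  irf <- read_histogram(file.path(dir, man$files$irf))
  buffer <- if (!is.null(man$files$buffer))
    read_histogram(file.path(dir, man$files$buffer))
  decays <- lapply(man$files$decays, function(d) {
    h <- read_histogram(file.path(dir, d$file))
    attr(h, "f_A2_true") <- d$f_A2_true
    h
  })
  rho2 <- if (!is.null(man$rho2))
    list(rbar = as.double(unlist(man$rho2$rbar)),
         sigma = as.double(unlist(man$rho2$sigma)))
  pv <- man$params
  params <- do.call(fret_params, c(pv[names(pv) %in% .PAR_NAMES],
                                   list(rho2 = rho2)))
  if (length(man$fixed))
    params <- .set_fixed(params, intersect(unlist(man$fixed), .PAR_NAMES),
                         TRUE)
  list(manifest = man, dir = dir, irf = irf, buffer = buffer,
       decays = decays, params = params,
       sharing = as.character(unlist(man$sharing)))
}

## Write a fit report as JSON plus residual/prediction and distance-
## distribution CSV tables.  Returns the report path.
.write_fit_report <- function(fit, out_dir, prefix, config = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list(
    tdfret_report = 1L,
    config = config,
    estimates = as.list(fit$estimates),
    std_errors = as.list(fit$std_errors),
    reduced_chi2 = fit$reduced_chi2,
    degrees_of_freedom = fit$degrees_of_freedom,
    converged = fit$converged,
    at_bounds = as.list(fit$at_bounds),
    sharing = as.list(fit$sharing %||% character()),
    status = list(info = fit$status$info, message = fit$status$message)
  )
  rp <- file.path(out_dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  for (k in seq_along(fit$predicted)) {
    pred <- fit$predicted[[k]]
    idx <- .window_index(fit$windows[[k]], pred$grid$n_bins)
    df <- data.frame(
      time_ns = bin_centers(pred$grid)[idx],
      predicted = pred$counts[idx],
      weighted_residual = fit$residuals[[k]]
    )
    utils::write.csv(df, file.path(out_dir,
                                   sprintf("%s_curve_%d.csv", prefix, k)),
                     row.names = FALSE)
  }
  rp
}

## Distance-distribution curve rho(r) on [10, 80] Angstrom for a fitted
## parameter set; written as CSV with per-component columns.
.write_distance_curve <- function(values, out_dir, prefix) {
  r <- seq(10, 80, by = 0.25)
  f2 <- values[["f_A2"]]
  d1 <- distance_distribution(values[["rbar_1"]], values[["sigma_1"]])
  d2 <- distance_distribution(values[["rbar_2"]], values[["sigma_2"]])
  df <- data.frame(
    r_angstrom = r,
    density = (1 - f2) * distance_density(d1, r) +
      f2 * distance_density(d2, r),
    density_resting = (1 - f2) * distance_density(d1, r),
    density_active = f2 * distance_density(d2, r)
  )
  path <- file.path(out_dir, paste0(prefix, "_rho.csv"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
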