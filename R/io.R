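# Readers and writers binding the pipeline together. The canonical tabular
# format is tab-separated text with a header row and units in column names;
# stacks can also be read from multi-page TIFF when the tiff package is
# available. Writers emit 6 significant digits, and every writer's output is
# readable by its reader at that precision.

fmt_num <- function(x) signif(x, 6)

#' Write / read a trajectory table
#'
#' Tab-separated with header `cell focus t_s x_um y_um`.
#'
#' @param tracks A [trajectory_set()].
#' @param path Output file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` returns a
#'   [trajectory_set()].
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "trajectory_set"))
  rec <- tracks$records
  rec$t_s <- fmt_num(rec$t_s); rec$x_um <- fmt_num(rec$x_um)
  rec$y_um <- fmt_num(rec$y_um)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param frame_interval,pixel Metadata passed to [trajectory_set()].
#' @export
read_tracks <- function(path, frame_interval = NA_real_, pixel = 0.066) {
  rec <- utils::read.delim(path)
  trajectory_set(rec, frame_interval = frame_interval, pixel = pixel)
}

#' Write / read an MSD curve
#'
#' Tab-separated with header `tau_s msd_um2 sem_um2 n`.
#'
#' @param msd An [compute_msd()] result.
#' @param path File path.
#' @return `write_msd` returns `path` invisibly; `read_msd` an `"msd_curve"`.
#' @export
write_msd <- function(msd, path) {
  d <- data.frame(tau_s = fmt_num(msd$tau), msd_um2 = fmt_num(msd$msd),
                  sem_um2 = fmt_num(msd$sem), n = msd$n)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  d <- utils::read.delim(path)
  out <- data.frame(tau = d$tau_s, msd = d$msd_um2, sem = d$sem_um2, n = d$n)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Write / read a kymograph table
#'
#' Long-format space-time table `t_s site species count` (species is
#' `mobile` or `polymer`).
#'
#' @param kymo Kymograph data frame from a simulation run (`t`, `site`,
#'   `mobile`, `polymer`).
#' @param path File path.
#' @return `write_kymograph` returns `path` invisibly; `read_kymograph` the
#'   wide data frame.
#' @export
write_kymograph <- function(kymo, path) {
  long <- rbind(
    data.frame(t_s = kymo$t, site = kymo$site, species = "mobile",
               count = kymo$mobile),
    data.frame(t_s = kymo$t, site = kymo$site, species = "polymer",
               count = kymo$polymer))
  long <- long[order(long$t_s, long$site, long$species), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  long <- utils::read.delim(path)
  wide <- stats::reshape(long, idvar = c("t_s", "site"), timevar = "species",
                         direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  out <- data.frame(t = wide$t_s, site = wide$site,
                    mobile = wide$mobile, polymer = wide$polymer)
  out[order(out$t, out$site), ]
}

#' Write / read an intensity stack
#'
#' Long-format delimited text `z x_um intensity` per cell/channel, or a
#' multi-page TIFF (one page per z plane) when `format = "tiff"` (requires
#' the tiff package; intensities are rescaled to [0, 1] on write and the
#' scale factor is lost, so TIFF is for interchange, TSV for round-trips).
#'
#' @param stack An [intensity_stack()].
#' @param path File path.
#' @param format `"tsv"` or `"tiff"`.
#' @return `write_stack` returns `path` invisibly; `read_stack` an
#'   [intensity_stack()].
#' @export
write_stack <- function(stack, path, format = c("tsv", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "intensity_stack"))
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required for TIFF output")
    }
    pages <- lapply(seq_len(ncol(stack$I)),
                    function(z) stack$I[, z, drop = TRUE] / max(stack$I, 1))
    tiff::writeTIFF(lapply(pages, function(p) matrix(p, nrow = 1L)), path)
    return(invisible(path))
  }
  d <- expand.grid(x_idx = seq_along(stack$x), z = seq_len(ncol(stack$I)))
  d <- data.frame(z = d$z, x_um = fmt_num(stack$x[d$x_idx]),
                  intensity = fmt_num(stack$I[cbind(d$x_idx, d$z)]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @param dz,poles,foci Metadata passed to [intensity_stack()] on read.
#' @export
read_stack <- function(path, dz = 0.1, poles = NULL, foci = numeric(0),
                       format = c("tsv", "tiff")) {
  format <- match.arg(format)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required for TIFF input")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    I <- do.call(cbind, lapply(pages, function(p) as.numeric(t(p))))
    x <- seq_len(nrow(I)) * 0.066        # pixel-grid coordinates
    return(intensity_stack(I, x, dz = dz,
                           poles = if (is.null(poles)) range(x) else poles,
                           foci = foci))
  }
  d <- utils::read.delim(path)
  x <- sort(unique(d$x_um))
  zs <- sort(unique(d$z))
  I <- matrix(0, length(x), length(zs))
  I[cbind(match(d$x_um, x), match(d$z, zs))] <- d$intensity
  intensity_stack(I, x, dz = dz,
                  poles = if (is.null(poles)) range(x) else poles,
                  foci = foci)
}

#' Write a resolved run configuration
#'
#' Every simulation run should leave its fully resolved parameter set and
#' seed next to its outputs; this writes a two-column `key value` table.
#'
#' @param config Named list of scalar settings (numbers, strings, logicals).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) paste(fmt_num(v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  utils::write.table(data.frame(key = names(config), value = vals),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  out <- lapply(d$value, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num
    else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
    else parts
  })
  names(out) <- d$key
  out
}
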