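#' Read a two-column spectrum file
#'
#' Reads whitespace-separated wavenumber/intensity text with `#`-prefixed
#' comment lines (which are preserved as metadata). An unsorted axis is
#' sorted on read, with a warning recorded in the metadata. An optional
#' constant readout offset can be subtracted on read.
#'
#' @param path File path.
#' @param offset Constant subtracted from all intensities (default 0).
#' @return A [raman_spectrum].
#' @export
read_spectrum <- function(path, offset = 0) {
  raw <- readLines(path)
  comments <- grep("^\\s*#", raw, value = TRUE)
  rows <- grep("^\\s*#|^\\s*$", raw, invert = TRUE)
  if (!length(rows)) .stopf("no data rows in '%s'", path)
  parts <- strsplit(trimws(raw[rows]), "\\s+")
  bad <- which(vapply(parts, function(p)
    length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2]))), TRUE))
  if (length(bad))
    .stopf("non-numeric row at line %d of '%s'", rows[bad[1L]], path)
  x <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  y <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1)) - offset
  meta <- list(file = path, header = comments)
  if (is.unsorted(x, strictly = TRUE)) {
    .warnf("unsorted wavenumber axis in '%s'; sorting on read", path)
    o <- order(x)
    x <- x[o]; y <- y[o]
    meta$sorted_on_read <- TRUE
  }
  raman_spectrum(x, y, meta = meta)
}

#' Write a spectrum as two-column text
#'
#' Writes full-precision wavenumber/intensity pairs, preceded by
#' `#`-prefixed metadata lines (including accumulated provenance), so that
#' `read_spectrum(write_spectrum(s))` round-trips exactly.
#'
#' @param s A [raman_spectrum].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  scalars <- Filter(function(v) is.character(v) || (is.numeric(v) &&
                      length(v) == 1L), s$meta)
  hdr <- sprintf("# %s: %s", names(scalars),
                 vapply(scalars, function(v)
                   paste(format(v, digits = 15), collapse = " "), ""))
  prov <- s$meta$provenance
  if (length(prov)) hdr <- c(hdr, sprintf("# step: %s", prov))
  body <- sprintf("%.15g %.15g", s$wavenumber, s$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Remove radiation spikes by comparing repeated scans
#'
#' Cosmic-ray spikes appear in single scans only; with three or more aligned
#' scans the per-point median suppresses them, with exactly two the
#' per-point minimum is the only robust choice. A single scan passes through
#' with a warning.
#'
#' @param scans A list of equal-length count vectors, or a matrix with one
#'   scan per column.
#' @return A single despiked vector.
#' @export
despike <- function(scans) {
  if (is.matrix(scans)) scans <- lapply(seq_len(ncol(scans)), function(i) scans[, i])
  lens <- lengths(scans)
  if (length(unique(lens)) != 1L) .stopf("scans must have equal lengths")
  n <- length(scans)
  if (n == 1L) {
    .warnf("single scan: despiking is a passthrough")
    return(scans[[1L]])
  }
  M <- do.call(cbind, scans)
  if (n == 2L) pmin(M[, 1L], M[, 2L])
  else apply(M, 1L, stats::median)
}

#' Correct pixel intensities for the nonlinearity of the wavenumber axis
#'
#' CCD pixels subtend unequal wavenumber widths; dividing each pixel's
#' counts by its spectral width (centred differences of the
#' pixel-to-wavenumber mapping, one-sided at the edges) converts counts per
#' pixel into a spectral density, preserving the total signal between pixel
#' sum and wavenumber integral.
#'
#' @param counts Counts per pixel.
#' @param wavenumber Wavenumber of each pixel centre (strictly monotone).
#' @return A [raman_spectrum] on the (ascending) wavenumber axis.
#' @export
jacobian_correct <- function(counts, wavenumber) {
  n <- length(counts)
  if (length(wavenumber) != n) .stopf("counts and wavenumber must be aligned")
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) .stopf("mapping must be strictly monotone")
  width <- numeric(n)
  width[1L] <- abs(wavenumber[2L] - wavenumber[1L])
  width[n] <- abs(wavenumber[n] - wavenumber[n - 1L])
  if (n > 2L) width[2:(n - 1L)] <- abs(wavenumber[3:n] - wavenumber[1:(n - 2L)]) / 2
  y <- counts / width
  if (d[1L] < 0) { wavenumber <- rev(wavenumber); y <- rev(y) }
  s <- raman_spectrum(wavenumber, y)
  .add_provenance(s, "jacobian_correct")
}

#' Stitch overlapping spectral windows into one spectrum
#'
#' Finite detector width forces long spectra to be recorded as overlapping
#' windows; they are catenated left to right by matching the peak height of
#' shared anchor signals. Each segment is rescaled so that its first shared
#' anchor equals the (already scaled) previous segment's height; overlapping
#' grid regions are averaged after scaling.
#'
#' @param segments List of [raman_spectrum] objects, ordered by wavenumber.
#' @param anchors Numeric vector of anchor signal positions in cm-1.
#' @param window Half-width in cm-1 for the anchor peak search (default 5).
#' @return A stitched [raman_spectrum].
#' @export
stitch_segments <- function(segments, anchors, window = 5) {
  stopifnot(all(vapply(segments, inherits, TRUE, "raman_spectrum")))
  k <- length(segments)
  if (k == 1L) return(segments[[1L]])
  scaled <- segments
  for (i in 2:k) {
    prev <- scaled[[i - 1L]]; cur <- scaled[[i]]
    rng <- c(max(min(prev$wavenumber), min(cur$wavenumber)),
             min(max(prev$wavenumber), max(cur$wavenumber)))
    shared <- anchors[anchors >= rng[1L] & anchors <= rng[2L]]
    if (!length(shared))
      .stopf("no shared anchor between segments %d and %d", i - 1L, i)
    a <- shared[1L]
    h_prev <- peak_height(prev, a, window)$height
    h_cur <- peak_height(cur, a, window)$height
    if (h_cur == 0) .stopf("anchor at %g cm-1 has zero height in segment %d", a, i)
    cur$intensity <- cur$intensity * (h_prev / h_cur)
    scaled[[i]] <- cur
  }
  # merge on the union grid, averaging overlaps
  x <- unlist(lapply(scaled, `[[`, "wavenumber"))
  y <- unlist(lapply(scaled, `[[`, "intensity"))
  agg_y <- rowsum(y, group = x)
  agg_n <- rowsum(rep(1, length(x)), group = x)
  out <- raman_spectrum(as.numeric(rownames(agg_y)),
                        as.numeric(agg_y / agg_n))
  .add_provenance(out, sprintf("stitch_segments(%d segments)", k))
}

#' Peak height within a window
#'
#' Maximum intensity within `[center - window, center + window]`, optionally
#' after subtracting the straight line through the window endpoints. When the
#' maximum sits on the window boundary the result carries `boundary = TRUE`,
#' signalling that the peak probably lies outside the window.
#'
#' @param s A [raman_spectrum].
#' @param center Window centre in cm-1.
#' @param window Half-width in cm-1.
#' @param baseline `"none"` (default) or `"linear_endpoints"`.
#' @return List with `height`, `position` and `boundary`.
#' @export
peak_height <- function(s, center, window,
                        baseline = c("none", "linear_endpoints")) {
  stopifnot(inherits(s, "raman_spectrum"))
  baseline <- match.arg(baseline)
  idx <- which(s$wavenumber >= center - window &
               s$wavenumber <= center + window)
  if (!length(idx)) .stopf("empty window around %g cm-1", center)
  x <- s$wavenumber[idx]; y <- s$intensity[idx]
  if (baseline == "linear_endpoints" && length(idx) > 1L) {
    slope <- (y[length(y)] - y[1L]) / (x[length(x)] - x[1L])
    y <- y - (y[1L] + slope * (x - x[1L]))
  }
  i <- which.max(y)
  list(height = y[i], position = x[i],
       boundary = i == 1L || i == length(y))
}

#' Concentration scaling exponent of a signal
#'
#' Least-squares slope of log(height) versus log(concentration). Monomer
#' signals scale with exponent ~1, dimer signals with ~2; the exponent is
#' the standard diagnostic for separating them in concentration series.
#'
#' @param heights Signal heights across >= 3 spectra (> 0).
#' @param concentrations Matching concentrations (> 0).
#' @return List with `exponent`, `se` (standard error) and `ci95`
#'   (approximate 95% confidence interval).
#' @export
concentration_scaling <- function(heights, concentrations) {
  if (length(heights) < 3L) .stopf("need at least 3 points")
  if (length(heights) != length(concentrations))
    .stopf("heights and concentrations must be aligned")
  if (any(heights <= 0) || any(concentrations <= 0))
    .stopf("heights and concentrations must be > 0")
  fit <- stats::lm(log(heights) ~ log(concentrations))
  co <- summary(fit)$coefficients
  est <- co[2L, 1L]; se <- co[2L, 2L]
  list(exponent = est, se = se, ci95 = est + c(-1.96, 1.96) * se)
}
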