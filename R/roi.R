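#' Discrete field samples
#'
#' Represents a computed E-field as weighted point samples: a position in
#' mm (MNI convention, right-anterior-superior axes), a volume weight in
#' mm^3 (e.g. the volume of the mesh element the sample abstracts), a
#' tissue label, and the field vector in V/m.
#'
#' @param x,y,z Positions in mm.
#' @param Ex,Ey,Ez Field vector components in V/m.
#' @param volume_mm3 Positive volume weights in mm^3 (default 1: unweighted).
#' @param tissue Tissue labels (default `"gray_matter"`).
#' @return Data frame of class `field_samples`.
#' @export
field_samples <- function(x, y, z, Ex, Ey, Ez, volume_mm3 = 1,
                          tissue = "gray_matter") {
  df <- data.frame(x_mm = x, y_mm = y, z_mm = z,
                   volume_mm3 = volume_mm3, tissue = tissue,
                   Ex = Ex, Ey = Ey, Ez = Ez, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[c("x_mm", "y_mm", "z_mm")]))))
    stop("sample positions must be finite")
  if (any(df$volume_mm3 <= 0)) stop("volume weights must be > 0")
  class(df) <- c("field_samples", "data.frame")
  df
}

#' Spherical region-of-interest specification
#'
#' @param center 3-vector, mm.
#' @param radius Sphere radius in mm (default 10).
#' @param tissue_filter Tissue labels to include (default gray matter
#'   only); `NULL` includes every tissue.
#' @return Object of class `roi_spec`.
#' @export
#' @examples
#' roi_spec(c(-52.2, -16.4, 57.8))
roi_spec <- function(center, radius = 10, tissue_filter = "gray_matter") {
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be a finite 3-vector (mm)")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  structure(list(center = center, radius = radius,
                 tissue_filter = tissue_filter), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("Spherical ROI: center (%g, %g, %g) mm, radius %g mm, tissue: %s\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              if (is.null(x$tissue_filter)) "any"
              else paste(x$tissue_filter, collapse = ", ")))
  invisible(x)
}

#' ROI-average E-field magnitude
#'
#' The study outcome measure: the average E-field magnitude (Euclidean
#' norm of the field vector, V/m) over samples inside a closed sphere
#' (`||position - center|| <= radius`) restricted to the ROI's tissue
#' labels. Magnitudes are averaged (mean of magnitudes, not magnitude of
#' the mean vector), by default volume-weighted.
#'
#' @param samples A [field_samples()] data frame.
#' @param roi A [roi_spec()].
#' @param weighted Volume-weight the average (default `TRUE`)?
#' @return ROI-average magnitude in V/m.
#' @export
#' @examples
#' s <- field_samples(x = 0, y = 0, z = 0, Ex = 0, Ey = 0, Ez = 80)
#' roi_mean_magnitude(s, roi_spec(c(0, 0, 0)))
roi_mean_magnitude <- function(samples, roi, weighted = TRUE) {
  stopifnot(is.data.frame(samples), inherits(roi, "roi_spec"))
  pos <- as.matrix(samples[c("x_mm", "y_mm", "z_mm")])
  d2 <- (pos[, 1] - roi$center[1])^2 + (pos[, 2] - roi$center[2])^2 +
    (pos[, 3] - roi$center[3])^2
  keep <- d2 <= roi$radius^2
  if (!is.null(roi$tissue_filter))
    keep <- keep & samples$tissue %in% roi$tissue_filter
  if (!any(keep))
    stop("empty ROI: no sample inside the sphere passes the tissue filter")
  mag <- sqrt(samples$Ex[keep]^2 + samples$Ey[keep]^2 + samples$Ez[keep]^2)
  w <- if (weighted) samples$volume_mm3[keep] else rep(1, sum(keep))
  sum(w * mag) / sum(w)
}

#' Write / read field-sample tables
#'
#' Comma-delimited text with header
#' `x_mm,y_mm,z_mm,volume_mm3,tissue,Ex,Ey,Ez`.
#'
#' @param samples A [field_samples()] data frame.
#' @param path File path.
#' @export
write_field_samples <- function(samples, path) {
  cols <- c("x_mm", "y_mm", "z_mm", "volume_mm3", "tissue", "Ex", "Ey", "Ez")
  out <- as.data.frame(samples)[, cols]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_field_samples
#' @export
read_field_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("x_mm", "y_mm", "z_mm", "volume_mm3", "tissue", "Ex", "Ey", "Ez")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed field-sample file, missing columns: ",
                         paste(miss, collapse = ", "))
  field_samples(df$x_mm, df$y_mm, df$z_mm, df$Ex, df$Ey, df$Ez,
                volume_mm3 = df$volume_mm3, tissue = df$tissue)
}
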