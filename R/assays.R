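#' Construct a melt curve
#' @param temperatures strictly increasing temperatures, degrees C
#' @param fluorescence same-length fluorescence trace (arbitrary units)
#' @return data.frame of class `melt_curve`
#' @export
melt_curve <- function(temperatures, fluorescence) {
  stopifnot(length(temperatures) == length(fluorescence),
            length(temperatures) >= 3,
            all(is.finite(temperatures)), all(is.finite(fluorescence)))
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  structure(data.frame(temperature = temperatures,
                       fluorescence = fluorescence),
            class = c("melt_curve", "data.frame"))
}

#' Read a melt curve from CSV
#'
#' Expects columns `temperature` and `fluorescence`; an optional `well`
#' column splits the file into one curve per well.
#'
#' @param path CSV path
#' @return a `melt_curve`, or a named list of them when `well` is present
#' @export
read_melt_curve <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "fluorescence")
  if (!all(need %in% names(d)))
    stop("melt-curve CSV needs columns: ", paste(need, collapse = ", "))
  if ("well" %in% names(d)) {
    lapply(split(d, d$well),
           function(x) melt_curve(x$temperature, x$fluorescence))
  } else {
    melt_curve(d$temperature, d$fluorescence)
  }
}

#' Melting temperature from a melt curve
#'
#' Min-max normalizes the full trace and reports the temperature of the
#' first upward crossing of 0.5, linearly interpolated between the
#' bracketing points. Invariant under any affine rescaling of the
#' fluorescence axis. A trace that never crosses 0.5 upward (for instance a
#' monotonically decreasing signal) has no transition and is an error.
#'
#' @param c a `melt_curve`
#' @return melting temperature, degrees C
#' @export
melting_temperature <- function(c) {
  f <- c$fluorescence
  rng <- range(f)
  if (rng[1] == rng[2]) stop("flat trace: no melting transition")
  fn <- (f - rng[1]) / (rng[2] - rng[1])
  below <- fn[-length(fn)] < 0.5
  above <- fn[-1] >= 0.5
  idx <- which(below & above)
  if (length(idx) == 0) stop("no upward crossing of 0.5: no melting transition")
  i <- idx[1]
  t0 <- c$temperature[i]; t1 <- c$temperature[i + 1]
  f0 <- fn[i]; f1 <- fn[i + 1]
  t0 + (0.5 - f0) / (f1 - f0) * (t1 - t0)
}

#' Read a grayscale assay image (PNG)
#' @param path PNG path
#' @return numeric matrix in \[0, 1\] (channels averaged if RGB)
#' @export
read_assay_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

# two-pass connected-component labeling under 8-connectivity (the installed
# image stack labels 4-connected components only)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1 && mask[i - 1, j]) nb <- c(nb, lab[i - 1, j])
      if (j > 1) {
        if (mask[i, j - 1]) nb <- c(nb, lab[i, j - 1])
        if (i > 1 && mask[i - 1, j - 1]) nb <- c(nb, lab[i - 1, j - 1])
        if (i < nr && mask[i + 1, j - 1]) nb <- c(nb, lab[i + 1, j - 1])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        keep <- min(roots)
        lab[i, j] <- keep
        for (r in roots) parent[r] <- keep
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  nzero <- lab != 0L
  lab[nzero] <- compact[lab[nzero]]
  lab
}

#' Quantify bead aggregates in a thresholded image
#'
#' Binarizes the image (`intensity > threshold`), labels connected
#' components under 8-connectivity, discards components smaller than
#' `min_size` pixels, and reports particle count, per-particle areas in
#' pixels, and the mean area. `threshold = "otsu"` picks the threshold by
#' Otsu's histogram method; a numeric value uses a fixed threshold. An empty
#' mask yields count 0 and mean 0, flagged.
#'
#' @param image numeric matrix of intensities in \[0, 1\]
#' @param threshold numeric, or `"otsu"` (default)
#' @param min_size minimum component area in pixels (default 1)
#' @return list of class `aggregate_stats`: `particle_count`, `areas`,
#'   `mean_area`, `threshold`, `empty`
#' @export
quantify_aggregates <- function(image, threshold = "otsu", min_size = 1) {
  stopifnot(length(image) > 0)
  image <- as.matrix(image)
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(EBImage::Image(image))
  }
  mask <- image > threshold
  lab <- label_components8(mask)
  areas <- if (max(lab) > 0) as.numeric(table(lab[lab > 0])) else numeric(0)
  areas <- areas[areas >= min_size]
  structure(list(particle_count = length(areas), areas = areas,
                 mean_area = if (length(areas)) mean(areas) else 0,
                 threshold = threshold, empty = length(areas) == 0),
            class = "aggregate_stats")
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat("Aggregates:", x$particle_count, "particle(s), mean area",
      sprintf("%.1f", x$mean_area), "px (threshold",
      sprintf("%.3f", x$threshold), ")\n")
  invisible(x)
}

#' Mean and SEM of aggregate size across replicate images
#'
#' Replicate time points (for instance T0, T60, and post-rocking images) are
#' treated as independent images; the mean aggregate size per image is
#' summarized as mean +/- standard error of the mean across replicates.
#'
#' @param stats_list list of `aggregate_stats`
#' @return list with `mean`, `sem`, `n`
#' @export
summarize_aggregates <- function(stats_list) {
  m <- vapply(stats_list, function(x) x$mean_area, numeric(1))
  list(mean = mean(m),
       sem = if (length(m) > 1) sd(m) / sqrt(length(m)) else NA_real_,
       n = length(m))
}
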