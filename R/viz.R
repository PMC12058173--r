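# Visualization: time-frequency rasters, condition differences, electrode
# layouts and interpolated 2D scalp maps.

#' Difference of two time-frequency results
#'
#' Elementwise `a - b` for two results on identical axes, channels and
#' (non-complex) measure — the within-subject condition contrast.
#'
#' @param a,b `tf_result` objects.
#' @return A `tf_result` whose condition label records `"A - B"`.
#' @export
diff_conditions <- function(a, b) {
  stopifnot(inherits(a, "tf_result"), inherits(b, "tf_result"))
  if (a$measure == "complex" || b$measure == "complex") {
    stop("condition differences need amplitude/power/dB results, not complex",
         call. = FALSE)
  }
  if (!identical(a$measure, b$measure)) {
    stop(sprintf("incompatible results: measures differ (%s vs %s)",
                 a$measure, b$measure), call. = FALSE)
  }
  if (!isTRUE(all.equal(a$frequencies, b$frequencies)) ||
      !isTRUE(all.equal(a$time_ms, b$time_ms)) ||
      !identical(a$channels, b$channels)) {
    stop("incompatible results: axes or channel labels differ",
         call. = FALSE)
  }
  a$values <- a$values - b$values
  a$sem <- NULL
  a$condition <- paste(a$condition, "-", b$condition)
  a
}

#' Plot a time-frequency raster
#'
#' Raster of the result values over (time, frequency) for one channel or for
#' the average of a channel subset, with user-defined time, frequency and
#' colour-scale ranges.  Baseline-corrected and difference data get a
#' diverging colour scale symmetric about zero; raw amplitude/power a
#' sequential one.  With `show_sem = TRUE` (requires the SEM sibling tensor,
#' see [tf_transform()]) a contour encloses the regions where the effect
#' exceeds twice its standard error across trials, a descriptive
#' effect-size aid.
#'
#' @param result A `tf_result` (non-complex).
#' @param channel Channel label/index, or a character vector of labels to
#'   average (via [average_channels()]); optional for single-channel results.
#' @param time_range,freq_range Optional display windows, ms / Hz.
#' @param zlim Optional colour-scale limits `c(min, max)` with min < max.
#' @param show_sem Overlay the SEM-based contour.
#' @param file Optional output path (png/svg/pdf by extension).
#' @return The ggplot object, invisibly if written to `file`.
#' @export
plot_tf <- function(result, channel = NULL, time_range = NULL,
                    freq_range = NULL, zlim = NULL, show_sem = FALSE,
                    file = NULL) {
  stopifnot(inherits(result, "tf_result"))
  if (result$measure == "complex") {
    stop("cannot plot complex coefficients; take a measure first",
         call. = FALSE)
  }
  if (!is.null(zlim) && (length(zlim) != 2L || zlim[1] >= zlim[2])) {
    stop("`zlim` must be c(min, max) with min < max", call. = FALSE)
  }
  if (is.character(channel) && length(channel) > 1L) {
    result <- average_channels(result, channel)
    channel <- NULL
  }
  ch <- resolve_channel(result, channel)
  ti <- if (is.null(time_range)) seq_along(result$time_ms) else
    snap_span(result$time_ms, time_range, "time_range")
  fi <- if (is.null(freq_range)) seq_along(result$frequencies) else
    snap_span(result$frequencies, freq_range, "freq_range")
  m <- result$values[ch, fi, ti, drop = TRUE]
  df <- expand.grid(frequency = result$frequencies[fi],
                    time = result$time_ms[ti])
  df$value <- as.vector(m)
  diverging <- !is.null(result$baseline) || grepl(" - ", result$condition)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)",
                  fill = result$measure,
                  title = sprintf("%s / %s [%s]", result$subject,
                                  result$condition, result$channels[ch])) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
  p <- p + if (diverging) {
    lim <- if (is.null(zlim)) max(abs(df$value)) * c(-1, 1) else zlim
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = lim,
                                  oob = scales_squish)
  } else {
    ggplot2::scale_fill_gradientn(colours = grDevices::hcl.colors(64, "Viridis"),
                                  limits = zlim, oob = scales_squish)
  }
  if (show_sem) {
    if (is.null(result$sem)) {
      stop("no SEM tensor stored; rerun tf_transform(..., keep_sem = TRUE)",
           call. = FALSE)
    }
    s <- result$sem[ch, fi, ti, drop = TRUE]
    df$ratio <- abs(as.vector(m)) / pmax(as.vector(s), .Machine$double.eps)
    p <- p + ggplot2::geom_contour(
      data = df, ggplot2::aes(x = .data$time, y = .data$frequency,
                              z = .data$ratio),
      breaks = 2, colour = "black", linewidth = 0.3, inherit.aes = FALSE)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

# Clamp out-of-range values to the colour-scale limits (the role scales::squish
# plays elsewhere; defined here to keep the dependency surface small).
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Read an electrode layout file
#'
#' Parses EEGLAB-style channel location dialects to a common 2D head-plane
#' convention: vertex (Cz) at the origin, nose along +y, unit radius at the
#' head equator.
#'
#' * `.ced`: tab/space table with `labels`, `theta` (degrees clockwise from
#'   the nose direction) and `radius` (0 = vertex, 0.5 = equator) columns.
#' * `.sfp`: `label x y z` Cartesian rows (nose +x, left ear +y, vertex +z);
#'   fiducial rows (labels starting with `fid`) are ignored.
#' * `.elp`: BESA-style spherical rows `type label theta phi` with theta the
#'   azimuth from the vertex toward the nose.
#'
#' @param path Layout file; the dialect follows the extension.
#' @return An `electrode_layout` data.frame with columns `label`, `x`, `y`.
#' @export
read_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ced", "sfp", "elp")) {
    stop("unsupported layout format: .", ext, call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lay <- switch(ext,
    ced = read_layout_ced(path),
    sfp = read_layout_sfp(path),
    elp = read_layout_elp(path),
    stop("unsupported layout format: .", ext, call. = FALSE))
  electrode_layout(lay$label, lay$x, lay$y)
}

#' Construct an electrode layout from 2D coordinates
#'
#' @param label Channel labels.
#' @param x,y Head-plane coordinates: vertex at the origin, nose along +y,
#'   radius 1 at the head equator.
#' @return An `electrode_layout` data.frame.
#' @export
electrode_layout <- function(label, x, y) {
  stopifnot(length(label) == length(x), length(x) == length(y))
  r <- sqrt(x^2 + y^2)
  if (any(r > 1 + 1e-6)) {
    warning("electrode(s) outside the unit disc: ",
            paste(label[r > 1 + 1e-6], collapse = ", "))
  }
  structure(data.frame(label = as.character(label), x = x, y = y,
                       stringsAsFactors = FALSE),
            class = c("electrode_layout", "data.frame"))
}

polar_to_xy <- function(theta_deg, radius) {
  # theta measured clockwise from the nose direction (+y)
  list(x = radius * sin(theta_deg * pi / 180),
       y = radius * cos(theta_deg * pi / 180))
}

read_layout_ced <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("labels", "theta", "radius") %in% names(tab))) {
    stop("malformed .ced file: need labels/theta/radius columns",
         call. = FALSE)
  }
  xy <- polar_to_xy(tab$theta, tab$radius / 0.5)
  data.frame(label = tab$labels, x = xy$x, y = xy$y,
             stringsAsFactors = FALSE)
}

read_layout_sfp <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) {
    stop("malformed .sfp file: need label x y z rows", call. = FALSE)
  }
  tab <- tab[!grepl("^fid", tab[[1]], ignore.case = TRUE), , drop = FALSE]
  cx <- as.numeric(tab[[2]]); cy <- as.numeric(tab[[3]])
  cz <- as.numeric(tab[[4]])
  elev <- atan2(cz, sqrt(cx^2 + cy^2))        # pi/2 at vertex
  radius <- (pi / 2 - elev) / (pi / 2)        # 0 vertex, 1 equator
  azim <- atan2(cy, cx)                       # 0 = nose (+x), ccw
  data.frame(label = tab[[1]],
             x = -radius * sin(azim),         # left ear (+y cart) -> -x plot
             y = radius * cos(azim),
             stringsAsFactors = FALSE)
}

read_layout_elp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|//|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  keep <- vapply(parts, length, 0L) >= 4L
  parts <- parts[keep]
  if (!length(parts)) stop("malformed .elp file", call. = FALSE)
  label <- vapply(parts, `[[`, "", 2L)
  theta <- as.numeric(vapply(parts, `[[`, "", 3L))  # inclination from vertex
  phi <- as.numeric(vapply(parts, `[[`, "", 4L))    # azimuth, nose = 0
  radius <- abs(theta) / 90
  azim <- ifelse(theta >= 0, phi, phi + 180)
  data.frame(label = label,
             x = radius * sin(azim * pi / 180),
             y = radius * cos(azim * pi / 180),
             stringsAsFactors = FALSE)
}

#' Approximate 10-20 system layout for the bundled fixture montage
#'
#' Standard-position approximation of the 19-channel 10-20 montage used by
#' the synthetic fixtures; no vendor data involved.
#'
#' @return An `electrode_layout`.
#' @export
layout_1020 <- function() {
  spec <- list(
    Fp1 = c(-18, 0.8), Fpz = c(0, 0.8), Fp2 = c(18, 0.8),
    F7 = c(-54, 0.8), F3 = c(-39, 0.56), Fz = c(0, 0.4), F4 = c(39, 0.56),
    F8 = c(54, 0.8),
    T7 = c(-90, 0.8), C3 = c(-90, 0.4), Cz = c(0, 0), C4 = c(90, 0.4),
    T8 = c(90, 0.8),
    P7 = c(-126, 0.8), P3 = c(-141, 0.56), Pz = c(180, 0.4),
    P4 = c(141, 0.56), P8 = c(126, 0.8), Oz = c(180, 0.8))
  theta <- vapply(spec, `[[`, 0, 1L)
  radius <- vapply(spec, `[[`, 0, 2L)
  xy <- polar_to_xy(theta, radius)
  electrode_layout(names(spec), xy$x, xy$y)
}

# Biharmonic spline interpolation (Green's function r^2 (log r - 1)) of
# scattered electrode values onto a grid; exact at the electrodes.
biharmonic_interp <- function(px, py, v, gx, gy) {
  green <- function(d2) {
    d2 <- pmax(d2, .Machine$double.eps)
    d2 * (0.5 * log(d2) - 1)       # r^2 (log r - 1) with d2 = r^2
  }
  n <- length(px)
  D <- outer(px, px, "-")^2 + outer(py, py, "-")^2
  G <- green(D)
  diag(G) <- 0
  # augment with a constant term so flat fields are reproduced exactly
  A <- rbind(cbind(G + diag(1e-10, n), 1), c(rep(1, n), 0))
  sol <- solve(A, c(v, 0))
  w <- sol[seq_len(n)]
  gp <- expand.grid(x = gx, y = gy)
  D2 <- outer(gp$x, px, "-")^2 + outer(gp$y, py, "-")^2
  vals <- green(D2) %*% w + sol[n + 1L]
  matrix(vals, length(gx), length(gy))
}

# Per-channel scalar for a topographic selection: a single time point at a
# single frequency, a time average at one frequency, or a frequency-range
# average at one time point -- all via window_mean for cross-module
# consistency.
topo_values <- function(result, time, frequency, time_window, freq_window) {
  tw <- if (!is.null(time_window)) time_window else {
    if (is.null(time)) stop("give `time` or `time_window`", call. = FALSE)
    c(time, time)
  }
  fw <- if (!is.null(freq_window)) freq_window else {
    if (is.null(frequency)) {
      stop("give `frequency` or `freq_window`", call. = FALSE)
    }
    c(frequency, frequency)
  }
  vapply(seq_along(result$channels), function(ch) {
    window_mean(result, tw, fw, ch)
  }, 0)
}

#' Plot an interpolated 2D scalp map
#'
#' Reduces the result to one scalar per channel — one time point at one
#' frequency, an average of time points at one frequency, or a
#' frequency-range average at one time point — then interpolates the values
#' over the head disc (biharmonic spline, masked beyond the electrode hull)
#' and draws them with a head outline.  A vector of `times` or `frequencies`
#' gives a series of maps as facets (time topography over frequency and vice
#' versa).
#'
#' @param result A `tf_result` (non-complex).
#' @param layout An `electrode_layout` covering all result channels.
#' @param time,frequency Scalar selections (ms / Hz).
#' @param time_window,freq_window Averaging windows replacing the scalar
#'   selections.
#' @param times,frequencies Optional series: one panel per listed value.
#' @param grid_n Interpolation grid resolution per axis.
#' @param zlim Optional colour limits.
#' @param file Optional output path.
#' @return The ggplot object; the per-channel scalars and interpolation are
#'   available in `attr(, "field")`.
#' @export
plot_topo2d <- function(result, layout, time = NULL, frequency = NULL,
                        time_window = NULL, freq_window = NULL,
                        times = NULL, frequencies = NULL,
                        grid_n = 67, zlim = NULL, file = NULL) {
  stopifnot(inherits(result, "tf_result"),
            inherits(layout, "electrode_layout"))
  if (result$measure == "complex") {
    stop("cannot map complex coefficients; take a measure first",
         call. = FALSE)
  }
  missing_ch <- setdiff(result$channels, layout$label)
  if (length(missing_ch)) {
    stop("channel(s) missing from the layout: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  panels <- if (!is.null(times)) {
    lapply(times, function(tt) list(time = tt, frequency = frequency,
                                    time_window = NULL,
                                    freq_window = freq_window,
                                    tag = sprintf("%g ms", tt)))
  } else if (!is.null(frequencies)) {
    lapply(frequencies, function(ff) list(time = time, frequency = ff,
                                          time_window = time_window,
                                          freq_window = NULL,
                                          tag = sprintf("%g Hz", ff)))
  } else {
    list(list(time = time, frequency = frequency, time_window = time_window,
              freq_window = freq_window, tag = ""))
  }
  idx <- match(result$channels, layout$label)
  px <- layout$x[idx]; py <- layout$y[idx]
  gx <- seq(-1.05, 1.05, length.out = grid_n)
  gy <- gx
  mask <- topo_mask(px, py, gx, gy)
  dfs <- list(); fields <- list()
  for (p in panels) {
    v <- topo_values(result, p$time, p$frequency, p$time_window,
                     p$freq_window)
    z <- biharmonic_interp(px, py, v, gx, gy)
    z[!mask] <- NA
    d <- expand.grid(x = gx, y = gy)
    d$value <- as.vector(z)   # grid is x-major, matching the matrix layout
    d$panel <- p$tag
    dfs[[length(dfs) + 1L]] <- d
    fields[[length(fields) + 1L]] <- list(values = v, grid = z, tag = p$tag)
  }
  df <- do.call(rbind, dfs)
  df <- df[!is.na(df$value), , drop = FALSE]   # cells outside the head mask
  diverging <- !is.null(result$baseline) || grepl(" - ", result$condition)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    head_outline() +
    ggplot2::annotate("point", x = px, y = py, size = 0.6) +
    ggplot2::coord_fixed(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = result$measure,
                  title = sprintf("%s / %s", result$subject,
                                  result$condition))
  pl <- pl + if (diverging) {
    lim <- if (is.null(zlim)) {
      max(abs(df$value), na.rm = TRUE) * c(-1, 1)
    } else zlim
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = lim,
                                  oob = scales_squish, na.value = NA)
  } else {
    ggplot2::scale_fill_gradientn(colours = grDevices::hcl.colors(64, "Viridis"),
                                  limits = zlim, oob = scales_squish,
                                  na.value = NA)
  }
  if (length(panels) > 1L) {
    df$panel <- factor(df$panel, levels = unique(df$panel))
    pl <- pl + ggplot2::facet_wrap(~panel)
  }
  attr(pl, "field") <- if (length(fields) == 1L) fields[[1]] else fields
  if (!is.null(file)) {
    ggplot2::ggsave(file, pl, width = 6, height = 6, dpi = 150)
    return(invisible(pl))
  }
  pl
}

# Mask: inside the unit disc AND inside the electrode convex hull expanded by
# a small margin about its centroid.
topo_mask <- function(px, py, gx, gy) {
  hull <- grDevices::chull(px, py)
  cx <- mean(px[hull]); cy <- mean(py[hull])
  margin <- 1.15
  bx <- cx + (px[hull] - cx) * margin
  by <- cy + (py[hull] - cy) * margin
  gp <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- mgcv::in.out(cbind(c(bx, bx[1]), c(by, by[1])), gp)
  disc <- gp[, 1]^2 + gp[, 2]^2 <= 1.05^2
  matrix(inside & disc, length(gx), length(gy))
}

head_outline <- function() {
  th <- seq(0, 2 * pi, length.out = 181)
  head <- data.frame(x = cos(th), y = sin(th))
  nose <- data.frame(x = c(-0.08, 0, 0.08), y = c(0.995, 1.12, 0.995))
  ear_r <- data.frame(x = 1 + 0.06 * cos(th), y = 0.12 * sin(th))
  ear_l <- data.frame(x = -1 - 0.06 * cos(th), y = 0.12 * sin(th))
  list(
    ggplot2::annotate("path", x = head$x, y = head$y, linewidth = 0.4),
    ggplot2::annotate("path", x = nose$x, y = nose$y, linewidth = 0.4),
    ggplot2::annotate("path", x = ear_r$x, y = ear_r$y, linewidth = 0.4),
    ggplot2::annotate("path", x = ear_l$x, y = ear_l$y, linewidth = 0.4))
}
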