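#' Specification of a synthetic fluorescence time-lapse
#'
#' Describes a synthetic single-channel stack with known ground truth,
#' emulating in vitro Min-wave imaging: default 15 s frame interval,
#' wavelengths of tens of um, crest speeds of hundreds of nm/s, additive
#' Gaussian noise (optional Poisson shot noise), mono-exponential bleaching
#' and static bright aggregates.
#'
#' @param kind `"planar"`, `"spiral"` or `"static"`.
#' @param wavelength pattern wavelength (um); must exceed 2 pixels.
#' @param speed crest speed (nm/s); `speed * interval` must stay below half
#'   a wavelength (no temporal aliasing).
#' @param angle propagation direction (degrees, 0 = +x = downstream,
#'   counter-clockwise).
#' @param amplitude wave amplitude (intensity units).
#' @param baseline background intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param poisson logical; add Poisson shot noise.
#' @param bleach_rate mono-exponential bleaching rate (1/frame).
#' @param aggregates data frame with columns `x`, `y` (pixels), `intensity`,
#'   `radius` (pixels) describing static bright blobs, or `NULL`.
#' @param H,W,T frame height, width (pixels) and frame count.
#' @param pixel_size um per pixel.
#' @param interval frame interval (s).
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @export
synthetic_stack_spec <- function(kind = c("planar", "spiral", "static"),
                                 wavelength = 60, speed = 300, angle = 0,
                                 amplitude = 0.5, baseline = 0.2,
                                 noise_sd = 0.02, poisson = FALSE,
                                 bleach_rate = 0, aggregates = NULL,
                                 H = 96, W = 96, T = 48,
                                 pixel_size = 2, interval = 15, seed = 1L) {
  kind <- match.arg(kind)
  if (wavelength <= 2 * pixel_size)
    stop("wavelength must exceed 2 pixels")
  if (kind != "static" && speed * interval / 1000 >= wavelength / 2)
    stop("temporal aliasing: speed * interval must be below wavelength/2")
  structure(list(kind = kind, wavelength = wavelength, speed = speed,
                 angle = angle, amplitude = amplitude, baseline = baseline,
                 noise_sd = noise_sd, poisson = poisson,
                 bleach_rate = bleach_rate, aggregates = aggregates,
                 H = as.integer(H), W = as.integer(W), T = as.integer(T),
                 pixel_size = pixel_size, interval = interval,
                 seed = as.integer(seed)),
            class = "synthetic_stack_spec")
}

#' Image stack container
#'
#' @param frames numeric array `[H, W, T]` of intensities.
#' @param pixel_size um per pixel.
#' @param interval frame interval (s).
#' @param flow_angle orientation of the downstream direction (deg; 0 = +x).
#' @export
image_stack <- function(frames, pixel_size, interval, flow_angle = 0) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            pixel_size > 0, interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 interval = interval, flow_angle = flow_angle),
            class = "image_stack")
}

.render_common <- function(spec, phase_fun) {
  H <- spec$H; W <- spec$W; T <- spec$T
  xs <- (seq_len(W) - 1) * spec$pixel_size
  ys <- (seq_len(H) - 1) * spec$pixel_size
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  agg <- matrix(0, H, W)
  agg_mask <- matrix(FALSE, H, W)
  if (!is.null(spec$aggregates)) {
    for (i in seq_len(nrow(spec$aggregates))) {
      a <- spec$aggregates[i, ]
      d2 <- (col(agg) - a$x)^2 + (row(agg) - a$y)^2
      agg <- agg + a$intensity * exp(-d2 / (2 * a$radius^2))
      agg_mask <- agg_mask | d2 <= (2 * a$radius)^2
    }
  }
  frames <- withr::with_seed(spec$seed, {
    fr <- array(0, c(H, W, T))
    for (t in seq_len(T)) {
      ph <- phase_fun(X, Y, (t - 1) * spec$interval)
      img <- spec$baseline + spec$amplitude * (1 + cos(ph)) / 2 + agg
      img <- img * exp(-spec$bleach_rate * (t - 1))
      if (spec$poisson) {
        scale <- 1000
        img <- stats::rpois(length(img), img * scale) / scale
      }
      img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
      fr[, , t] <- pmax(img, 0)
    }
    fr
  })
  list(stack = image_stack(frames, spec$pixel_size, spec$interval),
       agg_mask = agg_mask)
}

#' Synthetic planar traveling-wave stack
#'
#' Intensity `baseline + amplitude (1 + cos(k.r - w t))/2`, bleached,
#' noised, with optional static aggregates.  Fully reproducible from the
#' spec's seed.
#'
#' @param spec a `synthetic_stack_spec` with `kind = "planar"`.
#' @return list with `stack` (an `image_stack`) and `truth` (true velocity
#'   vector in nm/s, wavelength, aggregate mask).
#' @export
planar_wave_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_stack_spec"), spec$kind == "planar")
  k <- 2 * pi / spec$wavelength
  th <- spec$angle * pi / 180
  om <- 2 * pi * (spec$speed / 1000) / spec$wavelength
  r <- .render_common(spec, function(X, Y, t)
    k * (cos(th) * X + sin(th) * Y) - om * t)
  list(stack = r$stack,
       truth = list(v = spec$speed * c(cos(th), sin(th)),
                    speed = spec$speed, angle = spec$angle,
                    wavelength = spec$wavelength,
                    aggregate_mask = r$agg_mask))
}

#' Synthetic rotating-spiral stack
#'
#' Archimedean spiral phase `chirality * theta - k r + w t` rotating at
#' angular rate `w`; the local crest speed is `w / k` everywhere, with
#' isotropically distributed directions.
#'
#' @param spec a `synthetic_stack_spec` with `kind = "spiral"`.
#' @param chirality +1 or -1.
#' @return list with `stack` and `truth` (local speed, wavelength, mask).
#' @export
spiral_stack <- function(spec, chirality = 1) {
  stopifnot(inherits(spec, "synthetic_stack_spec"), spec$kind == "spiral")
  k <- 2 * pi / spec$wavelength
  om <- 2 * pi * (spec$speed / 1000) / spec$wavelength
  cx <- (spec$W - 1) / 2 * spec$pixel_size
  cy <- (spec$H - 1) / 2 * spec$pixel_size
  r <- .render_common(spec, function(X, Y, t) {
    dx <- X - cx; dy <- Y - cy
    chirality * atan2(dy, dx) - k * sqrt(dx^2 + dy^2) + om * t
  })
  list(stack = r$stack,
       truth = list(speed = spec$speed, wavelength = spec$wavelength,
                    chirality = chirality, aggregate_mask = r$agg_mask))
}

#' Static stack (no wave)
#' @param spec a `synthetic_stack_spec` with `kind = "static"`.
#' @export
static_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_stack_spec"), spec$kind == "static")
  r <- .render_common(spec, function(X, Y, t) 0 * X)
  list(stack = r$stack, truth = list(speed = 0,
                                     aggregate_mask = r$agg_mask))
}

#' Write / read a stack as multi-frame 16-bit grayscale TIFF
#'
#' Intensities are scaled by `scale` (default: the stack maximum) into
#' [0, 1] and quantized to 16 bits.
#'
#' @param stack an `image_stack`.
#' @param path output file.
#' @param scale intensity mapped to full scale.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  if (is.null(scale)) scale <- max(stack$frames)
  fr <- lapply(seq_len(dim(stack$frames)[3]), function(t)
    pmin(pmax(stack$frames[, , t] / scale, 0), 1))
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size,interval,flow_angle metadata for the returned stack
#'   (TIFF carries none).
#' @export
read_stack_tiff <- function(path, pixel_size, interval, flow_angle = 0) {
  fr <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(fr[[1]])[1], dim(fr[[1]])[2], length(fr)))
  for (t in seq_along(fr)) arr[, , t] <- fr[[t]]
  image_stack(arr, pixel_size, interval, flow_angle)
}

#' Traveling-wave-seeded initial condition
#'
#' Homogeneous steady state plus a finite-amplitude traveling-wave ansatz
#' built from the leading eigenvector of the linearized dynamics at the
#' seed wavenumber (evaluated at `v_f = 0`, where the two propagation
#' directions are exchanged by reflection).  `direction = +1` seeds a +x
#' (downstream for `v_f > 0`) mover, `-1` the mirror image.  Wavelengths
#' incommensurate with the periodic domain are snapped to the nearest
#' harmonic (recorded in `attr(, "wavelength")`).
#'
#' @param params a `min_params`.
#' @param grid a `min_grid`.
#' @param wavelength seed wavelength (um).
#' @param direction +1 (+x) or -1 (-x).
#' @param amp relative amplitude of the perturbation (fraction of the
#'   steady-state concentrations); `amp = 0` returns the bare steady state.
#' @export
seeded_wave_state <- function(params, grid, wavelength, direction = 1,
                              amp = 0.3) {
  stopifnot(direction %in% c(-1, 1), amp >= 0, amp < 1)
  k_int <- max(1L, as.integer(round(grid$L / wavelength)))
  q <- 2 * pi * k_int / grid$L
  p0 <- params; p0$v_f <- 0
  ss <- homogeneous_steady_state(p0, grid)
  if (amp == 0) return(ss)
  lin_par <- if (p0$variant == "reduced_switch") {
    pf <- p0; pf$variant <- "full"; pf
  } else p0
  ss1 <- homogeneous_steady_state(lin_par)
  eg <- eigen(jacobian_at_q(lin_par, ss1, q))
  # leading mode; of a conjugate pair take the member whose phase velocity
  # -Im(sigma)/q points along +x, then mirror via x -> -x if needed
  lead <- order(-Re(eg$values))
  i <- lead[1]
  if (Im(eg$values[i]) > 0) {
    j <- lead[which(abs(Re(eg$values[lead]) - Re(eg$values[i])) < 1e-10 &
                      Im(eg$values[lead]) < 0)][1]
    if (!is.na(j)) i <- j
  }
  v <- eg$vectors[, i]
  u0 <- ss$fields[1, ]
  vs <- v / max(abs(v) / pmax(u0, 1e-12 * max(u0)))
  phase <- exp(1i * direction * q * grid$x)
  pert <- amp * Re(outer(phase, vs))
  f <- ss$fields + pert
  f[f < 0] <- 0
  if (params$variant == "skeleton") f[, "c_Ei"] <- 0
  st <- field_state(f, t = 0)
  attr(st, "wavelength") <- grid$L / k_int
  attr(st, "snapped") <- abs(grid$L / k_int - wavelength) > 1e-9
  st
}
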