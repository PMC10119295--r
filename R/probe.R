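#' Average the feature maps of a convolutional layer
#'
#' The layer probe: the time series obtained by averaging all post-activation
#' feature maps of one convolutional layer,
#' `t_j = (1 / n_maps) * sum_i maps[i, j]`. This summation mirrors the way a
#' scalp electrode averages neural activity and yields an interpretable
#' trace of where the layer is most active.
#'
#' @param stack A `feature_map_stack` from [get_feature_maps()] (or a plain
#'   matrix with maps in rows).
#' @return Object of class `probe_series`: list with `values` (length = layer
#'   length), `layer_index`, `owner`, and (after [upsample_probe()])
#'   `upsampled` and `factor`.
#' @export
average_feature_maps <- function(stack) {
  maps <- if (inherits(stack, "feature_map_stack")) stack$maps else stack
  if (!is.matrix(maps)) maps <- matrix(maps, nrow = 1)
  if (nrow(maps) < 1 || length(maps) == 0) {
    stop("average_feature_maps: empty feature-map stack")
  }
  structure(list(values = colMeans(maps),
                 layer_index = if (inherits(stack, "feature_map_stack"))
                   stack$layer_index else NA_integer_,
                 owner = if (inherits(stack, "feature_map_stack"))
                   stack$owner else NA_character_,
                 upsampled = NULL, factor = 1L, rate = NA_real_),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("<probe_series> %s layer %s, length %d%s\n",
              x$owner, format(x$layer_index), length(x$values),
              if (!is.null(x$upsampled))
                sprintf(", upsampled x%d to %d", x$factor,
                        length(x$upsampled)) else ""))
  invisible(x)
}

#' Upsample a probe series to audio rate
#'
#' Linear interpolation of the layer time series by an integer factor.
#' Sample `j` of the layer is anchored at audio sample `(j - 1) * factor + 1`
#' (left-aligned convention); the trailing stretch holds the last value.
#' Endpoints and monotone segments are preserved and interpolation cannot
#' overshoot the original extrema.
#'
#' @param probe A `probe_series` (or numeric vector).
#' @param factor Integer upsampling factor (>= 1).
#' @param rate Optional audio rate (Hz) of the upsampled view, recorded on
#'   the result.
#' @return The probe with `upsampled` (length `length(values) * factor`),
#'   `factor`, and `rate` filled in; for a numeric input, the upsampled
#'   vector.
#' @export
upsample_probe <- function(probe, factor, rate = NA_real_) {
  if (factor < 1 || factor != round(factor)) {
    stop("upsample_probe: factor must be a positive integer")
  }
  factor <- as.integer(factor)
  v <- if (inherits(probe, "probe_series")) probe$values else as.numeric(probe)
  L <- length(v)
  up <- if (factor == 1L) v else
    stats::approx(x = (seq_len(L) - 1L) * factor, y = v,
                  xout = seq_len(L * factor) - 1L, rule = 2)$y
  if (inherits(probe, "probe_series")) {
    probe$upsampled <- up
    probe$factor <- factor
    probe$rate <- rate
    probe
  } else {
    up
  }
}

#' Probe a generator layer for a latent vector
#'
#' Runs the generator on `z`, extracts the post-activation feature maps of
#' the requested convolutional layer (default the second-to-last layer),
#' averages them, and upsamples the result to audio rate.
#'
#' @param G A generator network.
#' @param z Latent vector.
#' @param layer Convolutional layer index (default `n_layers - 1`).
#' @return List with `output` (the generated `waveform`) and `probe` (a
#'   `probe_series` with the upsampled view at the audio rate).
#' @export
probe_generator <- function(G, z, layer = G$cfg$n_layers - 1L) {
  stopifnot(inherits(G, "gan_network"), G$type == "generator")
  stack <- get_feature_maps(G, z, layer)
  probe <- average_feature_maps(stack)
  out <- generate(G, z)
  factor <- length(out$samples) / length(probe$values)
  if (factor != round(factor)) {
    stop("probe_generator: layer length does not divide out_len")
  }
  probe <- upsample_probe(probe, as.integer(factor), rate = out$rate)
  list(output = out, probe = probe)
}

#' Probe a discriminator layer for an input waveform
#'
#' Feeds `w` to the discriminator in evaluation mode (phase shuffle
#' disabled, so the probe is deterministic), extracts the post-activation
#' feature maps of the requested convolutional layer (default the first),
#' averages them, and upsamples to the input rate.
#'
#' @param D A discriminator network.
#' @param w A `waveform` (or numeric vector) of `cfg$out_len` samples.
#' @param layer Convolutional layer index (default 1).
#' @return A `probe_series` with the upsampled view at the input rate.
#' @export
probe_discriminator <- function(D, w, layer = 1L) {
  stopifnot(inherits(D, "gan_network"), D$type == "discriminator")
  rate <- if (inherits(w, "waveform")) w$rate else D$cfg$sample_rate
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  stack <- get_feature_maps(D, x, layer)
  probe <- average_feature_maps(stack)
  factor <- length(x) / length(probe$values)
  if (factor != round(factor)) {
    stop("probe_discriminator: layer length does not divide input length")
  }
  upsample_probe(probe, as.integer(factor), rate = rate)
}

#' Convert a probe series to a two-column trace
#'
#' @param probe A `probe_series` with an upsampled view.
#' @param rate Audio rate (Hz); defaults to the rate recorded on the probe.
#' @return data.frame with columns `time` (s) and `value`.
#' @export
probe_to_trace <- function(probe, rate = probe$rate) {
  stopifnot(inherits(probe, "probe_series"))
  v <- probe$upsampled %||% probe$values
  if (is.na(rate)) stop("probe_to_trace: no rate recorded; pass `rate`")
  data.frame(time = (seq_along(v) - 1) / rate, value = v)
}
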