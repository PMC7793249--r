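#' Clinical map parameters
#'
#' Per-electrode threshold (T) and comfort (C) current levels in clinical
#' units plus the compressive loudness-growth function parameters that
#' convert envelope levels (dB re audibility threshold) to stimulus
#' magnitudes.  Defaults use the classic ACE-family steepness (rho = 416.2)
#' over a 40 dB input dynamic range and flat T/C profiles; clinical fitting
#' would replace these per subject.
#'
#' @param t_levels,c_levels integer vectors (length `num_electrodes`) of
#'   threshold and comfort levels, clinical units 0..255, `t < c`.
#' @param rho loudness-growth steepness (> 0).
#' @param base_level_db input level mapped to magnitude 0 (dB re
#'   audibility threshold).
#' @param saturation_level_db input level mapped to magnitude 1; must
#'   exceed `base_level_db`.
#' @param num_electrodes number of electrodes (22 for the devices modeled).
#' @param flip_electrodes if `FALSE` (default) channel z maps to electrode
#'   `num_electrodes + 1 - z` (low-frequency channel 1 -> apical electrode
#'   22); `TRUE` flips the direction.
#' @return object of class `map_parameters`.
#' @export
map_parameters <- function(t_levels = rep(100L, 22L),
                           c_levels = rep(200L, 22L),
                           rho = 416.2,
                           base_level_db = 0,
                           saturation_level_db = 40,
                           num_electrodes = 22L,
                           flip_electrodes = FALSE) {
  num_electrodes <- as.integer(num_electrodes)
  t_levels <- rep_len(as.integer(t_levels), num_electrodes)
  c_levels <- rep_len(as.integer(c_levels), num_electrodes)
  if (any(t_levels < 0L) || any(c_levels > 255L))
    stop("clinical levels must lie in 0..255")
  if (any(t_levels >= c_levels)) stop("each T level must be below its C level")
  if (rho <= 0) stop("rho must be positive")
  if (saturation_level_db <= base_level_db)
    stop("saturation level must exceed base level")
  structure(list(t_levels = t_levels, c_levels = c_levels, rho = rho,
                 base_level_db = base_level_db,
                 saturation_level_db = saturation_level_db,
                 num_electrodes = num_electrodes,
                 flip_electrodes = isTRUE(flip_electrodes)),
            class = "map_parameters")
}

#' @export
print.map_parameters <- function(x, ...) {
  cat(sprintf("Clinical map: %d electrodes, T %s, C %s CU\n", x$num_electrodes,
              paste(range(x$t_levels), collapse = "-"),
              paste(range(x$c_levels), collapse = "-")))
  cat(sprintf("  loudness growth rho=%g over %g..%g dB%s\n", x$rho,
              x$base_level_db, x$saturation_level_db,
              if (x$flip_electrodes) ", flipped electrode order" else ""))
  invisible(x)
}

#' Compressive loudness-growth function
#'
#' Maps an input level in dB to a stimulus magnitude in \[0, 1\]:
#' 0 at/below the base level, 1 at/above saturation, and
#' `log(1 + rho x) / log(1 + rho)` in between, where x is the base-to-
#' saturation normalized level.
#'
#' @param level_db input level(s), dB re audibility threshold.
#' @param map a [map_parameters()].
#' @return magnitudes in \[0, 1\], same length as `level_db`.
#' @export
loudness_growth <- function(level_db, map) {
  stopifnot(inherits(map, "map_parameters"))
  x <- (level_db - map$base_level_db) /
       (map$saturation_level_db - map$base_level_db)
  x <- pmax(0, pmin(1, x))
  log(1 + map$rho * x) / log(1 + map$rho)
}

#' Magnitude to clinical current level
#'
#' Linear interpolation between the electrode's T and C level, rounded to
#' integer clinical units and clamped to \[T, C\].
#'
#' @param magnitude stimulus magnitude(s) in \[0, 1\].
#' @param electrode electrode index (1..22), recycled against `magnitude`.
#' @param map a [map_parameters()].
#' @return integer clinical units.
#' @export
to_current_level <- function(magnitude, electrode, map) {
  stopifnot(inherits(map, "map_parameters"))
  tl <- map$t_levels[electrode]
  cl <- map$c_levels[electrode]
  as.integer(pmax(tl, pmin(cl, round(tl + magnitude * (cl - tl)))))
}

channel_to_electrode <- function(channel, map) {
  if (map$flip_electrodes) as.integer(channel)
  else map$num_electrodes + 1L - as.integer(channel)
}

#' Convert one frame's selection into timed pulses
#'
#' The k selected channels of a frame become k biphasic-pulse entries
#' evenly spaced across the frame interval (spacing `hop_time / k`),
#' ordered base-to-apex (descending electrode number).  Channel z
#' stimulates electrode `23 - z` by default.  Amplitudes pass through
#' [loudness_growth()] and [to_current_level()].
#'
#' @param selection the `selection` data.frame from [select_channels()].
#' @param frame_time start time of the frame in seconds.
#' @param config a [strategy_config()].
#' @param map a [map_parameters()].
#' @param frame_index integer frame number stored with the pulses.
#' @return data.frame with columns `time_s`, `electrode`, `current_level`,
#'   `frame`, `channel`; zero rows for an empty selection.
#' @export
frame_to_pulses <- function(selection, frame_time, config, map,
                            frame_index = NA_integer_) {
  k <- nrow(selection)
  if (k == 0L)
    return(data.frame(time_s = numeric(0), electrode = integer(0),
                      current_level = integer(0), frame = integer(0),
                      channel = integer(0)))
  if (k > config$num_maxima) stop("selection larger than num_maxima")
  el <- channel_to_electrode(selection$channel, map)
  ord <- order(el, decreasing = TRUE)           # base-to-apex pulse order
  mag <- loudness_growth(selection$level_db, map)
  cu <- to_current_level(mag, el, map)
  spacing <- hop_seconds(config) / k
  data.frame(
    time_s = frame_time + (seq_len(k) - 1L) * spacing,
    electrode = el[ord],
    current_level = cu[ord],
    frame = as.integer(frame_index),
    channel = as.integer(selection$channel[ord])
  )
}

#' Electrodogram container
#'
#' A timed pulse table — the output of the coding strategy.  Rows are
#' biphasic pulses with `time_s`, `electrode` (1 = most basal, 22 = most
#' apical), `current_level` in clinical units, plus `frame` and `channel`
#' bookkeeping columns.  The generating [strategy_config()] and
#' [map_parameters()] travel along as attributes.
#'
#' @param pulses pulse data.frame.
#' @param config,map the configuration snapshot.
#' @param n_frames number of analysis frames encoded.
#' @param n_selected integer vector of per-frame selection counts.
#' @return object of class `electrodogram` (a data.frame).
#' @export
electrodogram <- function(pulses, config, map, n_frames = NA_integer_,
                          n_selected = NULL) {
  if (is.unsorted(pulses$time_s)) stop("pulse times must be non-decreasing")
  structure(pulses, class = c("electrodogram", "data.frame"),
            config = config, map = map, n_frames = as.integer(n_frames),
            n_selected = n_selected)
}

#' @export
print.electrodogram <- function(x, ...) {
  nf <- attr(x, "n_frames")
  cat(sprintf("<electrodogram: %d pulses over %s frames (%.3f s)>\n", nrow(x),
              if (is.na(nf)) "?" else nf,
              if (nrow(x)) max(x$time_s) else 0))
  if (nrow(x)) {
    ppf <- pulses_per_frame(x)
    cat(sprintf("  pulses/frame: max %d, mean %.2f; electrodes %d..%d\n",
                max(ppf), mean(ppf), min(x$electrode), max(x$electrode)))
  }
  invisible(x)
}

#' Per-frame pulse counts of an electrodogram
#'
#' @param e an `electrodogram`.
#' @return integer vector of pulse counts, one per frame that carries at
#'   least one pulse.
#' @export
pulses_per_frame <- function(e) {
  if (nrow(e) == 0L) return(integer(0))
  as.integer(table(e$frame))
}

#' Immediate same-electrode repeat rate
#'
#' Fraction of pulses whose electrode also carried a pulse in the directly
#' preceding frame.  Temporal masking suppresses such immediate repeats, so
#' this rate decreases as the masking half-life grows.
#'
#' @param e an `electrodogram`.
#' @return a proportion in \[0, 1\] (NA for fewer than 2 active frames).
#' @export
repeat_rate <- function(e) {
  if (nrow(e) == 0L) return(NA_real_)
  by_frame <- split(e$electrode, e$frame)
  frames <- as.integer(names(by_frame))
  if (length(frames) < 2L) return(NA_real_)
  rep_ct <- 0L; tot <- 0L
  idx <- stats::setNames(seq_along(frames), frames)
  for (i in seq_along(frames)[-1L]) {
    if (frames[i] - frames[i - 1L] != 1L) next
    cur <- by_frame[[i]]
    tot <- tot + length(cur)
    rep_ct <- rep_ct + sum(cur %in% by_frame[[i - 1L]])
  }
  if (tot == 0L) NA_real_ else rep_ct / tot
}

#' Electrodogram text round trip
#'
#' Plain-text serialization: `# key=value` header lines snapshotting the
#' configuration, then one tab-separated `time_s  electrode  current_level`
#' row per pulse (frame and channel are stored as extra columns so the
#' round trip is lossless).  Byte-identical for identical inputs.
#'
#' @param e an `electrodogram`.
#' @param path file path.
#' @return `read_pulse_table` returns an `electrodogram`;
#'   `write_pulse_table` returns `path` invisibly.
#' @export
write_pulse_table <- function(e, path) {
  cfg <- attr(e, "config")
  hdr <- character(0)
  if (!is.null(cfg)) {
    keys <- setdiff(names(cfg), "hop_samples")
    hdr <- vapply(keys, function(k)
      sprintf("# %s=%s", k, paste(format(cfg[[k]], digits = 17), collapse = ",")),
      character(1))
  }
  nf <- attr(e, "n_frames")
  if (!is.null(nf) && !is.na(nf)) hdr <- c(hdr, sprintf("# n_frames=%d", nf))
  hdr <- c(hdr, "# columns=time_s\telectrode\tcurrent_level\tframe\tchannel")
  rows <- sprintf("%.9f\t%d\t%d\t%d\t%d", e$time_s, e$electrode,
                  e$current_level, e$frame, e$channel)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_pulse_table
#' @export
read_pulse_table <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  meta <- list()
  for (h in hdr) {
    p <- regmatches(h, regexpr("=", h), invert = TRUE)[[1]]
    if (length(p) == 2L) meta[[p[1]]] <- p[2]
  }
  body <- which(!is_hdr & nzchar(trimws(lines)))
  n <- length(body)
  out <- data.frame(time_s = numeric(n), electrode = integer(n),
                    current_level = integer(n), frame = integer(n),
                    channel = integer(n))
  for (i in seq_len(n)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) < 3L || anyNA(v[seq_len(min(3L, length(v)))]))
      stop("malformed pulse-table line ", ln, ": ", lines[ln])
    out$time_s[i] <- v[1]
    out$electrode[i] <- as.integer(v[2])
    out$current_level[i] <- as.integer(v[3])
    out$frame[i] <- if (length(v) >= 4L) as.integer(v[4]) else NA_integer_
    out$channel[i] <- if (length(v) >= 5L) as.integer(v[5]) else NA_integer_
  }
  cfg <- NULL
  cfg_keys <- setdiff(names(meta), c("n_frames", "columns"))
  if (length(cfg_keys)) {
    vals <- lapply(meta[cfg_keys], function(v) {
      num <- suppressWarnings(as.numeric(strsplit(v, ",", fixed = TRUE)[[1]]))
      if (anyNA(num)) v else num
    })
    cfg <- try(do.call(strategy_config, vals), silent = TRUE)
    if (inherits(cfg, "try-error")) cfg <- NULL
  }
  nf <- if (!is.null(meta$n_frames)) as.integer(meta$n_frames) else NA_integer_
  electrodogram(out, config = cfg, map = NULL, n_frames = nf)
}

#' Plot an electrodogram
#'
#' Time-by-electrode raster in the conventional style: each pulse is a
#' vertical line at its time on its electrode's row, with line height
#' proportional to current level within the electrode's T-C range.
#'
#' @param x an `electrodogram`.
#' @param height maximum line height in electrode-row units.
#' @param ... passed to [graphics::plot()].
#' @export
plot.electrodogram <- function(x, height = 0.85, ...) {
  map <- attr(x, "map")
  amp <- if (!is.null(map)) {
    tl <- map$t_levels[x$electrode]; cl <- map$c_levels[x$electrode]
    (x$current_level - tl) / pmax(1L, cl - tl)
  } else {
    x$current_level / 255
  }
  graphics::plot(NA, xlim = range(0, x$time_s), ylim = c(0.5, 22.9),
                 xlab = "time (s)", ylab = "electrode", yaxs = "i", ...)
  graphics::segments(x$time_s, x$electrode, x$time_s,
                     x$electrode + height * pmax(0.05, amp), lwd = 1)
  invisible(x)
}
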