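#' List-mode event data
#'
#' Detection events as a stream of sinogram bin indices; the substrate for
#' bootstrap resampling. Events are stored in randomized order so that any
#' prefix is itself an unbiased subsample.
#'
#' @param events integer matrix with columns (radial, angle, slice), 1-based.
#' @param dims sinogram dims c(n_radial, n_angles, n_slices).
#' @param source_frame frame id string.
#' @param count_level fraction of the full frame this stream represents.
#' @return object of class `listmode`.
#' @export
listmode <- function(events, dims, source_frame = NA_character_,
                     count_level = 1) {
  storage.mode(events) <- "integer"
  dimnames(events) <- NULL
  stopifnot(ncol(events) == 3L, count_level > 0, count_level <= 1)
  structure(
    list(events = events, n_events = nrow(events), dims = as.integer(dims),
         source_frame = source_frame, count_level = count_level),
    class = "listmode"
  )
}

#' @export
print.listmode <- function(x, ...) {
  cat(sprintf("<listmode> %d events (%s, level %.2f), sinogram %s\n",
              x$n_events, x$source_frame, x$count_level,
              paste(x$dims, collapse = "x")))
  invisible(x)
}

events_to_linear <- function(lm) {
  d <- lm$dims
  lm$events[, 1] + d[1] * (lm$events[, 2] - 1L) +
    d[1] * d[2] * (lm$events[, 3] - 1L)
}

#' Bin a list-mode stream into a prompts sinogram
#'
#' @param lm a [listmode()].
#' @return integer-valued [sinogram()] of kind `"prompts"` whose total equals
#'   `lm$n_events`.
#' @export
bin_events <- function(lm) {
  d <- lm$dims
  counts <- tabulate(events_to_linear(lm), nbins = prod(d))
  sinogram(array(as.numeric(counts), d), kind = "prompts")
}

linear_to_events <- function(lin, dims) {
  lin0 <- lin - 1L
  r <- lin0 %% dims[1]
  a <- (lin0 %/% dims[1]) %% dims[2]
  z <- lin0 %/% (dims[1] * dims[2])
  cbind(r + 1L, a + 1L, z + 1L)
}

## Broad Gaussian blur along the radial axis of a sinogram array
## (FWHM in radial bins); used as the scatter shape model.
radial_blur <- function(arr, fwhm_bins) {
  d <- dim(arr)
  s <- fwhm_bins / (2 * sqrt(2 * log(2)))
  r <- ceiling(3 * s)
  k <- exp(-0.5 * ((-r:r) / s)^2)
  k <- k / sum(k)
  K <- matrix(0, d[1], d[1])
  for (off in -r:r) {
    idx <- seq_len(d[1])
    ok <- idx + off >= 1 & idx + off <= d[1]
    K[cbind(idx[ok], (idx + off)[ok])] <- k[off + r + 1]
  }
  out <- K %*% matrix(arr, d[1], d[2] * d[3])
  array(out, d)
}

#' Simulate list-mode prompts
#'
#' Forms the expected prompts sinogram as attenuated trues plus a scatter
#' background (broad radial Gaussian blur of the trues, FWHM 8 radial bins)
#' plus spatially uniform randoms, draws independent Poisson counts per bin,
#' and expands them into a randomized event list.
#'
#' Fractions are of total prompts: with trues total T, the expected prompts
#' total is `T / (1 - scatter_fraction - randoms_fraction)`.
#'
#' @param activity,mu_map [voxel_grid()] inputs on the same grid.
#' @param sys a [system_model()].
#' @param scatter_fraction,randoms_fraction in `[0, 0.5]`.
#' @param seed integer RNG seed; fixed seed gives an identical event list.
#' @return list with elements `listmode` ([listmode()]), `scatter` and
#'   `randoms` (expected-value [sinogram()]s), and `af` (the attenuation
#'   factors used).
#' @export
simulate_prompts <- function(activity, mu_map, sys, scatter_fraction = 0.2,
                             randoms_fraction = 0.1, seed = 1L) {
  stopifnot(scatter_fraction >= 0, scatter_fraction <= 0.5,
            randoms_fraction >= 0, randoms_fraction <= 0.5,
            scatter_fraction + randoms_fraction < 1)
  af <- attenuation_factors(mu_map, sys)
  trues <- forward_project(activity, sys)
  tsino <- trues$values * af$values
  tot <- sum(tsino)
  ptot <- tot / (1 - scatter_fraction - randoms_fraction)
  if (tot > 0 && scatter_fraction > 0) {
    sshape <- radial_blur(tsino, fwhm_bins = 8)
    svals <- sshape / sum(sshape) * (scatter_fraction * ptot)
  } else {
    svals <- array(0, dim(tsino))
  }
  rvals <- array(randoms_fraction * ptot / length(tsino), dim(tsino))
  ybar <- tsino + svals + rvals
  lin <- with_seed(seed, {
    cts <- stats::rpois(length(ybar), as.vector(ybar))
    drawn <- rep.int(seq_along(cts), cts)
    drawn[sample.int(length(drawn))]
  })
  ev <- linear_to_events(lin, dim(ybar))
  list(
    listmode = listmode(ev, dim(ybar),
                        source_frame = attr(activity, "frame_id") %||% NA_character_),
    scatter = sinogram(svals, kind = "scatter"),
    randoms = sinogram(rvals, kind = "randoms"),
    af = af
  )
}

#' Expand an integer prompts sinogram into a list-mode stream
#'
#' Inverse of [bin_events()] up to event order: emits one event per count.
#' With a seed the order is randomized; otherwise events are emitted in bin
#' order.
#'
#' @param sino integer-valued [sinogram()].
#' @param seed optional RNG seed for order randomization.
#' @param source_frame,count_level metadata carried into the result.
#' @return a [listmode()].
#' @export
sinogram_to_listmode <- function(sino, seed = NULL,
                                 source_frame = NA_character_,
                                 count_level = 1) {
  cts <- as.vector(sino$values)
  stopifnot(all(abs(cts - round(cts)) < 1e-9))
  lin <- rep.int(seq_along(cts), round(cts))
  if (!is.null(seed)) lin <- with_seed(seed, lin[sample.int(length(lin))])
  listmode(linear_to_events(lin, dim(sino$values)), dim(sino$values),
           source_frame = source_frame, count_level = count_level)
}

#' Bootstrap-resample a list-mode stream
#'
#' Draws `round(count_level * n_events)` events with replacement from the
#' original stream — the nonparametric bootstrap, emulating an independent
#' acquisition at a reduced count level.
#'
#' @param lm a [listmode()].
#' @param count_level in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return a [listmode()] with the resampled events.
#' @export
bootstrap_listmode <- function(lm, count_level, seed = 1L) {
  stopifnot(count_level > 0, count_level <= 1)
  if (lm$n_events == 0) stop("cannot bootstrap an empty list-mode stream")
  m <- round(count_level * lm$n_events)
  idx <- with_seed(seed, sample.int(lm$n_events, m, replace = TRUE))
  listmode(lm$events[idx, , drop = FALSE], lm$dims,
           source_frame = lm$source_frame, count_level = count_level)
}

#' Persist list-mode data as TSV + JSON sidecar
#'
#' Events go to a three-column tab-separated file (radial, angle, slice);
#' frame id, count level and sinogram dims go to `<path>.json`.
#'
#' @param lm a [listmode()].
#' @param path output TSV path.
#' @return `write_listmode` returns `path` invisibly; `read_listmode`
#'   returns a [listmode()].
#' @export
write_listmode <- function(lm, path) {
  utils::write.table(lm$events, path, sep = "\t", row.names = FALSE,
                     col.names = c("radial", "angle", "slice"), quote = FALSE)
  meta <- list(dims = lm$dims, source_frame = lm$source_frame,
               count_level = lm$count_level, n_events = lm$n_events)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  ev <- unname(as.matrix(utils::read.table(path, sep = "\t", header = TRUE)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  listmode(ev, meta$dims, source_frame = meta$source_frame,
           count_level = meta$count_level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
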