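# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small phantom for fast unit tests
small_phantom <- function() {
  fixture("small_phantom", function() make_phantom(1, c(32, 32, 32), c(2, 2, 2)))
}

small_sys <- function(psf = 0) {
  ph <- small_phantom()
  default_system(ph$labels, psf_fwhm_mm = psf)
}

# noiseless late-negative activity on the small phantom
small_activity <- function() {
  fixture("small_activity", function() {
    ph <- small_phantom()
    make_activity(ph$labels, ph$regions, default_frames()$late_neg,
                  small_sys(0))
  })
}

# a modest simulated list-mode dataset on the small phantom
small_simulation <- function() {
  fixture("small_simulation", function() {
    ph <- small_phantom()
    simulate_prompts(small_activity(), ph$mu_map, small_sys(0),
                     scatter_fraction = 0.2, randoms_fraction = 0.1,
                     seed = 99L)
  })
}

# tiny 16 x 16 x 4 reconstruction problem: warm disc with a hot insert
tiny_recon_problem <- function() {
  fixture("tiny_recon_problem", function() {
    g <- voxel_grid(array(0, c(16, 16, 4)), c(2, 2, 2))
    w <- grid_world_coords(g)
    disc <- (w[, 1]^2 + w[, 2]^2) <= 12^2
    hot <- ((w[, 1] - 4)^2 + w[, 2]^2) <= 4^2
    g$values[] <- disc * 1 + hot * 3
    sys <- system_model(n_angles = 28, n_radial = 24, n_slices = 4,
                        voxel_xy_mm = 2, psf_fwhm_mm = 0)
    prompts <- forward_project(g, sys)
    prompts$values <- round(prompts$values * 5)
    list(truth = g, sys = sys,
         prompts = sinogram(prompts$values, kind = "prompts"))
  })
}

# 6-connected single-component check by flood fill
is_single_blob <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(FALSE)
  visited <- logical(length(mask))
  queue <- idx[1]
  visited[queue] <- TRUE
  n1 <- d[1]; n12 <- d[1] * d[2]
  while (length(queue) > 0) {
    cur <- queue
    queue <- integer(0)
    for (off in c(-1L, 1L, -n1, n1, -n12, n12)) {
      nb <- cur + off
      ok <- nb >= 1 & nb <= length(mask)
      # guard against wrapping across rows/columns
      if (off == -1L) ok <- ok & ((cur - 1L) %% n1 != 0L)
      if (off == 1L) ok <- ok & (cur %% n1 != 0L)
      if (off == -n1) ok <- ok & (((cur - 1L) %/% n1) %% d[2] != 0L)
      if (off == n1) ok <- ok & (((cur - 1L) %/% n1) %% d[2] != d[2] - 1L)
      nb <- nb[ok]
      nb <- nb[mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  sum(visited) == length(idx)
}
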