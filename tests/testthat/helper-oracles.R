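# Independent oracles and small fixture builders. These deliberately use
# naive algorithms (BFS labeling, analytic Gaussian areas) so they share no
# code with the implementation they check.

# Brute-force connected-component labeling by breadth-first search.
bfs_label <- function(binary, connectivity = 8) {
  dims <- dim(binary)
  lab <- matrix(0L, dims[1], dims[2])
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (start in which(binary)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% dims[1]) + 1L
      c <- ((p - 1L) %/% dims[1]) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr >= 1 && rr <= dims[1] && cc >= 1 && cc <= dims[2]) {
          q <- (cc - 1L) * dims[1] + rr
          if (binary[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Raster with filled disks of given centers/radii at a set intensity.
disk_raster <- function(dims, centers, radius, value, background = 0) {
  m <- matrix(background, dims[1], dims[2])
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radius^2)
        m[r, c] <- value
    }
  }
  m
}

mask_of <- function(m) which(m > 0)

make_channel <- function(raster, role = "FLAPS", exposure = 35, bit_max = 4095) {
  channel_image(raster, role, exposure, bit_max)
}

# Minimal detected-object stub for classification tests.
stub_obj <- function(mask, id = 1L, sbr = 2, exposure = 35, saturated = FALSE,
                     dims = c(32, 32), px = 0.1) {
  r <- ((mask - 1L) %% dims[1]) + 1L
  c <- ((mask - 1L) %/% dims[1]) + 1L
  list(object_id = id, channel_role = "FLAPS", exposure_ms = exposure,
       mask = mask, area_um2 = length(mask) * px^2,
       centroid = c(mean(r) - 1, mean(c) - 1), mean_intensity = NA_real_,
       sbr = sbr, saturated = saturated, pixel_size_um = px)
}

# Analytic mass of a Gaussian peak (area A, centre mu, sd s) inside [lo, hi].
gauss_mass <- function(A, mu, s, lo, hi) A * (pnorm(hi, mu, s) - pnorm(lo, mu, s))

quant_stub <- function(frac, cells, timepoint) {
  structure(list(sample_id = "s", timepoint_h = timepoint, n_fov = 1,
                 total_cells = 100, cells_per_L = cells, n_flaps_pos = round(frac * 100),
                 frac_flaps_pos = frac, n_flaps_fish = c(probe = 0),
                 n_cyanobacteria = 0, ci95_frac = c(NA, NA)),
            class = "sample_quant")
}
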