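# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately do NOT share code with the package
# implementation: distances are computed exhaustively over the whole grid.

# Rasterised disk mask: pixel (i, j) in iff (i-cy)^2 + (j-cx)^2 <= r^2.
disk_mask <- function(nr, nc, cy, cx, r) {
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  matrix((ij$i - cy)^2 + (ij$j - cx)^2 <= r^2, nr, nc)
}

# Exhaustive Euclidean-distance compartment oracle. For every pixel the
# squared distance to every pixel of every nucleus (and, for erosion, to
# everything that is not the own nucleus, including virtual out-of-bounds
# pixels) is enumerated. Integer-squared arithmetic, so comparisons are
# exact.
oracle_compartments <- function(labels, erosion_px, ring_distance_px,
                                ring_width_px) {
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  coords <- cbind(i = as.vector(row(labels)), j = as.vector(col(labels)))
  nuc <- matrix(0L, nr, nc)
  ring <- matrix(0L, nr, nc)
  pix_by_id <- lapply(ids, function(id) coords[as.vector(labels) == id, ,
                                               drop = FALSE])
  names(pix_by_id) <- ids
  e2 <- erosion_px^2
  rin2 <- ring_distance_px^2
  rout2 <- (ring_distance_px + ring_width_px)^2
  for (p in seq_len(nr * nc)) {
    i <- coords[p, 1]; j <- coords[p, 2]
    lab <- labels[i, j]
    if (lab > 0L) {
      # min squared distance to any pixel not of this label
      own <- as.vector(labels) == lab
      d2 <- (coords[, 1] - i)^2 + (coords[, 2] - j)^2
      d2_bg <- if (any(!own)) min(d2[!own]) else Inf
      # virtual out-of-bounds background
      d2_edge <- min(i, nr + 1 - i, j, nc + 1 - j)^2
      if (min(d2_bg, d2_edge) > e2) nuc[i, j] <- lab
    } else {
      best_d2 <- Inf; best_id <- 0L
      for (id in ids) {
        q <- pix_by_id[[as.character(id)]]
        d2 <- min((q[, 1] - i)^2 + (q[, 2] - j)^2)
        if (d2 < best_d2) { best_d2 <- d2; best_id <- id }
        # ties go to the lower label: ids iterate in increasing order
      }
      if (best_id > 0L && best_d2 > rin2 && best_d2 <= rout2)
        ring[i, j] <- best_id
    }
  }
  list(nuclear = nuc, ring = ring)
}

# The <=10 hand-built 32x32 label fixtures for the compartment oracle.
compartment_fixtures <- function() {
  mk <- function(mask_list) {
    lab <- matrix(0L, 32, 32)
    for (k in seq_along(mask_list)) lab[mask_list[[k]]] <- k
    lab
  }
  square <- matrix(FALSE, 32, 32); square[10:20, 8:16] <- TRUE
  ell <- matrix(FALSE, 32, 32); ell[5:25, 5:9] <- TRUE; ell[21:25, 5:20] <- TRUE
  border <- disk_mask(32, 32, 3, 16, 5) # touches the top edge
  list(
    disk6_center = mk(list(disk_mask(32, 32, 16, 16, 6))),
    disk2_small = mk(list(disk_mask(32, 32, 16, 16, 2))),
    two_close_disks = mk(list(disk_mask(32, 32, 16, 10, 5),
                              disk_mask(32, 32, 16, 21, 5))),
    square = mk(list(square)),
    ell_shape = mk(list(ell)),
    border_disk = mk(list(border)),
    ellipse = mk(list({
      ij <- expand.grid(i = 1:32, j = 1:32)
      matrix((ij$i - 16)^2 / 64 + (ij$j - 16)^2 / 25 <= 1, 32, 32)
    })),
    three_cells = mk(list(disk_mask(32, 32, 9, 9, 4),
                          disk_mask(32, 32, 9, 23, 4),
                          disk_mask(32, 32, 23, 16, 5))))
}

# Scalar explicit-Euler reference integrator for the delay model, written
# independently of the package's vectorised method-of-steps code.
euler_reference <- function(params, stim_kind = "sustained", onset = 0,
                            duration = NA, amplitude = 1, t_end, dt) {
  nfun <- function(x) 1 / (1 + (x / params$K_i)^params$h)
  f <- function(x) params$k_basal_syn + params$k_syn * nfun(x) -
    params$k_turn * x
  up <- 1
  while (f(up) > 0) up <- up * 2
  xs <- uniroot(f, c(0, up), tol = 1e-13)$root
  nt <- round(t_end / dt)
  x <- numeric(nt + 1); x[1] <- xs
  tgrid <- seq(0, by = dt, length.out = nt + 1)
  sval <- function(tt) {
    on <- switch(stim_kind, none = FALSE, sustained = tt >= onset,
                 pulse = tt >= onset && tt < onset + duration)
    amplitude * as.numeric(on)
  }
  for (k in seq_len(nt)) {
    tt <- tgrid[k]
    td <- tt - params$tau
    xd <- if (td <= 0) xs else {
      i0 <- floor(td / dt); w <- td / dt - i0
      (1 - w) * x[i0 + 1] + w * x[i0 + 2]
    }
    dx <- -(params$k_deg * sval(tt) + params$k_turn) * x[k] +
      params$k_basal_syn + params$k_syn * nfun(xd)
    x[k + 1] <- max(0, x[k] + dt * dx)
  }
  list(t_min = tgrid, x_ikba = x, n_p65 = nfun(x))
}
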