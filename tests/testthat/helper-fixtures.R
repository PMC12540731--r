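# Fixture builders used across the test files. All fixtures are built in
# code; nothing is read from disk.

# A cell with static poles and pair tracks given as per-pair midpoint
# x/y series; sisters are placed at midpoint +/- half_ikd along x.
make_cell <- function(pair_mx, pair_my = NULL,
                      pole_a = c(0, 0), pole_b = c(12, 0),
                      dt = 1, half_ikd = 0.2,
                      t_nebd = 0, t_bip = 0, t_ana = NA_real_,
                      centrioles = c(2L, 2L),
                      cell_id = "cell1", condition = "test") {
  nt <- length(pair_mx[[1]])
  times <- seq(0, by = dt, length.out = nt)
  poles <- dplyr::bind_rows(
    tibble::tibble(pole_id = "P1", centriole_count = centrioles[1],
                   frame_index = seq_len(nt) - 1L, time_min = times,
                   x_um = pole_a[1], y_um = pole_a[2]),
    tibble::tibble(pole_id = "P2", centriole_count = centrioles[2],
                   frame_index = seq_len(nt) - 1L, time_min = times,
                   x_um = pole_b[1], y_um = pole_b[2])
  )
  if (is.null(pair_my)) {
    pair_my <- lapply(pair_mx, function(v) rep(0, length(v)))
  }
  pairs <- dplyr::bind_rows(lapply(seq_along(pair_mx), function(i) {
    tibble::tibble(
      pair_id = sprintf("K%02d", i),
      frame_index = seq_len(nt) - 1L,
      time_min = times,
      x1_um = pair_mx[[i]] - half_ikd, y1_um = pair_my[[i]],
      x2_um = pair_mx[[i]] + half_ikd, y2_um = pair_my[[i]]
    )
  }))
  cell_record(cell_id, condition, poles, pairs,
              t_nebd = t_nebd, t_bipolarization = t_bip,
              t_anaphase_onset = t_ana)
}

# Random rigid 2D transform (rotation + translation, optionally a
# reflection would not preserve orientation, so only proper rotations).
random_rigid <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- stats::rnorm(2, 0, 10)
  function(p) as.numeric(R %*% p + t)
}

# Independent per-frame scan for the alignment event: the oracle against
# which detect_alignment is checked. Works from raw positions.
brute_alignment_scan <- function(ax, ay, bx, by, mx, my, times, thr) {
  for (i in seq_along(times)) {
    ux <- bx[i] - ax[i]; uy <- by[i] - ay[i]
    nl <- sqrt(ux^2 + uy^2)
    cx <- (ax[i] + bx[i]) / 2; cy <- (ay[i] + by[i]) / 2
    dp <- abs((mx[i] - cx) * ux + (my[i] - cy) * uy) / nl
    if (!is.na(dp) && dp <= thr) return(times[i])
  }
  NA_real_
}
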