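# Fixture builders and independent brute-force oracles. Oracles are written
# as plain exhaustive scans/enumerations, independent of the package's
# algorithms.

# volume with a hot sphere (radius in mm, center in mm) on a uniform background
make_sphere_volume <- function(dim = c(15, 15, 15), spacing = c(4.8, 4.8, 4.8),
                               center_mm = dim * spacing / 2, radius_mm = 12,
                               hot = 30, bg = 5, unit = "SUV",
                               modality = "SPECT") {
  vals <- array(bg, dim)
  xc <- (seq_len(dim[1]) - 0.5) * spacing[1]
  yc <- (seq_len(dim[2]) - 0.5) * spacing[2]
  zc <- (seq_len(dim[3]) - 0.5) * spacing[3]
  d2 <- outer(outer((xc - center_mm[1])^2, (yc - center_mm[2])^2, `+`),
              (zc - center_mm[3])^2, `+`)
  vals[d2 <= radius_mm^2] <- hot
  quant_volume(vals, spacing, unit = unit, modality = modality)
}

random_volume <- function(dim = c(12, 12, 12), spacing = c(4, 4, 4),
                          levels = NULL) {
  vals <- if (is.null(levels)) {
    array(runif(prod(dim), 0, 30), dim)
  } else {
    array(sample(levels, prod(dim), replace = TRUE), dim)
  }
  quant_volume(vals, spacing, unit = "SUV")
}

# random connected VOI grown from a random seed by repeated neighbour accretion
random_voi <- function(vol, n_target = 40) {
  d <- dim(vol$values)
  seed <- sapply(d, function(k) sample.int(k, 1))
  sel <- matrix(seed, ncol = 3)
  taken <- array(FALSE, d)
  taken[seed[1], seed[2], seed[3]] <- TRUE
  while (nrow(sel) < n_target) {
    row <- sel[sample.int(nrow(sel), 1), ]
    nb <- row + sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    if (any(nb < 1L) || any(nb > d)) next
    if (taken[nb[1], nb[2], nb[3]]) next
    taken[nb[1], nb[2], nb[3]] <- TRUE
    sel <- rbind(sel, nb)
  }
  lesion_voi(sel, vol$spacing, d)
}

# exhaustive-scan oracle for the peak cube: every cube whose center voxel is
# in the VOI, mean computed by explicit triple loop
oracle_suv_peak <- function(vol, voi) {
  d <- dim(vol$values)
  sp <- vol$spacing
  dims <- pmax(1L, as.integer(floor(10 / sp + 0.5)))
  lo_off <- (dims - 1L) %/% 2L
  hi_off <- dims %/% 2L
  best <- -Inf
  for (r in seq_len(nrow(voi$idx))) {
    ctr <- voi$idx[r, ]
    tot <- 0; cnt <- 0L
    for (i in max(1, ctr[1] - lo_off[1]):min(d[1], ctr[1] + hi_off[1]))
      for (j in max(1, ctr[2] - lo_off[2]):min(d[2], ctr[2] + hi_off[2]))
        for (k in max(1, ctr[3] - lo_off[3]):min(d[3], ctr[3] + hi_off[3])) {
          tot <- tot + vol$values[i, j, k]
          cnt <- cnt + 1L
        }
    best <- max(best, tot / cnt)
  }
  best
}

# flood fill oracle (26-connectivity) by naive repeated sweeps
oracle_component <- function(mask, seed) {
  d <- dim(mask)
  comp <- array(FALSE, d)
  comp[seed[1], seed[2], seed[3]] <- mask[seed[1], seed[2], seed[3]]
  repeat {
    grew <- FALSE
    idx <- which(comp, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        p <- idx[r, ] + c(di, dj, dk)
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && !comp[p[1], p[2], p[3]]) {
          comp[p[1], p[2], p[3]] <- TRUE
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  which(comp)
}

# exhaustive volume-matching oracle: try every unique voxel value as a
# threshold (component computed with the flood-fill oracle), pick the volume
# closest to target, ties toward larger volume
oracle_match_volume <- function(vol, seed, target_cm3) {
  vals <- vol$values
  vox_cm3 <- prod(vol$spacing) / 1000
  seed_val <- vals[seed[1], seed[2], seed[3]]
  cand_thr <- sort(unique(as.vector(vals)))
  cand_thr <- cand_thr[cand_thr < seed_val]
  cand_thr <- c(cand_thr, seed_val * (1 - 1e-12))
  best_n <- NA_integer_; best_err <- Inf; best_comp <- NULL
  for (t in cand_thr) {
    comp <- oracle_component(vals > t, seed)
    err <- abs(length(comp) * vox_cm3 - target_cm3)
    # <= : later candidates (higher thresholds) give smaller volumes, so
    # keep the FIRST (largest-volume) among ties -> iterate ascending thr
    if (err < best_err - 1e-12) {
      best_err <- err; best_n <- length(comp); best_comp <- comp
    }
  }
  list(n = best_n, err = best_err, lin = sort(best_comp))
}

# full 2^n enumeration of the Wilcoxon signed-rank null (no ties)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
  min(1, p)
}

# full C(m+n, m) enumeration of the Mann-Whitney null (no ties)
oracle_mann_whitney_p <- function(a, b, alternative = "two.sided") {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  u_of <- function(sel) {
    aa <- pool[sel]; bb <- pool[-sel]
    sum(outer(aa, bb, `>`)) + 0.5 * sum(outer(aa, bb, `==`))
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, u_of)
  if (alternative == "greater") {
    mean(u_all >= u_obs - 1e-9)
  } else {
    mu <- m * n / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  }
}

expect_suvpair_error <- function(expr, class) {
  expect_error(expr, class = class)
}
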