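# Internal helpers: structured conditions and 3-D grid arithmetic.

abort_suvpair <- function(message, class, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "suvpair_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

warn_suvpair <- function(message, class) {
  warning(structure(
    class = c(class, "suvpair_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_suvpair(sprintf("`%s` must be a finite numeric scalar", name),
                  "suvpair_invalid_argument")
  }
  if (positive && x <= 0) {
    abort_suvpair(sprintf("`%s` must be > 0", name), "suvpair_invalid_argument")
  }
  if (nonneg && x < 0) {
    abort_suvpair(sprintf("`%s` must be >= 0", name), "suvpair_invalid_argument")
  }
  invisible(x)
}

# 26-connected neighbourhood offsets, one row per neighbour.
.offsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# (i,j,k) matrix -> linear index for array of dimension `dim` (all 1-based)
ijk_to_lin <- function(ijk, dim) {
  as.integer((ijk[, 1L] - 1L) + (ijk[, 2L] - 1L) * dim[1L] +
               (ijk[, 3L] - 1L) * dim[1L] * dim[2L] + 1L)
}

lin_to_ijk <- function(lin, dim) {
  lin0 <- lin - 1L
  i <- lin0 %% dim[1L]
  j <- (lin0 %/% dim[1L]) %% dim[2L]
  k <- lin0 %/% (dim[1L] * dim[2L])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

in_bounds <- function(ijk, dim) {
  ijk[, 1L] >= 1L & ijk[, 1L] <= dim[1L] &
    ijk[, 2L] >= 1L & ijk[, 2L] <= dim[2L] &
    ijk[, 3L] >= 1L & ijk[, 3L] <= dim[3L]
}

# All in-bounds 26-neighbours of the voxels in `ijk` (n x 3), as linear indices
# (may contain duplicates; callers dedupe as needed).
neighbours26_lin <- function(ijk, dim) {
  n <- nrow(ijk)
  if (n == 0L) return(integer(0))
  rep_ijk <- ijk[rep(seq_len(n), each = 26L), , drop = FALSE]
  off <- .offsets26[rep(seq_len(26L), times = n), , drop = FALSE]
  cand <- rep_ijk + off
  cand <- cand[in_bounds(cand, dim), , drop = FALSE]
  ijk_to_lin(cand, dim)
}

# Connected component (26-connectivity) of `seed_lin` within logical `mask`
# (a vector of length prod(dim)). Returns sorted linear indices.
connected_component <- function(mask, seed_lin, dim) {
  visited <- logical(length(mask))
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier) > 0L) {
    nb <- unique(neighbours26_lin(lin_to_ijk(frontier, dim), dim))
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  sort(which(visited))
}
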