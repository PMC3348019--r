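#' Derive a reproducible integer seed from a master seed and labels
#'
#' Expands one master seed into named substreams so that stages and tasks
#' draw from independent, order-insensitive random streams. The derivation
#' is a plain polynomial rolling hash over the label characters, reduced
#' modulo a prime below 2^31 so the result is always a valid R seed.
#'
#' @param master Integer master seed.
#' @param ... Character labels naming the substream (e.g. stage, task id).
#' @return A single integer in `[0, 2147483586]`.
#' @export
#' @examples
#' derive_seed(0, "tracking", "hippocampus->thalamus:left")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  p <- 2147483587 # prime < 2^31
  h <- as.numeric(master) %% p
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 131 + code) %% p
    }
  }
  as.integer(h)
}

# Wrap a value with a counted warning; `n` silently ignored when zero.
warn_count <- function(n, what) {
  if (n > 0L) {
    warning(sprintf("%d %s", n, what), call. = FALSE)
  }
  invisible(n)
}

# Row-normalise a numeric matrix to unit length; zero rows left untouched.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

# 0-based voxel triples (n x 3) -> 1-based linear index into an nx*ny*nz array
voxel_linear <- function(vox, dim) {
  as.integer(vox[, 1] + dim[1] * (vox[, 2] + dim[2] * vox[, 3]) + 1)
}

in_grid <- function(vox, dim) {
  vox[, 1] >= 0 & vox[, 1] < dim[1] &
    vox[, 2] >= 0 & vox[, 2] < dim[2] &
    vox[, 3] >= 0 & vox[, 3] < dim[3]
}
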