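# Independent oracles used across tests. These deliberately share no code
# with the package internals: the thresholder oracle evaluates the Gaussian
# closed form and the local mean by direct per-pixel summation.

# direct evaluation of the kernel closed form
oracle_gaussian_kernel <- function(z) {
  sigma <- 0.3 * ((z - 1) / 2 - 1) + 0.8
  half <- (z - 1) / 2
  w <- matrix(0, z, z)
  for (i in 1:z) for (j in 1:z) {
    x <- i - half - 1; y <- j - half - 1
    w[i, j] <- exp(-(x^2 + y^2) / (2 * sigma^2))
  }
  w / sum(w)
}

# per-pixel direct 2D summation of the Gaussian-weighted local mean with
# replicate-edge padding: for every pixel the full z x z window is extracted
# from the padded image and multiplied by the kernel. No separability, no
# shared code with the package implementation.
oracle_threshold_field <- function(values, z, offset = 0) {
  w <- oracle_gaussian_kernel(z)
  half <- (z - 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  ridx <- pmin(pmax(seq(1 - half, nr + half), 1), nr)
  cidx <- pmin(pmax(seq(1 - half, nc + half), 1), nc)
  padded <- values[ridx, cidx]
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    out[r, cc] <- sum(w * padded[r:(r + z - 1), cc:(cc + z - 1)])
  }
  out - offset
}

oracle_binarize <- function(values, z, offset = 0) {
  t_field <- oracle_threshold_field(values, z, offset)
  ifelse(values > t_field, 255, 0)
}

# brute-force flood fill, 8-connectivity: returns number of components
oracle_n_components_8 <- function(m) {
  seen <- matrix(FALSE, nrow(m), ncol(m))
  n <- 0
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    if (!m[r, cc] || seen[r, cc]) next
    n <- n + 1
    queue <- list(c(r, cc)); seen[r, cc] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; c2 <- p[2] + dc
        if (rr >= 1 && rr <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
            m[rr, c2] && !seen[rr, c2]) {
          seen[rr, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, c2)
        }
      }
    }
  }
  n
}

# small disc mask helper
disc_mask <- function(nr, nc, cr, cc, radius) {
  m <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c2 in 1:nc) {
    if ((r - cr)^2 + (c2 - cc)^2 <= radius^2) m[r, c2] <- TRUE
  }
  m
}

# analysis configuration used for synthetic scenes throughout the tests:
# threshold offset at -2x the generator's noise SD (see the methods
# vignette), explicit gate between the two score modes
scene_config <- function(...) {
  pipeline_config(offset = -6, gate_threshold = 10, ...)
}
scene_gate <- 10
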