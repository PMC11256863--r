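# Shared fixtures, built in code. The canonical specimen is deterministic
# (zero jitter/noise, canonical pose) and cached for the whole run.

canonical_specimen <- generate_specimen(labyrinth_params(), seed = 101L)

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# brute-force total-least-squares oracle: scatter matrix assembled by
# explicit outer-product accumulation, smallest-eigenvalue direction
oracle_tls_normal <- function(points) {
  ctr <- colMeans(points)
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(points))) {
    d <- points[i, ] - ctr
    S <- S + d %o% d
  }
  e <- eigen(S, symmetric = TRUE)
  e$vectors[, which.min(e$values)]
}

angle_between_dirs <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}

rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# the published spatial-attitude table used as frozen expected values
published_attitude <- data.frame(
  label = c("LPC_CA", "LHC_CA", "LAC_CA", "LPC_MEM", "LPC_BONY",
            "LHC_MEM", "LHC_BONY", "LAC_MEM", "LAC_BONY"),
  sagittal = c(138.33, 13.52, 57.56, 51.47, 49.06, 91.03, 90.28, 138.82,
               140.50),
  coronal = c(96.18, 96.04, 94.82, 134.56, 132.14, 70.72, 70.70, 126.33,
              124.35),
  horizontal = c(131.01, 102.05, 147.11, 110.24, 110.32, 160.68, 160.70,
                 106.70, 107.07))
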