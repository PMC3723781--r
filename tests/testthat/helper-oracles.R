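# Independent oracles used to cross-check the package's primitives. These
# deliberately share no code with the implementation paths they verify.

# Superposition RMSD via the quaternion characteristic-polynomial route
# (Horn's method): build the 4x4 key matrix from the covariance of the
# centered point sets and take its largest eigenvalue.
quaternion_rmsd_oracle <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  m <- nrow(x)
  S <- t(x) %*% y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lambda_max) / m
  sqrt(max(msd, 0))
}

# Textbook two-pass Pearson correlation.
pearson_oracle <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Four-point dihedral (degrees) from first principles, independent of the
# compiled measurement code.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Replay a sequence of same-length insertions through a reference
# interval-overwrite simulator: per residue, remember which (start, frag)
# insertion wrote it last; a window retains provenance only if all of its
# residues were last written by that same insertion event.
provenance_replay_oracle <- function(n_res, len, insertions) {
  owner <- rep(NA_integer_, n_res) # index into insertions
  for (k in seq_along(insertions)) {
    ins <- insertions[[k]]
    owner[ins$start:(ins$start + len - 1L)] <- k
  }
  prov <- list()
  for (k in seq_along(insertions)) {
    ins <- insertions[[k]]
    rows <- ins$start:(ins$start + len - 1L)
    if (all(owner[rows] == k))
      prov[[as.character(ins$start)]] <- ins$frag
  }
  prov
}

# Circular absolute difference between angle vectors in degrees.
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
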