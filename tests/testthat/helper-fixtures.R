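## Two-pool Solomon system with effective auto-rate rho = R1 + sigma and
## cross-rate sigma, no exchange.
solomonSystem <- function(R1 = 1, sigma = -0.05) {
  spinSystem(list(spinPool("A", "labile", R1 = R1),
                  spinPool("B", "nonlabile", R1 = R1)),
             sigma = data.frame(a = "A", b = "B", value = sigma))
}

## brute-force forward-Euler integrator for dM/dt = A M + b
eulerPropagate <- function(A, b, M0, t, dt = 1e-5) {
  M <- M0
  nsteps <- round(t / dt)
  for (i in seq_len(nsteps)) M <- M + dt * (A %*% M + b)
  as.numeric(M)
}

## quaternion-eigenvalue superposition RMSD (independent of the SVD route)
quaternionRmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)  # Sxy = sum over atoms of B_x * A_y
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Ac^2) + sum(Bc^2) - 2 * lmax)) / nrow(A))
}
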