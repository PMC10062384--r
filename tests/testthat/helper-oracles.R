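# Independent brute-force oracle for the layered correlation diffusion
# model: per transverse frequency s, solve the 1-D modified-Helmholtz
# two-point boundary problem with a flux-conservative finite-volume scheme
# (non-uniform grid so that the exact extrapolated boundary -zb, the
# surface, the source depth and both interfaces all fall on nodes;
# harmonic-mean D at half nodes; delta source at the z0 node; Dirichlet
# phi(-zb) = 0; discrete-exact radiation closure at the deep end), then
# invert the Hankel transform on the package's quadrature nodes. Entirely
# independent of the package's analytic layered recursion.

oracle_three_layer_g1 <- function(rho, tau, stack, wavelength_nm = 850,
                                  s_max = 250, n_panels = 80, nodes = 10,
                                  h = 5e-4, z_deep_extra = 2.0) {
  musp <- vapply(stack$props, `[[`, 0, "musp")
  mua <- vapply(stack$props, `[[`, 0, "mua")
  D <- 1 / (3 * musp)
  n_rel <- stack$props[[1]]$n
  k0 <- 2 * pi * n_rel / (wavelength_nm * 1e-7)
  z0 <- 1.5 / musp[1]  # package source-depth convention
  zb <- dcslayers:::extrapolation_length(musp[1], n_rel)
  quad <- dcslayers:::hankel_quadrature(s_max, n_panels, nodes)

  # two uniform sections joined at the surface: [-zb, 0] with its own
  # spacing (so -zb is exact) and [0, zmax] with spacing h
  z1 <- stack$L1
  z2 <- stack$L1 + stack$L2
  zmax <- z2 + z_deep_extra
  nA <- max(4L, as.integer(round(zb / h)))
  zA <- seq(-zb, 0, length.out = nA + 1L)
  zB <- seq(h, zmax, by = h)
  z <- c(zA, zB)
  n_nodes <- length(z)
  stopifnot(abs(z[nA + 1]) < 1e-12)
  i_src <- nA + 1L + as.integer(round(z0 / h))
  stopifnot(abs(z[i_src] - z0) < 1e-9)
  surf <- nA + 1L

  dz <- diff(z)                                   # length n_nodes - 1
  zmid <- (z[-n_nodes] + z[-1]) / 2               # interval midpoints
  lay_cell <- ifelse(zmid < z1, 1L, ifelse(zmid < z2, 2L, 3L))
  lay_cell[zmid < 0] <- 1L
  D_cell <- D[lay_cell]
  a_half <- D_cell / dz                           # conductances (cells are
                                                  # uniform, interfaces on
                                                  # nodes)

  tau_all <- c(0, tau)
  G_of_tau <- numeric(length(tau_all))
  J0w <- besselJ(quad$s * rho, 0) * quad$s * quad$w
  ns <- length(quad$s)
  mid <- 2:(n_nodes - 1)

  for (it in seq_along(tau_all)) {
    t1 <- tau_all[it]
    mt <- mua + 2 * musp * k0^2 * stack$bfi * t1  # mua + dynamic absorption
    # dual-cell reaction integral: half of each adjacent interval with that
    # interval's material (exact at interface nodes)
    react_D <- (dz[mid - 1] * D_cell[mid - 1] + dz[mid] * D_cell[mid]) / 2
    react_mt <- (dz[mid - 1] * mt[lay_cell[mid - 1]] +
                 dz[mid] * mt[lay_cell[mid]]) / 2
    # interior rows i = 2..n-1 (phi[1] = 0 eliminates the first column):
    # a_half[i-1] phi[i-1] - (a_half[i-1] + a_half[i] + integral of
    #   (D s^2 + mt) over the dual cell) phi[i] + a_half[i] phi[i+1] = -src[i]
    lower <- matrix(rep(a_half[mid - 1], ns), n_nodes - 2, ns)
    upper <- matrix(rep(a_half[mid], ns), n_nodes - 2, ns)
    diagm <- -(lower + upper + (outer(react_D, quad$s^2) + react_mt))
    rhs <- matrix(0, n_nodes - 2, ns)
    rhs[i_src - 1, ] <- -1   # delta source (scale cancels in normalization)
    # deep closure: in the uniform terminal medium the discrete solution
    # decays per cell by the root < 1 of r^2 - (2 + xi) r + 1 = 0 with
    # xi = h^2 alpha3^2; exact for the discrete operator
    xi <- h^2 * (quad$s^2 + mt[3] / D[3])
    half <- 1 + xi / 2
    r_d <- half - sqrt(half * half - 1)
    diagm[n_nodes - 2, ] <- diagm[n_nodes - 2, ] + upper[n_nodes - 2, ] * r_d
    # Thomas sweep, vectorized across the ns systems
    cp <- matrix(0, n_nodes - 2, ns)
    dp <- matrix(0, n_nodes - 2, ns)
    cp[1, ] <- upper[1, ] / diagm[1, ]
    dp[1, ] <- rhs[1, ] / diagm[1, ]
    for (i in 2:(n_nodes - 2)) {
      denom <- diagm[i, ] - lower[i, ] * cp[i - 1, ]
      cp[i, ] <- upper[i, ] / denom
      dp[i, ] <- (rhs[i, ] - lower[i, ] * dp[i - 1, ]) / denom
    }
    phi_im1 <- phi_i0 <- phi_ip1 <- NULL
    phi_i <- dp[n_nodes - 2, ]
    for (i in (n_nodes - 3):1) {
      phi_i <- dp[i, ] - cp[i, ] * phi_i
      if (i == surf) phi_ip1 <- phi_i        # node surf + 1 (z = h)
      if (i == surf - 1) phi_i0 <- phi_i     # node surf (z = 0)
      if (i == surf - 2) phi_im1 <- phi_i    # node surf - 1 (z = -hA)
    }
    # detected quantity: c_phi * phi + c_j * D * dphi/dz, with the surface
    # derivative from the second-order non-uniform central difference
    hL <- z[surf] - z[surf - 1]
    hR <- z[surf + 1] - z[surf]
    dphi <- (hL^2 * phi_ip1 - hR^2 * phi_im1 + (hR^2 - hL^2) * phi_i0) /
      (hL * hR * (hL + hR))
    cfb <- dcslayers:::boundary_coefficients(n_rel)
    detq <- cfb["c_phi"] * phi_i0 + cfb["c_j"] * D[1] * dphi
    G_of_tau[it] <- sum(detq * J0w)
  }
  G_of_tau[-1] / G_of_tau[1]
}
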