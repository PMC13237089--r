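# 1D radial finite volumes over [R_inner, R_t]: wall shell meshed explicitly
# with diffusivity D_w on [R_c, R_w] (the interface R_w falls exactly on a
# cell face, with harmonic-mean face diffusivity), tissue with D_t and a
# Michaelis-Menten sink beyond; inner Dirichlet (or Robin), outer no-flux.
# Dense Picard solve, independent of the package's solvers.
radial_two_layer <- function(R_c, R_w, R_t, D_w, D_t, c0, tissue,
                             robin = FALSE, Pi_w = NULL) {
  t_w <- R_w - R_c
  hr <- t_w / 20
  R0 <- if (robin) R_w else R_c
  n <- round((R_t - R0) / hr)
  rf <- R0 + (0:n) * hr               # faces; R_w is a face in walled mode
  rc <- R0 + (seq_len(n) - 0.5) * hr  # centers
  Dcell <- ifelse(rc < R_w, D_w, D_t)
  Dface <- c(Dcell[1],
             2 / (1 / Dcell[-n] + 1 / Dcell[-1]),  # harmonic mean
             Dcell[n])
  Tf <- Dface * rf / hr               # face conductance (per radian)
  Tf[1] <- if (robin) {
    1 / (1 / (Pi_w * R_w) + (hr / 2) / (Dcell[1] * rf[1]))
  } else {
    Dcell[1] * rf[1] / (hr / 2)       # Dirichlet half-cell
  }
  Tf[n + 1] <- 0                      # outer no-flux
  q <- q_of(tissue)
  Vr <- (rf[-1]^2 - rf[-(n + 1)]^2) / 2
  cvec <- rep(c0, n)
  for (it in 1:300) {
    sink <- ifelse(rc >= R_w, q * Vr / (tissue$k_m + pmax(cvec, 0)), 0)
    A <- matrix(0, n, n)
    b <- rep(0, n)
    for (i in seq_len(n)) {
      A[i, i] <- Tf[i] + Tf[i + 1] + sink[i]
      if (i > 1) A[i, i - 1] <- -Tf[i]
      if (i < n) A[i, i + 1] <- -Tf[i + 1]
    }
    b[1] <- Tf[1] * c0
    cnew <- solve(A, b)
    if (max(abs(cnew - cvec)) < 1e-13) break
    cvec <- cnew
  }
  list(r = rc, c = cvec)
}

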