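# Independent fixed-step Euler integrators, written directly from the rate
# laws (not via the package's RHS functions), used as brute-force oracles
# for the adaptive-solver simulations.

euler_invitro <- function(phe0, cells_per_ml, ph, t_end, dt = 0.001,
                          km = 0.0184, vmax = 0.0162) {
  kiph <- min(max(0.25 * ph - 0.7, 0), 1)
  phe <- phe0; tca <- 0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    kitca <- 0.67 * exp(-0.53 * tca) + 0.33
    v <- if (phe > 0) vmax / (1 + km / phe) * (cells_per_ml / 1e9) * kiph * kitca else 0
    phe <- phe - v * dt
    tca <- tca + v * dt
  }
  c(phe = phe, tca = tca)
}

euler_gi <- function(dose_cfu, phe_st0, t_end, dt = 0.01,
                     gp = gut_params("human"), km = 0.0184, vmax = 0.0162) {
  y <- c(cells_st = dose_cfu, cells_si = 0, phe_st = phe_st0, tca_st = 0,
         phe_si = gp$phe_si0, tca_si = 0, phe_abs = 0, tca_abs = 0)
  kiph <- function(ph) min(max(0.25 * ph - 0.7, 0), 1)
  kitca <- function(tca) 0.67 * exp(-0.53 * tca) + 0.33
  flux <- function(phe, tca, cells, vol, ph) {
    if (phe <= 0) return(0)
    conc <- phe / vol
    vmax / (1 + km / conc) * (cells / 1e9) * kiph(ph) * kitca(tca / vol)
  }
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    f <- 2^(-(t / gp$t_half)^gp$beta)
    k <- if (t == 0) 0 else log(2) * gp$beta / gp$t_half * (t / gp$t_half)^(gp$beta - 1)
    vst <- gp$vol_st + gp$dose_vehicle_ml * f
    ph_st <- (gp$ph0 - gp$ph_min) * exp(-gp$k_ph * t) + gp$ph_min
    fst <- flux(y[["phe_st"]], y[["tca_st"]], y[["cells_st"]], vst, ph_st)
    fsi <- flux(y[["phe_si"]], y[["tca_si"]], y[["cells_si"]], gp$vol_si, gp$ph_si)
    dy <- c(
      -k * y[["cells_st"]], k * y[["cells_st"]],
      -fst - k * y[["phe_st"]], fst - k * y[["tca_st"]],
      -fsi + k * y[["phe_st"]] - gp$lam * y[["phe_si"]],
      fsi + k * y[["tca_st"]] - gp$lam * y[["tca_si"]],
      gp$lam * y[["phe_si"]], gp$lam * y[["tca_si"]]
    )
    y <- y + dy * dt
  }
  y
}
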