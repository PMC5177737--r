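# Independent ODE oracle (adaptive integrator) for the infusion models,
# and random positive parameter draws per compartment count.

ode_conc <- function(ncpt, p, regimen, times, baseline = 0, resid = 0) {
  V1 <- p[2]
  K <- matrix(0, ncpt, ncpt)
  K[1, 1] <- -p[1] / V1
  if (ncpt >= 2) {
    Q <- p[3]; Vp <- p[4]
    K[1, 1] <- K[1, 1] - Q / V1; K[2, 1] <- Q / V1
    K[1, 2] <- Q / Vp; K[2, 2] <- -Q / Vp
  }
  if (ncpt == 3) {
    Q3 <- p[5]; V3 <- p[6]
    K[1, 1] <- K[1, 1] - Q3 / V1; K[3, 1] <- Q3 / V1
    K[1, 3] <- Q3 / V3; K[3, 3] <- -Q3 / V3
  }
  rate_at <- function(t) {
    r <- 0
    for (d in seq_len(nrow(regimen)))
      if (t > regimen$start_h[d] &&
          t <= regimen$start_h[d] + regimen$duration_h[d])
        r <- r + regimen$amount_iu[d] / regimen$duration_h[d]
    r
  }
  rhs <- function(t, y, parms) {
    dy <- as.numeric(K %*% y)
    dy[1] <- dy[1] + rate_at(t)
    list(dy)
  }
  y0 <- c(resid * V1, rep(0, ncpt - 1))
  evt <- sort(unique(c(0, times, regimen$start_h,
                       regimen$start_h + regimen$duration_h)))
  o <- deSolve::ode(y0, evt, rhs, NULL, rtol = 1e-11, atol = 1e-9,
                    method = "lsoda")
  baseline + o[match(times, evt), 2] / V1
}

rand_params <- function(ncpt) {
  switch(ncpt,
    c(CL = runif(1, 0.05, 0.5), V = runif(1, 1, 6)),
    c(CL = runif(1, 0.05, 0.5), V1 = runif(1, 1, 5),
      Q = runif(1, 0.05, 1), V2 = runif(1, 0.5, 8)),
    c(CL = runif(1, 0.05, 0.5), V1 = runif(1, 1, 5),
      Q2 = runif(1, 0.05, 1), V2 = runif(1, 0.5, 8),
      Q3 = runif(1, 0.02, 0.5), V3 = runif(1, 1, 10)))
}
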