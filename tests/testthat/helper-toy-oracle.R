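# Independent oracle for the toy parameter set: explicit scalar arithmetic
# over the nine strata, written without any package engine code, with every
# constant hard-coded from the toy configuration. Order of strata:
# 1 NS, 2 S, 3 C, 4 SC, 5 NS+i, 6 S+i, 7 C+i, 8 SC+i, 9 dead.
#
# Worksheet (cycle structure identical to the full model):
#   cycle t: [screen] -> fracture overlay + utility + continuing CVD cost on
#   start-of-cycle occupancy -> 9x9 transition -> initial CVD cost on the
#   cycle's CVD inflow. Discount (1.03)^-t on every component.
toy_oracle <- function(sens = NA, spec = NA, unit_cost = NA, interval = NA,
                       two_step = FALSE, n_cycles = 3) {
  prev <- 0.12; inc <- 0.04; rec <- 0.16
  rr_fall <- 1.89; rr_cvdfall <- 2.17; pfrac0 <- 0.26
  rr_cvd <- 1.33; rr_death <- 2.00; rr_fx <- 1.71
  int_inc <- 0.45; int_rec <- 3.61; poss <- 0.40; bg <- 0.09
  c_int <- 1119.05; c_fx <- 3599.05; c_cvd0 <- 4149.29; c_cvd1 <- 1904.77
  c_hg <- 1.31; c_gait <- 0.71; c_dxa <- 42.86
  u <- c(0.76, 0.68, 0.75, 0.56)
  ufx <- c(0.57, 0.51, 0.75 * 0.57 / 0.76, 0.42)
  dr <- 0.03
  # toy schedules: (cvd_inc, cvd_prev, cvd_mort, fall_inc, fall_prev, fall_mort)
  sched <- function(age) {
    if (age <= 61) c(0.05, 0.20, 0.02, 0.10, 0.10, 0.001)
    else c(0.10, 0.20, 0.04, 0.20, 0.20, 0.004)
  }

  occ <- c(1 - prev, prev, 0, 0, 0, 0, 0, 0, 0)
  cost <- 0; qaly <- 0; ly <- 0
  for (t in seq_len(n_cycles) - 1L) {
    d <- 1 / (1 + dr)^t
    age <- 60 + t
    s <- sched(age)

    # the intervention episode from the previous cycle expires
    occ[1:4] <- occ[1:4] + occ[5:8]; occ[5:8] <- 0
    if (!is.na(interval) && t %% interval == 0) {
      screened <- sum(occ[1:4])
      sarc <- occ[2] + occ[4]
      if (two_step) {
        cost <- cost + d * (screened * (c_hg + c_gait) +
                              (sarc + (screened - sarc) * poss) * c_dxa)
      } else {
        cost <- cost + d * screened * unit_cost
      }
      pos <- c(1 - spec, sens, 1 - spec, sens)
      moved <- occ[1:4] * pos
      cost <- cost + d * c_int * sum(moved)
      occ[5:8] <- moved; occ[1:4] <- occ[1:4] - moved
    }

    # per-health-state event quantities (flag does not matter for events)
    pfall <- c(s[4], s[4] * rr_fall, s[4] * rr_cvdfall, s[4] * rr_fall * rr_cvdfall)
    pfx <- pfall * c(pfrac0, pfrac0 * rr_fx, pfrac0, pfrac0 * rr_fx)
    fall_fat <- s[6] / s[5]
    cvd_fat <- s[3] / s[2]
    pdie <- 1 - (1 - c(bg, bg * rr_death, bg, bg * rr_death)) *
      (1 - c(0, 0, cvd_fat, cvd_fat)) * (1 - pfall * fall_fat)
    pcvd <- c(s[1], s[1] * rr_cvd, 0, 0)

    fx_flow <- occ[1:8] * pfx[c(1:4, 1:4)]
    cost <- cost + d * c_fx * sum(fx_flow)
    qaly <- qaly + d * (sum((occ[1:8] - fx_flow) * u[c(1:4, 1:4)]) +
                          sum(fx_flow * ufx[c(1:4, 1:4)]))
    ly <- ly + 1 - occ[9]
    cost <- cost + d * c_cvd1 * sum(occ[c(3, 4, 7, 8)])

    # transition, flag-block by flag-block
    new <- numeric(9)
    for (b in c(0L, 4L)) {
      i2 <- if (b == 0L) inc else inc * int_inc
      r2 <- if (b == 0L) rec else min(rec * int_rec, 1)
      ns <- occ[1 + b]; sa <- occ[2 + b]; cv <- occ[3 + b]; sc <- occ[4 + b]
      new[1 + b] <- new[1 + b] + ns * (1 - pdie[1]) * (1 - i2 * (1 - pcvd[1]) - pcvd[1] * (1 - i2)) +
        sa * (1 - pdie[2]) * r2 * (1 - pcvd[2])
      new[2 + b] <- new[2 + b] + ns * (1 - pdie[1]) * i2 * (1 - pcvd[1]) +
        sa * (1 - pdie[2]) * (1 - r2 * (1 - pcvd[2]) - pcvd[2] * (1 - r2))
      new[3 + b] <- new[3 + b] + ns * (1 - pdie[1]) * pcvd[1] * (1 - i2) +
        cv * (1 - pdie[3]) * (1 - i2) + sc * (1 - pdie[4]) * r2
      new[4 + b] <- new[4 + b] + sa * (1 - pdie[2]) * pcvd[2] * (1 - r2) +
        cv * (1 - pdie[3]) * i2 + sc * (1 - pdie[4]) * (1 - r2)
      new[9] <- new[9] + ns * pdie[1] + sa * pdie[2] + cv * pdie[3] + sc * pdie[4]
    }
    new[9] <- new[9] + occ[9]
    # CVD inflow: from NS (either flag) to C, from S to SC
    inflow <- 0
    for (b in c(0L, 4L)) {
      i2 <- if (b == 0L) inc else inc * int_inc
      r2 <- if (b == 0L) rec else min(rec * int_rec, 1)
      inflow <- inflow + occ[1 + b] * (1 - pdie[1]) * pcvd[1] * (1 - i2) +
        occ[2 + b] * (1 - pdie[2]) * pcvd[2] * (1 - r2)
    }
    cost <- cost + d * c_cvd0 * inflow
    occ <- new
  }
  list(cost = cost, qaly = qaly, life_years = ly)
}
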