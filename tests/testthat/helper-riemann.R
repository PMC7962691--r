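# Exact Riemann solver for the 1D Euler equations (ideal gas), used as an
# independent oracle for the finite-volume kernel. Classic two-shock /
# two-rarefaction pressure iteration with exact sampling of the fan.
exact_riemann <- function(rhoL, uL, pL, rhoR, uR, pR, gamma = 1.4) {
  g <- gamma
  aL <- sqrt(g * pL / rhoL)
  aR <- sqrt(g * pR / rhoR)
  fK <- function(p, rhoK, pK, aK) {
    if (p > pK) {  # shock
      AK <- 2 / ((g + 1) * rhoK)
      BK <- (g - 1) / (g + 1) * pK
      (p - pK) * sqrt(AK / (p + BK))
    } else {       # rarefaction
      2 * aK / (g - 1) * ((p / pK)^((g - 1) / (2 * g)) - 1)
    }
  }
  f <- function(p) fK(p, rhoL, pL, aL) + fK(p, rhoR, pR, aR) + (uR - uL)
  p_star <- stats::uniroot(f, c(1e-8 * min(pL, pR), 10 * max(pL, pR)),
                           tol = 1e-14)$root
  u_star <- 0.5 * (uL + uR) +
    0.5 * (fK(p_star, rhoR, pR, aR) - fK(p_star, rhoL, pL, aL))

  sample_xi <- function(xi) {  # xi = x / t
    if (xi <= u_star) {  # left of contact
      if (p_star > pL) {  # left shock
        SL <- uL - aL * sqrt((g + 1) / (2 * g) * p_star / pL +
                               (g - 1) / (2 * g))
        if (xi <= SL) return(c(rhoL, uL, pL))
        rho <- rhoL * ((p_star / pL + (g - 1) / (g + 1)) /
                         ((g - 1) / (g + 1) * p_star / pL + 1))
        return(c(rho, u_star, p_star))
      } else {            # left rarefaction
        SHL <- uL - aL
        a_star <- aL * (p_star / pL)^((g - 1) / (2 * g))
        STL <- u_star - a_star
        if (xi <= SHL) return(c(rhoL, uL, pL))
        if (xi >= STL) {
          rho <- rhoL * (p_star / pL)^(1 / g)
          return(c(rho, u_star, p_star))
        }
        u <- 2 / (g + 1) * (aL + (g - 1) / 2 * uL + xi)
        a <- 2 / (g + 1) * (aL + (g - 1) / 2 * (uL - xi))
        rho <- rhoL * (a / aL)^(2 / (g - 1))
        p <- pL * (a / aL)^(2 * g / (g - 1))
        return(c(rho, u, p))
      }
    } else {             # right of contact
      if (p_star > pR) {  # right shock
        SR <- uR + aR * sqrt((g + 1) / (2 * g) * p_star / pR +
                               (g - 1) / (2 * g))
        if (xi >= SR) return(c(rhoR, uR, pR))
        rho <- rhoR * ((p_star / pR + (g - 1) / (g + 1)) /
                         ((g - 1) / (g + 1) * p_star / pR + 1))
        return(c(rho, u_star, p_star))
      } else {            # right rarefaction
        SHR <- uR + aR
        a_star <- aR * (p_star / pR)^((g - 1) / (2 * g))
        STR <- u_star + a_star
        if (xi >= SHR) return(c(rhoR, uR, pR))
        if (xi <= STR) {
          rho <- rhoR * (p_star / pR)^(1 / g)
          return(c(rho, u_star, p_star))
        }
        u <- 2 / (g + 1) * (-aR + (g - 1) / 2 * uR + xi)
        a <- 2 / (g + 1) * (aR - (g - 1) / 2 * (uR - xi))
        rho <- rhoR * (a / aR)^(2 / (g - 1))
        p <- pR * (a / aR)^(2 * g / (g - 1))
        return(c(rho, u, p))
      }
    }
  }
  function(x, t, x0 = 0) {
    out <- t(vapply(x, function(xx) sample_xi((xx - x0) / t), numeric(3)))
    data.frame(rho = out[, 1], u = out[, 2], p = out[, 3])
  }
}
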