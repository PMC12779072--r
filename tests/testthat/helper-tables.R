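# Shared fixture builders: small synthetic tables with closed forms.

# Pure power-law cross-section table: total = alpha * E^-beta per element,
# compton = fraction * total. Log-log interpolation is exact on these.
make_powerlaw_xs <- function(elements = data.frame(
                               element = c("H", "C", "N", "O"),
                               Z = c(1L, 6L, 7L, 8L),
                               alpha = c(0.12, 0.15, 0.16, 0.17),
                               beta = c(0.30, 0.35, 0.36, 0.37),
                               fraction = c(0.95, 0.85, 0.80, 0.75)
                             ),
                             energies = exp(seq(log(0.05), log(10), length.out = 8))) {
  out <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    total <- e$alpha * energies^(-e$beta)
    data.frame(element = e$element, Z = e$Z, energy_MeV = energies,
               total_mu_rho_cm2_g = total,
               compton_mu_rho_cm2_g = e$fraction * total)
  }))
  attr(out, "coef") <- elements
  tibble::as_tibble(out)
}

# G-P table linear in log Z at each energy, with known surface.
make_linear_gp <- function(Zs = c(4L, 6L, 8L, 13L),
                           energies = c(0.1, 1, 10),
                           kind = "EBF") {
  surf <- list(
    b = list(p0 = c(1.2, 1.4, 1.3), p1 = c(0.10, 0.05, 0.08)),
    c = list(p0 = c(0.9, 0.8, 0.7), p1 = c(-0.02, 0.01, 0.02)),
    a = list(p0 = c(0.05, 0.0, -0.05), p1 = c(0.01, -0.01, 0.0)),
    Xk = list(p0 = c(14, 12, 10), p1 = c(0.5, 0.2, -0.2)),
    d = list(p0 = c(-0.02, 0.01, 0.03), p1 = c(0.005, -0.005, 0.0))
  )
  gp <- do.call(rbind, lapply(Zs, function(z) {
    do.call(rbind, lapply(seq_along(energies), function(j) {
      data.frame(kind = kind, Z = z, energy_MeV = energies[j],
                 b = surf$b$p0[j] + surf$b$p1[j] * log(z),
                 c = surf$c$p0[j] + surf$c$p1[j] * log(z),
                 a = surf$a$p0[j] + surf$a$p1[j] * log(z),
                 Xk = surf$Xk$p0[j] + surf$Xk$p1[j] * log(z),
                 d = surf$d$p0[j] + surf$d$p1[j] * log(z))
    }))
  }))
  attr(gp, "surface") <- surf
  tibble::as_tibble(gp)
}

# Monotone-in-Z elemental ratio table for Zeq tests.
make_ratios <- function(Zs = 4:10, R0 = 0.99, step = 0.97) {
  tibble::tibble(Z = Zs, R = R0 * step^(seq_along(Zs) - 1))
}
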