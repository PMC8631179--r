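# Independent oracles, written directly from the defining formulas with
# plain loops; deliberately kept apart from the package's vectorised code.

RT_310 <- 1.9872e-3 * 310

# naive per-path rates: R[s,t] = -k A[t,s] e^{-(Gt-Gs)/RT} Cs
#   + sum_s' Lf[s,t] k A[t,s'] e^{-(Gt-Gs')/RT} (nu_s'/nu_s) Cs'
naive_path_rates <- function(net, cs, k_scale = 1) {
  ns <- length(net$states); nt <- length(net$transitions)
  rt <- net$gas_constant * net$temperature
  sid <- vapply(net$states, `[[`, "", "id")
  gs <- vapply(net$states, `[[`, 0, "g_monomer")
  nu <- vapply(net$states, function(s) s$nu, 0L)
  R <- matrix(0, ns, nt, dimnames = list(sid, vapply(net$transitions, `[[`, "", "id")))
  for (j in seq_len(nt)) {
    tr <- net$transitions[[j]]
    a <- setNames(rep(0, ns), sid)
    a[names(tr$links)] <- tr$links
    lf <- a / sum(a)
    for (s in seq_len(ns)) {
      if (a[s] == 0) next
      out <- -k_scale * a[s] * exp(-(tr$g_monomer - gs[s]) / rt) * cs[s]
      inn <- 0
      for (sp in seq_len(ns))
        inn <- inn + lf[s] * k_scale * a[sp] *
          exp(-(tr$g_monomer - gs[sp]) / rt) * (nu[sp] / nu[s]) * cs[sp]
      R[s, j] <- out + inn
    }
  }
  R
}

# naive state rates: plain row sums of the naive path rates
naive_state_rates <- function(net, cs, k_scale = 1)
  rowSums(naive_path_rates(net, cs, k_scale))

# reference ODE integration of dC/dt = A C with tight tolerances
ode_evolve <- function(A, c_init, times) {
  sol <- deSolve::lsoda(y = c_init, times = times,
                        func = function(t, y, p) list(as.numeric(A %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  unname(sol[, -1, drop = FALSE])
}

# delta-method standard error of the Jarzynski estimator
jarzynski_se <- function(works, kt) {
  x <- exp(-(works - min(works)) / kt)
  kt * stats::sd(x) / (sqrt(length(works)) * mean(x))
}

# equilibrium-flux scale of a network (largest one-way path flux), used to
# express stationarity residuals relatively
flux_scale <- function(net) max(equilibrium_flux(net))

# write a minimal multi-model PDB text file; coords is a list of N x 3
# matrices (one per model)
write_multimodel_pdb <- function(path, coords, elety = NULL, resno = NULL) {
  n <- nrow(coords[[1]])
  elety <- elety %||% rep("CA", n)
  resno <- resno %||% seq_len(n)
  lines <- character(0)
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, elety[i], resno[i],
        coords[[m]][i, 1], coords[[m]][i, 2], coords[[m]][i, 3]))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
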