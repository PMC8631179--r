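make_net <- function(a = c(S1 = 1, S2 = 1, S3 = 1), gt = 1,
                     g_tot = c(-6, -8, -3), nu = c(2, 2, 1)) {
  self_assembly_network(
    lapply(1:3, function(i) stable_state(paste0("S", i), nu[i], g_tot[i])),
    list(transition_state("T1", gt, a)))
}

test_that("linking fractions follow the frequency-factor ratios", {
  # all A equal over 3 links -> uniform 1/3
  expect_equal(unname(linking_fractions(make_net())[, 1]), rep(1 / 3, 3))
  # single link -> 1
  net1 <- make_net(a = c(S2 = 5))
  expect_equal(unname(linking_fractions(net1)["S2", 1]), 1)
  # A = (2, 1, 1) -> (0.5, 0.25, 0.25)
  net2 <- make_net(a = c(S1 = 2, S2 = 1, S3 = 1))
  expect_equal(unname(linking_fractions(net2)[, 1]), c(0.5, 0.25, 0.25))
})

test_that("linking-fraction columns sum to one on random networks", {
  for (seed in 1:25) {
    net <- random_network(sample(1:6, 1), sample(1:4, 1),
                          a_range = c(0.2, 3), seed = seed)
    lf <- linking_fractions(net)
    expect_equal(colSums(lf), setNames(rep(1, ncol(lf)), colnames(lf)),
                 tolerance = 1e-12)
    # zero exactly where unlinked
    for (j in seq_along(net$transitions))
      expect_identical(unname(lf[, j] == 0),
                       !rownames(lf) %in% names(net$transitions[[j]]$links))
  }
})

test_that("equilibrium distribution follows Boltzmann weights over the accessible set", {
  # equal per-monomer energies -> equal probabilities
  net <- make_net(g_tot = c(-8, -8, -4), nu = c(2, 2, 1))
  eq <- equilibrium_distribution(net)
  expect_equal(unname(eq$p), rep(1 / 3, 3))
  # two-state restriction: frozen oracle from direct evaluation of the
  # Boltzmann ratio with G1 = -23.63/2, G2 = -31.15/2, RT = 0.616032
  eq2 <- equilibrium_distribution(pdl1_network(), accessible = c("S1", "S2"))
  expect_equal(unname(eq2$p[["S2"]]), 0.9977701287, tolerance = 1e-9)
  expect_equal(eq2$p[["S2"]] / eq2$p[["S1"]], 447.4563696, tolerance = 1e-8)
  expect_equal(sum(eq2$p), 1)
  expect_equal(unname(eq2$c[["S3"]]), 0)
  # single accessible state -> P = 1, C = C0/nu
  eq1 <- equilibrium_distribution(net, accessible = "S3")
  expect_equal(unname(eq1$p[["S3"]]), 1)
  expect_equal(unname(eq1$c[["S3"]]), net$c0 / 1)
  expect_error(equilibrium_distribution(net, character(0)), "empty")
})

test_that("overflow-prone energies still give normalized probabilities", {
  net <- self_assembly_network(
    list(stable_state("S1", 1, -900), stable_state("S2", 1, -890)),
    list(transition_state("T1", 0, c(S1 = 1, S2 = 1))))
  eq <- equilibrium_distribution(net)
  expect_true(all(is.finite(eq$p)))
  expect_equal(sum(eq$p), 1)
})

test_that("path rates vanish at the equilibrium distribution", {
  for (seed in 1:30) {
    net <- random_network(sample(2:6, 1), sample(1:4, 1),
                          a_range = c(0.5, 2), seed = seed + 100)
    eq <- equilibrium_distribution(net)
    rt <- path_rates(net, eq)
    expect_lt(max(abs(rt$path_rates)) / flux_scale(net), 1e-10)
  }
})

test_that("zero concentrations give zero rates and negative ones error", {
  net <- make_net()
  rt <- path_rates(net, rep(0, 3))
  expect_true(all(rt$path_rates == 0))
  expect_error(path_rates(net, c(-1, 1, 1)), "negative concentration")
})

test_that("path and state rates match the loop-written oracle", {
  for (seed in 1:10) {
    net <- random_network(4, 3, a_range = c(0.3, 2.5),
                          g_state_range = c(-8, 0), seed = seed + 40)
    cs <- stats::runif(4)
    rt <- path_rates(net, cs, k_scale = 1.7)
    expect_equal(rt$path_rates, naive_path_rates(net, cs, 1.7),
                 tolerance = 1e-12)
    expect_equal(state_rates(rt),
                 naive_state_rates(net, cs, 1.7), tolerance = 1e-12)
    expect_equal(state_rates(rt), rowSums(rt$path_rates))
  }
})

test_that("one-way equilibrium flux depends only on the transition energy", {
  # two states with different energies feeding the same transition, equal A:
  # monomer-form fluxes are equal
  net <- make_net(g_tot = c(-10, -2, -6), nu = c(1, 1, 1))
  fl <- equilibrium_flux(net, monomer_form = TRUE)
  expect_equal(fl["S1", 1], fl["S2", 1])
  expect_equal(fl["S2", 1], fl["S3", 1])
  # cluster form divides by nu
  net2 <- make_net(g_tot = c(-10, -2, -6), nu = c(2, 1, 1))
  fl2 <- equilibrium_flux(net2)
  expect_equal(fl2["S1", 1] * 2, fl2["S2", 1])
  # raising the barrier drives the flux to zero
  hi <- make_net(gt = 500)
  expect_equal(max(equilibrium_flux(hi)), 0, tolerance = 1e-300)
  # flux ratio between two transitions is the Boltzmann factor of their gap
  net3 <- self_assembly_network(
    list(stable_state("S1", 1, -3), stable_state("S2", 1, -5)),
    list(transition_state("T1", 1.0, c(S1 = 1, S2 = 1)),
         transition_state("T2", 2.5, c(S1 = 1, S2 = 1))))
  fl3 <- equilibrium_flux(net3, monomer_form = TRUE)
  rt <- net3$gas_constant * net3$temperature
  expect_equal(fl3["S1", "T2"] / fl3["S1", "T1"], exp(-(2.5 - 1.0) / rt))
})

test_that("kinetic matrix reproduces the state rates and conserves monomers", {
  for (seed in 1:15) {
    net <- random_network(sample(2:6, 1), sample(1:3, 1),
                          a_range = c(0.5, 2), g_state_range = c(-8, 0),
                          seed = seed + 7)
    ks <- gitr_kinetics(net)
    nu <- vapply(net$states, function(s) as.numeric(s$nu), 0)
    expect_lt(max(abs(nu %*% ks$A)), 1e-12 * max(abs(ks$A)))
    cs <- stats::runif(length(nu))
    expect_equal(as.numeric(ks$A %*% cs), unname(naive_state_rates(net, cs)),
                 tolerance = 1e-10)
    # stationary at equilibrium
    eq <- equilibrium_distribution(net)
    expect_lt(max(abs(ks$A %*% eq$c)) / flux_scale(net), 1e-10)
  }
})

test_that("a self-looped single state has a null kinetic matrix", {
  net <- self_assembly_network(list(stable_state("S1", 1, 0)),
                               list(transition_state("T1", 2, c(S1 = 1))))
  ks <- gitr_kinetics(net)
  expect_equal(unname(ks$A), matrix(0, 1, 1), tolerance = 1e-15)
})

test_that("evolution from equilibrium is constant and conserves monomers", {
  net <- pdl1_network()
  ks <- gitr_kinetics(net)
  eq <- equilibrium_distribution(net)
  relax <- summary(ks)$slowest_relaxation_time
  times <- seq(0, 5 * relax, length.out = 7)
  tr <- evolve(ks, eq, times)
  expect_equal(unclass(tr)[1, ], eq$c)
  for (i in seq_along(times))
    expect_equal(unclass(tr)[i, ], eq$c, tolerance = 1e-9)
  # monomer conservation from an arbitrary start
  c0 <- c(S1 = 0.3, S2 = 0.05, S3 = 0.02)
  tr2 <- evolve(ks, c0, times)
  nu <- c(2, 2, 2)
  total <- unclass(tr2) %*% nu
  expect_equal(as.numeric(total), rep(sum(nu * c0), length(times)),
               tolerance = 1e-8)
})

test_that("eigen-solution evolution matches stiff ODE integration", {
  for (seed in 1:8) {
    net <- random_network(sample(2:6, 1), sample(1:3, 1),
                          g_state_range = c(-4, 0),
                          g_transition_range = c(0, 1.5),
                          a_range = c(0.5, 2), seed = seed + 300)
    ks <- gitr_kinetics(net)
    ns <- nrow(ks$A)
    c_init <- stats::runif(ns)
    relax <- summary(ks)$slowest_relaxation_time
    tmax <- if (is.finite(relax)) 3 * relax else 1
    times <- seq(0, tmax, length.out = 9)
    got <- unclass(evolve(ks, c_init, times))
    ref <- ode_evolve(ks$A, c_init, times)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("ill-conditioned eigenbases fall back to the matrix exponential", {
  net <- pdl1_network()
  ks <- gitr_kinetics(net)
  ks$diagonalizable <- FALSE     # force the fallback path
  c0 <- c(S1 = 0.2, S2 = 0.1, S3 = 0)
  times <- c(0, 1e10, 1e11)
  a <- evolve(gitr_kinetics(net), c0, times)
  b <- evolve(ks, c0, times)
  expect_equal(attr(b, "method"), "expm")
  expect_equal(unclass(a), unclass(b), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("evolve validates its inputs", {
  ks <- gitr_kinetics(pdl1_network())
  expect_error(evolve(ks, c(1, 1, 0), c(-1, 0)), "negative time")
  expect_error(evolve(ks, c(1, 1), c(0, 1)), "concentration per state")
})

test_that("long-time evolution converges to the all-state equilibrium", {
  net <- pdl1_network()
  ks <- gitr_kinetics(net)
  pre <- equilibrium_distribution(net, accessible = c("S1", "S2"))
  eq <- equilibrium_distribution(net)
  relax <- summary(ks)$slowest_relaxation_time
  times <- c(0, 10^(seq(log10(relax / 10), log10(50 * relax), length.out = 8)))
  tr <- unclass(evolve(ks, pre, times))
  expect_equal(tr[nrow(tr), ], eq$c, tolerance = 1e-6)
  # the drug-bound state fills monotonically, the apo states drain
  expect_true(all(diff(tr[, "S3"]) >= -1e-12))
  expect_true(all(diff(tr[, "S2"]) <= 1e-12))
  expect_true(all(diff(tr[, "S1"]) <= 1e-12))
})

test_that("dominant-path ranking orders by |rate| with joint ties", {
  # symmetric two-path network -> joint dominance
  net <- self_assembly_network(
    list(stable_state("S1", 1, -3), stable_state("S2", 1, -3)),
    list(transition_state("T1", 1, c(S1 = 1, S2 = 1)),
         transition_state("T2", 1, c(S1 = 1, S2 = 1))))
  dp <- dominant_path(net, c(S1 = 1, S2 = 0))
  expect_equal(dp$rank[1:2], c(1L, 1L))
  # at a stationary point the ranking is empty with a diagnostic
  expect_message(dp0 <- dominant_path(net, equilibrium_distribution(net)),
                 "stationary")
  expect_equal(nrow(dp0), 0)
  # raising the barrier of the dominant transition flips the ranking
  pre <- equilibrium_distribution(pdl1_network(), accessible = c("S1", "S2"))
  base <- dominant_path(pdl1_network(), pre)
  expect_equal(base$transition[1], "T2")
  raised <- pdl1_network()
  raised$transitions[[2]]$g_monomer <- 6   # push T2 far above T1
  dp2 <- dominant_path(raised, equilibrium_distribution(raised,
                                                        accessible = c("S1", "S2")))
  expect_equal(dp2$transition[1], "T1")
})
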