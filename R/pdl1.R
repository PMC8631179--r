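# Packaged PD-L1 five-state network and the random-network generator used
# by the property-based tests.

#' The PD-L1 dimerization-mode network
#'
#' Builds the five-state network describing the dimerization modes of the
#' immune-checkpoint protein PD-L1 with the small-molecule inhibitor
#' BMS-202:
#' \itemize{
#'   \item S1: apo dimer with the 4Z18-type interface, nu = 2,
#'     G_total = -23.63 kcal/mol;
#'   \item S2: apo dimer with the drug-site interface (IS^PP), nu = 2,
#'     G_total = -31.15 kcal/mol;
#'   \item S3: holo (drug-bound, 5J89-type) dimer, nu = 2,
#'     G_total = -43.97 kcal/mol, a *derived* composite: the drug adds
#'     -12.82 kcal/mol of stabilization to S2 (-31.15 - 12.82);
#'   \item T1: three-body-separation transition state at the free-monomer
#'     zero (G_total = 0), linked to S1, S2 and S3;
#'   \item T2: drug-insertion transition state, G_total = -10.87 kcal/mol
#'     (itself composed as -31.15 + 20.28, the geometric insertion
#'     barrier), linked to S2 and S3 only.
#' }
#' The drug does not count towards nu (protein monomers only). With all
#' frequency factors equal the linking-fraction columns are
#' (1/3, 1/3, 1/3) and (0, 1/2, 1/2). Transition-state cluster energies
#' are converted to per-monomer values by dividing by nu = 2 by default;
#' `convention = "per_cluster"` instead uses the cluster value unchanged
#' as the per-monomer energy (both conventions give the same dominant
#' path).
#'
#' @param temperature Temperature, K.
#' @param c0 Total analytical monomer concentration.
#' @param convention `"per_monomer"` (default) or `"per_cluster"` handling
#'   of the transition-state energies.
#' @return A `self_assembly_network`.
#' @export
pdl1_network <- function(temperature = 310, c0 = 1,
                         convention = c("per_monomer", "per_cluster")) {
  convention <- match.arg(convention)
  div <- if (convention == "per_monomer") 2 else 1
  self_assembly_network(
    states = list(
      stable_state("S1", 2, -23.63),
      stable_state("S2", 2, -31.15),
      stable_state("S3", 2, compose_transition_energy(-31.15, -12.82))),
    transitions = list(
      transition_state("T1", 0 / div, c(S1 = 1, S2 = 1, S3 = 1)),
      transition_state("T2", compose_transition_energy(-31.15, 20.28) / div,
                       c(S2 = 1, S3 = 1))),
    temperature = temperature, c0 = c0)
}

#' Walk through the PD-L1 rate analysis
#'
#' Reproduces the pre-drug kinetic analysis on the packaged network:
#' before drug addition the holo state S3 cannot form, so S1 and S2 sit at
#' the two-state equilibrium (`C3 = 0`, Z over S1 and S2 only); the three
#' transformation paths out of the apo states (S1 via T1, S2 via T1, S2
#' via T2) are then compared and ranked by rate magnitude. With the
#' packaged energies the drug-insertion path S2 -> T2 (-> S3) dominates,
#' under either transition-energy convention.
#'
#' @param c0 Total monomer concentration (> 0; rates are linear in it).
#' @param temperature Temperature, K.
#' @param convention Passed to [pdl1_network()].
#' @param quiet Suppress the printed walkthrough.
#' @return Invisibly, a list with the network, the equilibrium
#'   concentrations, the three path rates, the full [dominant_path()]
#'   ranking, and `dominant` (the outflow path with the largest |rate|).
#' @export
reproduce_application <- function(c0 = 1, temperature = 310,
                                  convention = "per_monomer",
                                  quiet = FALSE) {
  if (c0 <= 0) stop("c0 must be positive")
  net <- pdl1_network(temperature = temperature, c0 = c0,
                      convention = convention)
  say <- function(...) if (!quiet) cat(sprintf(...))
  eq <- equilibrium_distribution(net, accessible = c("S1", "S2"))
  say("Pre-drug equilibrium over {S1, S2} (C3 = 0):\n")
  say("  P(S1) = %.4f   P(S2) = %.4f\n", eq$p[["S1"]], eq$p[["S2"]])
  say("  C1 = %.4g   C2 = %.4g (per cluster, C0 = %g)\n",
      eq$c[["S1"]], eq$c[["S2"]], c0)
  rt <- path_rates(net, eq)
  out <- c(R1t1 = rt$path_rates["S1", "T1"],
           R2t1 = rt$path_rates["S2", "T1"],
           R2t2 = rt$path_rates["S2", "T2"])
  say("Transformation path rates (reduced units, minus = outflow):\n")
  say("  R(S1,T1) = %.4g\n  R(S2,T1) = %.4g\n  R(S2,T2) = %.4g\n",
      out[1], out[2], out[3])
  dom <- names(out)[which.max(abs(out))]
  say("Dominant outflow path: %s (drug insertion, S2 -> T2 -> S3)\n", dom)
  ranking <- dominant_path(net, eq)
  invisible(list(network = net, equilibrium = eq, path_rates = out,
                 ranking = ranking, dominant = dom))
}

#' Random self-assembly network generator
#'
#' Draws a connected bipartite network for property-based testing:
#' cluster sizes nu uniform in 1..4, state cluster energies uniform in
#' `g_state_range`, transition per-monomer energies uniform in
#' `g_transition_range`, frequency factors uniform in `a_range`.
#' Connectivity is guaranteed by first threading a spanning chain through
#' all states and transitions, then adding random extra links.
#'
#' @param n_states,n_transitions Positive counts.
#' @param g_state_range Range of total (cluster) state energies, kcal/mol.
#' @param g_transition_range Range of per-monomer transition energies,
#'   kcal/mol.
#' @param a_range Range of frequency factors (componentwise > 0).
#' @param extra_link_prob Probability of each optional extra link.
#' @param temperature,c0 Network conditions.
#' @param seed Optional RNG seed (reproducible networks).
#' @return A validated `self_assembly_network`.
#' @export
random_network <- function(n_states, n_transitions,
                           g_state_range = c(-20, 0),
                           g_transition_range = c(0, 3),
                           a_range = c(1, 1), extra_link_prob = 0.3,
                           temperature = 310, c0 = 1, seed = NULL) {
  if (n_states < 1 || n_transitions < 1)
    stop("need at least one state and one transition")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    }
    set.seed(seed)
  }
  sid <- paste0("S", seq_len(n_states))
  tid <- paste0("T", seq_len(n_transitions))
  states <- lapply(seq_len(n_states), function(i)
    stable_state(sid[i], sample(1:4, 1),
                 stats::runif(1, g_state_range[1], g_state_range[2])))
  # spanning chain: alternate states and transitions so the bipartite
  # graph is connected even when counts differ
  links <- vector("list", n_transitions)
  for (j in seq_len(n_transitions)) {
    base <- ((j - 1) %% n_states) + 1L
    nxt <- (j %% n_states) + 1L
    links[[j]] <- unique(c(base, nxt))
  }
  # every state must appear somewhere; attach leftovers to random transitions
  covered <- unique(unlist(links))
  for (i in setdiff(seq_len(n_states), covered)) {
    j <- sample(n_transitions, 1)
    links[[j]] <- c(links[[j]], i)
  }
  transitions <- lapply(seq_len(n_transitions), function(j) {
    lk <- links[[j]]
    extra <- setdiff(seq_len(n_states), lk)
    if (length(extra))
      lk <- c(lk, extra[stats::runif(length(extra)) < extra_link_prob])
    a <- stats::runif(length(lk), a_range[1], a_range[2])
    transition_state(tid[j],
                     stats::runif(1, g_transition_range[1], g_transition_range[2]),
                     setNames(a, sid[lk]))
  })
  self_assembly_network(states, transitions, temperature = temperature,
                        c0 = c0)
}
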