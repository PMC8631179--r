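# MM-PBSA free-energy bookkeeping.
#
# Single-trajectory convention: the internal-energy terms (bond, angle,
# torsion) cancel in binding deltas, so they are optional and excluded
# from binding arithmetic by default. Values are stored at full precision;
# rounding happens only at presentation.

#' Bundle MM-PBSA energy components
#'
#' @param e_vdw van der Waals energy, kcal/mol.
#' @param e_ele Electrostatic energy, kcal/mol.
#' @param g_pb Polar solvation free energy (Poisson-Boltzmann), kcal/mol.
#' @param g_sa Nonpolar solvation free energy (surface area), kcal/mol.
#' @param t_delta_s Conformational entropy term T*dS, kcal/mol.
#' @param sd Optional named numeric vector of standard deviations for any
#'   of the five components (all must be >= 0).
#' @param e_bond,e_angle,e_torsion Optional internal-energy terms.
#' @return Object of class `"energy_components"`.
#' @export
energy_components <- function(e_vdw, e_ele, g_pb, g_sa, t_delta_s,
                              sd = NULL, e_bond = NULL, e_angle = NULL,
                              e_torsion = NULL) {
  need <- c(e_vdw = e_vdw, e_ele = e_ele, g_pb = g_pb, g_sa = g_sa,
            t_delta_s = t_delta_s)
  for (k in names(need))
    if (!is.numeric(need[[k]]) || !is.finite(need[[k]]))
      stop("missing or non-finite component: ", k)
  if (!is.null(sd) && any(sd < 0)) stop("standard deviations must be >= 0")
  structure(list(e_vdw = e_vdw, e_ele = e_ele, g_pb = g_pb, g_sa = g_sa,
                 t_delta_s = t_delta_s, sd = sd, e_bond = e_bond,
                 e_angle = e_angle, e_torsion = e_torsion),
            class = "energy_components")
}

#' Recombine MM-PBSA components into a binding summary
#'
#' Applies the standard identities: polar term `e_ele + g_pb`, nonpolar
#' term `e_vdw + g_sa`, `g_mmpbsa = e_polar + e_nonpolar`, and
#' `g_bind = g_mmpbsa - t_delta_s`. If component standard deviations were
#' supplied, those of the derived rows propagate in quadrature
#' (presentation only; independence assumed).
#'
#' @param c An [energy_components()] object (or arguments to build one).
#' @return Object of class `"binding_summary"` with fields `e_polar`,
#'   `e_nonpolar`, `g_mmpbsa`, `g_bind` and the inputs.
#' @examples
#' # apo PD-L1 dimer (4Z18-type interface)
#' combine_mmpbsa(energy_components(-113.96, -456.16, 487.86, -14.65, -73.28))
#' @export
combine_mmpbsa <- function(c) {
  if (!inherits(c, "energy_components")) stop("need an 'energy_components' object")
  e_polar <- c$e_ele + c$g_pb
  e_nonpolar <- c$e_vdw + c$g_sa
  g_mmpbsa <- e_polar + e_nonpolar
  g_bind <- g_mmpbsa - c$t_delta_s
  sd <- NULL
  if (!is.null(c$sd)) {
    q <- function(...) sqrt(sum(c(...)^2))
    s <- function(k) if (k %in% names(c$sd)) c$sd[[k]] else 0
    sd <- c(e_polar = q(s("e_ele"), s("g_pb")),
            e_nonpolar = q(s("e_vdw"), s("g_sa")),
            g_mmpbsa = q(s("e_ele"), s("g_pb"), s("e_vdw"), s("g_sa")),
            g_bind = q(s("e_ele"), s("g_pb"), s("e_vdw"), s("g_sa"),
                       s("t_delta_s")))
  }
  structure(list(e_polar = e_polar, e_nonpolar = e_nonpolar,
                 g_mmpbsa = g_mmpbsa, g_bind = g_bind,
                 components = c, sd = sd),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  rows <- c(e_vdw = x$components$e_vdw, e_ele = x$components$e_ele,
            g_pb = x$components$g_pb, g_sa = x$components$g_sa,
            e_polar = x$e_polar, e_nonpolar = x$e_nonpolar,
            g_mmpbsa = x$g_mmpbsa, t_delta_s = x$components$t_delta_s,
            g_bind = x$g_bind)
  cat("MM-PBSA binding summary (kcal/mol):\n")
  for (k in names(rows)) cat(sprintf("  %-10s %9.2f\n", k, rows[[k]]))
  invisible(x)
}

#' Recover the raw components from a binding summary
#'
#' Exact inverse of [combine_mmpbsa()] on the stored (unrounded) values.
#'
#' @param s A `"binding_summary"`.
#' @return The original [energy_components()] object.
#' @export
decompose_mmpbsa <- function(s) {
  stopifnot(inherits(s, "binding_summary"))
  s$components
}

#' Binding free energy from a precombined MM-PBSA total
#'
#' `g_bind = g_mmpbsa - t_delta_s`. Useful when only the combined total is
#' reported (e.g. copied from a published table) rather than raw components.
#'
#' @param g_mmpbsa Combined MM-PBSA energy, kcal/mol.
#' @param t_delta_s Entropy term T*dS, kcal/mol.
#' @return Binding free energy, kcal/mol.
#' @export
binding_free_energy <- function(g_mmpbsa, t_delta_s) g_mmpbsa - t_delta_s

#' Nonpolar solvation free energy from solvent-accessible surface area
#'
#' Linear SASA model `gamma * SASA + beta`. Defaults are the common
#' PB/SA surface-tension parameters.
#'
#' @param sasa Solvent-accessible surface area, Angstrom^2 (>= 0).
#' @param gamma Surface tension, kcal mol^-1 A^-2.
#' @param beta Offset, kcal/mol.
#' @return Nonpolar solvation free energy, kcal/mol.
#' @export
nonpolar_solvation <- function(sasa, gamma = 0.00542, beta = 0.92) {
  if (any(sasa < 0)) stop("negative SASA")
  gamma * sasa + beta
}

#' Component-wise binding deltas between complex, receptor and ligand
#'
#' `delta X = X_complex - X_receptor - X_ligand` for every MM-PBSA
#' component and derived row; `delta g_bind = delta g_mmpbsa - delta T dS`.
#' All three summaries must use the same (single-trajectory) convention.
#'
#' @param complex,receptor,ligand `"binding_summary"` objects.
#' @return A `"binding_summary"` of the deltas.
#' @export
binding_delta <- function(complex, receptor, ligand) {
  for (x in list(complex, receptor, ligand))
    if (!inherits(x, "binding_summary"))
      stop("all three arguments must be 'binding_summary' objects")
  d <- function(k) complex$components[[k]] - receptor$components[[k]] -
    ligand$components[[k]]
  combine_mmpbsa(energy_components(d("e_vdw"), d("e_ele"), d("g_pb"),
                                   d("g_sa"), d("t_delta_s")))
}

#' Geometric insertion barrier from a PMF endpoint
#'
#' Splits the total reversible work of extracting a bound ligand into the
#' thermodynamic stabilization it provided and the geometric resistance of
#' the cavity: `barrier = pmf_total - stabilization`. A negative result is
#' allowed but flagged with a warning.
#'
#' @param pmf_total Total PMF change over the pulling path, kcal/mol.
#' @param stabilization Binding stabilization energy recovered, kcal/mol.
#' @return Geometric barrier, kcal/mol.
#' @examples
#' insertion_barrier(33.10, 12.82)  # 20.28
#' @export
insertion_barrier <- function(pmf_total, stabilization) {
  if (!is.finite(pmf_total) || !is.finite(stabilization))
    stop("inputs must be finite")
  b <- pmf_total - stabilization
  if (b < 0) warning("negative barrier: stabilization exceeds the PMF total")
  b
}

#' Compose a transition-state energy from a base state and a barrier
#'
#' `G_T(total) = G_state(total) + barrier`, at cluster level; divide by the
#' destination state's nu (the network-model convention) for the
#' per-monomer value.
#'
#' @param base_state_g_total Total free energy of the base stable state,
#'   kcal/mol.
#' @param barrier Barrier height above the base state, kcal/mol.
#' @return Transition-state total free energy, kcal/mol.
#' @examples
#' compose_transition_energy(-31.15, 20.28)  # -10.87
#' @export
compose_transition_energy <- function(base_state_g_total, barrier) {
  base_state_g_total + barrier
}

#' Read a tabular MM-PBSA component file
#'
#' Accepts tab- or comma-separated tables with one system per column (rows
#' named by component) or one system per row (columns named by component).
#' Component names may be the ASCII aliases `Evdw`, `Eele`, `GPB`, `GSA`,
#' `TdS` or the package's field names.
#'
#' @param path File path.
#' @return Named list of [energy_components()], one per system.
#' @export
read_mmpbsa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  alias <- c(Evdw = "e_vdw", Eele = "e_ele", GPB = "g_pb", GSA = "g_sa",
             TdS = "t_delta_s", e_vdw = "e_vdw", e_ele = "e_ele",
             g_pb = "g_pb", g_sa = "g_sa", t_delta_s = "t_delta_s")
  canon <- function(x) unname(alias[x])
  if (all(!is.na(canon(rownames(df))))) {
    rownames(df) <- canon(rownames(df))
    systems <- colnames(df)
    get <- function(sys, k) as.numeric(df[k, sys])
  } else if (all(!is.na(canon(colnames(df))))) {
    colnames(df) <- canon(colnames(df))
    systems <- rownames(df)
    get <- function(sys, k) as.numeric(df[sys, k])
  } else stop("cannot map table headers to MM-PBSA components")
  out <- lapply(systems, function(sys)
    energy_components(get(sys, "e_vdw"), get(sys, "e_ele"), get(sys, "g_pb"),
                      get(sys, "g_sa"), get(sys, "t_delta_s")))
  names(out) <- systems
  out
}
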