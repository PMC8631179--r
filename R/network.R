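#' @importFrom stats setNames
NULL

# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.9872e-3

#' Declare a stable self-assembly state
#'
#' A stable state is a cluster of `nu` monomers sitting at a local
#' free-energy minimum. Its energy is supplied per cluster, as the total
#' binding free energy relative to free monomers (the sum of stepwise
#' binding free energies); the per-monomer value used by the rate theory
#' is derived as `g_bind_total / nu`.
#'
#' @param id Short unique label, e.g. `"S1"`.
#' @param nu Positive integer, number of monomers per cluster. Small-molecule
#'   ligands do not count towards `nu`; it is user-declared, never inferred.
#' @param g_bind_total Total binding free energy of the cluster, kcal/mol.
#'   The free-monomer reference state has `g_bind_total = 0`.
#' @return An object of class `"stable_state"`.
#' @export
stable_state <- function(id, nu, g_bind_total) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu < 1 ||
      nu != round(nu))
    stop("'nu' must be a positive integer for state '", id, "'")
  if (!is.numeric(g_bind_total) || length(g_bind_total) != 1L ||
      !is.finite(g_bind_total))
    stop("non-numeric 'g_bind_total' for state '", id, "'")
  structure(list(id = id, nu = as.integer(nu),
                 g_bind_total = as.numeric(g_bind_total),
                 g_monomer = as.numeric(g_bind_total) / nu),
            class = "stable_state")
}

#' Declare a transition state
#'
#' A transition state is the Gibbs free-energy maximum on a transformation
#' path. It carries a per-monomer free energy directly (no cluster size of
#' its own) and a set of links to stable states, each with a dimensionless
#' frequency factor `A > 0`. `A = 0` means "not linked" and must be omitted.
#'
#' @param id Short unique label, e.g. `"T1"`.
#' @param g_monomer Per-monomer free energy of the transition state, kcal/mol,
#'   relative to the free-monomer zero.
#' @param links Named numeric vector: names are stable-state ids, values the
#'   frequency factors A (default 1 for each named state if unnamed values
#'   are not given).
#' @return An object of class `"transition_state"`.
#' @export
transition_state <- function(id, g_monomer, links) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(g_monomer) || length(g_monomer) != 1L ||
      !is.finite(g_monomer))
    stop("non-numeric 'g_monomer' for transition '", id, "'")
  if (is.character(links)) links <- setNames(rep(1, length(links)), links)
  if (length(links) < 1L || is.null(names(links)) || any(!nzchar(names(links))))
    stop("transition '", id, "' needs at least one named link")
  structure(list(id = id, g_monomer = as.numeric(g_monomer),
                 links = links),
            class = "transition_state")
}

#' Assemble a self-assembly network
#'
#' Builds the bipartite network of stable states and transition states that
#' every rate computation consumes. There are no direct state-state or
#' transition-transition links by construction.
#'
#' @param states List of [stable_state()] objects.
#' @param transitions List of [transition_state()] objects.
#' @param temperature Temperature in K (default 310).
#' @param c0 Total analytical monomer concentration C0 (arbitrary
#'   concentration units; rates scale linearly in it).
#' @param gas_constant Gas constant, kcal mol^-1 K^-1.
#' @return An object of class `"self_assembly_network"`.
#' @seealso [load_network()], [validate_network()], [gitr_kinetics()]
#' @examples
#' net <- self_assembly_network(
#'   states = list(stable_state("S1", 2, -23.63), stable_state("S2", 2, -31.15)),
#'   transitions = list(transition_state("T1", 0, c(S1 = 1, S2 = 1))))
#' validate_network(net)
#' @export
self_assembly_network <- function(states, transitions, temperature = 310,
                                  c0 = 1, gas_constant = .R_KCAL) {
  if (inherits(states, "stable_state")) states <- list(states)
  if (inherits(transitions, "transition_state")) transitions <- list(transitions)
  net <- structure(list(states = states, transitions = transitions,
                        temperature = as.numeric(temperature),
                        c0 = as.numeric(c0),
                        gas_constant = as.numeric(gas_constant)),
                   class = "self_assembly_network")
  diag <- validate_network(net)
  if (length(diag)) stop("invalid network:\n  ", paste(diag, collapse = "\n  "))
  net
}

#' Validate a self-assembly network
#'
#' Checks every structural invariant (unique ids, positive cluster sizes,
#' link targets declared, strictly positive frequency factors, consistent
#' per-monomer energies) and returns human-readable diagnostics. Never
#' throws and never mutates; an empty character vector means the network
#' is valid.
#'
#' @param net A `self_assembly_network` (possibly built by hand).
#' @return Character vector of diagnostics, `character(0)` if valid.
#' @export
validate_network <- function(net) {
  out <- character(0)
  say <- function(...) out <<- c(out, paste0(...))
  st <- net$states; tr <- net$transitions
  if (!length(st)) say("network has no stable states")
  if (!length(tr)) say("network has no transition states")
  sid <- vapply(st, function(s) as.character(s$id %||% NA_character_), "")
  tid <- vapply(tr, function(t) as.character(t$id %||% NA_character_), "")
  if (anyDuplicated(sid)) say("duplicate stable-state id: ",
                              paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(tid)) say("duplicate transition id: ",
                              paste(unique(tid[duplicated(tid)]), collapse = ", "))
  if (length(intersect(sid, tid)))
    say("id used for both a state and a transition: ",
        paste(intersect(sid, tid), collapse = ", "))
  for (s in st) {
    if (!is.numeric(s$nu) || s$nu < 1 || s$nu != round(s$nu))
      say("state '", s$id, "': nu must be a positive integer")
    if (!is.numeric(s$g_bind_total) || !is.finite(s$g_bind_total))
      say("state '", s$id, "': non-numeric g_bind_total")
    else if (is.numeric(s$g_monomer) &&
             abs(s$g_monomer * s$nu - s$g_bind_total) > 1e-9 * max(1, abs(s$g_bind_total)))
      say("state '", s$id, "': g_monomer * nu != g_bind_total")
  }
  for (t in tr) {
    if (!is.numeric(t$g_monomer) || !is.finite(t$g_monomer))
      say("transition '", t$id, "': non-numeric g_monomer")
    if (length(t$links) < 1L) {
      say("transition '", t$id, "': no links declared")
      next
    }
    bad <- setdiff(names(t$links), sid)
    if (length(bad))
      say("transition '", t$id, "': link to undeclared state ",
          paste(bad, collapse = ", "))
    if (any(t$links == 0))
      say("transition '", t$id, "': zero frequency factor on link to ",
          paste(names(t$links)[t$links == 0], collapse = ", "),
          " (omit the link instead)")
    if (any(t$links < 0))
      say("transition '", t$id, "': negative frequency factor")
    if (anyDuplicated(names(t$links)))
      say("transition '", t$id, "': duplicate link target")
  }
  if (!is.numeric(net$temperature) || net$temperature <= 0)
    say("temperature must be positive")
  if (!is.numeric(net$c0) || net$c0 < 0) say("c0 must be non-negative")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.self_assembly_network <- function(x, ...) {
  cat("Self-assembly network:", length(x$states), "stable state(s),",
      length(x$transitions), "transition state(s)\n")
  cat(sprintf("  T = %g K, C0 = %g, RT = %.4f kcal/mol\n",
              x$temperature, x$c0, x$gas_constant * x$temperature))
  for (s in x$states)
    cat(sprintf("  %-4s nu = %d  G_total = %8.3f  G/monomer = %8.3f kcal/mol\n",
                s$id, s$nu, s$g_bind_total, s$g_monomer))
  for (t in x$transitions)
    cat(sprintf("  %-4s G/monomer = %8.3f  links: %s\n", t$id, t$g_monomer,
                paste(sprintf("%s (A=%g)", names(t$links), t$links),
                      collapse = ", ")))
  invisible(x)
}

# --- internal indexed view ---------------------------------------------------

# Dense arrays used by the engine: per-monomer state energies gs, transition
# energies gt, frequency-factor matrix Af[t, s] (0 where unlinked), nu vector.
.net_index <- function(net) {
  sid <- vapply(net$states, `[[`, "", "id")
  tid <- vapply(net$transitions, `[[`, "", "id")
  ns <- length(sid); nt <- length(tid)
  Af <- matrix(0, nt, ns, dimnames = list(tid, sid))
  for (i in seq_len(nt)) {
    lk <- net$transitions[[i]]$links
    Af[i, names(lk)] <- lk
  }
  list(sid = sid, tid = tid, ns = ns, nt = nt,
       nu = vapply(net$states, function(s) as.numeric(s$nu), 0),
       gs = vapply(net$states, `[[`, 0, "g_monomer"),
       gt = vapply(net$transitions, `[[`, 0, "g_monomer"),
       Af = Af, rt = net$gas_constant * net$temperature)
}

# --- file I/O ----------------------------------------------------------------

#' Read a self-assembly network from a file
#'
#' Reads the declarative network format: JSON (default) or YAML (by `.yaml`/
#' `.yml` extension). Schema: `temperature_K`, `c0`,
#' `states: [{id, nu, g_bind_total}]`,
#' `transitions: [{id, g_monomer | (g_total, g_total_over_nu_of), links:
#' [{state, A}]}]`. A transition may give its barrier at cluster level via
#' `g_total` plus `g_total_over_nu_of` naming a stable state; it is then
#' divided by that state's `nu`. Missing `temperature_K` defaults to 310 K,
#' missing link `A` to 1.
#'
#' @param path Path to the network file.
#' @return A validated `self_assembly_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$states)) stop("schema error: missing key 'states'")
  if (is.null(raw$transitions)) stop("schema error: missing key 'transitions'")
  num <- function(x, key, where) {
    if (is.null(x)) stop("schema error: missing key '", key, "' in ", where)
    x <- suppressWarnings(as.numeric(x))
    if (length(x) != 1L || is.na(x))
      stop("schema error: non-numeric '", key, "' in ", where)
    x
  }
  states <- lapply(raw$states, function(s) {
    if (is.null(s$id)) stop("schema error: state without 'id'")
    stable_state(s$id, num(s$nu, "nu", s$id), num(s$g_bind_total, "g_bind_total", s$id))
  })
  sid <- vapply(states, `[[`, "", "id")
  nu_of <- setNames(vapply(states, function(s) as.numeric(s$nu), 0), sid)
  transitions <- lapply(raw$transitions, function(t) {
    if (is.null(t$id)) stop("schema error: transition without 'id'")
    if (!is.null(t$g_monomer)) {
      g <- num(t$g_monomer, "g_monomer", t$id)
    } else if (!is.null(t$g_total)) {
      ref <- t$g_total_over_nu_of
      if (is.null(ref) || !ref %in% sid)
        stop("schema error: 'g_total_over_nu_of' in ", t$id,
             " must name a declared state")
      g <- num(t$g_total, "g_total", t$id) / nu_of[[ref]]
    } else stop("schema error: transition '", t$id,
                "' needs 'g_monomer' or 'g_total' + 'g_total_over_nu_of'")
    if (is.null(t$links) || !length(t$links))
      stop("schema error: transition '", t$id, "' has no links")
    lk <- vapply(t$links, function(l) {
      if (is.null(l$state)) stop("schema error: link without 'state' in ", t$id)
      num(l$A %||% 1, "A", t$id)
    }, 0)
    names(lk) <- vapply(t$links, `[[`, "", "state")
    transition_state(t$id, g, lk)
  })
  self_assembly_network(states, transitions,
                        temperature = num(raw$temperature_K %||% 310,
                                          "temperature_K", "header"),
                        c0 = num(raw$c0 %||% 1, "c0", "header"))
}

#' Write a self-assembly network to a JSON file
#'
#' Field order is fixed so that serialization is bit-stable:
#' `load_network(write_network(net))` reproduces `net` field by field.
#'
#' @param net A `self_assembly_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(
    temperature_K = net$temperature,
    c0 = net$c0,
    states = lapply(net$states, function(s)
      list(id = s$id, nu = s$nu, g_bind_total = s$g_bind_total)),
    transitions = lapply(net$transitions, function(t)
      list(id = t$id, g_monomer = t$g_monomer,
           links = lapply(seq_along(t$links), function(i)
             list(state = names(t$links)[i], A = unname(t$links[i]))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Wrap a concentration vector as a concentration state
#'
#' Concentrations are per cluster (`Cs`); the per-monomer view is
#' `Ms = nu * Cs`.
#'
#' @param net The network the concentrations refer to.
#' @param c Named or ordered numeric vector of per-cluster concentrations,
#'   one per stable state.
#' @param time Time stamp (default 0).
#' @return An object of class `"concentration_state"` with elements `c`
#'   (per cluster), `monomer` (`nu * c`) and `time`.
#' @export
concentration_state <- function(net, c, time = 0) {
  ix <- .net_index(net)
  if (!is.null(names(c))) {
    if (!setequal(names(c), ix$sid))
      stop("concentration names do not match state ids")
    c <- c[ix$sid]
  } else if (length(c) != ix$ns) stop("need one concentration per state")
  if (any(!is.finite(c))) stop("non-finite concentration")
  structure(list(c = setNames(as.numeric(c), ix$sid),
                 monomer = setNames(as.numeric(c) * ix$nu, ix$sid),
                 time = time),
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat("Concentration state (t =", x$time, ")\n")
  print(rbind(cluster = x$c, monomer = x$monomer))
  invisible(x)
}
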