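# Rate theory for the bipartite self-assembly network.
#
# Conventions, used consistently below:
#   * all state/transition energies are per monomer, kcal/mol, relative to
#     the free-monomer zero;
#   * concentrations are per cluster (Cs); monomer-form quantities are
#     explicit, separately named variants;
#   * the absolute prefactor k = (kB*T/h)*A is not fixed by the theory's
#     inputs, so every rate carries a single configurable scale `k_scale`
#     (default 1, "reduced rate units"); conclusions are rate ratios.

# log-sum-exp with max subtraction
.lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Linking-fraction matrix
#'
#' Column-stochastic matrix distributing the outflow of each transition
#' state over its directly linked stable states:
#' `Lf[s,t] = A_t^s / sum_s' A_t^s'` (the kBT/h prefactor cancels).
#' With all frequency factors equal, each column is uniform `1/n` over its
#' `n` linked states.
#'
#' @param net A `self_assembly_network`.
#' @return `ns x nt` matrix with rows named by stable states and columns by
#'   transition states; each column sums to 1.
#' @export
linking_fractions <- function(net) {
  ix <- .net_index(net)
  tot <- rowSums(ix$Af)
  if (any(tot <= 0))
    stop("isolated transition state: ", paste(ix$tid[tot <= 0], collapse = ", "))
  t(ix$Af / tot)
}

#' Equilibrium monomer distribution over accessible states
#'
#' The probability that a monomer sits in stable state s at equilibrium is
#' `Ps = exp(-Gs/RT) / Z` with `Z = sum exp(-Gs'/RT)` over the *accessible*
#' states only, and the per-cluster equilibrium concentration is
#' `Cs_eq = Ps * C0 / nu_s`. Which states enter Z is a modelling decision
#' (for example, a product state that cannot yet form is excluded), so
#' `accessible` must be given explicitly when it is not all states.
#' Exponentials are computed with max shifting so large |G|/RT are safe.
#'
#' @param net A `self_assembly_network`.
#' @param accessible Character vector of accessible state ids (default: all).
#' @return A [concentration_state()] with an extra element `p` (the monomer
#'   probabilities, summing to 1 over accessible states) and `accessible`.
#' @export
equilibrium_distribution <- function(net, accessible = NULL) {
  ix <- .net_index(net)
  if (is.null(accessible)) accessible <- ix$sid
  if (!length(accessible)) stop("empty accessible set")
  bad <- setdiff(accessible, ix$sid)
  if (length(bad)) stop("unknown state id: ", paste(bad, collapse = ", "))
  acc <- ix$sid %in% accessible
  lw <- -ix$gs[acc] / ix$rt
  p <- setNames(numeric(ix$ns), ix$sid)
  p[acc] <- exp(lw - .lse(lw))
  cs <- p * net$c0 / ix$nu
  out <- concentration_state(net, cs)
  out$p <- p
  out$accessible <- ix$sid[acc]
  out
}

# concentration input -> plain per-cluster vector in state order
.conc_vec <- function(net, conc) {
  ix <- .net_index(net)
  v <- if (inherits(conc, "concentration_state")) conc$c else conc
  if (!is.null(names(v))) {
    if (!setequal(names(v), ix$sid)) stop("concentration names do not match state ids")
    v <- v[ix$sid]
  }
  if (length(v) != ix$ns) stop("need one concentration per state")
  if (any(v < 0)) stop("negative concentration")
  as.numeric(v)
}

#' Path rates of the network at given concentrations
#'
#' For every directly linked pair (stable state s, transition state t) the
#' transformation rate along that path is
#' \deqn{R_{s,t} = -k_t^s e^{-(G_t-G_s)/RT} C_s +
#'   \sum_{s'} Lf_{s,t}\, k_t^{s'} e^{-(G_t-G_{s'})/RT}
#'   \frac{\nu_{s'}}{\nu_s} C_{s'}}
#' with `k_t^s = k_scale * A_t^s`. The minus sign is outflow from s via t;
#' the positive sum is the inflow redistributed through the
#' linking-fraction matrix. At the equilibrium distribution all path rates
#' vanish identically.
#'
#' @param net A `self_assembly_network`.
#' @param conc A [concentration_state()] or per-cluster concentration vector.
#' @param k_scale Common rate prefactor (kB*T/h absorbed), default 1.
#' @return Object of class `"rate_table"`: list with `path_rates`
#'   (`ns x nt` matrix, zero where unlinked), `state_rates` (exact row
#'   sums), `lf`, and `k_scale`.
#' @export
path_rates <- function(net, conc, k_scale = 1) {
  ix <- .net_index(net)
  cs <- .conc_vec(net, conc)
  lf <- linking_fractions(net)                     # ns x nt
  K <- k_scale * t(ix$Af)                          # ns x nt, k_t^s
  # B[s,t] = k_t^s * exp(-(G_t - G_s)/RT) * C_s : outflow magnitude
  B <- K * exp(outer(ix$gs / ix$rt, -ix$gt / ix$rt, `+`)) * cs
  # inflow through t redistributed by Lf, weighted per-monomer
  inflow_t <- colSums(B * ix$nu)                   # sum_s' nu_s' * B[s',t]
  R <- -B + lf * rep(inflow_t, each = ix$ns) / ix$nu
  R[t(ix$Af) == 0] <- 0
  structure(list(path_rates = R, state_rates = rowSums(R),
                 lf = lf, k_scale = k_scale),
            class = "rate_table")
}

#' State concentration-change rates
#'
#' `Rs = sum_t R[s,t]`, the exact row sums of the path-rate matrix:
#' the net rate of change of each stable state's cluster concentration.
#'
#' @param rate_table A `"rate_table"` from [path_rates()].
#' @return Named numeric vector, one entry per stable state.
#' @export
state_rates <- function(rate_table) {
  stopifnot(inherits(rate_table, "rate_table"))
  rowSums(rate_table$path_rates)
}

#' @export
print.rate_table <- function(x, digits = 4, ...) {
  cat("Path rates (rows = stable states, cols = transition states):\n")
  print(signif(x$path_rates, digits))
  cat("State rates:\n")
  print(signif(x$state_rates, digits))
  invisible(x)
}

#' One-way equilibrium path flux
#'
#' The single-direction rate flowing along each linked path when the
#' network sits at the equilibrium distribution:
#' `|R|_eq(s,t) = k_t^s * (1/nu_s) * (1/Z) * exp(-G_t/RT) * C0` in cluster
#' form; the monomer form omits the `1/nu_s`. Both depend only on the
#' transition-state energy and the frequency factor, not on the energy of
#' the stable state.
#'
#' @inheritParams path_rates
#' @param accessible Accessible state ids defining Z (default: all states).
#' @param monomer_form Logical; drop the `1/nu_s` factor.
#' @return `ns x nt` matrix of non-negative fluxes, zero where unlinked.
#' @export
equilibrium_flux <- function(net, accessible = NULL, monomer_form = FALSE,
                             k_scale = 1) {
  ix <- .net_index(net)
  if (is.null(accessible)) accessible <- ix$sid
  if (!length(accessible)) stop("empty accessible set")
  acc <- ix$sid %in% accessible
  logZ <- .lse(-ix$gs[acc] / ix$rt)
  K <- k_scale * t(ix$Af)                          # ns x nt
  fl <- K * rep(exp(-ix$gt / ix$rt - logZ) * net$c0, each = ix$ns)
  if (!monomer_form) fl <- fl / ix$nu
  fl
}

#' Build the kinetic system dC/dt = A C
#'
#' Assembles the `ns x ns` rate matrix of the linear kinetics,
#' \deqn{A_{sj} = \delta_{sj} \sum_t -k_t^s e^{-(G_t-G_s)/RT} +
#'   \sum_t \frac{\nu_j}{\nu_s} Lf_{s,t}\, k_t^j e^{-(G_t-G_j)/RT}}
#' and its eigendecomposition. The monomer-count vector (nu_1..nu_ns) is a
#' left null vector of A, so total monomer is conserved exactly. If the
#' eigenbasis is ill-conditioned (condition number > 1e12) or defective,
#' [evolve()] transparently switches to a matrix-exponential evaluation.
#'
#' @inheritParams path_rates
#' @return Object of class `"gitr_kinetics"`: the network, matrix `A`,
#'   eigenvalues/vectors, and diagnostics.
#' @seealso [evolve()], [predict.gitr_kinetics()]
#' @export
gitr_kinetics <- function(net, k_scale = 1) {
  ix <- .net_index(net)
  lf <- linking_fractions(net)
  K <- k_scale * t(ix$Af)
  # W[s,t] = k_t^s exp(-(G_t - G_s)/RT): per-cluster escape rate constants
  W <- K * exp(outer(ix$gs / ix$rt, -ix$gt / ix$rt, `+`))
  A <- (lf * ix$nu^-1) %*% t(W * ix$nu)            # inflow part, A[s,j]
  diag(A) <- diag(A) - rowSums(W)
  dimnames(A) <- list(ix$sid, ix$sid)
  eg <- eigen(A)
  # Frobenius-norm condition estimate; works for complex eigenbases too
  fro <- function(M) sqrt(sum(Mod(M)^2))
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  kappa <- if (is.null(Vi)) Inf else fro(eg$vectors) * fro(Vi)
  diagonalizable <- is.finite(kappa) && kappa < 1e12
  structure(list(net = net, A = A, k_scale = k_scale,
                 eigenvalues = eg$values, eigenvectors = eg$vectors,
                 kappa = kappa, diagonalizable = diagonalizable),
            class = "gitr_kinetics")
}

#' Alias for the kinetic-matrix constructor
#' @inheritParams gitr_kinetics
#' @return See [gitr_kinetics()].
#' @export
kinetic_matrix <- function(net, k_scale = 1) gitr_kinetics(net, k_scale)

#' @export
print.gitr_kinetics <- function(x, digits = 4, ...) {
  cat("Kinetic system dC/dt = A C,", nrow(x$A), "stable states\n")
  cat("Eigenvalues:", paste(signif(x$eigenvalues, digits), collapse = ", "), "\n")
  if (!x$diagonalizable)
    cat("(eigenbasis ill-conditioned; evolution uses the matrix exponential)\n")
  invisible(x)
}

#' @export
summary.gitr_kinetics <- function(object, ...) {
  ix <- .net_index(object$net)
  eq <- equilibrium_distribution(object$net)
  lam <- object$eigenvalues
  neg <- Re(lam)[Re(lam) < -1e-14]
  relax <- if (length(neg)) -1 / max(neg) else NA_real_
  structure(list(A = object$A, eigenvalues = lam,
                 conservation_residual = max(abs(ix$nu %*% object$A)),
                 equilibrium = eq, slowest_relaxation_time = relax),
            class = "summary.gitr_kinetics")
}

#' @export
print.summary.gitr_kinetics <- function(x, ...) {
  cat("Kinetic matrix A:\n"); print(signif(x$A, 4))
  cat("Eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat("Monomer-conservation residual |nu' A|:",
      format(x$conservation_residual, digits = 3), "\n")
  if (is.finite(x$slowest_relaxation_time))
    cat("Slowest relaxation time:", signif(x$slowest_relaxation_time, 4),
        "(reduced units)\n")
  cat("All-state equilibrium cluster concentrations:\n")
  print(signif(x$equilibrium$c, 4))
  invisible(x)
}

#' Time evolution of the network concentrations
#'
#' Solves `dC/dt = A C` from `c_init`. When A has a well-conditioned
#' eigenbasis the analytic superposition `C(t) = sum_i z_i xi_i exp(lambda_i t)`
#' is used, with the weights `z` solved from the initial condition;
#' otherwise a dense matrix-exponential evaluation (same contract) is used.
#' Total monomer `sum nu_s C_s(t)` is conserved along the trajectory.
#'
#' @param system A `"gitr_kinetics"` object.
#' @param c_init Initial per-cluster concentrations (vector or
#'   [concentration_state()]).
#' @param times Sorted non-negative time points (reduced units unless
#'   `k_scale` was given physical units).
#' @return Object of class `"gitr_trajectory"`: matrix of concentrations
#'   (`length(times) x ns`) with a `times` attribute and the method used.
#' @export
evolve <- function(system, c_init, times) {
  stopifnot(inherits(system, "gitr_kinetics"))
  cs <- .conc_vec(system$net, c_init)
  if (any(times < 0)) stop("negative time")
  if (is.unsorted(times)) stop("'times' must be sorted increasing")
  ns <- nrow(system$A)
  if (length(cs) != ns) stop("dimension mismatch")
  method <- "eigen"
  out <- NULL
  if (system$diagonalizable) {
    V <- system$eigenvectors
    z <- tryCatch(solve(V, cs), error = function(e) NULL)
    if (!is.null(z)) {
      E <- exp(outer(times, system$eigenvalues))   # nt_times x ns
      out <- Re(t(V %*% t(E * rep(z, each = length(times)))))
    }
  }
  if (is.null(out)) {
    method <- "expm"
    out <- t(vapply(times, function(tt)
      as.numeric(Matrix::expm(system$A * tt) %*% cs), numeric(ns)))
  }
  dimnames(out) <- list(NULL, colnames(system$A))
  structure(out, times = times, method = method, net = system$net,
            class = c("gitr_trajectory", "matrix"))
}

#' @rdname evolve
#' @param object A `"gitr_kinetics"` object.
#' @param ... Unused.
#' @export
predict.gitr_kinetics <- function(object, c_init, times, ...)
  evolve(object, c_init, times)

#' @export
print.gitr_trajectory <- function(x, ...) {
  tm <- attr(x, "times")
  cat("Concentration time course,", length(tm), "time points,",
      ncol(x), "states (method:", attr(x, "method"), ")\n")
  show <- cbind(time = tm, unclass(x))
  n <- nrow(show)
  print(signif(show[unique(c(1, seq_len(min(5, n)), n)), , drop = FALSE], 4))
  invisible(x)
}

#' @export
plot.gitr_trajectory <- function(x, ...) {
  tm <- attr(x, "times")
  graphics::matplot(tm, unclass(x), type = "l", lty = 1,
                    xlab = "time (reduced units)",
                    ylab = "cluster concentration", ...)
  graphics::legend("right", legend = colnames(x), lty = 1,
                   col = seq_len(ncol(x)), bty = "n")
  invisible(x)
}

#' Rank transformation paths by rate magnitude
#'
#' Computes the path rates at the given concentrations and ranks every
#' linked path by `|R[s,t]|`, descending. Paths whose magnitudes agree
#' within a relative tolerance of 1e-9 are reported as joint-dominant
#' (same rank) rather than ordered arbitrarily.
#'
#' @inheritParams path_rates
#' @param tol Relative tie tolerance on `|R|`.
#' @return A data frame with columns `state`, `transition`, `rate`,
#'   `abs_rate`, `rank` (ties share a rank), sorted by `abs_rate`
#'   descending. Zero rows (with a message) if all rates vanish.
#' @export
dominant_path <- function(net, conc, k_scale = 1, tol = 1e-9) {
  rt <- path_rates(net, conc, k_scale)
  ix <- .net_index(net)
  linked <- which(t(ix$Af) != 0, arr.ind = TRUE)   # ns x nt indexing
  df <- data.frame(state = ix$sid[linked[, 1]],
                   transition = ix$tid[linked[, 2]],
                   rate = rt$path_rates[linked],
                   stringsAsFactors = FALSE)
  df$abs_rate <- abs(df$rate)
  if (all(df$abs_rate <= .Machine$double.xmin)) {
    message("all path rates are zero (system at a stationary point)")
    df <- df[0, ]
    df$rank <- integer(0)
    return(df)
  }
  df <- df[order(-df$abs_rate), ]
  rnk <- integer(nrow(df)); rnk[1] <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    tied <- (df$abs_rate[i - 1] - df$abs_rate[i]) <=
      tol * max(df$abs_rate[i - 1], .Machine$double.xmin)
    rnk[i] <- if (tied) rnk[i - 1] else rnk[i - 1] + 1L
  }
  df$rank <- rnk
  rownames(df) <- NULL
  df
}
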