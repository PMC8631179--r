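# Jarzynski-equality free-energy estimation from nonequilibrium pulling
# work, with the staged (adaptive) protocol and a synthetic work generator
# whose ground truth is known in closed form.

#' Jarzynski free-energy estimate from a work sample
#'
#' `dG = -kT * log( mean( exp(-W/kT) ) )`, evaluated in log space with
#' max-work subtraction so that widely spread work values are safe. By
#' Jensen's inequality the estimate never exceeds the arithmetic mean of
#' the works.
#'
#' @param works Numeric vector of pulling work values, kcal/mol (>= 1).
#' @param temperature Temperature, K.
#' @param gas_constant Gas constant, kcal mol^-1 K^-1.
#' @return Free-energy estimate, kcal/mol.
#' @examples
#' jarzynski_average(c(10, 10, 10), 310)  # exactly 10
#' @export
jarzynski_average <- function(works, temperature = 310,
                              gas_constant = .R_KCAL) {
  if (!length(works)) stop("empty work sample")
  if (temperature <= 0) stop("temperature must be positive")
  if (any(!is.finite(works))) stop("non-finite work value")
  kt <- gas_constant * temperature
  x <- -works / kt
  -kt * (.lse(x) - log(length(works)))
}

#' Bundle one stage of pulling-work replicates
#'
#' @param xi Strictly increasing pulling-coordinate grid, Angstrom,
#'   spanning the stage interval.
#' @param works Matrix (`length(xi) x n_replicates`) of cumulative work
#'   along the stage, kcal/mol, zero at the stage start.
#' @param stage Stage index (informational).
#' @param temperature Temperature, K.
#' @return Object of class `"work_ensemble"`.
#' @export
work_ensemble <- function(xi, works, stage = 1L, temperature = 310) {
  works <- as.matrix(works)
  if (length(xi) != nrow(works))
    stop("grid and work traces have different lengths")
  if (ncol(works) < 1L) stop("need at least one replicate")
  if (any(diff(xi) <= 0)) stop("xi must be strictly increasing")
  structure(list(xi = as.numeric(xi), works = works, stage = stage,
                 temperature = temperature),
            class = "work_ensemble")
}

#' @export
print.work_ensemble <- function(x, ...) {
  cat(sprintf("Work ensemble, stage %s: xi in [%.3g, %.3g] A, %d replicates, %d grid points\n",
              x$stage, x$xi[1], x$xi[length(x$xi)], ncol(x$works), length(x$xi)))
  invisible(x)
}

#' Staged potential of mean force via Jarzynski averaging
#'
#' Applies [jarzynski_average()] pointwise along the pulling coordinate
#' within each stage, then chains the stage offsets so the profile is
#' continuous across stage boundaries, anchored at `dG = 0` at the start
#' of the first stage. For each stage the replicate whose end-of-stage
#' work lies closest to the stage's Jarzynski average is recorded (the
#' adaptive protocol restarts the next stage from that trajectory; here
#' the flag is informational metadata).
#'
#' @param stages List of [work_ensemble()] objects, contiguous in xi
#'   (each stage starts where the previous one ends).
#' @param temperature Temperature, K (default: taken from the first stage).
#' @return Object of class `"pmf_profile"`: data frame with columns `xi`
#'   and `dG`, with attributes `stage_seeds` (chosen replicate per stage)
#'   and `stage_offsets`.
#' @export
staged_pmf <- function(stages, temperature = NULL) {
  if (inherits(stages, "work_ensemble")) stages <- list(stages)
  if (!length(stages)) stop("no stages")
  idx <- order(vapply(stages, function(s) s$xi[1], 0))
  stages <- stages[idx]
  temperature <- temperature %||% stages[[1]]$temperature
  tol <- 1e-8
  xi_all <- numeric(0); dg_all <- numeric(0)
  offset <- 0
  seeds <- integer(length(stages)); offs <- numeric(length(stages))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    if (k > 1) {
      gap <- st$xi[1] - stages[[k - 1]]$xi[length(stages[[k - 1]]$xi)]
      if (abs(gap) > tol * max(1, abs(st$xi[1])))
        stop(sprintf("stage %d does not start where stage %d ends (gap %.3g A)",
                     k, k - 1, gap))
    }
    dg <- apply(st$works, 1, jarzynski_average, temperature = temperature)
    dg <- dg - dg[1]                       # anchor the stage at its start
    seeds[k] <- which.min(abs(st$works[nrow(st$works), ] - dg[length(dg)]))
    offs[k] <- offset
    keep <- if (k > 1) -1L else TRUE       # drop duplicated boundary point
    xi_all <- c(xi_all, st$xi[keep])
    dg_all <- c(dg_all, (offset + dg)[keep])
    offset <- offset + dg[length(dg)]
  }
  structure(data.frame(xi = xi_all, dG = dg_all),
            stage_seeds = seeds, stage_offsets = offs,
            temperature = temperature,
            class = c("pmf_profile", "data.frame"))
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: xi in [%.3g, %.3g] A, endpoint dG = %.3f kcal/mol (%d points)\n",
              x$xi[1], x$xi[nrow(x)], x$dG[nrow(x)], nrow(x)))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$xi, x$dG, type = "l", xlab = "pulling coordinate (A)",
                 ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
  invisible(x)
}

#' Synthetic steered-pulling work generator with closed-form ground truth
#'
#' Simulates an overdamped Langevin particle in a quadratic well
#' `U0(x) = well_k/2 * x^2` pulled by a moving harmonic restraint
#' `Us(x) = spring_k/2 * (x - c(t))^2` whose centre moves at constant
#' `speed` from 0 to `length`. Cumulative external work is accumulated per
#' step as `dW = -spring_k (x - c) dc`. The pulling range is split into
#' `n_stages` contiguous stages; each stage's replicates restart from the
#' analytic equilibrium at the stage boundary. The exact equilibrium free
#' energy of the combined potential is quadratic in the restraint centre,
#' `dG(c) = k_eff c^2 / 2` with `k_eff = well_k*spring_k/(well_k+spring_k)`,
#' and is returned for oracle use.
#'
#' @param spring_k Restraint spring constant, kcal mol^-1 A^-2.
#' @param speed Pulling speed, A/ns.
#' @param well_k Static well force constant, kcal mol^-1 A^-2.
#' @param length Total pulling distance, A.
#' @param n_stages Number of contiguous stages.
#' @param n_replicates Replicates per stage.
#' @param n_steps Integration steps per stage (> 0).
#' @param friction Friction coefficient, kcal mol^-1 ns A^-2.
#' @param temperature Temperature, K.
#' @param record_every Record the work every this many steps.
#' @param seed Optional RNG seed for reproducible ensembles.
#' @return List with `stages` (list of [work_ensemble()]),
#'   `analytic_dG` (function of xi, kcal/mol) and `k_eff`.
#' @export
synth_pulling <- function(spring_k = 20, speed = 2, well_k = 2, length = 20,
                          n_stages = 10, n_replicates = 20, n_steps = 500,
                          friction = 1, temperature = 310,
                          record_every = 10, seed = NULL) {
  stopifnot(spring_k > 0, speed > 0, well_k > 0, length > 0,
            n_stages >= 1, n_replicates >= 1, friction > 0)
  if (n_steps < 1) stop("non-positive step count")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    }
    set.seed(seed)
  }
  kt <- .R_KCAL * temperature
  k_tot <- well_k + spring_k
  stage_len <- length / n_stages
  dt <- stage_len / speed / n_steps          # ns
  if (dt * k_tot / friction > 0.25)
    warning("integration step is coarse for this stiffness; increase n_steps")
  rec <- unique(c(seq(0, n_steps, by = record_every), n_steps))
  stages <- vector("list", n_stages)
  for (st in seq_len(n_stages)) {
    c0 <- (st - 1) * stage_len
    # analytic equilibrium of the combined quadratic potential at centre c0
    x <- stats::rnorm(n_replicates, mean = spring_k * c0 / k_tot,
                      sd = sqrt(kt / k_tot))
    W <- numeric(n_replicates)
    works <- matrix(0, length(rec), n_replicates)
    xi <- c0 + rec / n_steps * stage_len
    works[1, ] <- W
    row <- 2L
    cen <- c0
    for (i in seq_len(n_steps)) {
      cen_new <- c0 + i / n_steps * stage_len
      dc <- cen_new - cen
      # work done by moving the restraint (midpoint rule in the centre)
      W <- W - spring_k * (x - (cen + cen_new) / 2) * dc
      cen <- cen_new
      drift <- -(well_k * x + spring_k * (x - cen)) / friction
      x <- x + drift * dt + sqrt(2 * kt * dt / friction) *
        stats::rnorm(n_replicates)
      if (i %in% rec) {
        works[row, ] <- W
        row <- row + 1L
      }
    }
    stages[[st]] <- work_ensemble(xi, works, stage = st,
                                  temperature = temperature)
  }
  k_eff <- well_k * spring_k / k_tot
  list(stages = stages,
       analytic_dG = function(xi) 0.5 * k_eff * xi^2,
       k_eff = k_eff)
}

#' Read one stage of pulling work from a tab-separated file
#'
#' Expected columns: `xi`, then one column per replicate (any names).
#'
#' @param path File path.
#' @param stage Stage index to record.
#' @param temperature Temperature, K.
#' @return A [work_ensemble()].
#' @export
read_work_stage <- function(path, stage = 1L, temperature = 310) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!"xi" %in% colnames(df)) stop("work table needs an 'xi' column")
  work_ensemble(df$xi, as.matrix(df[, setdiff(colnames(df), "xi"), drop = FALSE]),
                stage = stage, temperature = temperature)
}
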