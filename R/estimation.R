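# Weighted least-squares estimation of RaM parameters from uptake
# observations, with microscopic reversibility enforced at every candidate,
# normalized finite-difference sensitivities, Fisher-information covariance
# and Cramer-Rao 95% confidence intervals.

#' Uptake observations tied to pulse protocols
#'
#' @param protocols list of \code{pulse_protocol} objects, one per record.
#' @param observed observed total pulse uptake per record, nmol/mg.
#' @param variance measurement variance per record, (nmol/mg)^2 (> 0).
#' @param tissue_label tissue the records belong to.
#' @return an object of class \code{experiment_dataset}.
#' @export
experimentDataset <- function(protocols, observed, variance,
                              tissue_label = "custom") {
  if (length(protocols) < 1L) stop("at least one record is required")
  if (!all(vapply(protocols, inherits, logical(1), "pulse_protocol")))
    stop("'protocols' must be a list of pulse_protocol objects")
  observed <- as.numeric(observed)
  variance <- as.numeric(variance)
  if (length(observed) != length(protocols) ||
      length(variance) != length(protocols))
    stop("'observed' and 'variance' must match the number of protocols")
  if (any(!is.finite(variance)) || any(variance <= 0))
    stop("'variance' entries must be finite and > 0")
  structure(list(protocols = protocols, observed = observed,
                 variance = variance,
                 tissue_label = as.character(tissue_label)),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf("Uptake dataset [%s]: %d record(s), uptake %.3g-%.3g nmol/mg\n",
              x$tissue_label, length(x$observed),
              min(x$observed), max(x$observed)))
  invisible(x)
}

#' Fitting specification
#'
#' Declares which of the nine kinetic/transport parameters are free, which
#' are held fixed, which are shared across tissues, and which transition
#' rate is eliminated by the detailed-balance constraint (recomputed at
#' every objective evaluation, so microscopic reversibility holds at every
#' optimizer iterate).
#'
#' @param free character vector of free parameter names.
#' @param fixed named numeric vector of parameters pinned to given values.
#' @param shared names (subset of \code{free}) shared across all tissue
#'   datasets in a joint fit.
#' @param dependent_rate transition rate eliminated by detailed balance
#'   (default "k_I1_O", the derived rate of the published sets).
#' @param bounds optional named list of c(lower, upper) per free parameter;
#'   defaults to a factor of 100 either side of the start value.
#' @param fd_relative_step relative step for central finite differences in
#'   the sensitivity matrix (default 1e-6).
#' @param n_starts number of seeded multi-start optimizer launches
#'   (default 5: the supplied start plus perturbed restarts).
#' @param start_spread relative spread of the multi-start perturbations
#'   (default 0.2).
#' @return an object of class \code{fit_spec}.
#' @export
fitSpec <- function(free,
                    fixed = numeric(0),
                    shared = character(0),
                    dependent_rate = "k_I1_O",
                    bounds = NULL,
                    fd_relative_step = 1e-6,
                    n_starts = 5L,
                    start_spread = 0.2) {
  all_names <- c("X_RaM", "K_Ca", "n", "K_O", "K_I",
                 "k_O_I1", "k_I1_O", "k_I2_R", "k_R_I2")
  if (!all(free %in% all_names))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, all_names), collapse = ", "))
  if (!dependent_rate %in% c("k_I1_O", "k_R_I2", "k_O_I1", "k_I2_R"))
    stop("'dependent_rate' must be a transition rate name")
  if (length(fixed) && is.null(names(fixed)))
    stop("'fixed' must be a named numeric vector")
  sets <- list(free = free, fixed = names(fixed),
               dependent = dependent_rate)
  for (a in seq_along(sets)) for (b in seq_along(sets)) {
    if (a < b && length(intersect(sets[[a]], sets[[b]])))
      stop("free, fixed and dependent parameter sets must be disjoint")
  }
  if (!all(shared %in% free))
    stop("'shared' must be a subset of 'free'")
  if (!is.null(bounds)) {
    if (!all(names(bounds) %in% free))
      stop("'bounds' names must be free parameters")
    if (any(vapply(bounds, function(b) any(b <= 0) || b[1] >= b[2],
                   logical(1))))
      stop("bounds must be positive with lower < upper")
  }
  if (fd_relative_step <= 0) stop("'fd_relative_step' must be > 0")
  structure(list(free = free, fixed = fixed, shared = shared,
                 dependent_rate = dependent_rate, bounds = bounds,
                 fd_relative_step = fd_relative_step,
                 n_starts = as.integer(n_starts),
                 start_spread = start_spread),
            class = "fit_spec")
}

# Theta vector naming: shared (or single-dataset) free parameters use the
# plain name; tissue-specific entries use "<tissue>:<name>".
thetaNames <- function(spec, tissues) {
  if (length(tissues) == 1L) return(spec$free)
  unlist(lapply(spec$free, function(nm) {
    if (nm %in% spec$shared) nm else paste0(tissues, ":", nm)
  }))
}

thetaFromStart <- function(start, spec, tissues) {
  nms <- thetaNames(spec, tissues)
  vapply(nms, function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) start[[parts[1]]][[parts[2]]]
    else start[[tissues[1]]][[nm]]
  }, numeric(1))
}

# Materialize one tissue's parameter set from the theta vector: apply free
# and fixed values, then eliminate the dependent rate via detailed balance.
applyTheta <- function(theta, base, spec, tissue, single) {
  p <- base
  for (nm in spec$free) {
    key <- if (single || nm %in% spec$shared) nm else paste0(tissue, ":", nm)
    p[[nm]] <- unname(theta[[key]])
  }
  for (nm in names(spec$fixed)) p[[nm]] <- unname(spec$fixed[[nm]])
  p$balanced <- FALSE
  enforceDetailedBalance(p, spec$dependent_rate)
}

# Total pulse uptake of one protocol without trajectory sampling; the fast
# path used inside the objective and sensitivity loops. Per-segment Hill
# fractions, rates and amplitudes are computed once, vectorized; the
# postpulse tail is skipped (it contributes nothing to pulse summaries and
# nothing follows it). Agrees with simulateProtocol()$total_pulse_uptake.
protocolPulseUptake <- function(protocol, p, env) {
  np <- protocol$n_pulses
  ca <- rep(c(protocol$pulse_height, protocol$interpulse_height),
            length.out = 2L * np - 1L)
  dur <- rep(c(protocol$pulse_duration, protocol$interpulse_duration),
             length.out = 2L * np - 1L)
  f <- hillFraction(ca, p$K_O, p$n)
  g <- hillFraction(ca, p$K_I, p$n)
  kout <- p$k_O_I1 * f + p$k_R_I2 * (1 - f)
  kin <- p$k_I1_O * g + p$k_I2_R * (1 - g)
  tau <- 1 / (kin + kout)
  roinf <- kin * tau
  amp <- p$X_RaM * (ca / (ca + p$K_Ca)) * voltageFactor(env) * f
  ro <- if (protocol$prepulse_equilibration)
    steadyStateRO(protocol$prepulse_height, p) else 1
  total <- 0
  for (i in seq_along(ca)) {
    e <- exp(-dur[i] / tau[i])
    if (i %% 2L == 1L)
      total <- total + amp[i] * (roinf[i] * dur[i] +
                                 (ro - roinf[i]) * tau[i] * (1 - e))
    ro <- roinf[i] + (ro - roinf[i]) * e
  }
  total
}

# Predicted total pulse uptake for every record of every dataset,
# concatenated in dataset order.
predictUptake <- function(params_by_tissue, datasets, env) {
  unlist(lapply(datasets, function(d) {
    p <- params_by_tissue[[d$tissue_label]]
    vapply(d$protocols, protocolPulseUptake, numeric(1), p = p, env = env)
  }))
}

#' Variance-weighted least-squares objective
#'
#' Sum over all datasets and records of squared residuals weighted by the
#' measurement variance: \code{sum((y - obs)^2 / var)}, with model uptake
#' from \code{\link{simulateProtocol}}. Candidate parameters are expected
#' to already satisfy detailed balance (the fitter recomputes the dependent
#' rate before every call).
#'
#' @param params a \code{ram_params} object (applied to every dataset) or a
#'   named list of them keyed by tissue label.
#' @param datasets a single \code{experiment_dataset} or a list of them.
#' @param env a \code{membrane_env} object.
#' @return the dimensionless objective value (>= 0).
#' @export
wlsObjective <- function(params, datasets, env = membraneEnv()) {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  if (inherits(params, "ram_params")) {
    params <- stats::setNames(
      rep(list(params), length(datasets)),
      vapply(datasets, `[[`, character(1), "tissue_label"))
  }
  y <- predictUptake(params, datasets, env)
  obs <- unlist(lapply(datasets, `[[`, "observed"))
  v <- unlist(lapply(datasets, `[[`, "variance"))
  sum((y - obs)^2 / v)
}

# Objective over the log-theta vector; invalid parameter sets map to a
# large finite penalty so bound-constrained optimizers stay in-domain.
thetaObjective <- function(log_theta, nms, bases, datasets, spec, env,
                           single) {
  theta <- stats::setNames(exp(log_theta), nms)
  pb <- tryCatch({
    lapply(bases, function(b)
      applyTheta(theta, b, spec, b$tissue_label, single))
  }, error = function(e) NULL)
  if (is.null(pb)) return(1e10)
  names(pb) <- vapply(bases, `[[`, character(1), "tissue_label")
  val <- tryCatch(wlsObjective(pb, datasets, env), error = function(e) NA)
  if (!is.finite(val)) 1e10 else val
}

#' Fit RaM parameters to uptake datasets
#'
#' Seeded multi-start bound-constrained local minimization (L-BFGS-B on
#' log-scaled parameters) of the variance-weighted least-squares objective.
#' The dependent rate is recomputed from detailed balance at every
#' evaluation; fixed parameters are pinned; shared parameters take a single
#' value across all tissue datasets (joint fitting as one concatenated
#' objective). Deterministic for a given seed.
#'
#' @param datasets one \code{experiment_dataset} or a list of them.
#' @param spec a \code{fit_spec}.
#' @param start a \code{ram_params} start point, or a named list of them
#'   keyed by tissue label for joint fits. Non-free fields supply the fixed
#'   structure of each tissue's model.
#' @param env a \code{membrane_env} object.
#' @param seed integer seed for the multi-start perturbations.
#' @return an object of class \code{ram_fit}: best parameters per tissue
#'   (\code{p_star}), best free-parameter vector (\code{theta_star}),
#'   \code{objective}, \code{converged} flag with optimizer diagnostics,
#'   normalized sensitivity matrix \code{S}, covariance \code{C},
#'   normalized 95% half-widths \code{delta}, and absolute intervals
#'   \code{ci}.
#' @export
fitRaM <- function(datasets, spec, start, env = membraneEnv(), seed = 1L) {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  tissues <- vapply(datasets, `[[`, character(1), "tissue_label")
  if (anyDuplicated(tissues))
    stop("datasets must have distinct tissue labels")
  if (inherits(start, "ram_params"))
    start <- stats::setNames(rep(list(start), length(tissues)), tissues)
  if (!all(tissues %in% names(start)))
    stop("'start' must provide parameters for every dataset tissue")
  bases <- lapply(tissues, function(tl) {
    b <- start[[tl]]; b$tissue_label <- tl; b
  })
  single <- length(tissues) == 1L
  n_rec <- sum(vapply(datasets, function(d) length(d$observed), integer(1)))
  nms <- thetaNames(spec, tissues)
  if (n_rec < length(nms))
    stop("need at least as many records as free parameters")
  theta0 <- thetaFromStart(start, spec, tissues)
  names(theta0) <- nms
  lower <- upper <- numeric(length(nms))
  for (i in seq_along(nms)) {
    base_nm <- sub("^.*:", "", nms[i])
    b <- if (!is.null(spec$bounds)) spec$bounds[[base_nm]] else NULL
    if (is.null(b)) b <- c(theta0[i] / 100, theta0[i] * 100)
    lower[i] <- log(b[1]); upper[i] <- log(b[2])
  }
  obj <- function(lt) thetaObjective(lt, nms, bases, datasets, spec, env,
                                     single)
  set.seed(seed)
  starts <- list(log(theta0))
  if (spec$n_starts > 1L) {
    for (k in seq_len(spec$n_starts - 1L)) {
      pert <- log(theta0) + log(1 + stats::runif(length(nms),
                                                 -spec$start_spread,
                                                 spec$start_spread))
      starts[[k + 1L]] <- pmin(pmax(pert, lower), upper)
    }
  }
  best <- NULL
  diagnostics <- character(0)
  # the steep Hill thresholds (n = 24) carve canyon-shaped objectives whose
  # cliffs defeat gradient line searches started off-canyon; a Nelder-Mead
  # walk first, then an L-BFGS-B polish inside the canyon
  objBounded <- function(lt) {
    if (any(lt < lower) || any(lt > upper)) return(1e10)
    obj(lt)
  }
  for (s in starts) {
    fit <- tryCatch({
      nm <- stats::optim(s, objBounded, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
      stats::optim(pmin(pmax(nm$par, lower), upper), obj,
                   method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500L, factr = 10,
                                  ndeps = rep(1e-7, length(s))))
    }, error = function(e) NULL)
    if (is.null(fit)) { diagnostics <- c(diagnostics, "start failed"); next }
    diagnostics <- c(diagnostics,
                     sprintf("value %.3g, convergence %d", fit$value,
                             fit$convergence))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, diagnostics = diagnostics,
                          p_star = start, objective = NA_real_),
                     class = "ram_fit"))
  }
  theta_star <- stats::setNames(exp(best$par), nms)
  p_star <- lapply(bases, function(b)
    applyTheta(theta_star, b, spec, b$tissue_label, single))
  names(p_star) <- tissues
  S <- sensitivityMatrix(p_star, datasets, spec, env)
  cc <- covarianceCI(S, theta_star)
  structure(
    list(p_star = p_star, theta_star = theta_star,
         objective = best$value,
         converged = best$convergence == 0,
         diagnostics = diagnostics,
         S = S, C = cc$C, delta = cc$delta, ci = cc$ci,
         unidentifiable = cc$unidentifiable),
    class = "ram_fit")
}

#' @export
print.ram_fit <- function(x, ...) {
  cat(sprintf("RaM weighted least-squares fit: objective %.4g (%s)\n",
              x$objective,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$ci)) {
    cat("  95% confidence intervals (Cramer-Rao):\n")
    for (i in seq_len(nrow(x$ci)))
      cat(sprintf("    %-16s %.4g  [%.4g, %.4g]\n", rownames(x$ci)[i],
                  x$ci$estimate[i], x$ci$lower[i], x$ci$upper[i]))
  }
  if (length(x$unidentifiable))
    cat("  unidentifiable (excluded from covariance):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Normalized finite-difference sensitivity matrix
#'
#' Rows are model outputs normalized by the experimental standard
#' deviation (\code{y_k / sigma_k}, concatenated over datasets and
#' records); columns are free parameters normalized by their best value:
#' \code{S[k, l] = p*_l d(y_k / sigma_k) / d p_l}, computed by central
#' finite differences with relative step \code{spec$fd_relative_step}. The
#' double normalization is what keeps the Fisher information matrix
#' well-conditioned across parameters spanning eight orders of magnitude.
#' The detailed-balance dependent rate is recomputed at each perturbed
#' point.
#'
#' @param p_star named list of best-fit \code{ram_params} by tissue (or a
#'   single \code{ram_params}).
#' @param datasets one \code{experiment_dataset} or a list of them.
#' @param spec a \code{fit_spec}.
#' @param env a \code{membrane_env} object.
#' @return matrix with one row per record and one column per free
#'   parameter (named).
#' @export
sensitivityMatrix <- function(p_star, datasets, spec, env = membraneEnv()) {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  tissues <- vapply(datasets, `[[`, character(1), "tissue_label")
  if (inherits(p_star, "ram_params"))
    p_star <- stats::setNames(rep(list(p_star), length(tissues)), tissues)
  single <- length(tissues) == 1L
  nms <- thetaNames(spec, tissues)
  theta <- vapply(nms, function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) p_star[[parts[1]]][[parts[2]]]
    else p_star[[1]][[nm]]
  }, numeric(1))
  names(theta) <- nms
  bases <- lapply(tissues, function(tl) p_star[[tl]])
  sigma <- sqrt(unlist(lapply(datasets, `[[`, "variance")))
  normOut <- function(th) {
    pb <- lapply(seq_along(bases), function(i)
      applyTheta(th, bases[[i]], spec, tissues[i], single))
    names(pb) <- tissues
    predictUptake(pb, datasets, env) / sigma
  }
  S <- matrix(0, nrow = length(sigma), ncol = length(nms),
              dimnames = list(NULL, nms))
  for (l in seq_along(nms)) {
    h <- spec$fd_relative_step * theta[l]
    if (h == 0 || theta[l] + h == theta[l])
      stop(sprintf("finite-difference step underflow for '%s'", nms[l]))
    up <- theta; up[l] <- theta[l] + h
    dn <- theta; dn[l] <- theta[l] - h
    S[, l] <- theta[l] * (normOut(up) - normOut(dn)) / (2 * h)
  }
  S
}

#' Fisher-information covariance and Cramer-Rao 95% intervals
#'
#' Approximates the parameter covariance as \code{C = (S'S)^-1} from the
#' normalized sensitivity matrix. When \code{S'S} is (near-)singular the
#' Moore-Penrose pseudo-inverse is used instead, with a warning naming the
#' unidentifiable parameters (those loading on the discarded directions);
#' their rows of the interval table are set to NA. The normalized 95%
#' half-width is \code{delta_l = 1.96 sqrt(C_ll)} and the absolute interval
#' \code{p*_l (1 +/- delta_l)}; a negative lower bound is replaced by
#' \code{1e-3 p*_l} (rates are positive, so a Gaussian interval crossing
#' zero only says the data cannot resolve how small the rate is).
#'
#' @param S normalized sensitivity matrix (columns named by parameter).
#' @param p_star named numeric vector of best values matching the columns.
#' @return list with covariance \code{C}, normalized half-widths
#'   \code{delta}, data.frame \code{ci} (estimate, lower, upper) and the
#'   character vector \code{unidentifiable}.
#' @export
covarianceCI <- function(S, p_star) {
  if (is.null(dim(S)) || nrow(S) == 0L || ncol(S) == 0L)
    stop("'S' must be a non-empty matrix")
  p_star <- p_star[colnames(S)]
  sv <- svd(S)
  tol <- max(sv$d) * 1e-10
  keep <- sv$d > tol
  unident <- character(0)
  if (!all(keep)) {
    null_load <- apply(abs(sv$v[, !keep, drop = FALSE]), 1, max)
    unident <- colnames(S)[null_load > 1e-8]
    warning("singular information matrix; pseudo-inverse used; ",
            "unidentifiable: ", paste(unident, collapse = ", "))
  }
  Vr <- sv$v[, keep, drop = FALSE]
  C <- Vr %*% diag(1 / sv$d[keep]^2, sum(keep)) %*% t(Vr)
  dimnames(C) <- list(colnames(S), colnames(S))
  delta <- 1.96 * sqrt(pmax(diag(C), 0))
  lower <- p_star * (1 - delta)
  neg <- lower < 0
  lower[neg] <- 1e-3 * p_star[neg]
  upper <- p_star * (1 + delta)
  if (length(unident)) {
    delta[unident] <- NA_real_
    lower[unident] <- NA_real_
    upper[unident] <- NA_real_
  }
  list(C = C, delta = delta,
       ci = data.frame(estimate = p_star, lower = lower, upper = upper,
                       row.names = names(p_star)),
       unidentifiable = unident)
}

#' Generate a synthetic uptake dataset
#'
#' Simulates each protocol with the true parameters and applies seeded
#' multiplicative Gaussian noise, \code{obs = y (1 + eps)} with
#' \code{eps ~ N(0, noise_cv^2)}, emulating the constant-coefficient-of-
#' variation error structure of stopped-flow uptake measurements. The
#' stored variance is \code{(noise_cv y)^2} floored at \code{var_floor},
#' representing the absolute detection noise of the uptake assay, so that
#' near-zero-uptake records (sub-threshold pulses) carry realistic rather
#' than unbounded weight.
#'
#' @param p_true a \code{ram_params} object.
#' @param protocols list of \code{pulse_protocol} objects.
#' @param noise_cv coefficient of variation of the noise (>= 0).
#' @param seed integer seed; the dataset is bit-identical on repeat.
#' @param env a \code{membrane_env} object.
#' @param tissue_label label for the generated dataset.
#' @param var_floor absolute variance floor, (nmol/mg)^2; default
#'   (0.005)^2, a 0.005 nmol/mg assay detection floor.
#' @return an \code{experiment_dataset}.
#' @export
synthesizeDataset <- function(p_true, protocols, noise_cv, seed = 1L,
                              env = membraneEnv(),
                              tissue_label = p_true$tissue_label,
                              var_floor = 2.5e-5) {
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  if (var_floor <= 0) stop("'var_floor' must be > 0")
  y <- vapply(protocols, protocolPulseUptake, numeric(1), p = p_true,
              env = env)
  set.seed(seed)
  eps <- if (noise_cv > 0) stats::rnorm(length(y), 0, noise_cv) else
    numeric(length(y))
  experimentDataset(protocols, y * (1 + eps),
                    pmax((noise_cv * y)^2, var_floor), tissue_label)
}
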