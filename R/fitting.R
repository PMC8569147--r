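# Weighted linear least-squares fitting of 2B/3B PIP coefficients to
# reference n-body energies. The targets are short-range residuals: the
# backend's n-body energy minus the n-body part already supplied by the
# model's permanent electrostatics, dispersion and induction, so the PIP
# term only has to represent what the long-range physics misses.

#' Low-energy emphasis weights for training configurations
#'
#' w = (dE_w / (E - E_min + dE_w))^2: unity at the minimum target energy
#' and strictly decreasing with E.
#'
#' @param E target energies, kcal/mol.
#' @param E_min reference minimum (default \code{min(E)}); every E must be
#'   >= E_min.
#' @param dE_w softness scale, kcal/mol (> 0).
#' @return Weights in (0, 1].
#' @export
training_weights <- function(E, E_min = min(E), dE_w = 25) {
  if (dE_w <= 0) stop("dE_w must be positive")
  if (any(E < E_min)) stop("all energies must be >= E_min")
  (dE_w / (E - E_min + dE_w))^2
}

strip_pip <- function(model, order) {
  if (order == 2) model$pip2b <- NULL else model$pip3b <- NULL
  model
}

#' Build a PIP training set from a backend and a base model
#'
#' For each dimer (order 2) or trimer (order 3), the target is the
#' backend's n-body energy (via the exact many-body decomposition) minus
#' the n-body energy of the model with the PIP term of that order removed,
#' i.e. the short-range residual the PIP must represent.
#'
#' @param configs list of dimer/trimer \code{mbpef_cluster}s.
#' @param backend reference \code{mbpef_backend}.
#' @param model base \code{mbpef_model} whose long-range parameters are
#'   held fixed.
#' @param order 2 or 3.
#' @param dE_w weighting scale passed to \code{\link{training_weights}}.
#' @return An object of class \code{mbpef_training_set}: list with
#'   \code{configs}, \code{targets}, \code{backend_nbody},
#'   \code{model_nbody}, \code{weights} and \code{order}.
#' @export
build_targets <- function(configs, backend, model, order, dE_w = 25) {
  if (!order %in% c(2, 3)) stop("order must be 2 or 3")
  for (cl in configs)
    if (cl$n_monomers != order)
      stop(sprintf("order-%d fitting needs %d-monomer configurations",
                   order, order))
  lr_backend <- pef_backend(strip_pip(model, order))
  key <- subset_key(seq_len(order) - 1L)
  eb <- numeric(length(configs))
  em <- numeric(length(configs))
  for (i in seq_along(configs)) {
    eb[i] <- nbody_decompose(configs[[i]], backend)$terms[[key]]
    em[i] <- nbody_decompose(configs[[i]], lr_backend)$terms[[key]]
  }
  targets <- eb - em
  structure(list(configs = configs, targets = targets, backend_nbody = eb,
                 model_nbody = em,
                 weights = training_weights(eb, dE_w = dE_w),
                 order = as.integer(order)),
            class = "mbpef_training_set")
}

#' @export
print.mbpef_training_set <- function(x, ...) {
  cat(sprintf("<mbpef_training_set: %dB, %d configurations, target range [%.3f, %.3f] kcal/mol>\n",
              x$order, length(x$configs), min(x$targets), max(x$targets)))
  invisible(x)
}

#' Design matrix of a PIP basis over a set of configurations
#'
#' Row i is the switch-weighted vector of symmetrized basis functions at
#' configuration i, exactly as the PEF evaluates the term.
#'
#' @param basis an \code{mbpef_pip_basis}.
#' @param configs list of clusters with \code{basis$nmon} monomers.
#' @return Numeric matrix (configurations x basis functions).
#' @export
pip_design_matrix <- function(basis, configs) {
  xis <- t(vapply(configs, function(cl) pip_xi(basis, cl$coords),
                  numeric(basis$nvar)))
  Phi <- pip_design_cpp(xis, basis)
  sw <- vapply(configs, function(cl) pip_switch(basis, cl$coords),
               numeric(1))
  Phi * sw
}

#' Fit PIP coefficients by weighted ridge-regularized least squares
#'
#' Minimizes sum_i w_i (y_i - Phi_i . c)^2 + lambda_eff |c|^2, solved by
#' singular-value decomposition (rank-revealing, deterministic). The ridge
#' strength is \code{lambda} scaled by the mean diagonal of the weighted
#' normal matrix.
#'
#' @param training an \code{mbpef_training_set} (or any list with
#'   \code{configs}, \code{targets}, \code{weights}).
#' @param basis the \code{mbpef_pip_basis} to fit.
#' @param lambda relative ridge parameter (0 for an unregularized fit).
#' @return If the fitted term's predictions never exceed 1e-8 kcal/mol on
#'   the training set, the coefficients are collapsed to exact zeros (the
#'   term is numerically absent and evaluators can skip it).
#'   An object of class \code{mbpef_fit}: \code{coef},
#'   \code{lambda}, \code{lambda_eff}, \code{condition} (design-matrix
#'   condition number), \code{basis}, and training \code{mue}/\code{rmse}.
#' @export
fit_linear <- function(training, basis, lambda = 1e-6) {
  y <- training$targets
  w <- training$weights
  if (is.null(w)) w <- rep(1, length(y))
  if (length(y) < basis$norbit && lambda == 0)
    stop("fewer configurations than basis functions; use lambda > 0")
  Phi <- pip_design_matrix(basis, training$configs)
  sw <- sqrt(w)
  Phiw <- Phi * sw
  yw <- y * sw
  # column equilibration: unit RMS columns for a well-scaled decomposition
  cs <- sqrt(colMeans(Phiw^2))
  cs[cs == 0] <- 1
  Phis <- sweep(Phiw, 2, cs, `/`)
  sv <- svd(Phis)
  if (lambda == 0 && min(sv$d) < max(sv$d) * 1e-12)
    stop("design matrix is numerically rank-deficient; use lambda > 0")
  # ridge relative to the mean diagonal of the per-row normal matrix
  lambda_eff <- lambda * mean(colMeans(Phis^2))
  shrink <- sv$d / (sv$d^2 + lambda_eff)
  coef <- (sv$v %*% (shrink * crossprod(sv$u, yw))) / cs
  pred <- as.numeric(Phi %*% coef)
  # a term whose predictions never exceed numerical noise is exactly zero;
  # representing it as such lets the evaluator skip it
  if (length(pred) && max(abs(pred)) < 1e-8) {
    coef[] <- 0
    pred[] <- 0
  }
  res <- y - pred
  structure(list(coef = as.numeric(coef), lambda = lambda,
                 lambda_eff = lambda_eff,
                 condition = max(sv$d) / min(sv$d),
                 basis = basis,
                 train_mue = mean(abs(res)),
                 train_rmse = sqrt(mean(res^2)),
                 n_train = length(y)),
            class = "mbpef_fit")
}

#' @export
print.mbpef_fit <- function(x, ...) {
  cat(sprintf("<mbpef_fit: %d coefficients, train MUE %.4g / RMSE %.4g kcal/mol, cond %.3g>\n",
              length(x$coef), x$train_mue, x$train_rmse, x$condition))
  invisible(x)
}

#' Held-out error report for a fitted PIP term
#'
#' Recomputes residuals on an independent set and reports MUE and RMSE,
#' overall and restricted to configurations whose reference n-body energy
#' magnitude is at most \code{threshold}.
#'
#' @param fit an \code{mbpef_fit}.
#' @param heldout an \code{mbpef_training_set} disjoint from the training
#'   data.
#' @param threshold low-energy window, kcal/mol.
#' @return Data frame with columns \code{subset}, \code{n}, \code{mue},
#'   \code{rmse}.
#' @export
fit_report <- function(fit, heldout, threshold = 25) {
  if (length(heldout$configs) == 0) stop("held-out set is empty")
  Phi <- pip_design_matrix(fit$basis, heldout$configs)
  res <- heldout$targets - as.numeric(Phi %*% fit$coef)
  sel <- abs(heldout$backend_nbody) <= threshold
  stat <- function(r) c(mue = mean(abs(r)), rmse = sqrt(mean(r^2)))
  all_s <- stat(res)
  low_s <- if (any(sel)) stat(res[sel]) else c(mue = NA_real_, rmse = NA_real_)
  data.frame(subset = c("all", sprintf("|E| <= %g", threshold)),
             n = c(length(res), sum(sel)),
             mue = c(all_s["mue"], low_s["mue"]),
             rmse = c(all_s["rmse"], low_s["rmse"]),
             row.names = NULL)
}

#' Seeded train/held-out split stratified by target energy quartile
#'
#' @param training an \code{mbpef_training_set}.
#' @param heldout_fraction fraction of rows held out.
#' @param seed RNG seed.
#' @return List with \code{train} and \code{heldout} training sets.
#' @export
split_training_set <- function(training, heldout_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  n <- length(training$targets)
  qs <- stats::quantile(training$targets, c(0.25, 0.5, 0.75))
  strat <- findInterval(training$targets, qs) + 1L
  hold <- logical(n)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    nh <- max(1L, round(heldout_fraction * length(idx)))
    hold[sample(idx, nh)] <- TRUE
  }
  take <- function(sel) {
    out <- training
    out$configs <- training$configs[sel]
    out$targets <- training$targets[sel]
    out$backend_nbody <- training$backend_nbody[sel]
    out$model_nbody <- training$model_nbody[sel]
    out$weights <- training$weights[sel]
    out
  }
  list(train = take(!hold), heldout = take(hold))
}

#' Fit a 2B or 3B PIP term end to end and attach it to the model
#'
#' Convenience wrapper: builds targets against the backend, splits off a
#' held-out fraction, fits, reports, and returns the updated model.
#'
#' @inheritParams build_targets
#' @param basis the \code{mbpef_pip_basis} to fit.
#' @param lambda ridge parameter for \code{\link{fit_linear}}.
#' @param heldout_fraction,seed split controls.
#' @return List with \code{model} (PIP attached), \code{fit},
#'   \code{report} (held-out \code{\link{fit_report}}) and \code{split}.
#' @export
fit_pip_term <- function(configs, backend, model, order, basis,
                         lambda = 1e-6, heldout_fraction = 0.1, seed = 1L,
                         dE_w = 25) {
  ts <- build_targets(configs, backend, model, order, dE_w = dE_w)
  sp <- split_training_set(ts, heldout_fraction, seed)
  fit <- fit_linear(sp$train, basis, lambda)
  rep <- fit_report(fit, sp$heldout)
  list(model = set_pip_term(model, order, basis, fit$coef),
       fit = fit, report = rep, split = sp)
}
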