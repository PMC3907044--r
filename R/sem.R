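# Bayesian structural equation model: latent traffic pollution measured by
# four pollutant indicators, latent parasympathetic tone measured by three
# log HRV markers, log LF/HF as a directly observed outcome, subject-level
# random intercepts, and optional traffic-by-modifier interactions. The
# model is linear-Gaussian throughout, so the sampler is a blocked Gibbs
# with fully conjugate (Normal/Gamma) conditionals.

#' Prior specification
#'
#' Vague conjugate priors: Normal(0, `v_coef`) on every free intercept,
#' loading and regression coefficient, and Gamma(`shape`, `rate`) on every
#' precision (measurement, latent, residual and random-intercept).
#'
#' @param v_coef prior variance of coefficients (default 1e6).
#' @param shape,rate Gamma prior on precisions (default 0.001, 0.001).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(v_coef = 1e6, shape = 0.001, rate = 0.001) {
  if (v_coef <= 0 || shape <= 0 || rate <= 0)
    stop("prior_spec: v_coef, shape and rate must be positive")
  structure(list(v_coef = v_coef, shape = shape, rate = rate),
            class = "prior_spec")
}

#' Structural equation model specification
#'
#' @param window moving-average window (hours) this fit corresponds to
#'   (metadata; each window is a separate fit).
#' @param outcome `"parasympathetic"` (latent tone measured by the HRV
#'   markers), `"lfhf"` (observed log LF/HF), or `"joint"` (both structural
#'   equations sharing one traffic latent).
#' @param pollutants indicator columns of the latent traffic exposure.
#' @param markers indicator columns of the latent parasympathetic tone.
#' @param reference_pollutant,reference_marker indicators whose loadings are
#'   fixed at 1 to set the latent scales (defaults: BC and log HF).
#' @param covariates fixed covariate columns of the structural equations.
#' @param modifier optional dichotomous visit-table column; adds a
#'   traffic-by-modifier interaction to each structural equation.
#' @param priors a [prior_spec()].
#' @param chains,iter,burnin,thin MCMC settings (defaults 2 chains of
#'   20000 iterations, 10000 burn-in, no thinning).
#' @param seed integer seed; chain c uses `seed + 7919 * (c - 1)`.
#' @param store_scores also keep thinned draws of the latent scores.
#' @param observed_latents treat the single pollutant indicator as the
#'   latent traffic score and the single marker as (intercept-shifted)
#'   parasympathetic tone, i.e. the zero-measurement-error limit in which
#'   the model collapses to a linear mixed model.
#' @return list of class `sem_spec`.
#' @export
sem_spec <- function(window = 24L,
                     outcome = c("parasympathetic", "lfhf", "joint"),
                     pollutants = .POLLUTANTS,
                     markers = .MARKERS,
                     reference_pollutant = "bc",
                     reference_marker = "log_hf",
                     covariates = .COVARIATES,
                     modifier = NULL,
                     priors = prior_spec(),
                     chains = 2L, iter = 20000L, burnin = 10000L, thin = 1L,
                     seed = 1L, store_scores = FALSE,
                     observed_latents = FALSE) {
  outcome <- match.arg(outcome)
  if (!reference_pollutant %in% pollutants)
    stop("reference_pollutant must be among pollutants")
  if (outcome != "lfhf" && !reference_marker %in% markers)
    stop("reference_marker must be among markers")
  if (iter <= burnin) stop("iter must exceed burnin")
  if (observed_latents &&
      (length(pollutants) != 1 ||
       (outcome != "lfhf" && length(markers) != 1)))
    stop("observed_latents requires a single pollutant (and single marker)")
  structure(list(window = window, outcome = outcome, pollutants = pollutants,
                 markers = markers,
                 reference_pollutant = reference_pollutant,
                 reference_marker = reference_marker,
                 covariates = covariates, modifier = modifier,
                 priors = priors, chains = as.integer(chains),
                 iter = as.integer(iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 store_scores = isTRUE(store_scores),
                 observed_latents = isTRUE(observed_latents)),
            class = "sem_spec")
}

#' Assemble the model state
#'
#' Joins the per-window exposure design to the visit table, applies the
#' complete-case rule (visits missing any indicator or covariate are dropped
#' for this window's fit, with a message), builds the internal
#' participant/visit index maps, and initializes nothing stochastic: the
#' returned object carries data, dimensions and flags only until a chain
#' seeds its state.
#'
#' @param design one window's data.frame from [build_exposure_design()] or
#'   [design_from_cohort()].
#' @param visits the visit table.
#' @param spec a [sem_spec()].
#' @return list of class `sem_model` with elements `dat` (matrices and index
#'   maps), `spec`, `state` (NULL until initialized).
#' @export
build_sem <- function(design, visits, spec) {
  stopifnot(inherits(spec, "sem_spec"))
  has_para <- spec$outcome %in% c("parasympathetic", "joint")
  has_lfhf <- spec$outcome %in% c("lfhf", "joint")
  vcols <- unique(c("visit_id", spec$covariates,
                    if (has_para) spec$markers,
                    if (has_lfhf) "log_lfhf",
                    spec$modifier))
  missing_cols <- setdiff(vcols, names(visits))
  if (length(missing_cols) > 0)
    stop("visit table lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- merge(design, visits[, vcols], by = "visit_id")
  if (nrow(d) == 0) stop("design and visit table share no visits")
  d <- d[order(d$visit_id), ]
  need <- c(spec$pollutants, spec$covariates, .SEASONAL,
            if (has_para) spec$markers, if (has_lfhf) "log_lfhf",
            spec$modifier)
  ok <- complete.cases(d[, need])
  if (any(!ok))
    message("build_sem: dropping ", sum(!ok), " incomplete visits")
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 complete visits")
  upart <- unique(d$participant)
  pidx <- match(d$participant, upart)
  ni <- tabulate(pidx, nbins = length(upart))
  singleton_grouping <- max(ni) == 1
  if (singleton_grouping)
    warning("all participants have a single visit: random-intercept ",
            "variance is not identified from the data")
  M <- NULL
  if (!is.null(spec$modifier)) {
    M <- as.numeric(d[[spec$modifier]])
    if (!all(M %in% c(0, 1)))
      stop("modifier '", spec$modifier, "' must be dichotomous 0/1")
    if (length(unique(M)) < 2)
      stop("modifier '", spec$modifier, "' is constant in the sample")
    ng <- min(sum(M == 1), sum(M == 0))
    if (ng == 1)
      warning("a modifier subgroup has a single visit; expect very wide ",
              "group-specific intervals")
  }
  # the covariate block is centered internally: with no structural
  # intercepts (gamma0 = delta0 = 0) and raw covariates of large mean, a
  # near-constant covariate direction trades off against the latent
  # location and mixes pathologically; centering removes the ridge and
  # leaves every slope, loading and precision invariant (alpha0 is then
  # the marker mean at average covariate values)
  W <- as.matrix(d[, c(spec$covariates, .SEASONAL)])
  W_center <- colMeans(W)
  W <- sweep(W, 2, W_center)
  dat <- list(
    n = nrow(d), npart = length(upart), pidx = pidx, ni = ni,
    visit_id = d$visit_id, participant = d$participant,
    Xp = as.matrix(d[, spec$pollutants, drop = FALSE]),
    Y = if (has_para) as.matrix(d[, spec$markers, drop = FALSE]) else NULL,
    L = if (has_lfhf) d$log_lfhf else NULL,
    W = W, W_center = W_center,
    Z = as.matrix(d[, .SEASONAL]),
    M = M,
    refj = match(spec$reference_pollutant, spec$pollutants),
    refk = if (has_para) match(spec$reference_marker, spec$markers) else NA,
    iqr_ref = unname(diff(quantile(d[[spec$reference_pollutant]],
                                   c(0.25, 0.75)))))
  dat$ZtZ <- crossprod(dat$Z)
  structure(list(dat = dat, spec = spec, state = NULL,
                 has_para = has_para, has_lfhf = has_lfhf,
                 obs_latent = spec$observed_latents,
                 singleton_grouping = singleton_grouping),
            class = "sem_model")
}

# ---- state initialization -------------------------------------------------

.gamma_names <- function(model, eq = c("gamma", "delta")) {
  eq <- match.arg(eq)
  c(if (eq == "gamma" && model$obs_latent) "intercept",
    "traffic",
    if (!is.null(model$dat$M)) "traffic_int",
    colnames(model$dat$W))
}

.init_state <- function(model) {
  d <- model$dat; spec <- model$spec
  J <- ncol(d$Xp); K <- if (!is.null(d$Y)) ncol(d$Y) else 0L
  jit <- function(k) rnorm(k, 0, 0.1)
  s <- list()
  if (model$obs_latent) {
    s$T <- unname(d$Xp[, 1])
  } else {
    s$T <- unname(d$Xp[, d$refj] - mean(d$Xp[, d$refj]))
    s$lam0 <- colMeans(d$Xp) + jit(J)
    s$lam1 <- rep(1, J) + jit(J)
    s$lam1[d$refj] <- 1
    s$tau_x <- rep(1, J)
    s$phi <- jit(4)
    s$tau_t <- 1
    names(s$lam0) <- names(s$lam1) <- names(s$tau_x) <- spec$pollutants
    names(s$phi) <- .SEASONAL
  }
  if (model$has_para) {
    if (!model$obs_latent) {
      s$P <- unname(d$Y[, d$refk] - mean(d$Y[, d$refk]))
      s$al0 <- colMeans(d$Y) + jit(K)
      s$al1 <- rep(1, K) + jit(K)
      s$al1[d$refk] <- 1
      s$tau_y <- rep(1, K)
      names(s$al0) <- names(s$al1) <- names(s$tau_y) <- spec$markers
    }
    gn <- .gamma_names(model, "gamma")
    s$gamma <- setNames(jit(length(gn)), gn)
    s$a <- rep(0, d$npart)
    s$tau_a <- 1
    s$tau_p <- 1
  }
  if (model$has_lfhf) {
    dn <- .gamma_names(model, "delta")
    s$delta <- setNames(jit(length(dn)), dn)
    s$b <- rep(0, d$npart)
    s$tau_b <- 1
    s$tau_l <- 1
  }
  s
}

# traffic slope per visit for one structural equation
.slope_vec <- function(state, dat, eq) {
  g <- state[[eq]]
  sl <- g[["traffic"]]
  if (!is.null(dat$M) && "traffic_int" %in% names(g))
    sl <- sl + g[["traffic_int"]] * dat$M
  sl
}

# fixed (non-traffic) part of a structural mean, excluding random intercepts
.fixed_part <- function(state, dat, eq) {
  g <- state[[eq]]
  out <- as.numeric(dat$W %*% g[colnames(dat$W)])
  if ("intercept" %in% names(g)) out <- out + g[["intercept"]]
  out
}

# ---- block updates --------------------------------------------------------

.up_latent_traffic <- function(model) {
  d <- model$dat; s <- model$state
  prec <- s$tau_t + sum(s$lam1^2 * s$tau_x)
  num <- s$tau_t * as.numeric(d$Z %*% s$phi) +
    as.numeric(d$Xp %*% (s$lam1 * s$tau_x)) - sum(s$lam1 * s$tau_x * s$lam0)
  prec <- rep(prec, d$n)
  if (model$has_para) {
    sl <- .slope_vec(s, d, "gamma")
    r <- s$P - .fixed_part(s, d, "gamma") - s$a[d$pidx]
    num <- num + s$tau_p * sl * r
    prec <- prec + s$tau_p * sl^2
  }
  if (model$has_lfhf) {
    sl <- .slope_vec(s, d, "delta")
    r <- d$L - .fixed_part(s, d, "delta") - s$b[d$pidx]
    num <- num + s$tau_l * sl * r
    prec <- prec + s$tau_l * sl^2
  }
  model$state$T <- .draw_norm_prec(prec, num)
  model
}

.up_latent_para <- function(model) {
  d <- model$dat; s <- model$state
  sl <- .slope_vec(s, d, "gamma")
  mu_struct <- sl * s$T + .fixed_part(s, d, "gamma") + s$a[d$pidx]
  prec <- s$tau_p + sum(s$al1^2 * s$tau_y)
  num <- s$tau_p * mu_struct +
    as.numeric(d$Y %*% (s$al1 * s$tau_y)) - sum(s$al1 * s$tau_y * s$al0)
  model$state$P <- .draw_norm_prec(rep(prec, d$n), num)
  model
}

.up_loadings <- function(model, side = c("x", "y")) {
  side <- match.arg(side)
  d <- model$dat; s <- model$state
  pc <- 1 / model$spec$priors$v_coef
  if (side == "x") {
    lat <- s$T; obs <- d$Xp; ref <- d$refj
    i0 <- "lam0"; i1 <- "lam1"; tau <- s$tau_x
  } else {
    lat <- s$P; obs <- d$Y; ref <- d$refk
    i0 <- "al0"; i1 <- "al1"; tau <- s$tau_y
  }
  n <- d$n; sl <- sum(lat); sll <- sum(lat^2)
  for (j in seq_len(ncol(obs))) {
    if (j == ref) {
      prec <- n * tau[j] + pc
      num <- tau[j] * (sum(obs[, j]) - sl)
      model$state[[i0]][j] <- .draw_norm_prec(prec, num)
    } else {
      A <- tau[j] * matrix(c(n, sl, sl, sll), 2) + pc * diag(2)
      bb <- tau[j] * c(sum(obs[, j]), sum(obs[, j] * lat))
      th <- .draw_mvn_prec(A, bb)
      model$state[[i0]][j] <- th[1]
      model$state[[i1]][j] <- th[2]
    }
  }
  model
}

.up_phi <- function(model) {
  d <- model$dat; s <- model$state
  pc <- 1 / model$spec$priors$v_coef
  A <- s$tau_t * d$ZtZ + pc * diag(4)
  bb <- s$tau_t * crossprod(d$Z, s$T)
  model$state$phi <- setNames(.draw_mvn_prec(A, bb), .SEASONAL)
  model
}

.structural_design <- function(model, eq) {
  d <- model$dat
  cols <- list()
  if (eq == "gamma" && model$obs_latent) cols$intercept <- rep(1, d$n)
  cols$traffic <- model$state$T
  if (!is.null(d$M)) cols$traffic_int <- model$state$T * d$M
  cbind(do.call(cbind, cols), d$W)
}

.outcome_response <- function(model, eq) {
  if (eq == "gamma") {
    if (model$obs_latent) model$dat$Y[, 1] else model$state$P
  } else model$dat$L
}

.up_structural <- function(model, eq) {
  d <- model$dat; s <- model$state
  pc <- 1 / model$spec$priors$v_coef
  tau <- if (eq == "gamma") s$tau_p else s$tau_l
  u <- if (eq == "gamma") s$a else s$b
  D <- .structural_design(model, eq)
  r <- .outcome_response(model, eq) - u[d$pidx]
  A <- tau * crossprod(D)
  diag(A) <- diag(A) + pc
  bb <- tau * crossprod(D, r)
  model$state[[eq]] <- setNames(.draw_mvn_prec(A, bb), colnames(D))
  model
}

.struct_resid <- function(model, eq, with_u = TRUE) {
  d <- model$dat; s <- model$state
  sl <- .slope_vec(s, d, eq)
  r <- .outcome_response(model, eq) - sl * s$T - .fixed_part(s, d, eq)
  if (with_u) {
    u <- if (eq == "gamma") s$a else s$b
    r <- r - u[d$pidx]
  }
  r
}

.up_intercepts <- function(model, eq) {
  d <- model$dat; s <- model$state
  tau <- if (eq == "gamma") s$tau_p else s$tau_l
  tau_u <- if (eq == "gamma") s$tau_a else s$tau_b
  r <- .struct_resid(model, eq, with_u = FALSE)
  sums <- rowsum(r, d$pidx)[, 1]
  prec <- tau_u + d$ni * tau
  u <- .draw_norm_prec(prec, tau * sums)
  if (eq == "gamma") model$state$a <- u else model$state$b <- u
  model
}

.up_precisions <- function(model) {
  d <- model$dat; s <- model$state
  pr <- model$spec$priors
  draw <- function(n_eff, ss) rgamma(1, pr$shape + n_eff / 2, pr$rate + ss / 2)
  if (!model$obs_latent) {
    for (j in seq_len(ncol(d$Xp))) {
      ss <- sum((d$Xp[, j] - s$lam0[j] - s$lam1[j] * s$T)^2)
      model$state$tau_x[j] <- draw(d$n, ss)
    }
    model$state$tau_t <- draw(d$n, sum((s$T - as.numeric(d$Z %*% s$phi))^2))
    if (model$has_para) {
      for (k in seq_len(ncol(d$Y))) {
        ss <- sum((d$Y[, k] - s$al0[k] - s$al1[k] * s$P)^2)
        model$state$tau_y[k] <- draw(d$n, ss)
      }
    }
  }
  if (model$has_para) {
    model$state$tau_p <- draw(d$n, sum(.struct_resid(model, "gamma")^2))
    model$state$tau_a <- draw(d$npart, sum(model$state$a^2))
  }
  if (model$has_lfhf) {
    model$state$tau_l <- draw(d$n, sum(.struct_resid(model, "delta")^2))
    model$state$tau_b <- draw(d$npart, sum(model$state$b^2))
  }
  model
}

#' One full Gibbs sweep
#'
#' Updates, from their closed-form full conditionals: the latent traffic
#' score at every visit (Gaussian, combining its seasonal prior, the
#' pollutant-indicator likelihoods, and the structural-outcome likelihoods,
#' with slope `gamma1 + gamma_int * M` under a modifier), the latent
#' parasympathetic score, the free loadings and intercepts (Gaussian,
#' reference loadings held at 1), the seasonal and structural coefficient
#' blocks (joint Gaussian), the random intercepts, and all precisions
#' (Gamma). A subset of blocks may be requested, e.g. to draw repeatedly
#' from one conditional while the rest of the state is held fixed.
#'
#' @param model a [build_sem()] model whose `state` is set (either by
#'   [fit_sem()] internals or manually).
#' @param blocks `"all"` or a subset of `c("latent_traffic", "latent_para",
#'   "loadings_x", "loadings_y", "phi", "gamma", "a", "delta", "b",
#'   "precisions")`.
#' @return the model with an updated state.
#' @export
gibbs_step <- function(model, blocks = "all") {
  stopifnot(inherits(model, "sem_model"))
  if (is.null(model$state)) model$state <- .init_state(model)
  all_blocks <- c(
    if (!model$obs_latent) c("latent_traffic",
                             if (model$has_para) "latent_para",
                             "loadings_x",
                             if (model$has_para) "loadings_y",
                             "phi"),
    if (model$has_para) c("gamma", "a"),
    if (model$has_lfhf) c("delta", "b"),
    "precisions")
  todo <- if (identical(blocks, "all")) all_blocks else
    intersect(all_blocks, blocks)
  for (blk in todo) {
    model <- switch(blk,
      latent_traffic = .up_latent_traffic(model),
      latent_para = .up_latent_para(model),
      loadings_x = .up_loadings(model, "x"),
      loadings_y = .up_loadings(model, "y"),
      phi = .up_phi(model),
      gamma = .up_structural(model, "gamma"),
      a = .up_intercepts(model, "gamma"),
      delta = .up_structural(model, "delta"),
      b = .up_intercepts(model, "delta"),
      precisions = .up_precisions(model))
  }
  model
}

.param_vector <- function(model) {
  s <- model$state; spec <- model$spec
  out <- c()
  if (!model$obs_latent) {
    out <- c(out,
             setNames(s$lam0, paste0("lambda0_", spec$pollutants)),
             setNames(s$lam1, paste0("lambda1_", spec$pollutants)),
             setNames(s$tau_x, paste0("tau_x_", spec$pollutants)),
             setNames(s$phi, paste0("phi_", .SEASONAL)),
             tau_traffic = s$tau_t)
    if (model$has_para)
      out <- c(out,
               setNames(s$al0, paste0("alpha0_", spec$markers)),
               setNames(s$al1, paste0("alpha1_", spec$markers)),
               setNames(s$tau_y, paste0("tau_y_", spec$markers)))
  }
  if (model$has_para)
    out <- c(out, setNames(s$gamma, paste0("gamma_", names(s$gamma))),
             tau_para = s$tau_p, tau_a = s$tau_a)
  if (model$has_lfhf)
    out <- c(out, setNames(s$delta, paste0("delta_", names(s$delta))),
             tau_lfhf = s$tau_l, tau_b = s$tau_b)
  out
}

#' Fit the structural equation model by blocked Gibbs sampling
#'
#' Runs `spec$chains` chains from dispersed initial values, discards the
#' burn-in, and returns stacked posterior draws with convergence diagnostics
#' (split R-hat and effective sample size per scalar; a warning is issued if
#' any R-hat exceeds 1.1).
#'
#' @param design one window's exposure design.
#' @param visits visit table.
#' @param spec a [sem_spec()].
#' @return list of class `sem_fit`: `draws` (kept iterations x parameters),
#'   `diagnostics`, `scores` (posterior-mean latent scores per visit, plus
#'   thinned score draws when `store_scores`), `iqr` (in-sample IQR of the
#'   reference pollutant), `n`, `n_participants`, `spec`.
#' @export
fit_sem <- function(design, visits, spec = sem_spec()) {
  model <- build_sem(design, visits, spec)
  keep <- floor((spec$iter - spec$burnin) / spec$thin)
  draws_list <- vector("list", spec$chains)
  t_mean <- p_mean <- 0
  score_draws <- NULL
  if (spec$store_scores)
    score_draws <- list(traffic = list(), para = list())
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 7919L * (ch - 1L))
    model$state <- .init_state(model)
    first <- .param_vector(model)
    dm <- matrix(NA_real_, keep, length(first),
                 dimnames = list(NULL, names(first)))
    kept <- 0L
    for (it in seq_len(spec$iter)) {
      model <- gibbs_step(model)
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
        kept <- kept + 1L
        pv <- .param_vector(model)
        if (any(!is.finite(pv)))
          stop("divergent chain ", ch, " at iteration ", it, ": ",
               paste(names(pv)[!is.finite(pv)], collapse = ", "))
        dm[kept, ] <- pv
        t_mean <- t_mean + model$state$T
        if (model$has_para && !model$obs_latent)
          p_mean <- p_mean + model$state$P
        if (spec$store_scores && kept %% max(1L, keep %/% 200L) == 0L) {
          score_draws$traffic[[length(score_draws$traffic) + 1L]] <-
            model$state$T
          if (model$has_para && !model$obs_latent)
            score_draws$para[[length(score_draws$para) + 1L]] <-
              model$state$P
        }
      }
    }
    draws_list[[ch]] <- dm[seq_len(kept), , drop = FALSE]
  }
  draws <- do.call(rbind, draws_list)
  total_kept <- nrow(draws)
  diagnostics <- .diagnose(draws, spec$chains)
  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) &
                                 diagnostics$rhat > 1.1]
  if (length(bad) > 0)
    warning("R-hat > 1.1 for: ", paste(bad, collapse = ", "))
  scores <- list(
    traffic = t_mean / total_kept,
    para = if (model$has_para && !model$obs_latent) p_mean / total_kept
           else NULL)
  if (spec$store_scores)
    scores$draws <- lapply(score_draws, function(x)
      if (length(x)) do.call(rbind, x) else NULL)
  structure(list(draws = draws, diagnostics = diagnostics, scores = scores,
                 iqr = model$dat$iqr_ref, n = model$dat$n,
                 n_participants = model$dat$npart, spec = spec,
                 visit_id = model$dat$visit_id),
            class = "sem_fit")
}

#' Fit with an effect modifier and derive group-specific traffic effects
#'
#' Adds a traffic-by-modifier interaction to each structural equation and
#' augments the returned draws with the modifier-positive group effects
#' (`gamma_traffic_pos = gamma_traffic + gamma_traffic_int`, likewise for
#' delta); `gamma_traffic` itself is the modifier-negative group effect.
#' Four-way analyses (e.g. obesity by diabetes) are run as two-group
#' contrasts on the corresponding subsets.
#'
#' @param design,visits,spec as in [fit_sem()]; `spec$modifier` must name a
#'   dichotomous visit-table column (e.g. `"diabetic"`, `"obese"`).
#' @return a `sem_fit` with the extra derived draw columns.
#' @export
fit_effect_modification <- function(design, visits, spec) {
  if (is.null(spec$modifier))
    stop("spec$modifier must be set for an effect-modification fit")
  fit <- fit_sem(design, visits, spec)
  dr <- fit$draws
  if ("gamma_traffic_int" %in% colnames(dr))
    fit$draws <- cbind(fit$draws, gamma_traffic_pos =
                         dr[, "gamma_traffic"] + dr[, "gamma_traffic_int"])
  if ("delta_traffic_int" %in% colnames(dr))
    fit$draws <- cbind(fit$draws, delta_traffic_pos =
                         dr[, "delta_traffic"] + dr[, "delta_traffic_int"])
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Bayesian SEM fit (", x$spec$outcome, " outcome, ",
      x$spec$window, "-hr window)\n", sep = "")
  cat("  visits:", x$n, " participants:", x$n_participants,
      " kept draws:", nrow(x$draws), "\n")
  cat("  reference-pollutant IQR:", signif(x$iqr, 4), "\n")
  mx <- suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))
  cat("  max R-hat:", signif(mx, 4), "\n")
  invisible(x)
}
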