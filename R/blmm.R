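# Comparison Bayesian linear mixed model (single pollutant, random subject
# intercept) fitted by Gibbs sampling, plus a frequentist REML fit used as
# an internal oracle. The sampler is deliberately self-contained (it shares
# no update code with the SEM engine) so that SEM-vs-BLMM agreement checks
# compare two genuinely distinct routes.

#' Bayesian linear mixed model specification
#'
#' @param outcome outcome column (`"log_hf"` or `"log_lfhf"`).
#' @param exposure exposure pollutant column (default `"bc"`).
#' @param window moving-average window this fit corresponds to (metadata).
#' @param covariates fixed covariate columns (seasonal sine/cosine and the
#'   apparent-temperature residuals are always appended).
#' @param priors a [prior_spec()].
#' @param chains,iter,burnin,thin,seed MCMC settings.
#' @param random_intercept set `FALSE` to force the subject-intercept
#'   variance to zero, reducing the model to ordinary Bayesian regression.
#' @return list of class `blmm_spec`.
#' @export
blmm_spec <- function(outcome = "log_hf", exposure = "bc", window = 24L,
                      covariates = .COVARIATES, priors = prior_spec(),
                      chains = 2L, iter = 20000L, burnin = 10000L,
                      thin = 1L, seed = 1L, random_intercept = TRUE) {
  if (iter <= burnin) stop("iter must exceed burnin")
  structure(list(outcome = outcome, exposure = exposure, window = window,
                 covariates = covariates, priors = priors,
                 chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 random_intercept = isTRUE(random_intercept)),
            class = "blmm_spec")
}

# complete-case fixed-effects assembly shared by the Gibbs and REML fits;
# the complete-case rule matches the SEM engine so comparisons use the same
# rows
.assemble_blmm <- function(design, visits, spec) {
  vcols <- unique(c("visit_id", spec$covariates, spec$outcome))
  missing_cols <- setdiff(vcols, names(visits))
  if (length(missing_cols) > 0)
    stop("visit table lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- merge(design, visits[, vcols], by = "visit_id")
  if (nrow(d) == 0) stop("design and visit table share no visits")
  d <- d[order(d$visit_id), ]
  need <- c(spec$exposure, spec$covariates, .SEASONAL, spec$outcome)
  ok <- complete.cases(d[, need])
  if (any(!ok))
    message("dropping ", sum(!ok), " incomplete visits")
  d <- d[ok, , drop = FALSE]
  X <- cbind(intercept = 1,
             as.matrix(d[, c(spec$exposure, spec$covariates, .SEASONAL)]))
  colnames(X)[2] <- spec$exposure
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effects design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  upart <- unique(d$participant)
  pidx <- match(d$participant, upart)
  list(y = d[[spec$outcome]], X = X, pidx = pidx,
       ni = tabulate(pidx, nbins = length(upart)),
       n = nrow(d), npart = length(upart),
       iqr = unname(diff(quantile(d[[spec$exposure]], c(0.25, 0.75)))))
}

#' Fit the Bayesian linear mixed model by Gibbs sampling
#'
#' Standard conjugate sampler for `y = X beta + c_i + e` with vague
#' Normal/Gamma priors: the coefficient block is joint Gaussian, the subject
#' intercepts Gaussian, and the residual and intercept precisions Gamma.
#'
#' @param design one window's exposure design.
#' @param visits visit table.
#' @param spec a [blmm_spec()].
#' @return list of class `blmm_fit` with `draws` (columns `beta_*`, `tau_e`,
#'   `tau_c`), `diagnostics`, `iqr`, `n`, `n_participants`, `spec`.
#' @export
fit_blmm <- function(design, visits, spec = blmm_spec()) {
  dat <- .assemble_blmm(design, visits, spec)
  pr <- spec$priors
  pc <- 1 / pr$v_coef
  XtX <- crossprod(dat$X)
  p <- ncol(dat$X)
  keep <- floor((spec$iter - spec$burnin) / spec$thin)
  cn <- c(paste0("beta_", colnames(dat$X)), "tau_e",
          if (spec$random_intercept) "tau_c")
  draws_list <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 7919L * (ch - 1L))
    beta <- rnorm(p, 0, 0.1)
    cc <- rep(0, dat$npart)
    tau_e <- tau_c <- 1
    dm <- matrix(NA_real_, keep, length(cn), dimnames = list(NULL, cn))
    kept <- 0L
    for (it in seq_len(spec$iter)) {
      # beta | rest
      A <- tau_e * XtX
      diag(A) <- diag(A) + pc
      bb <- tau_e * crossprod(dat$X, dat$y - cc[dat$pidx])
      beta <- .draw_mvn_prec(A, bb)
      r <- dat$y - as.numeric(dat$X %*% beta)
      if (spec$random_intercept) {
        # c_i | rest
        prec <- tau_c + dat$ni * tau_e
        cc <- .draw_norm_prec(prec, tau_e * rowsum(r, dat$pidx)[, 1])
        tau_c <- rgamma(1, pr$shape + dat$npart / 2,
                        pr$rate + sum(cc^2) / 2)
      }
      re <- r - cc[dat$pidx]
      tau_e <- rgamma(1, pr$shape + dat$n / 2, pr$rate + sum(re^2) / 2)
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0) {
        kept <- kept + 1L
        dm[kept, ] <- c(beta, tau_e,
                        if (spec$random_intercept) tau_c)
      }
    }
    draws_list[[ch]] <- dm[seq_len(kept), , drop = FALSE]
  }
  draws <- do.call(rbind, draws_list)
  if (any(!is.finite(draws))) stop("divergent BLMM chain")
  diagnostics <- .diagnose(draws, spec$chains)
  structure(list(draws = draws, diagnostics = diagnostics, iqr = dat$iqr,
                 n = dat$n, n_participants = dat$npart, spec = spec),
            class = "blmm_fit")
}

# REML deviance (up to a constant) of the random-intercept model at the
# given log variances, computed from per-participant sufficient statistics
.reml_deviance <- function(lv, dat, Sx, Sy, XtX, Xty, yty) {
  s2e <- exp(lv[1]); s2c <- exp(lv[2])
  ci <- s2c / (s2e + dat$ni * s2c)
  XtViX <- (XtX - crossprod(Sx, ci * Sx)) / s2e
  XtViy <- (Xty - crossprod(Sx, ci * Sy)) / s2e
  ytViy <- (yty - sum(ci * Sy^2)) / s2e
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, backsolve(ch, XtViy, transpose = TRUE))
  rss <- ytViy - sum(beta * XtViy)
  logdetV <- sum((dat$ni - 1) * log(s2e) + log(s2e + dat$ni * s2c))
  logdetX <- 2 * sum(log(diag(ch)))
  unname(logdetV + logdetX + rss)
}

#' Frequentist linear mixed model by direct REML
#'
#' Maximizes the restricted likelihood of the random-intercept Gaussian
#' model over (residual variance, intercept variance), parameterized in log
#' variances for unconstrained search, with the fixed effects profiled out.
#' Deterministic given the data; used as an oracle for [fit_blmm()].
#'
#' @param design,visits,spec as in [fit_blmm()] (`spec$priors` is ignored).
#' @return list of class `lmm_fit`: `coef`, `se`, `sigma2_e`, `sigma2_c`,
#'   `criterion` (the minimized REML deviance), `n`, `n_participants`,
#'   `iqr`.
#' @export
fit_lmm_reml <- function(design, visits, spec = blmm_spec()) {
  dat <- .assemble_blmm(design, visits, spec)
  XtX <- crossprod(dat$X); Xty <- crossprod(dat$X, dat$y)
  yty <- sum(dat$y^2)
  Sx <- rowsum(dat$X, dat$pidx); Sy <- rowsum(dat$y, dat$pidx)[, 1]
  v0 <- var(dat$y)
  fn <- function(lv) .reml_deviance(lv, dat, Sx, Sy, XtX, Xty, yty)
  opt <- optim(log(c(0.7 * v0, 0.3 * v0)), fn, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  if (opt$convergence != 0)
    stop("REML variance optimization failed to converge (code ",
         opt$convergence, ", value ", opt$value, ", par ",
         paste(signif(opt$par, 6), collapse = ", "), ")")
  s2e <- exp(opt$par[1]); s2c <- exp(opt$par[2])
  ci <- s2c / (s2e + dat$ni * s2c)
  XtViX <- (XtX - crossprod(Sx, ci * Sx)) / s2e
  XtViy <- (Xty - crossprod(Sx, ci * Sy)) / s2e
  ch <- chol(XtViX)
  beta <- backsolve(ch, backsolve(ch, XtViy, transpose = TRUE))
  cov_beta <- chol2inv(ch)
  nm <- paste0("beta_", colnames(dat$X))
  structure(list(coef = setNames(as.numeric(beta), nm),
                 se = setNames(sqrt(diag(cov_beta)), nm),
                 sigma2_e = s2e, sigma2_c = s2c, criterion = opt$value,
                 n = dat$n, n_participants = dat$npart, iqr = dat$iqr,
                 spec = spec),
            class = "lmm_fit")
}
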