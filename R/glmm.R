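# Crossed random-intercepts models of per-trial examiner responses.
#
# Per-trial correctness y[i,j] for pair i and expert j follows
#   y[i,j] ~ Bernoulli(logit^-1(b0 + X[i,j] b + printID_i + expertID_j))
# with printID_i ~ N(0, var_print) and expertID_j ~ N(0, var_expert)
# crossed (not nested). Estimation is maximum likelihood via the Laplace
# approximation (lme4::glmer); with no random terms the model reduces to an
# ordinary GLM. Continuous responses (normalized response time, difficulty,
# confidence ratings) use the Gaussian analogue fitted by REML.

build_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1",
           if (length(random)) sprintf("(1 | %s)", random))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a crossed random-intercepts regression of a per-trial response
#'
#' Binomial (logit link, Laplace approximation) or Gaussian (REML) fits with
#' random intercepts for print pair and/or expert. With `random = character(0)`
#' the fit is an ordinary `glm`/`lm`. Non-convergence is flagged on the
#' result, never silent; diverging coefficients (separation) raise an error
#' naming the offending columns.
#'
#' @param data Data.frame holding the response, fixed-effect columns and the
#'   grouping columns (typically the trial table joined to pair features).
#' @param response Response column name (0/1 for binomial).
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param random Subset of `c("pair_id", "expert_id")` (or any grouping
#'   columns); empty for a fixed-effects-only fit.
#' @param family `"binomial"` or `"gaussian"`.
#' @param nAGQ Integrand approximation for binomial fits: 1 = Laplace
#'   (default), 0 = faster penalized-least-squares approximation used inside
#'   large model scans.
#' @param fix_theta_zero Constrain every random-intercept variance to zero
#'   (binomial only): the Laplace deviance is evaluated with the variance
#'   parameters pinned at 0 and optimized over the fixed effects alone.
#'   Statistically this reduces the model to ordinary logistic regression,
#'   which is exactly its use: a constrained fit whose agreement with an
#'   independent GLM is a correctness check on the mixed-model machinery.
#' @return An object of class `fp_glmm`: list with `beta` (term, estimate,
#'   se, stat), `var_print`, `var_expert`, `blups`, `loglik`, `df`, `aic`,
#'   `bic`, `nobs`, `converged`, plus the fitted `model` and the model
#'   specification (`response`, `fixed`, `random`, `family`).
#' @export
fit_glmm <- function(data, response, fixed = character(0),
                     random = c("pair_id", "expert_id"),
                     family = c("binomial", "gaussian"), nAGQ = 1,
                     fix_theta_zero = FALSE) {
  family <- match.arg(family)
  need <- c(response, fixed, random)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  y <- data[[response]]
  if (family == "binomial" && length(unique(y[!is.na(y)])) < 2L) {
    stop("response '", response,
         "' is constant; the logistic model is inestimable (separation)")
  }
  form <- build_formula(response, fixed, random)
  if (fix_theta_zero) {
    if (family != "binomial" || length(random) == 0L) {
      stop("fix_theta_zero applies to binomial fits with random terms")
    }
    devfun <- lme4::glmer(form, data = data, family = stats::binomial(),
                          nAGQ = 1, devFunOnly = TRUE)
    p <- length(fixed) + 1L
    zeros <- rep(0, length(random))
    fn <- function(beta) devfun(c(zeros, beta))
    opt <- stats::optim(rep(0, p), fn, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-13),
                        hessian = TRUE)
    vcov <- 2 * solve(opt$hessian)   # deviance curvature -> coef covariance
    se <- sqrt(diag(vcov))
    beta <- data.frame(term = c("(Intercept)", fixed),
                       estimate = opt$par, se = se, stat = opt$par / se)
    n <- nrow(data)
    return(structure(list(
      beta = beta, var_print = 0, var_expert = 0, blups = list(),
      loglik = -opt$value / 2, df = p, aic = opt$value + 2 * p,
      bic = opt$value + log(n) * p, nobs = n,
      converged = opt$convergence == 0, model = NULL, response = response,
      fixed = fixed, random = random, family = family, nAGQ = 1
    ), class = "fp_glmm"))
  }
  converged <- TRUE
  mod <- withCallingHandlers(
    {
      if (length(random) == 0L) {
        if (family == "binomial") {
          stats::glm(form, data = data, family = stats::binomial())
        } else {
          stats::lm(form, data = data)
        }
      } else if (family == "binomial") {
        lme4::glmer(form, data = data, family = stats::binomial(),
                    nAGQ = nAGQ)
      } else {
        lme4::lmer(form, data = data, REML = TRUE)
      }
    },
    warning = function(w) {
      if (grepl("converge|Hessian|singular", conditionMessage(w),
                ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) {
      # variance estimates on the zero boundary are legitimate fits
      if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    }
  )
  if (inherits(mod, "merMod") &&
      !is.null(mod@optinfo$conv$lme4$messages)) {
    converged <- FALSE
  }

  sm <- summary(mod)
  cf <- stats::coef(sm)
  if (inherits(mod, "glm") || inherits(mod, "lm")) cf <- cf[, 1:3, drop = FALSE]
  beta <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                     stat = cf[, 3], row.names = NULL)
  dropped_terms <- setdiff(fixed, beta$term)
  if (length(dropped_terms)) {
    # rank-deficient columns silently removed by the fitter
    warning("term(s) dropped as rank-deficient: ",
            paste(dropped_terms, collapse = ", "))
    fixed <- intersect(fixed, beta$term)
  }
  if (family == "binomial") {
    runaway <- beta$term[abs(beta$estimate) > 15]
    if (length(runaway)) {
      stop("coefficient diverging (likely separation) for: ",
           paste(runaway, collapse = ", "))
    }
  }

  var_print <- var_expert <- NA_real_
  blups <- list()
  if (inherits(mod, "merMod")) {
    vc <- lme4::VarCorr(mod)
    re <- lme4::ranef(mod, condVar = TRUE)
    for (g in names(vc)) {
      v <- as.numeric(vc[[g]][1])
      r <- re[[g]]
      pv <- attr(r, "postVar")
      tab <- data.frame(level = rownames(r), offset = r[, 1],
                        se = sqrt(pv[1, 1, ]), row.names = NULL)
      if (g == "pair_id") var_print <- v else if (g == "expert_id")
        var_expert <- v
      blups[[g]] <- tab
    }
  } else {
    var_print <- if ("pair_id" %in% random) NA_real_ else 0
    var_expert <- if ("expert_id" %in% random) NA_real_ else 0
  }

  ll <- stats::logLik(mod)
  structure(list(
    beta = beta, var_print = var_print, var_expert = var_expert,
    blups = blups, loglik = as.numeric(ll), df = attr(ll, "df"),
    aic = stats::AIC(mod), bic = stats::BIC(mod), nobs = stats::nobs(mod),
    converged = converged, model = mod, response = response, fixed = fixed,
    random = random, family = family, nAGQ = nAGQ
  ), class = "fp_glmm")
}

#' @export
print.fp_glmm <- function(x, ...) {
  cat(sprintf("<fp_glmm %s: %s ~ %d fixed + (%s), n = %d, AIC = %.1f%s>\n",
              x$family, x$response, length(x$fixed),
              paste(x$random, collapse = ", "), x$nobs, x$aic,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$beta, digits = 3)
  cat(sprintf("random-intercept variances: printID %.3f, expertID %.3f\n",
              x$var_print, x$var_expert))
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' @param full,null `fp_glmm` fits on the same rows, `null` nested in
#'   `full` (its fixed and random terms are subsets).
#' @return List with `chi2` (>= 0), `df` and upper-tail `p`. Identical
#'   models give `chi2 = 0`, `p = 1`.
#' @export
lrt <- function(full, null) {
  if (full$nobs != null$nobs) stop("fits use different numbers of rows")
  nested <- all(null$fixed %in% full$fixed) &&
    all(null$random %in% full$random) && null$family == full$family
  df <- full$df - null$df
  if (!nested || df < 0) stop("'null' is not nested in 'full'")
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

# Interactions named <base>_LxK depend on mains <base>_L, <base>_K;
# a:b-style terms depend on a and b.
default_hierarchy <- function(fixed) {
  h <- list()
  for (term in fixed) {
    if (grepl("_LxK$", term)) {
      mains <- intersect(paste0(sub("_LxK$", "", term), c("_L", "_K")),
                         fixed)
      if (length(mains)) h[[term]] <- mains
    } else if (grepl(":", term, fixed = TRUE)) {
      mains <- intersect(strsplit(term, ":", fixed = TRUE)[[1]], fixed)
      if (length(mains)) h[[term]] <- mains
    }
  }
  h
}

#' Greedy backward elimination of fixed effects by AIC
#'
#' At each step the single fixed effect whose removal most lowers the AIC is
#' dropped; elimination stops when no removal lowers it. By default a main
#' effect cannot be dropped while an interaction built from it is still in
#' the model (`hierarchy = NULL` derives this from the `<base>_LxK` naming
#' convention); pass `hierarchy = list()` to drop terms freely.
#'
#' @inheritParams fit_glmm
#' @param hierarchy Named list mapping interaction terms to the main-effect
#'   terms they protect, `NULL` to derive from names, `list()` for none.
#' @return List with `fit` (the reduced `fp_glmm`), `fixed` (surviving
#'   terms) and `trace` (data.frame: step, dropped, aic_before, aic_after;
#'   zero rows when the initial model is already minimal).
#' @export
aic_backward_select <- function(data, response, fixed,
                                random = c("pair_id", "expert_id"),
                                family = "binomial", nAGQ = 1,
                                hierarchy = NULL) {
  if (is.null(hierarchy)) hierarchy <- default_hierarchy(fixed)
  current <- fixed
  fit <- fit_glmm(data, response, current, random, family, nAGQ)
  trace <- data.frame(step = integer(0), dropped = character(0),
                      aic_before = numeric(0), aic_after = numeric(0))
  step <- 0L
  repeat {
    protected <- unique(unlist(hierarchy[intersect(names(hierarchy),
                                                   current)]))
    candidates <- setdiff(current, protected)
    if (length(candidates) == 0L) break
    fits <- lapply(candidates, function(term) {
      fit_glmm(data, response, setdiff(current, term), random, family, nAGQ)
    })
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    if (aics[best] >= fit$aic) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     dropped = candidates[best],
                                     aic_before = fit$aic,
                                     aic_after = aics[best]))
    current <- setdiff(current, candidates[best])
    fit <- fits[[best]]
  }
  list(fit = fit, fixed = current, trace = trace)
}

#' Compare crossed, print-only and expert-only random structures
#'
#' Fits the model with both random intercepts, with printID only, and with
#' expertID only; reports AIC/BIC for each, the likelihood-ratio test for
#' the expertID component (1 df), and the expert intercept offsets with
#' standard errors. `drop_expert` is TRUE when every expert offset lies
#' within two SE of zero -- the decision rule for averaging over examiners
#' in subsequent modeling.
#'
#' @inheritParams fit_glmm
#' @return List: `fits`, `ic` (data.frame of AIC/BIC), `lrt_expert`,
#'   `expert_offsets`, `drop_expert`.
#' @export
compare_random_structures <- function(data, response, fixed,
                                      family = "binomial", nAGQ = 1) {
  if (length(unique(data$expert_id)) < 2L ||
      length(unique(data$pair_id)) < 2L) {
    stop("need at least 2 experts and 2 pairs")
  }
  fits <- list(
    both = fit_glmm(data, response, fixed, c("pair_id", "expert_id"),
                    family, nAGQ),
    print_only = fit_glmm(data, response, fixed, "pair_id", family, nAGQ),
    expert_only = fit_glmm(data, response, fixed, "expert_id", family, nAGQ)
  )
  ic <- data.frame(model = names(fits),
                   aic = vapply(fits, `[[`, numeric(1), "aic"),
                   bic = vapply(fits, `[[`, numeric(1), "bic"),
                   row.names = NULL)
  test <- lrt(fits$both, fits$print_only)
  offsets <- fits$both$blups$expert_id
  list(fits = fits, ic = ic, lrt_expert = test, expert_offsets = offsets,
       drop_expert = all(abs(offsets$offset) < 2 * offsets$se))
}

#' Normalize response time
#'
#' Per-expert z-score by default (examiners differ greatly in pace); global
#' z-score available as an alternative. An expert with zero RT variance gets
#' centered zeros.
#'
#' @param trials Trial data.frame with `response_time` and `expert_id`.
#' @param method `"per_expert"` or `"global"`.
#' @return Numeric vector of normalized response times.
#' @export
normalize_rt <- function(trials, method = c("per_expert", "global")) {
  method <- match.arg(method)
  rt <- trials$response_time
  if (method == "global") {
    s <- stats::sd(rt)
    return(if (s < 1e-12) rt - mean(rt) else (rt - mean(rt)) / s)
  }
  out <- numeric(length(rt))
  for (e in unique(trials$expert_id)) {
    i <- trials$expert_id == e
    s <- stats::sd(rt[i])
    out[i] <- if (is.na(s) || s < 1e-12) rt[i] - mean(rt[i]) else
      (rt[i] - mean(rt[i])) / s
  }
  out
}

#' Linear mixed model for a continuous per-trial measure
#'
#' REML fit with crossed print/expert intercepts, used for normalized
#' response time and for difficulty/confidence ratings (both kept with both
#' random terms).
#'
#' @inheritParams fit_glmm
#' @return An `fp_glmm` with `family = "gaussian"` (`stat` column holds t).
#' @export
fit_lmm <- function(data, response, fixed,
                    random = c("pair_id", "expert_id")) {
  fit_glmm(data, response, fixed, random, family = "gaussian")
}

#' Predicted probability of a correct comparison for a pair
#'
#' Inverse-logit of the fixed-effect linear predictor; for pairs seen in
#' fitting, the printID intercept offset can be added, while unseen pairs
#' get the population-level prediction (offset 0). Feature rows must be
#' standardized with the fit's training statistics.
#'
#' @param fit A binomial `fp_glmm`.
#' @param features Data.frame of feature rows (with `pair_id` when
#'   `include_print_blup`).
#' @param include_print_blup Add each pair's predicted random intercept?
#' @return Numeric vector of probabilities.
#' @export
predict_accuracy <- function(fit, features, include_print_blup = FALSE) {
  if (fit$family != "binomial") stop("fit is not a logistic model")
  missing_cols <- setdiff(fit$fixed, names(features))
  if (length(missing_cols)) {
    stop("features lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  b <- stats::setNames(fit$beta$estimate, fit$beta$term)
  eta <- rep(b[["(Intercept)"]], nrow(features))
  for (term in fit$fixed) eta <- eta + b[[term]] * features[[term]]
  if (include_print_blup) {
    bl <- fit$blups$pair_id
    if (is.null(bl)) stop("fit has no printID random effect")
    idx <- match(as.character(features$pair_id), bl$level)
    eta <- eta + ifelse(is.na(idx), 0, bl$offset[idx])
  }
  stats::plogis(eta)
}
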