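# Latent-factor simulator of paired two-tissue cohorts. Blood and
# target-tissue ("brain") expression share L latent factors; each brain
# gene's population fraction of variance explained by the factors is
# set exactly, giving an analytic ceiling for imputation accuracy.

#' Specification for the paired-cohort simulator
#'
#' Defines a simulated study: paired blood-brain donors whose
#' expression shares `n_latent` latent factors. Blood gene `j` is
#' `Z w_j + noise_sd * e` with a unit-norm loading vector `w_j`; brain
#' gene `g` is `sqrt(v_g) * Z w_g + sqrt(1 - v_g) * e` with unit-norm
#' `w_g`, so the population R-squared of predicting gene `g` from the
#' factors is exactly `v_g = shared_variance[g]` — the quantity
#' cross-validated imputation accuracy should converge to.
#'
#' Brain genes reuse the first `n_brain_genes` blood gene identifiers
#' (the same gene measured in two tissues, with tissue-specific
#' loadings), so blood-level and brain-level effect vectors can be
#' compared gene-by-gene.
#'
#' Case-control cohorts (see [generate_case_control()]) shift the
#' latent factors of cases by a vector `gamma`, transmitting a
#' fraction `tau` of each brain gene's total diagnosis effect
#' `delta_g` through the shared factors (the remaining
#' `(1 - tau) * delta_g` acts on brain only); `case_delta_sd` scales
#' the per-gene effect sizes.
#'
#' All loadings, covariate coefficients and case effects derive
#' deterministically from `seed`, so every cohort generated from one
#' spec shares the same gene-level structure; donor-level draws use
#' separate streams per cohort type.
#'
#' @param n_donors paired donors for [generate_paired()] (default 150,
#'   a typical paired-cohort size).
#' @param n_blood_genes,n_brain_genes gene counts (defaults 300 / 200;
#'   `n_brain_genes <= n_blood_genes`).
#' @param n_latent number of shared latent factors (default 5).
#' @param shared_variance scalar or per-brain-gene vector in `[0, 1]`
#'   (default 0.3).
#' @param noise_sd blood measurement-noise standard deviation relative
#'   to the unit-variance factor signal (default 1).
#' @param covariate_effects optional named numeric vector of effect
#'   scales for `"age"`, `"sex"`, `"study"`; per-gene coefficients are
#'   drawn `N(0, scale^2)` and applied additively on the log scale to
#'   standardized covariates.
#' @param tau blood-transmission fraction of case effects, in
#'   `[0, 1]` (default 0.5).
#' @param case_delta_sd scale of per-gene diagnosis effects on brain
#'   expression, in within-group SD units (default 0.5).
#' @param seed integer seed (default 1).
#' @return object of class `"ximpute_sim_spec"`.
#' @export
generator_spec <- function(n_donors = 150, n_blood_genes = 300,
                           n_brain_genes = 200, n_latent = 5,
                           shared_variance = 0.3, noise_sd = 1,
                           covariate_effects = NULL,
                           tau = 0.5, case_delta_sd = 0.5, seed = 1) {
  spec <- list(n_donors = as.integer(n_donors),
               n_blood_genes = as.integer(n_blood_genes),
               n_brain_genes = as.integer(n_brain_genes),
               n_latent = as.integer(n_latent),
               shared_variance = as.numeric(shared_variance),
               noise_sd = as.numeric(noise_sd),
               covariate_effects = covariate_effects,
               tau = as.numeric(tau),
               case_delta_sd = as.numeric(case_delta_sd),
               seed = as.integer(seed))
  with(spec, {
    if (n_donors < 2L || n_blood_genes < 1L || n_brain_genes < 1L ||
        n_latent < 1L) {
      ximpute_stop("ximpute_invalid_spec", "all dimensions must be >= 1 (donors >= 2)")
    }
    if (n_brain_genes > n_blood_genes) {
      ximpute_stop("ximpute_invalid_spec",
                   "n_brain_genes must not exceed n_blood_genes (shared gene universe)")
    }
    if (any(shared_variance < 0 | shared_variance > 1) ||
        !length(shared_variance) %in% c(1L, n_brain_genes)) {
      ximpute_stop("ximpute_invalid_spec",
                   "shared_variance must be a scalar or per-brain-gene vector in [0, 1]")
    }
    if (noise_sd <= 0 || tau < 0 || tau > 1 || case_delta_sd <= 0) {
      ximpute_stop("ximpute_invalid_spec",
                   "need noise_sd > 0, tau in [0, 1], case_delta_sd > 0")
    }
  })
  structure(spec, class = "ximpute_sim_spec")
}

#' @export
print.ximpute_sim_spec <- function(x, ...) {
  cat(sprintf("Paired-cohort simulator: %d donors, %d blood / %d brain genes, %d latent factors\n",
              x$n_donors, x$n_blood_genes, x$n_brain_genes, x$n_latent))
  cat(sprintf("  shared variance %s, blood noise sd %g, tau = %g, seed %d\n",
              if (length(x$shared_variance) == 1L) format(x$shared_variance)
              else sprintf("[%g..%g]", min(x$shared_variance), max(x$shared_variance)),
              x$noise_sd, x$tau, x$seed))
  invisible(x)
}

# Gene-level structure shared by every cohort drawn from one spec:
# loadings, baselines, covariate coefficients, case effects.
sim_params <- function(spec) {
  stopifnot(inherits(spec, "ximpute_sim_spec"))
  p <- spec$n_blood_genes; m <- spec$n_brain_genes; L <- spec$n_latent
  blood_ids <- sprintf("G%05d", seq_len(p))
  brain_ids <- blood_ids[seq_len(m)]
  v <- rep_len(spec$shared_variance, m)
  with_seed(spec$seed, {
    W_blood <- matrix(stats::rnorm(L * p), L, p)
    W_blood <- sweep(W_blood, 2L, sqrt(colSums(W_blood^2)), "/")
    W_brain <- matrix(stats::rnorm(L * m), L, m)
    W_brain <- sweep(W_brain, 2L, sqrt(colSums(W_brain^2)), "/")
    mu_blood <- stats::rnorm(p, mean = 5, sd = 1)
    mu_brain <- stats::rnorm(m, mean = 5, sd = 1)
    cov_eff <- NULL
    if (!is.null(spec$covariate_effects)) {
      cov_eff <- lapply(spec$covariate_effects, function(s) {
        list(blood = stats::rnorm(p, sd = s), brain = stats::rnorm(m, sd = s))
      })
    }
    # Case effects: the transmitted part of a diagnosis effect must lie
    # in the span of the shared factors, so the latent shift gamma is
    # drawn first and per-gene totals delta_g are derived from it as
    # t_g / tau (t_g = sqrt(v_g) * w_g' gamma); with tau = 0 the
    # effects are purely brain-specific and drawn iid.
    if (spec$tau > 0) {
      vbar <- mean(v[v > 0])
      if (!is.finite(vbar) || vbar <= 0) {
        gamma <- rep(0, L)
        delta <- rep(0, m)
      } else {
        sigma_gamma <- spec$tau * spec$case_delta_sd / sqrt(vbar)
        gamma <- stats::rnorm(L, sd = sigma_gamma)
        t_g <- sqrt(v) * drop(crossprod(W_brain, gamma))
        delta <- t_g / spec$tau
      }
    } else {
      gamma <- rep(0, L)
      delta <- stats::rnorm(m, sd = spec$case_delta_sd)
    }
    list(blood_ids = blood_ids, brain_ids = brain_ids, v = v,
         W_blood = W_blood, W_brain = W_brain,
         mu_blood = mu_blood, mu_brain = mu_brain,
         cov_eff = cov_eff, gamma = gamma, delta = delta)
  })
}

# Standardized covariate design for n donors (age, sex, study), plus
# the raw covariate table.
sim_covariates <- function(n, sample_ids, seed) {
  with_seed(seed, {
    age <- stats::rnorm(n, 50, 10)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    study <- factor(sample(c("study1", "study2"), n, replace = TRUE))
    covs <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                       study = study, stringsAsFactors = FALSE)
    rownames(covs) <- sample_ids
    z <- cbind(age = as.numeric(scale(age)),
               sex = as.numeric(sex == "M"),
               study = as.numeric(study == "study2"))
    list(table = covs, design = z)
  })
}

add_covariate_effects <- function(expr_t, cov_eff, design, tissue) {
  if (is.null(cov_eff)) return(expr_t)
  for (nm in names(cov_eff)) {
    if (!nm %in% colnames(design)) next
    expr_t <- expr_t + outer(design[, nm], cov_eff[[nm]][[tissue]])
  }
  expr_t
}

#' Generate a paired blood-brain training cohort
#'
#' Draws `n_donors` samples from the latent-factor construction of
#' [generator_spec()]: shared standard-normal factors `Z`, blood
#' expression `Z W_blood + noise`, and brain expression whose per-gene
#' fraction of factor-explained variance equals the spec's
#' `shared_variance` exactly in population. Optional age/sex/study
#' effects are added additively on the log scale to both tissues.
#'
#' @param spec an `"ximpute_sim_spec"`.
#' @return list with `blood` and `brain` (genes x samples matrices,
#'   flagged log-scale), `truth` (data.frame `gene_id`,
#'   `shared_variance`), `covariates` (data.frame, or `NULL` when the
#'   spec has no covariate effects), `latent` (donors x L factor
#'   matrix, for oracle checks), and `spec`.
#' @export
generate_paired <- function(spec) {
  par <- sim_params(spec)
  n <- spec$n_donors
  ids <- sprintf("D%04d", seq_len(n))
  cov <- sim_covariates(n, ids, seed = spec$seed + 1L)
  sim <- with_seed(spec$seed + 2L, {
    Z <- matrix(stats::rnorm(n * spec$n_latent), n, spec$n_latent)
    blood_t <- Z %*% par$W_blood +
      spec$noise_sd * matrix(stats::rnorm(n * spec$n_blood_genes), n)
    f <- Z %*% par$W_brain
    brain_t <- sweep(f, 2L, sqrt(par$v), "*") +
      sweep(matrix(stats::rnorm(n * spec$n_brain_genes), n), 2L,
            sqrt(1 - par$v), "*")
    list(Z = Z, blood_t = blood_t, brain_t = brain_t)
  })
  blood_t <- sweep(sim$blood_t, 2L, par$mu_blood, "+")
  brain_t <- sweep(sim$brain_t, 2L, par$mu_brain, "+")
  if (!is.null(par$cov_eff)) {
    blood_t <- add_covariate_effects(blood_t, par$cov_eff, cov$design, "blood")
    brain_t <- add_covariate_effects(brain_t, par$cov_eff, cov$design, "brain")
  }
  blood <- t(blood_t); dimnames(blood) <- list(par$blood_ids, ids)
  brain <- t(brain_t); dimnames(brain) <- list(par$brain_ids, ids)
  attr(blood, "log_scale") <- TRUE
  attr(brain, "log_scale") <- TRUE
  rownames(sim$Z) <- ids
  list(blood = blood, brain = brain,
       truth = data.frame(gene_id = par$brain_ids,
                          shared_variance = par$v,
                          stringsAsFactors = FALSE),
       covariates = if (is.null(par$cov_eff)) NULL else cov$table,
       latent = sim$Z,
       spec = spec)
}

#' Generate a case-control blood cohort with known brain ground truth
#'
#' Simulates the deployment scenario: a blood-only case-control cohort
#' drawn from the same gene-level structure as the paired training
#' cohort of the same spec. Cases' latent factors are shifted by the
#' spec's `gamma` vector, so a fraction `tau` of each brain gene's
#' total diagnosis effect `delta_g` is transmitted through the shared
#' factors and is, in principle, recoverable by imputation; the
#' remaining `(1 - tau) * delta_g` affects brain tissue only and is
#' invisible in blood. The true brain differential-expression t-values
#' are computed analytically from `delta_g`, the unit within-group
#' brain SD, and the group sizes.
#'
#' @param spec an `"ximpute_sim_spec"`.
#' @param n_cases,n_controls group sizes (each >= 2).
#' @return list with `blood` (genes x samples), `covariates`
#'   (data.frame with `diagnosis`, `age`, `sex`, `study`), and
#'   `true_brain_dge` (data.frame `gene_id`, `effect` = analytic
#'   t-value, `se`, `p`, `delta`, `delta_transmitted`), plus `spec`.
#' @export
generate_case_control <- function(spec, n_cases, n_controls) {
  if (n_cases < 2L || n_controls < 2L) {
    ximpute_stop("ximpute_invalid_spec", "need at least 2 cases and 2 controls")
  }
  par <- sim_params(spec)
  n <- n_cases + n_controls
  ids <- sprintf("S%04d", seq_len(n))
  dx <- c(rep(1, n_cases), rep(0, n_controls))
  cov <- sim_covariates(n, ids, seed = spec$seed + 3L)
  cov$table$diagnosis <- factor(ifelse(dx == 1, "case", "control"),
                                levels = c("control", "case"))
  blood_t <- with_seed(spec$seed + 4L, {
    Z <- matrix(stats::rnorm(n * spec$n_latent), n, spec$n_latent) +
      outer(dx, par$gamma)
    Z %*% par$W_blood +
      spec$noise_sd * matrix(stats::rnorm(n * spec$n_blood_genes), n)
  })
  blood_t <- sweep(blood_t, 2L, par$mu_blood, "+")
  if (!is.null(par$cov_eff)) {
    blood_t <- add_covariate_effects(blood_t, par$cov_eff, cov$design, "blood")
  }
  blood <- t(blood_t); dimnames(blood) <- list(par$blood_ids, ids)
  attr(blood, "log_scale") <- TRUE
  se <- sqrt(1 / n_cases + 1 / n_controls)   # unit within-group brain SD
  tval <- par$delta / se
  truth <- data.frame(gene_id = par$brain_ids,
                      effect = tval,
                      se = rep(se, length(tval)),
                      p = 2 * stats::pt(-abs(tval), df = n - 2L),
                      delta = par$delta,
                      delta_transmitted = spec$tau * par$delta,
                      stringsAsFactors = FALSE)
  list(blood = blood, covariates = cov$table, true_brain_dge = truth,
       spec = spec)
}

#' Population imputation ceiling for a simulated gene
#'
#' Returns the spec's shared-variance fraction for one brain gene —
#' by construction the population R-squared of predicting that gene
#' from the latent factors, hence the ceiling any imputation model can
#' reach.
#'
#' @param spec an `"ximpute_sim_spec"`.
#' @param gene a brain gene identifier (e.g. `"G00001"`).
#' @return numeric scalar in `[0, 1]`.
#' @export
theoretical_r2 <- function(spec, gene) {
  stopifnot(inherits(spec, "ximpute_sim_spec"))
  brain_ids <- sprintf("G%05d", seq_len(spec$n_brain_genes))
  i <- match(gene, brain_ids)
  if (is.na(i)) {
    ximpute_stop("ximpute_unknown_gene",
                 sprintf("gene '%s' is not a simulated brain gene", gene))
  }
  rep_len(spec$shared_variance, spec$n_brain_genes)[i]
}
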