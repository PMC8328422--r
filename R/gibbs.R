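#' Fit the Bayesian growth model by blocked Gibbs sampling
#'
#' Samples the joint posterior of the Gaussian linear mixed model
#' `log(width) = X beta + u_fish + u_year + eps` with crossed random
#' intercepts. Each sweep draws the full coefficient vector
#' `theta = (beta, u_fish, u_year)` in one block from its multivariate
#' normal full conditional (the mixed-model normal equations, solved with a
#' sparse Cholesky factorization whose symbolic analysis is reused across
#' sweeps), then updates each SD by its conjugate Gamma step (inverse-gamma
#' family) or a slice-sampling step on `log(sigma)` (PC and half-Cauchy
#' families); `prior_fixed()` components are held constant, which makes the
#' conditional posterior of `theta` exactly normal and provides the
#' analytic-oracle regime.
#'
#' Convergence is summarized by split-chain potential scale reduction
#' factors on the three SDs; values above `rhat_warn` trigger a warning.
#' Runs with identical seed and configuration are bit-identical.
#'
#' @param design a [build_design()] result (or a [trout_dataset()], in which
#'   case the design is built with `spec`).
#' @param spec a [growth_model_spec()]; ignored when `design` is already a
#'   `growth_design`.
#' @param draws post-burn-in draws to keep per chain.
#' @param burnin discarded initial sweeps per chain.
#' @param thin keep every `thin`-th sweep.
#' @param chains number of independent chains (seeds derived from `seed`).
#' @param seed integer seed.
#' @param rhat_warn split-R-hat warning threshold on the SDs.
#' @return An object of class `growth_posterior`: draw matrices `beta`
#'   (draws x p), `u_fish`, `u_year`, `sigma` (columns `obs`, `fish`,
#'   `year`), the chain index, `rhat`, and the `design` (sans response-free
#'   extras) needed by downstream summaries.
#' @export
fit_growth_model <- function(design, spec = growth_model_spec(),
                             draws = 2000, burnin = 500, thin = 1,
                             chains = 1, seed = 1, rhat_warn = 1.01) {
  if (inherits(design, "trout_dataset")) design <- build_design(design, spec)
  stopifnot(inherits(design, "growth_design"), draws >= 1, burnin >= 0,
            thin >= 1, chains >= 1)
  spec <- design$spec
  d <- design$p + design$nf + design$ny
  # empty cells (e.g. no wild SW3 fish) give all-zero columns whose
  # coefficients are identified by the prior alone; true collinearity among
  # populated columns is a design error
  nonzero <- which(colSums(abs(design$X)) > 0)
  if (length(nonzero) > 0 &&
      qr(design$X[, nonzero, drop = FALSE])$rank < length(nonzero)) {
    stop("singular fixed-effect design", call. = FALSE)
  }
  if (length(nonzero) < design$p) {
    warning("fixed-effect column(s) with no observations (prior-only): ",
            paste(colnames(design$X)[-nonzero], collapse = ", "),
            call. = FALSE)
  }

  res <- lapply(seq_len(chains), function(ch) {
    run_gibbs_chain(design, spec, draws, burnin, thin,
                    seed = derive_seed(seed, ch))
  })
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  u_fish <- do.call(rbind, lapply(res, `[[`, "u_fish"))
  u_year <- do.call(rbind, lapply(res, `[[`, "u_year"))
  sigma <- do.call(rbind, lapply(res, `[[`, "sigma"))
  chain <- rep(seq_len(chains), each = draws)

  free <- c(obs = spec$prior_obs$family != "fixed",
            fish = spec$prior_fish$family != "fixed" && design$nf > 0,
            year = spec$prior_year$family != "fixed" && design$ny > 0)
  rhat <- vapply(colnames(sigma), function(k) {
    if (free[[k]]) split_rhat(sigma[, k], chain) else NA_real_
  }, numeric(1))
  if (any(rhat > rhat_warn, na.rm = TRUE)) {
    warning("possible non-convergence: split R-hat ",
            paste(sprintf("%s=%.3f", names(rhat)[which(rhat > rhat_warn)],
                          rhat[which(rhat > rhat_warn)]), collapse = ", "),
            " exceeds ", rhat_warn, call. = FALSE)
  }
  structure(list(beta = beta, u_fish = u_fish, u_year = u_year,
                 sigma = sigma, chain = chain, rhat = rhat,
                 design = design,
                 sampler = list(draws = draws, burnin = burnin, thin = thin,
                                chains = chains, seed = seed)),
            class = "growth_posterior")
}

run_gibbs_chain <- function(design, spec, draws, burnin, thin, seed) {
  set.seed(as.integer(seed))
  y <- design$y
  W <- design$W
  n <- design$n
  p <- design$p
  nf <- design$nf
  ny <- design$ny
  d <- p + nf + ny
  WtW <- Matrix::crossprod(W)
  Wty <- as.numeric(Matrix::crossprod(W, y))

  init_sigma <- function(prior, fallback) {
    if (prior$family == "fixed") prior$value else fallback
  }
  s_obs <- init_sigma(spec$prior_obs, max(stats::sd(y), 1e-3))
  s_fish <- init_sigma(spec$prior_fish, 0.1)
  s_year <- init_sigma(spec$prior_year, 0.1)

  chol_analysis <- NULL
  keep <- matrix(0, draws, d)
  sig <- matrix(0, draws, 3, dimnames = list(NULL, c("obs", "fish", "year")))
  total <- burnin + draws * thin
  kept <- 0
  for (it in seq_len(total)) {
    prior_prec <- c(rep(1 / spec$fixed_effect_sd^2, p),
                    rep(1 / s_fish^2, nf), rep(1 / s_year^2, ny))
    Q <- WtW / s_obs^2 + Matrix::Diagonal(d, prior_prec)
    if (is.null(chol_analysis)) {
      chol_analysis <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
    } else {
      chol_analysis <- Matrix::update(chol_analysis, Q)
    }
    mu <- as.numeric(Matrix::solve(chol_analysis, Wty / s_obs^2,
                                   system = "A"))
    z <- stats::rnorm(d)
    v <- Matrix::solve(chol_analysis, z, system = "Lt")
    x <- as.numeric(Matrix::solve(chol_analysis, v, system = "Pt"))
    theta <- mu + x

    r <- y - as.numeric(W %*% theta)
    s_obs <- draw_sigma(s_obs, sum(r^2), n, spec$prior_obs)
    # with zero levels the update degenerates to prior-only draws
    uf <- theta[p + seq_len(nf)]
    s_fish <- draw_sigma(s_fish, sum(uf^2), nf, spec$prior_fish)
    uy <- theta[p + nf + seq_len(ny)]
    s_year <- draw_sigma(s_year, sum(uy^2), ny, spec$prior_year)

    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1
      keep[kept, ] <- theta
      sig[kept, ] <- c(s_obs, s_fish, s_year)
    }
  }
  beta <- keep[, seq_len(p), drop = FALSE]
  colnames(beta) <- colnames(design$X)
  u_fish <- keep[, p + seq_len(nf), drop = FALSE]
  if (nf > 0) colnames(u_fish) <- design$fish_levels
  u_year <- keep[, p + nf + seq_len(ny), drop = FALSE]
  if (ny > 0) {
    colnames(u_year) <- paste(design$year_cells$group,
                              design$year_cells$environment,
                              design$year_cells$year, sep = ":")
  }
  list(beta = beta, u_fish = u_fish, u_year = u_year, sigma = sig)
}

# split-chain potential scale reduction factor (each chain halved)
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' @export
print.growth_posterior <- function(x, ...) {
  cat("<growth_posterior> ", nrow(x$sigma), " draws (",
      x$sampler$chains, " chain(s))\n", sep = "")
  cat("fixed effects (posterior mean [95% CrI]):\n")
  qs <- apply(x$beta, 2, stats::quantile, c(0.025, 0.975))
  for (j in seq_len(ncol(x$beta))) {
    cat(sprintf("  %-28s %6.3f [%6.3f, %6.3f]\n", colnames(x$beta)[j],
                mean(x$beta[, j]), qs[1, j], qs[2, j]))
  }
  cat(sprintf("SDs: obs %.4f, fish %.4f, year %.4f\n",
              mean(x$sigma[, "obs"]), mean(x$sigma[, "fish"]),
              mean(x$sigma[, "year"])))
  invisible(x)
}

#' Summarise a growth-model posterior
#'
#' @param object a `growth_posterior`.
#' @param ... unused.
#' @return tibble with one row per fixed effect and SD: posterior mean, SD
#'   and 95% credible interval.
#' @export
summary.growth_posterior <- function(object, ...) {
  draws <- cbind(object$beta,
                 sd_obs = object$sigma[, "obs"],
                 sd_fish = object$sigma[, "fish"],
                 sd_year = object$sigma[, "year"])
  tibble::tibble(
    parameter = colnames(draws),
    mean = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, stats::sd)),
    q2.5 = unname(apply(draws, 2, stats::quantile, 0.025)),
    q97.5 = unname(apply(draws, 2, stats::quantile, 0.975)))
}
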