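# TE+NTE tumor dose-response model:
#   M(D) = B + T_i * D + N_i * (1 - exp(-s * D))
# fitted jointly across radiation types by Poisson maximum likelihood on
# per-mouse tumor counts, with a shared background B, a shared NTE
# saturation rate s, and ion TE slopes constrained to be no less than the
# gamma-ray slope (reparameterized as T_i = T_gamma + delta_i, delta_i >= 0).

#' Construct/validate a tumor-yield dataset
#'
#' One row per mouse: radiation label, absorbed dose in Gy, and the number
#' of intestinal tumors observed in that mouse. Zero-dose rows (any label)
#' form the shared control cohort.
#'
#' @param data A data.frame with columns `radiation` (character),
#'   `dose_Gy` (numeric, >= 0), `tumors` (non-negative integer).
#' @return The validated data.frame with class `tumor_dataset` prepended.
#' @export
tumor_dataset <- function(data) {
  req <- c("radiation", "dose_Gy", "tumors")
  if (!all(req %in% names(data)))
    stop("dataset needs columns: ", paste(req, collapse = ", "))
  data$radiation <- as.character(data$radiation)
  if (any(!is.finite(data$dose_Gy)) || any(data$dose_Gy < 0))
    stop("doses must be finite and >= 0 (Gy)")
  if (any(!is.finite(data$tumors)) || any(data$tumors < 0) ||
      any(data$tumors != round(data$tumors)))
    stop("tumor counts must be non-negative integers")
  class(data) <- unique(c("tumor_dataset", class(data)))
  data
}

#' Read a tumor-yield dataset from TSV
#'
#' Expects columns `radiation_label`, `dose_cGy`, `tumor_count` (one row
#' per mouse); doses are converted from cGy to Gy.
#'
#' @param path File path.
#' @return A [tumor_dataset()].
#' @export
read_tumor_dataset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("radiation_label", "dose_cGy", "tumor_count")
  if (!all(req %in% names(tab)))
    stop("expected columns: ", paste(req, collapse = ", "))
  tumor_dataset(data.frame(radiation = tab$radiation_label,
                           dose_Gy = tab$dose_cGy / 100,
                           tumors = tab$tumor_count,
                           stringsAsFactors = FALSE))
}

#' Write a tumor-yield dataset to TSV (doses in cGy)
#' @param dataset A [tumor_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tumor_dataset <- function(dataset, path) {
  utils::write.table(
    data.frame(radiation_label = dataset$radiation,
               dose_cGy = dataset$dose_Gy * 100,
               tumor_count = dataset$tumors),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Aggregate per-mouse rows into (group, dose) cells; Poisson sufficiency
# means only per-cell totals and mouse numbers enter the likelihood.
aggregate_cells <- function(dataset) {
  key <- interaction(dataset$radiation, dataset$dose_Gy, drop = TRUE)
  cells <- do.call(rbind, lapply(split(dataset, key), function(g)
    data.frame(radiation = g$radiation[1], dose_Gy = g$dose_Gy[1],
               n = nrow(g), total = sum(g$tumors),
               stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  cells[order(cells$radiation, cells$dose_Gy), ]
}

# Parameter vector layout for a fit with ion groups i1..iK:
#   theta = (B, s, T_gamma, delta_i1..delta_iK, N_gamma, N_i1..N_iK)
# All components bounded below by zero (B slightly above, so log-mean is
# finite when controls have tumors).
theta_layout <- function(groups, gamma_label) {
  ions <- setdiff(groups, gamma_label)
  list(
    groups = c(gamma_label, ions), ions = ions,
    names = c("B", "s", paste0("T_", gamma_label),
              if (length(ions)) paste0("delta_", ions),
              paste0("N_", c(gamma_label, ions))),
    n = 3L + 2L * length(ions) + 1L)
}

# Per-cell model means and their derivatives for a theta vector.
cell_means <- function(theta, layout, cells, group_idx) {
  K <- length(layout$ions)
  B <- theta[1]; s <- theta[2]; Tg <- theta[3]
  delta <- if (K) theta[4:(3 + K)] else numeric(0)
  N <- theta[(4 + K):(4 + 2 * K)]
  Tvec <- c(Tg, Tg + delta)          # per fitted group, gamma first
  D <- cells$dose_Gy
  sat <- 1 - exp(-s * D)
  Tg_cell <- ifelse(is.na(group_idx), 0, Tvec[group_idx])
  N_cell <- ifelse(is.na(group_idx), 0, N[group_idx])
  mu <- B + Tg_cell * D + N_cell * sat
  list(mu = mu, sat = sat, N_cell = N_cell, D = D)
}

make_nll <- function(cells, layout, gamma_label) {
  # group index per cell among fitted groups; NA for zero-dose cells
  group_idx <- match(cells$radiation, layout$groups)
  group_idx[cells$dose_Gy == 0] <- NA_integer_
  K <- length(layout$ions)
  nll <- function(theta) {
    cm <- cell_means(theta, layout, cells, group_idx)
    mu <- pmax(cm$mu, 1e-12)
    -sum(cells$total * log(mu) - cells$n * mu)
  }
  gr <- function(theta) {
    cm <- cell_means(theta, layout, cells, group_idx)
    mu <- pmax(cm$mu, 1e-12)
    w <- cells$total / mu - cells$n          # d ll / d mu per cell
    D <- cm$D
    g <- numeric(layout$n)
    g[1] <- sum(w)                                        # B
    g[2] <- sum(w * cm$N_cell * D * exp(-theta[2] * D))   # s
    in_fit <- !is.na(group_idx)
    g[3] <- sum(w[in_fit] * D[in_fit])                    # T_gamma (all groups)
    if (K) for (k in seq_len(K)) {
      sel <- in_fit & group_idx == k + 1L
      g[3 + k] <- sum(w[sel] * D[sel])                    # delta_k
    }
    for (j in seq_len(K + 1L)) {
      sel <- in_fit & group_idx == j
      g[3 + K + j] <- sum(w[sel] * cm$sat[sel])           # N_j
    }
    -g
  }
  list(nll = nll, gr = gr, group_idx = group_idx)
}

#' Evaluate the TE+NTE dose-response model
#'
#' Returns the expected tumor yield B + T*D + N*(1 - exp(-s*D)) for the
#' given radiation type at the given dose(s).
#'
#' @param fit A `dose_response_fit` (from [fit_dose_response()] or
#'   [as_dose_response_fit()]).
#' @param radiation Radiation label present in the fit.
#' @param dose_Gy Dose(s), Gy, >= 0.
#' @return Expected tumors per mouse (vectorized over `dose_Gy`).
#' @export
model_yield <- function(fit, radiation, dose_Gy) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(dose_Gy < 0)) stop("dose must be >= 0")
  i <- match(radiation, fit$params$radiation)
  if (is.na(i)) stop("unknown radiation label: ", radiation)
  fit$B + fit$params$T[i] * dose_Gy +
    fit$params$N[i] * (1 - exp(-fit$s * dose_Gy))
}

#' Build a dose-response fit object from known parameter values
#'
#' Wraps a parameter table (such as [apc_dose_response_params()]) in the
#' same object the fitter returns, so published estimates can be pushed
#' through [model_yield()], [effect_metrics()] and the synthetic-data
#' generators.
#'
#' @param params data.frame with columns `radiation`, `T`, `N` (optional
#'   `T_lo`, `T_hi`, `N_lo`, `N_hi`).
#' @param B Background yield, tumors/mouse.
#' @param s Shared NTE saturation rate, 1/Gy.
#' @param gamma_label Label of the reference radiation.
#' @return A `dose_response_fit`.
#' @examples
#' truth <- as_dose_response_fit(apc_dose_response_params(), B = 0.7)
#' model_yield(truth, "Si", 0.1)
#' @export
as_dose_response_fit <- function(params, B, s = 38.7,
                                 gamma_label = "gamma") {
  stopifnot(is.data.frame(params), all(c("radiation", "T", "N") %in% names(params)))
  for (cn in c("T_lo", "T_hi", "N_lo", "N_hi"))
    if (is.null(params[[cn]])) params[[cn]] <- NA_real_
  if (!gamma_label %in% params$radiation)
    stop("params must contain the reference group '", gamma_label, "'")
  if (any(c(params$T, params$N, B, s) < 0))
    stop("all parameters must be >= 0")
  structure(list(params = params[, c("radiation", "T", "T_lo", "T_hi",
                                     "N", "N_lo", "N_hi")],
                 B = B, B_ci = c(NA, NA), s = s, s_ci = c(NA, NA),
                 gamma_label = gamma_label, logLik = NA_real_,
                 restarts = NULL, cells = NULL),
            class = "dose_response_fit")
}

#' Fit the TE+NTE dose-response model
#'
#' Maximizes the Poisson log-likelihood of per-mouse tumor counts jointly
#' across radiation types, with a shared background `B`, a shared NTE rate
#' `s`, and ion TE slopes bounded below by the gamma-ray slope. The
#' bound-constrained optimization (`L-BFGS-B` with analytic gradients) is
#' restarted from `n_starts` random initial points plus one moment-based
#' start; the best local optimum is reported.
#'
#' @param dataset A [tumor_dataset()] containing a zero-dose control group
#'   and the reference gamma group.
#' @param gamma_label Label of the reference radiation (default "gamma").
#' @param n_starts Number of random restarts (>= 1); default 50.
#' @param seed Integer seed making the restarts reproducible.
#' @param compute_ci If `TRUE`, attach profile-likelihood 95% CIs for all
#'   parameters via [confidence_intervals()].
#' @return A `dose_response_fit`: parameter table with per-radiation `T`
#'   and `N`, shared `B` and `s`, the maximized log-likelihood, and the
#'   restart trace.
#' @export
fit_dose_response <- function(dataset, gamma_label = "gamma",
                              n_starts = 50L, seed = 1L,
                              compute_ci = FALSE) {
  stopifnot(inherits(dataset, "tumor_dataset"))
  if (n_starts < 1L) stop("n_starts must be >= 1")
  cells <- aggregate_cells(dataset)
  groups <- unique(cells$radiation[cells$dose_Gy > 0])
  if (!gamma_label %in% groups)
    stop("dataset lacks the reference group '", gamma_label,
         "' at positive dose")
  if (!any(cells$dose_Gy == 0))
    stop("dataset lacks a zero-dose control group")
  ok <- vapply(groups, function(g)
    length(unique(cells$dose_Gy[cells$radiation == g & cells$dose_Gy > 0])) >= 2L,
    logical(1))
  if (!all(ok))
    warning("groups with < 2 positive doses: ",
            paste(groups[!ok], collapse = ", "),
            " (T and N weakly identified)")
  layout <- theta_layout(groups, gamma_label)
  funs <- make_nll(cells, layout, gamma_label)
  K <- length(layout$ions)

  lower <- c(1e-9, 1e-6, rep(0, 1L + K), rep(0, K + 1L))
  upper <- rep(Inf, layout$n)

  starts <- make_starts(cells, layout, gamma_label, n_starts, seed)
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    res <- try(stats::optim(starts[i, ], funs$nll, funs$gr,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 500L, factr = 1e7)),
               silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs))
    stop("fit failure: no restart converged")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  theta <- best$par
  names(theta) <- layout$names

  Tvec <- c(theta[3], if (K) theta[3] + theta[4:(3 + K)])
  Nvec <- theta[(4 + K):(4 + 2 * K)]
  fit <- structure(list(
    params = data.frame(radiation = layout$groups, T = Tvec,
                        T_lo = NA_real_, T_hi = NA_real_,
                        N = Nvec, N_lo = NA_real_, N_hi = NA_real_,
                        stringsAsFactors = FALSE, row.names = NULL),
    B = unname(theta[1]), B_ci = c(NA, NA),
    s = unname(theta[2]), s_ci = c(NA, NA),
    gamma_label = gamma_label, logLik = -best$value,
    theta = theta, layout = layout, cells = cells,
    restarts = data.frame(start = seq_along(vals), nll = vals),
    data_rows = data.frame(radiation = dataset$radiation,
                           dose_Gy = dataset$dose_Gy,
                           tumors = dataset$tumors,
                           stringsAsFactors = FALSE),
    convergence = best$convergence),
    class = "dose_response_fit")
  if (compute_ci) {
    ci <- confidence_intervals(fit)
    fit <- attach_ci(fit, ci)
  }
  fit
}

make_starts <- function(cells, layout, gamma_label, n_starts, seed) {
  K <- length(layout$ions)
  # moment-based start: background from zero-dose cells, gamma slope from
  # a crude regression, plateaus from high-dose excess
  ctrl <- cells[cells$dose_Gy == 0, , drop = FALSE]
  B0 <- if (nrow(ctrl)) max(sum(ctrl$total) / sum(ctrl$n), 0.05) else 0.3
  gcells <- cells[cells$radiation == gamma_label & cells$dose_Gy > 0, ]
  T0 <- max((sum(gcells$total / gcells$n * gcells$dose_Gy) /
               sum(gcells$dose_Gy^2)), 0.1)
  N0 <- vapply(layout$groups, function(g) {
    gc <- cells[cells$radiation == g & cells$dose_Gy > 0, ]
    top <- gc[which.max(gc$dose_Gy), ]
    max(top$total / top$n - B0 - T0 * top$dose_Gy, 0.05)
  }, numeric(1))
  s0 <- 1 / max(min(cells$dose_Gy[cells$dose_Gy > 0]), 1e-3)
  mom <- c(B0, s0, T0, rep(0.1, K), N0)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    expr
  }
  rand <- withr_seed({
    n_r <- max(n_starts - 1L, 0L)
    if (n_r == 0L) NULL else
      cbind(stats::runif(n_r, 0.01, 3),
            exp(stats::runif(n_r, log(1), log(200))),
            stats::runif(n_r, 0.1, 12),
            matrix(stats::runif(n_r * K, 0, 8), n_r, K),
            matrix(stats::runif(n_r * (K + 1L), 0.01, 6), n_r, K + 1L))
  })
  rbind(mom, rand)
}

attach_ci <- function(fit, ci) {
  p <- fit$params
  for (i in seq_len(nrow(p))) {
    rT <- ci[ci$parameter == paste0("T_", p$radiation[i]), ]
    rN <- ci[ci$parameter == paste0("N_", p$radiation[i]), ]
    if (nrow(rT)) { p$T_lo[i] <- rT$lo; p$T_hi[i] <- rT$hi }
    if (nrow(rN)) { p$N_lo[i] <- rN$lo; p$N_hi[i] <- rN$hi }
  }
  fit$params <- p
  rB <- ci[ci$parameter == "B", ]; rs <- ci[ci$parameter == "s", ]
  if (nrow(rB)) fit$B_ci <- c(rB$lo, rB$hi)
  if (nrow(rs)) fit$s_ci <- c(rs$lo, rs$hi)
  fit$ci <- ci
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("TE+NTE dose-response fit\n")
  cat(sprintf("  B = %.3f tumors/mouse, s = %.2f 1/Gy, logLik = %.2f\n",
              x$B, x$s, x$logLik))
  print(x$params, digits = 3)
  invisible(x)
}

# Reduced-problem machinery shared by the profiler: fix one reportable
# parameter (B, s, T_<group>, N_<group>) at a value and optimize the rest.
fixed_param_problem <- function(fit, parameter) {
  layout <- fit$layout
  if (is.null(layout)) stop("fit carries no data; refit with fit_dose_response()")
  funs <- make_nll(fit$cells, layout, fit$gamma_label)
  K <- length(layout$ions)
  nm <- layout$names
  gamma_T <- paste0("T_", fit$gamma_label)
  if (parameter %in% c("B", "s", gamma_T, paste0("N_", layout$groups))) {
    j <- match(parameter, nm)
    build <- function(red, t) append(red, t, after = j - 1L)
    reduce <- function(theta) theta[-j]
    grad_red <- function(gfull, t) gfull[-j]
    bounds <- function(t, lower, upper) list(lower = lower[-j], upper = upper[-j])
  } else if (grepl("^T_", parameter)) {
    ion <- sub("^T_", "", parameter)
    k <- match(ion, layout$ions)
    if (is.na(k)) stop("unknown parameter: ", parameter)
    jd <- 3L + k                       # delta_k slot
    build <- function(red, t) {
      th <- append(red, t - red[3], after = jd - 1L)  # delta = t - T_gamma
      th
    }
    reduce <- function(theta) theta[-jd]
    grad_red <- function(gfull, t) {
      g <- gfull[-jd]
      g[3] <- g[3] - gfull[jd]         # T_gamma moves delta to keep T_i = t
      g
    }
    bounds <- function(t, lower, upper) {
      lo <- lower[-jd]; up <- upper[-jd]
      up[3] <- t                       # T_gamma <= T_i
      list(lower = lo, upper = up)
    }
  } else stop("unknown parameter: ", parameter)
  lower <- c(1e-9, 1e-6, rep(0, 1L + K), rep(0, K + 1L))
  upper <- rep(Inf, layout$n)
  list(
    value = function(t, start_red) {
      bb <- bounds(t, lower, upper)
      start_red <- pmin(pmax(start_red, bb$lower), bb$upper)
      res <- stats::optim(start_red,
                          fn = function(r) funs$nll(build(r, t)),
                          gr = function(r) grad_red(funs$gr(build(r, t)), t),
                          method = "L-BFGS-B",
                          lower = bb$lower, upper = bb$upper,
                          control = list(maxit = 300L, factr = 1e7))
      list(nll = res$value, par = res$par)
    },
    reduce = reduce)
}

theta_estimate <- function(fit, parameter) {
  if (parameter == "B") return(fit$B)
  if (parameter == "s") return(fit$s)
  tab <- fit$params
  if (grepl("^T_", parameter))
    return(tab$T[match(sub("^T_", "", parameter), tab$radiation)])
  if (grepl("^N_", parameter))
    return(tab$N[match(sub("^N_", "", parameter), tab$radiation)])
  stop("unknown parameter: ", parameter)
}

#' Confidence intervals for dose-response parameters
#'
#' Profile-likelihood intervals (deviance cutoff `qchisq(level, 1)`) by
#' default, or a nonparametric case-resampling bootstrap (mice resampled
#' within each radiation-dose group). Profiles that run into the
#' non-negativity bound (or the `T_i >= T_gamma` constraint) report the
#' bound as the one-sided limit, so a parameter sitting on an active
#' constraint gets a lower limit equal to the constraint value.
#'
#' @param fit A `dose_response_fit` from [fit_dose_response()].
#' @param parameters Character vector of parameter names (`"B"`, `"s"`,
#'   `"T_<group>"`, `"N_<group>"`); default all.
#' @param method `"profile"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (method = "bootstrap"); must be >= 1.
#' @param seed Seed for the bootstrap resampling.
#' @return data.frame with columns `parameter`, `estimate`, `lo`, `hi`.
#' @export
confidence_intervals <- function(fit, parameters = NULL,
                                 method = c("profile", "bootstrap"),
                                 level = 0.95, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "dose_response_fit"))
  method <- match.arg(method)
  if (is.null(fit$layout))
    stop("fit carries no data (built from a parameter table); ",
         "CIs require a fit_dose_response() result")
  layout <- fit$layout
  if (is.null(parameters))
    parameters <- c("B", "s", paste0("T_", layout$groups),
                    paste0("N_", layout$groups))
  if (method == "bootstrap") {
    if (n_boot < 1L) stop("n_boot must be >= 1")
    return(bootstrap_ci(fit, parameters, level, n_boot, seed))
  }
  cutoff <- stats::qchisq(level, 1) / 2
  out <- lapply(parameters, function(p) {
    est <- theta_estimate(fit, p)
    prob <- fixed_param_problem(fit, p)
    red0 <- prob$reduce(fit$theta)
    nll_hat <- -fit$logLik
    lim <- function(direction) {
      # step outward until the profiled deviance crosses the cutoff,
      # then bisect; warm-start each solve at the previous solution
      step <- max(abs(est), 0.05) * 0.1
      t_prev <- est; red <- red0; d_prev <- 0
      for (i in 1:40) {
        t_new <- t_prev + direction * step
        if (direction < 0 && t_new < 0) t_new <- 0
        sol <- prob$value(t_new, red)
        d_new <- sol$nll - nll_hat
        red <- sol$par
        if (d_new >= cutoff) {
          # bisection between t_prev (inside) and t_new (outside)
          lo_t <- t_prev; hi_t <- t_new
          for (b in 1:30) {
            mid <- (lo_t + hi_t) / 2
            sm <- prob$value(mid, red)
            red <- sm$par
            if (sm$nll - nll_hat >= cutoff) hi_t <- mid else lo_t <- mid
            if (abs(hi_t - lo_t) < 1e-4 * max(abs(est), 1)) break
          }
          return((lo_t + hi_t) / 2)
        }
        if (direction < 0 && t_new <= 0) return(0)   # hit the bound flat
        t_prev <- t_new; d_prev <- d_new
        step <- step * 1.6
      }
      warning("flat profile for ", p, " (",
              if (direction > 0) "upper" else "lower",
              "); reporting search bound")
      t_prev
    }
    data.frame(parameter = p, estimate = est,
               lo = lim(-1), hi = lim(+1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

bootstrap_ci <- function(fit, parameters, level, n_boot, seed) {
  cells <- fit$cells
  # reconstitute per-mouse rows from cells is impossible (totals only), so
  # bootstrap on the stored per-mouse data if present, else parametric
  data <- fit$data_rows
  if (is.null(data))
    stop("bootstrap CIs need the per-mouse data; refit via fit_dose_response()",
         " on a tumor_dataset (per-mouse rows are retained)")
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(parameters),
                 dimnames = list(NULL, parameters))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(split(seq_len(nrow(data)),
                               interaction(data$radiation, data$dose_Gy,
                                           drop = TRUE)),
                         function(ii) sample(ii, length(ii), replace = TRUE)))
    bs <- tumor_dataset(data[idx, , drop = FALSE])
    bf <- try(fit_dose_response(bs, gamma_label = fit$gamma_label,
                                n_starts = 4L, seed = seed + b),
              silent = TRUE)
    if (inherits(bf, "try-error")) next
    reps[b, ] <- vapply(parameters, function(p) theta_estimate(bf, p),
                        numeric(1))
  }
  alpha <- (1 - level) / 2
  out <- lapply(parameters, function(p) {
    v <- reps[, p]; v <- v[is.finite(v)]
    data.frame(parameter = p, estimate = theta_estimate(fit, p),
               lo = unname(stats::quantile(v, alpha)),
               hi = unname(stats::quantile(v, 1 - alpha)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "replicates") <- reps
  res
}

#' Low-dose relative biological effect metrics from a fit
#'
#' The TE metric for each ion is its TE slope divided by the gamma-ray
#' slope, `E_TE = T_i / T_gamma`; the NTE metric is the ratio of NTE
#' plateaus, `E_NTE = N_i / N_gamma`. The gamma reference maps to exactly
#' 1 on both scales. Confidence intervals, when requested, come from
#' bootstrap ratio percentiles (per-mouse resampling) or a normal-theory
#' delta method on the parameter covariance.
#'
#' @param fit A `dose_response_fit`.
#' @param ci `"none"` (default), `"bootstrap"`, or `"delta"`.
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @param seed Bootstrap seed.
#' @return data.frame of class `effect_metrics` with columns `radiation`,
#'   `E_TE`, `E_TE_lo`, `E_TE_hi`, `E_NTE`, `E_NTE_lo`, `E_NTE_hi`, and
#'   `E_TE_ciw`/`E_NTE_ciw` widths when CIs are present.
#' @examples
#' fit <- as_dose_response_fit(apc_dose_response_params(), B = 0.7)
#' effect_metrics(fit)
#' @export
effect_metrics <- function(fit, ci = c("none", "bootstrap", "delta"),
                           level = 0.95, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "dose_response_fit"))
  ci <- match.arg(ci)
  tab <- fit$params
  g <- match(fit$gamma_label, tab$radiation)
  if (is.na(g)) stop("fit lacks the reference group '", fit$gamma_label, "'")
  Tg <- tab$T[g]; Ng <- tab$N[g]
  if (Tg <= 0) stop("reference TE slope is zero; TE metrics undefined")
  if (Ng <= 0) stop("reference NTE plateau is zero; NTE metrics undefined")
  out <- data.frame(radiation = tab$radiation,
                    E_TE = tab$T / Tg, E_TE_lo = NA_real_, E_TE_hi = NA_real_,
                    E_NTE = tab$N / Ng, E_NTE_lo = NA_real_, E_NTE_hi = NA_real_,
                    stringsAsFactors = FALSE)
  if (ci == "bootstrap") {
    pars <- c(paste0("T_", tab$radiation), paste0("N_", tab$radiation))
    bci <- bootstrap_ci(fit, pars, level, n_boot, seed)
    reps <- attr(bci, "replicates")
    alpha <- (1 - level) / 2
    for (i in seq_len(nrow(tab))) {
      rT <- reps[, paste0("T_", tab$radiation[i])] / reps[, paste0("T_", fit$gamma_label)]
      rN <- reps[, paste0("N_", tab$radiation[i])] / reps[, paste0("N_", fit$gamma_label)]
      qT <- stats::quantile(rT[is.finite(rT)], c(alpha, 1 - alpha))
      qN <- stats::quantile(rN[is.finite(rN)], c(alpha, 1 - alpha))
      out$E_TE_lo[i] <- qT[1]; out$E_TE_hi[i] <- qT[2]
      out$E_NTE_lo[i] <- qN[1]; out$E_NTE_hi[i] <- qN[2]
    }
  } else if (ci == "delta") {
    out <- delta_metric_ci(fit, out, level)
  }
  if (ci != "none") {
    out$E_TE_ciw <- out$E_TE_hi - out$E_TE_lo
    out$E_NTE_ciw <- out$E_NTE_hi - out$E_NTE_lo
  }
  class(out) <- c("effect_metrics", class(out))
  out
}

# Normal-theory CI for ratios via the inverse observed information.
delta_metric_ci <- function(fit, out, level) {
  if (is.null(fit$layout))
    stop("delta-method CIs need an optimized fit with data")
  funs <- make_nll(fit$cells, fit$layout, fit$gamma_label)
  H <- stats::optimHess(fit$theta, funs$nll, funs$gr)
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error")) {
    warning("singular information matrix; delta CIs unavailable")
    return(out)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  layout <- fit$layout; K <- length(layout$ions)
  nm <- layout$names
  jTg <- 3L
  for (i in seq_len(nrow(out))) {
    rad <- out$radiation[i]
    # gradient of T_i/T_gamma wrt theta
    gT <- numeric(layout$n)
    Ti <- fit$params$T[match(rad, fit$params$radiation)]
    Tg <- fit$params$T[match(fit$gamma_label, fit$params$radiation)]
    if (rad == fit$gamma_label) {
      seT <- 0
    } else {
      k <- match(rad, layout$ions)
      gT[jTg] <- 1 / Tg - Ti / Tg^2          # via T_i = T_gamma + delta
      gT[3L + k] <- 1 / Tg
      seT <- sqrt(max(drop(t(gT) %*% V %*% gT), 0))
    }
    gN <- numeric(layout$n)
    jNg <- 3L + K + 1L
    jNi <- 3L + K + match(rad, layout$groups)
    Ni <- fit$params$N[match(rad, fit$params$radiation)]
    Ng <- fit$params$N[match(fit$gamma_label, fit$params$radiation)]
    if (rad == fit$gamma_label) {
      seN <- 0
    } else {
      gN[jNi] <- 1 / Ng
      gN[jNg] <- -Ni / Ng^2
      seN <- sqrt(max(drop(t(gN) %*% V %*% gN), 0))
    }
    out$E_TE_lo[i] <- max(out$E_TE[i] - z * seT, 0)
    out$E_TE_hi[i] <- out$E_TE[i] + z * seT
    out$E_NTE_lo[i] <- max(out$E_NTE[i] - z * seN, 0)
    out$E_NTE_hi[i] <- out$E_NTE[i] + z * seN
  }
  out
}
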