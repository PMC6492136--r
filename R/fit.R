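# Inverse fitting: genetic-algorithm estimation of tissue optical
# properties from averaged log A-scans, and the linear-perturbation
# sensitivity analysis of the inverse problem.

#' Genetic-algorithm settings
#'
#' Real-coded GA defaults: population 100, 200 generations, tournament
#' selection (size 3), blend (BLX-alpha) crossover, per-gene Gaussian
#' mutation scaled to the parameter range, elitism. The amplitude factor a
#' is profiled analytically for every candidate (the least-squares dB
#' offset, clamped to its bounds), so the genome is (mu_s, g, p_b).
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param p_crossover crossover probability.
#' @param p_mutation per-gene mutation probability.
#' @param blx_alpha blend-crossover expansion factor.
#' @param mut_sd mutation standard deviation as a fraction of each
#'   parameter's range.
#' @param tournament tournament size.
#' @param elite number of elite individuals copied unchanged.
#' @return list of settings.
#' @export
ga_config <- function(pop_size = 100, generations = 200, p_crossover = 0.9,
                      p_mutation = 0.25, blx_alpha = 0.3, mut_sd = 0.08,
                      tournament = 3, elite = 2) {
  list(pop_size = as.integer(pop_size), generations = as.integer(generations),
       p_crossover = p_crossover, p_mutation = p_mutation,
       blx_alpha = blx_alpha, mut_sd = mut_sd,
       tournament = as.integer(tournament), elite = as.integer(elite))
}

#' Fit the EHF model to an averaged log A-scan
#'
#' Minimizes the sum of squared differences between the EHF model (in
#' 10 log10 scale) and the A-scan over the fitted depth range, using a
#' real-coded genetic algorithm to avoid the local optima of the strongly
#' nonconvex landscape. Parameter bounds: `1 <= mu_s <= 15` mm^-1,
#' `0.8 <= g <= 1`, `0.001 <= p_b <= 0.5`, `1e-3 <= a <= 1e3`.
#'
#' @param ascan an `oct_ascan_avg` tibble (columns `depth_mm`, `log_db`),
#'   or any tibble with those columns.
#' @param geometry the [beam_geometry()] used for the scan.
#' @param ga a [ga_config()] list.
#' @param seed RNG seed for the GA.
#' @param fit_range depth interval (mm) used in the objective; the default
#'   drops the shallowest bins, which carry windowing leakage of the
#'   zero-depth DC term.
#' @param polish refine the GA optimum with a bounded quasi-Newton step.
#' @param normalize when `TRUE` (default) both the A-scan and every
#'   candidate model curve are referenced to their value at the first fitted
#'   depth before comparison — the protocol used for simulated A-scans,
#'   whose absolute scale is arbitrary. Use `FALSE` when the data is already
#'   on the model's absolute scale (then `a` is identified directly).
#' @return object of class `oct_fit` with elements `par` (named estimates
#'   including `a`), `objective`, `n_generations`, `seed`, `converged`, and
#'   the fitted curve (`data` tibble with `model_db`).
#' @export
fit_ehf <- function(ascan, geometry, ga = ga_config(), seed = 1,
                    fit_range = NULL, normalize = TRUE, polish = TRUE) {
  stopifnot(inherits(geometry, "oct_beam"))
  if (!all(c("depth_mm", "log_db") %in% names(ascan)))
    abort("ascan must have depth_mm and log_db columns",
          class = "octmc_contract_error")
  if (is.null(fit_range))
    fit_range <- c(4 * (ascan$depth_mm[2] - ascan$depth_mm[1]),
                   max(ascan$depth_mm))
  keep <- ascan$depth_mm >= fit_range[1] & ascan$depth_mm <= fit_range[2]
  zz <- ascan$depth_mm[keep]
  yy <- ascan$log_db[keep]
  if (length(zz) < 10)
    abort("too few depth samples in the fitting range",
          class = "octmc_contract_error")
  b <- ehf_bounds()
  lo <- c(b$mu_s[1], b$g[1], b$p_b[1])
  hi <- c(b$mu_s[2], b$g[2], b$p_b[2])
  a_lo_db <- 10 * log10(b$a[1])
  a_hi_db <- 10 * log10(b$a[2])

  if (normalize) yy <- yy - yy[1]

  model_db <- function(theta) {
    p <- ehf_params(theta[1], min(theta[2], 1 - 1e-9), theta[3], geometry)
    m <- 10 * log10(ehf_signal(p, zz))
    if (normalize) m - m[1] else m
  }
  obj <- function(theta) {
    m <- model_db(theta)
    off <- min(max(mean(yy - m), a_lo_db), a_hi_db)
    sum((m + off - yy)^2)
  }

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  np <- ga$pop_size
  pop <- matrix(stats::runif(np * 3, rep(lo, each = np), rep(hi, each = np)),
                nrow = np)
  fit <- apply(pop, 1, obj)
  init_best <- min(fit)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    newpop <- matrix(NA_real_, np, 3)
    newpop[seq_len(ga$elite), ] <- pop[ord[seq_len(ga$elite)], ]
    i <- ga$elite
    while (i < np) {
      pick <- function() {
        cand <- sample.int(np, ga$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < ga$p_crossover) {
        d <- abs(p1 - p2)
        l <- pmin(p1, p2) - ga$blx_alpha * d
        u <- pmax(p1, p2) + ga$blx_alpha * d
        c1 <- stats::runif(3, l, u)
        c2 <- stats::runif(3, l, u)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (ch in list(c1, c2)) {
        if (i >= np) break
        mut <- stats::runif(3) < ga$p_mutation
        ch[mut] <- ch[mut] + stats::rnorm(sum(mut)) * ga$mut_sd * (hi - lo)[mut]
        ch <- pmin(pmax(ch, lo), hi)
        i <- i + 1
        newpop[i, ] <- ch
      }
    }
    pop <- newpop
    fit <- apply(pop, 1, obj)
  }
  best <- which.min(fit)
  theta <- pop[best, ]
  if (polish) {
    # bounded local refinement from the best GA individuals (memetic step)
    cand_val <- obj(theta)
    for (idx in order(fit)[1:3]) {
      opt <- tryCatch(
        stats::optim(pop[idx, ], obj, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(opt) && opt$value < cand_val) {
        theta <- opt$par
        cand_val <- opt$value
      }
    }
  }
  converged <- obj(theta) < init_best
  if (!converged)
    warn("GA did not improve on its initial population")
  m <- model_db(theta)
  off <- min(max(mean(yy - m), a_lo_db), a_hi_db)
  structure(list(
    par = c(mu_s = theta[1], g = theta[2], p_b = theta[3],
            a = 10^(off / 10)),
    objective = sum((m + off - yy)^2),
    n_generations = ga$generations, seed = seed, converged = converged,
    geometry = geometry,
    data = tibble(depth_mm = zz, log_db = yy, model_db = m + off)),
    class = "oct_fit")
}

# save/restore .Random.seed so package fits don't disturb the caller's RNG
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
}

#' @export
print.oct_fit <- function(x, ...) {
  cat("<oct_fit> EHF parameters fitted by genetic algorithm\n")
  cat(sprintf("  mu_s = %.3f mm^-1, g = %.4f, p_b = %.4f, a = %.3g\n",
              x$par[["mu_s"]], x$par[["g"]], x$par[["p_b"]], x$par[["a"]]))
  cat(sprintf("  objective (SSD, dB^2) = %.4g after %d generations\n",
              x$objective, x$n_generations))
  invisible(x)
}

#' @export
tidy.oct_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.oct_fit <- function(x, ...) {
  tibble(objective = x$objective, n_depths = nrow(x$data),
         n_generations = x$n_generations, converged = x$converged,
         seed = x$seed)
}

#' @export
autoplot.oct_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$depth_mm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$log_db, colour = "A-scan")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model_db, colour = "EHF fit")) +
    ggplot2::labs(x = "depth (mm)", y = "10 log10 intensity (dB)",
                  colour = NULL, title = "EHF fit to simulated A-scan")
}

# --- sensitivity analysis ----------------------------------------------------

#' Linear-perturbation error bounds of the inverse problem
#'
#' For each optical property u in {mu_s, g, p_b}, bounds the relative
#' estimation error achievable from an A-scan with per-depth measurement
#' error `delta I`:
#' \deqn{\frac{\delta u}{u} \le \frac{1}{N_z} \sum_i
#'   \left|\frac{\partial u}{\partial I(z_i)}\right|
#'   \frac{I(z_i)}{u} \frac{\delta I(z_i)}{I(z_i)}
#'   = \frac{1}{N_z} \sum_i \frac{\delta I}
#'   {|\partial I(z_i)/\partial u| \; |u|}.}
#' The forward sensitivities \eqn{\partial I/\partial u} (I in dB) come from
#' the EHF model by central finite differences (relative step 1e-3), holding
#' the other parameters fixed.
#'
#' @param params an [ehf_params()] object (the operating point).
#' @param measurement_error_db per-depth measurement error `delta I` (dB).
#' @param z_grid depth samples (mm).
#' @return tibble of class `oct_sensitivity`: `parameter`,
#'   `relative_error_bound`; attributes `measurement_error_db`, `z_grid`.
#' @export
sensitivity_bounds <- function(params, measurement_error_db, z_grid) {
  stopifnot(inherits(params, "ehf_params"))
  if (measurement_error_db < 0)
    abort("measurement_error_db must be >= 0", class = "octmc_config_error")
  pars <- c(mu_s = params$mu_s, g = params$g, p_b = params$p_b)
  bound_for <- function(name) {
    u <- pars[[name]]
    h <- 1e-3 * abs(u)
    up <- pars; up[[name]] <- u + h
    dn <- pars; dn[[name]] <- u - h
    f <- function(p) 10 * log10(ehf_signal(
      ehf_params(p[["mu_s"]], min(p[["g"]], 1 - 1e-9), p[["p_b"]],
                 params$geometry, a = params$a), z_grid))
    dIdu <- (f(up) - f(dn)) / (2 * h)
    # the fit determines curves only up to a constant offset (the free
    # amplitude a): project that uninformative component out
    dIdu <- dIdu - mean(dIdu)
    if (any(dIdu == 0)) return(Inf)
    mean(measurement_error_db / (abs(dIdu) * abs(u)))
  }
  out <- tibble(parameter = names(pars),
                relative_error_bound = unname(vapply(names(pars), bound_for,
                                                     numeric(1))))
  class(out) <- c("oct_sensitivity", class(out))
  attr(out, "measurement_error_db") <- measurement_error_db
  attr(out, "z_grid") <- z_grid
  out
}

#' Measurement error from repeated A-scans
#'
#' Depth-resolved standard deviation of the log A-scan across repeats,
#' averaged over depth and over tissue types: the single dB figure that
#' feeds [sensitivity_bounds()].
#'
#' @param ascans tibble with columns `tissue`, `rep`, `depth_mm`, `log_db`
#'   (>= 2 repeats per tissue), or a list of lists of `oct_ascan_avg`
#'   objects (outer: tissue, inner: repeats).
#' @return scalar (dB).
#' @export
measurement_error_db <- function(ascans) {
  if (!is.data.frame(ascans)) {
    ascans <- purrr::imap_dfr(ascans, function(reps, ti) {
      purrr::imap_dfr(reps, function(a, ri) {
        tibble(tissue = as.character(ti), rep = as.integer(ri),
               depth_mm = a$depth_mm, log_db = a$log_db)
      })
    })
  }
  counts <- dplyr::count(dplyr::distinct(ascans, .data$tissue, .data$rep),
                         .data$tissue)
  if (any(counts$n < 2))
    abort("need at least 2 repeats per tissue",
          class = "octmc_contract_error")
  per_depth <- dplyr::summarise(
    dplyr::group_by(ascans, .data$tissue, .data$depth_mm),
    sd_db = sd(.data$log_db), .groups = "drop_last")
  per_tissue <- dplyr::summarise(per_depth, mean_sd = mean(.data$sd_db),
                                 .groups = "drop")
  mean(per_tissue$mean_sd)
}

# --- end-to-end recovery protocol -------------------------------------------

#' Run the parameter-recovery protocol over a tissue grid
#'
#' For each tissue in `grid` (default: the full 18-tissue crossing of
#' [phantom_grid()]), simulates `n_repeats` averaged A-scans and fits the
#' EHF model to each; returns per-tissue means and 95% confidence
#' half-widths of the fitted parameters.
#'
#' @param geometry an [beam_geometry()] object.
#' @param source an [source_spectrum()] object.
#' @param grid tibble with `mu_s`, `g`, `p_b` rows.
#' @param n_photons photon packets per sub-A-scan.
#' @param n_ascans sub-A-scans averaged per profile.
#' @param n_repeats fitted profiles per tissue.
#' @param seed base seed.
#' @param ga GA settings.
#' @return tibble with the true parameters, fitted means, and 95% CI
#'   half-widths (`t`-based), one row per tissue.
#' @export
run_recovery_grid <- function(geometry, source, grid = phantom_grid(),
                              n_photons = 1e5, n_ascans = 10, n_repeats = 3,
                              seed = 1, ga = ga_config()) {
  purrr::pmap_dfr(grid, function(mu_s, g, p_b) {
    fits <- purrr::map(seq_len(n_repeats), function(r) {
      cfg <- oct_config(geometry, source,
                        make_phantom("single_layer", mu_s = mu_s, g = g,
                                     p_b = p_b),
                        n_photons = n_photons, n_ascans = n_ascans,
                        seed = subscan_seed(seed, r * 7919 +
                                              round(1e4 * (mu_s + g + p_b))))
      avg <- oct_ascan(cfg, mode = "intensity")
      fit_ehf(avg, geometry, ga = ga, seed = seed + r)
    })
    est <- t(vapply(fits, function(f) f$par[c("mu_s", "g", "p_b")],
                    numeric(3)))
    ci <- function(x) {
      if (length(x) < 2) return(NA_real_)
      stats::qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
    }
    tibble(mu_s = mu_s, g = g, p_b = p_b,
           mu_s_hat = mean(est[, 1]), mu_s_ci = ci(est[, 1]),
           g_hat = mean(est[, 2]), g_ci = ci(est[, 2]),
           p_b_hat = mean(est[, 3]), p_b_ci = ci(est[, 3]),
           n_repeats = n_repeats)
  })
}
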