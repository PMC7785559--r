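#' Define a calibration parameter space
#'
#' @param name Parameter names. Substance-specific parameters are written
#'   `"<substance>.<field>"` (e.g. `"PFOA.k_foc"`); global parameters are
#'   `"albedo"`, `"dv"` (dispersivity, cm), `"rsmin_crops"`,
#'   `"rsmin_canola"`.
#' @param lower,upper Bounds (natural scale), `lower < upper`.
#' @param transform `"linear"` or `"log10"`; log10-transformed parameters
#'   are searched uniformly on the log scale (used for `f_star`, whose
#'   prior range spans three orders of magnitude).
#' @return Tibble of class `pfas_space`.
#' @export
param_space <- function(name, lower, upper, transform = "linear") {
  if (any(lower >= upper)) stop("need lower < upper", call. = FALSE)
  sp <- tibble::tibble(name = name, lower = lower, upper = upper,
                       transform = rep_len(transform, length(name)))
  if (any(sp$transform == "log10" & sp$lower <= 0)) {
    stop("log10-transformed parameters need positive bounds", call. = FALSE)
  }
  class(sp) <- c("pfas_space", class(sp))
  sp
}

#' Default prior parameter ranges
#'
#' The literature/prior ranges used for calibration: NER formation rate
#' 0.001-0.014 1/d (half-life 1000-50 d), kinetic adsorption rate
#' 0.0001-0.1 1/d, kinetic-site fraction 0-1, substance-specific `K_fOC`
#' (PFOA 22-332, PFOS 254-1176 ml/g) and Freundlich exponents (PFOA
#' 0.78-1.27, PFOS 0.6-1.0), transpiration-stream factor 1e-6 to 1e-3
#' (log10), dispersivity 2-12 cm, albedo 0.05-0.25 and the two minimum
#' stomatal resistances 25-100 s/m.
#'
#' @param substances Character vector of substance names (default PFOA and
#'   PFOS, in that order, picking the matching `K_fOC`/`n` ranges; further
#'   names reuse the PFOA ranges).
#' @param scenario `"II"` includes `r_ner`; `"I"` includes `alpha_k` and
#'   `f_ne`.
#' @param include_site Include albedo, dispersivity and stomatal
#'   resistances.
#' @return A [param_space()].
#' @export
default_param_space <- function(substances = c("PFOA", "PFOS"),
                                scenario = c("II", "I"),
                                include_site = TRUE) {
  scenario <- match.arg(scenario)
  kfoc_rng <- list(PFOA = c(22, 332), PFOS = c(254, 1176))
  n_rng <- list(PFOA = c(0.78, 1.27), PFOS = c(0.6, 1.0))
  rows <- purrr::map_dfr(substances, function(s) {
    kf <- kfoc_rng[[s]] %||% c(22, 332)
    nn <- n_rng[[s]] %||% c(0.78, 1.27)
    base <- tibble::tibble(
      name = paste0(s, c(".k_foc", ".n", ".f_star")),
      lower = c(kf[1], nn[1], 1e-6), upper = c(kf[2], nn[2], 1e-3),
      transform = c("linear", "linear", "log10")
    )
    kin <- if (scenario == "II") {
      tibble::tibble(name = paste0(s, ".r_ner"), lower = 0.001,
                     upper = 0.014, transform = "linear")
    } else {
      tibble::tibble(name = paste0(s, c(".alpha_k", ".f_ne")),
                     lower = c(1e-4, 0), upper = c(0.1, 1),
                     transform = "linear")
    }
    dplyr::bind_rows(kin, base)
  })
  if (include_site) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      name = c("dv", "albedo", "rsmin_crops", "rsmin_canola"),
      lower = c(2, 0.05, 25, 25), upper = c(12, 0.25, 100, 100),
      transform = "linear"
    ))
  }
  param_space(rows$name, rows$lower, rows$upper, rows$transform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

water_params <- c("albedo", "rsmin_crops", "rsmin_canola")

#' Apply a named parameter vector to a configuration
#'
#' @param config A configuration list.
#' @param par Named numeric vector; `"<substance>.<field>"` entries set
#'   substance fields, `"dv"` sets the dispersivity of every substance,
#'   `"albedo"` the site albedo and `"rsmin_crops"`/`"rsmin_canola"` the
#'   stomatal resistances in the rotation.
#' @return The modified configuration.
#' @export
apply_params <- function(config, par) {
  config <- as_config(config)
  subst_names <- vapply(config$substances, `[[`, "", "name")
  for (nm in names(par)) {
    val <- unname(par[[nm]])
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, "\\.")[[1]]
      i <- match(parts[1], subst_names)
      if (is.na(i)) stop("unknown substance '", parts[1], "'", call. = FALSE)
      if (!parts[2] %in% names(config$substances[[i]])) {
        stop("unknown substance field '", parts[2], "'", call. = FALSE)
      }
      config$substances[[i]][[parts[2]]] <- val
    } else if (nm == "dv") {
      for (i in seq_along(config$substances)) {
        config$substances[[i]]$dispersivity_cm <- val
      }
    } else if (nm == "albedo") {
      config$site$albedo <- val
    } else if (nm == "rsmin_crops") {
      config$rotation$rsmin[config$rotation$name != "canola"] <- val
    } else if (nm == "rsmin_canola") {
      config$rotation$rsmin[config$rotation$name == "canola"] <- val
    } else {
      stop("unknown parameter '", nm, "'", call. = FALSE)
    }
  }
  config
}

#' Build the multi-target KGE calibration objective
#'
#' Returns a scoring function over named parameter vectors plus a predictor
#' returning the matched simulated series (used for uncertainty envelopes).
#' When no calibrated parameter affects the water balance (albedo, stomatal
#' resistances), the water simulation is computed once and reused across
#' evaluations.
#'
#' @param config Base configuration.
#' @param obs Observation tibble.
#' @param space The [param_space()] being searched (to decide water reuse).
#' @return List with `score(par)` (scalar KGE_all; -Inf if the simulation
#'   fails), `predict(par)` (list of paired series), `details(par)`
#'   (per-target KGE table).
#' @export
make_kge_objective <- function(config, obs, space = NULL) {
  config <- as_config(config)
  reuse_water <- is.null(space) ||
    !any(space$name %in% water_params)
  water0 <- if (reuse_water) {
    run_water_balance(config$weather, config$soil, config$rotation,
                      config$site, config$options)
  }
  run <- function(par) {
    cfg <- apply_params(config, par)
    simulate_column(cfg, water = water0)
  }
  list(
    score = function(par) {
      sc <- tryCatch(score_simulation(run(par), obs)$kge_all,
                     error = function(e) -Inf)
      sc
    },
    predict = function(par) match_sim_to_obs(run(par), obs),
    details = function(par) score_simulation(run(par), obs)
  )
}

# transform helpers between natural and search coordinates
to_search <- function(x, space) {
  ifelse(space$transform == "log10", log10(x), x)
}
from_search <- function(x, space) {
  ifelse(space$transform == "log10", 10^x, x)
}

#' One particle-swarm optimisation stage
#'
#' Independent global-best PSO chains over a bounded parameter space,
#' maximising the objective. Every evaluated parameter vector is retained
#' with its score (the behavioural analysis uses all evaluations, not just
#' the optima). A chain stops when the improvement of its best
#' personal-best between consecutive iterations is at most the square root
#' of the smallest positive double, or at its simulation cap.
#'
#' @param space A [param_space()].
#' @param objective Function taking a named parameter vector, returning a
#'   scalar to maximise.
#' @param n_chains Number of independent chains.
#' @param n_particles Particles per chain.
#' @param max_sims_per_chain Evaluation budget per chain (>= `n_particles`).
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param inertia,c_cog,c_soc PSO hyperparameters (0.72, 1.49, 1.49);
#'   reflecting boundary handling.
#' @param cache Optional environment used to memoise evaluations across
#'   stages and chains.
#' @return Tibble of class `pfas_evals`: one row per evaluation with the
#'   parameter columns, `score`, `chain`, `iteration`.
#' @export
pso_stage <- function(space, objective, n_chains = 15, n_particles = 32,
                      max_sims_per_chain = 3000, seed = 1,
                      inertia = 0.72, c_cog = 1.49, c_soc = 1.49,
                      cache = NULL) {
  if (max_sims_per_chain < n_particles) {
    stop("budget smaller than one full iteration (", n_particles,
         " particles)", call. = FALSE)
  }
  np <- nrow(space)
  lo <- to_search(space$lower, space)
  hi <- to_search(space$upper, space)
  rng <- hi - lo
  tol <- sqrt(.Machine$double.xmin)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  eval_cached <- function(x_nat) {
    key <- paste(signif(x_nat, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- objective(setNames(x_nat, space$name))
    cache[[key]] <- val
    val
  }
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, n_chains)

  all_evals <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    x <- matrix(runif(n_particles * np, rep(lo, each = n_particles),
                      rep(hi, each = n_particles)), n_particles, np)
    v <- matrix(runif(n_particles * np, -1, 1), n_particles, np) *
      matrix(rng, n_particles, np, byrow = TRUE) * 0.25
    pbest_x <- x; pbest_s <- rep(-Inf, n_particles)
    gbest_s <- -Inf; gbest_x <- x[1, ]
    prev_best <- -Inf
    sims <- 0L; iter <- 0L
    rows <- list()
    while (sims < max_sims_per_chain) {
      iter <- iter + 1L
      n_eval <- min(n_particles, max_sims_per_chain - sims)
      idx <- seq_len(n_eval)
      xs_nat <- x[idx, , drop = FALSE]          # n_eval x np
      islog <- space$transform == "log10"
      xs_nat[, islog] <- 10^xs_nat[, islog]
      sc <- vapply(seq_len(n_eval),
                   function(j) eval_cached(xs_nat[j, ]), numeric(1))
      sims <- sims + n_eval
      rows[[iter]] <- cbind(as.data.frame(xs_nat), score = sc,
                            chain = ch, iteration = iter)
      better <- sc > pbest_s[idx]
      imp <- idx[better]
      pbest_s[imp] <- sc[better]
      pbest_x[imp, ] <- x[imp, , drop = FALSE]
      if (max(pbest_s) > gbest_s) {
        gbest_s <- max(pbest_s)
        gbest_x <- pbest_x[which.max(pbest_s), ]
      }
      if (iter > 1 && abs(gbest_s - prev_best) <= tol) break
      prev_best <- gbest_s
      r1 <- matrix(runif(n_particles * np), n_particles, np)
      r2 <- matrix(runif(n_particles * np), n_particles, np)
      v <- inertia * v + c_cog * r1 * (pbest_x - x) +
        c_soc * r2 * (matrix(gbest_x, n_particles, np, byrow = TRUE) - x)
      x <- x + v
      # reflecting boundaries
      for (k in seq_len(np)) {
        below <- x[, k] < lo[k]; above <- x[, k] > hi[k]
        x[below, k] <- pmin(2 * lo[k] - x[below, k], hi[k])
        x[above, k] <- pmax(2 * hi[k] - x[above, k], lo[k])
        v[below | above, k] <- -v[below | above, k]
      }
    }
    all_evals[[ch]] <- do.call(rbind, rows)
  }
  out <- tibble::as_tibble(do.call(rbind, all_evals))
  names(out)[seq_len(np)] <- space$name
  class(out) <- c("pfas_evals", class(out))
  out
}

#' Two-stage behavioural particle-swarm calibration
#'
#' Stage 1 searches the full prior space; evaluations scoring above the
#' first behavioural threshold define the stage-2 search intervals (their
#' per-parameter minima and maxima). Stage 2 re-searches that reduced space;
#' all stage-2 evaluations above the second threshold form the behavioural
#' ensemble, from which pointwise min/max uncertainty envelopes of every
#' target series and posterior parameter quantiles are computed.
#'
#' @param space Prior [param_space()].
#' @param objective A [make_kge_objective()] result (or any list with
#'   `score` and `predict` functions).
#' @param stage1,stage2 Lists with `n_chains`, `n_particles`,
#'   `max_sims_per_chain` (defaults: 15 x 32 x 3000 and 10 x 32 x 32000).
#' @param thresholds Behavioural KGE_all thresholds, stage 1 and stage 2
#'   (defaults 0.6 and 0.75).
#' @param seed Master seed.
#' @param envelope_max Cap on ensemble members re-simulated for envelopes.
#' @return Object of class `pfas_ensemble`.
#' @export
two_stage_calibrate <- function(space, objective,
                                stage1 = list(), stage2 = list(),
                                thresholds = c(0.6, 0.75), seed = 1,
                                envelope_max = 200) {
  s1 <- modifyList(list(n_chains = 15, n_particles = 32,
                        max_sims_per_chain = 3000), stage1)
  s2 <- modifyList(list(n_chains = 10, n_particles = 32,
                        max_sims_per_chain = 32000), stage2)
  cache <- new.env(parent = emptyenv())
  ev1 <- pso_stage(space, objective$score, s1$n_chains, s1$n_particles,
                   s1$max_sims_per_chain, seed = seed, cache = cache)
  behav1 <- dplyr::filter(ev1, .data$score > thresholds[1])
  if (nrow(behav1) == 0) {
    stop("no behavioural models in stage 1 (best KGE_all = ",
         signif(max(ev1$score), 3), ", threshold ", thresholds[1], ")",
         call. = FALSE)
  }
  space2 <- space
  for (k in seq_len(nrow(space))) {
    vals <- behav1[[space$name[k]]]
    space2$lower[k] <- min(vals)
    space2$upper[k] <- max(vals)
  }
  # PSO needs nonzero width; keep a degenerate dimension fixed via tiny width
  w <- space2$upper - space2$lower
  fix <- w <= 0
  space2$upper[fix] <- space2$lower[fix] * (1 + 1e-9) + 1e-12
  ev2 <- pso_stage(space2, objective$score, s2$n_chains, s2$n_particles,
                   s2$max_sims_per_chain, seed = seed + 1L, cache = cache)
  ensemble <- dplyr::filter(ev2, .data$score > thresholds[2])
  env <- NULL
  if (nrow(ensemble) > 0 && !is.null(objective$predict)) {
    mem <- dplyr::distinct(ensemble,
                           dplyr::across(dplyr::all_of(space$name)),
                           .keep_all = TRUE)
    if (nrow(mem) > envelope_max) {
      mem <- dplyr::slice_max(mem, .data$score, n = envelope_max,
                              with_ties = FALSE)
    }
    preds <- lapply(seq_len(nrow(mem)), function(i) {
      objective$predict(unlist(mem[i, space$name]))
    })
    env <- purrr::map_dfr(names(preds[[1]]), function(v) {
      mat <- vapply(preds, function(p) p[[v]]$sim,
                    numeric(nrow(preds[[1]][[v]])))
      mat <- matrix(mat, nrow = nrow(preds[[1]][[v]]))
      tibble::tibble(target = v, date = preds[[1]][[v]]$date,
                     obs = preds[[1]][[v]]$obs,
                     env_min = apply(mat, 1, min),
                     env_max = apply(mat, 1, max))
    })
  }
  structure(list(
    stage1 = ev1, stage2 = ev2, behavioural = ensemble,
    space = space, space_stage2 = space2, thresholds = thresholds,
    envelopes = env,
    posterior = if (nrow(ensemble)) posterior_table(ensemble, space$name)
  ), class = "pfas_ensemble")
}

#' Posterior parameter statistics of a behavioural ensemble
#'
#' Minimum, 5th, 50th and 95th percentile and maximum per parameter,
#' linear-interpolation quantiles (R type 7).
#'
#' @param ensemble Tibble of behavioural evaluations (or a `pfas_ensemble`).
#' @param params Parameter column names; defaults to all columns except
#'   `score`, `chain`, `iteration`.
#' @return Tibble with one row per parameter.
#' @export
posterior_table <- function(ensemble, params = NULL) {
  if (inherits(ensemble, "pfas_ensemble")) {
    params <- params %||% ensemble$space$name
    ensemble <- ensemble$behavioural
  }
  if (nrow(ensemble) == 0) stop("empty ensemble", call. = FALSE)
  params <- params %||%
    setdiff(names(ensemble), c("score", "chain", "iteration"))
  purrr::map_dfr(params, function(p) {
    q <- quantile(ensemble[[p]], c(0, 0.05, 0.5, 0.95, 1), type = 7,
                  names = FALSE)
    tibble::tibble(parameter = p, min = q[1], q05 = q[2], q50 = q[3],
                   q95 = q[4], max = q[5])
  })
}

#' @export
tidy.pfas_ensemble <- function(x, ...) x$behavioural

#' @export
glance.pfas_ensemble <- function(x, ...) {
  tibble::tibble(
    n_stage1 = nrow(x$stage1), n_stage2 = nrow(x$stage2),
    n_behavioural = nrow(x$behavioural),
    best_kge_all = max(c(x$stage1$score, x$stage2$score)),
    median_behavioural_kge = if (nrow(x$behavioural))
      stats::median(x$behavioural$score) else NA_real_
  )
}

#' @export
print.pfas_ensemble <- function(x, ...) {
  cat("<pfas_ensemble>\n")
  print(glance(x))
  if (!is.null(x$posterior)) {
    cat("posterior parameter statistics:\n")
    print(x$posterior)
  }
  invisible(x)
}

#' Uncertainty-envelope plot of a calibrated ensemble
#'
#' @param object A `pfas_ensemble` with envelopes.
#' @param ... Unused.
#' @return A ggplot object: observations with the behavioural min/max band
#'   per target.
#' @export
autoplot.pfas_ensemble <- function(object, ...) {
  if (is.null(object$envelopes)) stop("ensemble has no envelopes",
                                      call. = FALSE)
  ggplot2::ggplot(object$envelopes, ggplot2::aes(.data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_min,
                                      ymax = .data$env_max),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs), size = 0.7) +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
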