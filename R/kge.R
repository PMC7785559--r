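#' Kling-Gupta efficiency of a simulated series against observations
#'
#' `KGE = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2)` with `r` the
#' Pearson correlation, `alpha = sd(sim)/sd(obs)` the variability ratio
#' (sample standard deviations) and `beta = mean(sim)/mean(obs)` the bias
#' ratio. A perfect simulation scores 1.
#'
#' @param sim,obs Paired numeric series of equal length (>= 2).
#' @return One-row tibble with `r`, `alpha`, `beta`, `kge`.
#' @details If the simulated series is constant its correlation with the
#'   observations is undefined; `r` is set to 0 in that case (a constant
#'   simulation carries no dynamics). A constant or zero-mean *observation*
#'   series makes the metric itself undefined and raises an error.
#' @export
kge <- function(sim, obs) {
  if (length(sim) != length(obs)) stop("`sim` and `obs` lengths differ",
                                       call. = FALSE)
  if (length(obs) < 2) stop("need at least 2 paired points", call. = FALSE)
  if (anyNA(sim) || anyNA(obs)) stop("NA in paired series", call. = FALSE)
  s_o <- sd(obs); m_o <- mean(obs)
  if (s_o == 0) stop("KGE undefined: observations have zero variance",
                     call. = FALSE)
  if (m_o == 0) stop("KGE undefined: observations have zero mean",
                     call. = FALSE)
  s_m <- sd(sim)
  r <- if (s_m == 0) 0 else cor(sim, obs)
  alpha <- s_m / s_o
  beta <- mean(sim) / m_o
  tibble::tibble(r = r, alpha = alpha, beta = beta,
                 kge = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2))
}

#' Multi-target likelihood: arithmetic mean of per-target KGEs
#'
#' @param kges Numeric vector of per-target KGE values (typically the five
#'   targets Q, C_PFOA, U_PFOA, C_PFOS, U_PFOS); no missing values allowed.
#' @return Scalar mean KGE.
#' @export
kge_all <- function(kges) {
  kges <- unlist(kges, use.names = FALSE)
  if (length(kges) == 0 || anyNA(kges)) {
    stop("kge_all requires every target KGE to be available", call. = FALSE)
  }
  mean(kges)
}

#' Pair simulation output with an observation set, target by target
#'
#' Pairing rules: monthly percolation `Q` is paired on every observed month
#' (calendar-month labels, not index); leachate concentrations `C_*` only on
#' months where both an observation exists and the simulation produced
#' outflow (concentrations are undefined without leachate); seasonal uptake
#' `U_*` by harvest year.
#'
#' @param sim A `pfas_sim`.
#' @param obs Observation tibble with columns `date`, `variable`, `value`
#'   (variables `Q`, `C_<substance>`, `U_<substance>`).
#' @return Named list of tibbles (`date`, `obs`, `sim`), one per target.
#' @export
match_sim_to_obs <- function(sim, obs) {
  stopifnot(inherits(sim, "pfas_sim"))
  obs <- dplyr::mutate(obs, date = as.Date(.data$date))
  out <- list()
  for (v in unique(obs$variable)) {
    o <- dplyr::filter(obs, .data$variable == v)
    if (v == "Q") {
      o <- dplyr::mutate(o, month = as.Date(format(.data$date, "%Y-%m-01")))
      p <- dplyr::inner_join(o, sim$monthly_q, by = "month")
      pairing <- tibble::tibble(date = p$month, obs = p$value, sim = p$q_l)
    } else if (grepl("^C_", v)) {
      nm <- sub("^C_", "", v)
      r <- sim$substances[[nm]]
      if (is.null(r)) stop("no simulated substance '", nm, "'", call. = FALSE)
      o <- dplyr::mutate(o, month = as.Date(format(.data$date, "%Y-%m-01")))
      m <- dplyr::filter(r$monthly, .data$q_l > 0, !is.na(.data$c_ugl))
      p <- dplyr::inner_join(o, m, by = "month")
      pairing <- tibble::tibble(date = p$month, obs = p$value, sim = p$c_ugl)
    } else if (grepl("^U_", v)) {
      nm <- sub("^U_", "", v)
      r <- sim$substances[[nm]]
      if (is.null(r)) stop("no simulated substance '", nm, "'", call. = FALSE)
      o <- dplyr::mutate(o, season = as.integer(format(.data$date, "%Y")))
      p <- dplyr::inner_join(o, r$seasonal, by = "season")
      pairing <- tibble::tibble(date = p$date, obs = p$value,
                                sim = p$uptake_g)
    } else {
      stop("unknown observation variable '", v, "'", call. = FALSE)
    }
    if (nrow(pairing) == 0) {
      stop("empty sim/obs pairing for target '", v, "'", call. = FALSE)
    }
    out[[v]] <- pairing
  }
  out
}

#' Score a simulation against an observation set
#'
#' @param sim A `pfas_sim`.
#' @param obs Observation tibble (see [match_sim_to_obs()]).
#' @return List with `targets` (tibble of per-target r/alpha/beta/KGE) and
#'   `kge_all`.
#' @export
score_simulation <- function(sim, obs) {
  pairs <- match_sim_to_obs(sim, obs)
  tab <- purrr::imap_dfr(pairs, function(p, v) {
    dplyr::mutate(kge(p$sim, p$obs), target = v, .before = 1)
  })
  list(targets = tab, kge_all = kge_all(tab$kge))
}
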