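#' Freundlich coefficient from the organic-carbon normalised coefficient
#'
#' Perfluoroalkyl acid sorption in soil is dominated by organic carbon, so the
#' Freundlich coefficient of a soil layer scales linearly with its
#' organic-carbon fraction: `K_f = K_fOC * f_OC`.
#'
#' @param k_foc Organic-carbon normalised Freundlich coefficient (ml/g).
#' @param f_oc Organic-carbon mass fraction of the soil (0-1).
#' @return Freundlich coefficient `K_f` in ml/g (equivalently l/kg when
#'   concentrations are mg/l and sorbed loads mg/kg).
#' @examples
#' kf_from_koc(510, 0.015)
#' @export
kf_from_koc <- function(k_foc, f_oc) {
  if (any(k_foc < 0) || any(f_oc < 0)) {
    stop("`k_foc` and `f_oc` must be non-negative", call. = FALSE)
  }
  k_foc * f_oc
}

#' Transpiration-stream concentration factor from log K_OW
#'
#' Empirical bell-shaped relation between a compound's octanol-water partition
#' coefficient and the ratio of its concentration in the root transpiration
#' stream to that in soil pore water:
#' `TSCF = 0.784 * exp(-(log K_OW - 1.78)^2 / 2.44)`.
#' Developed for pesticides; for perfluoroalkyl acids the log K_OW itself is
#' a model estimate (it cannot be measured for surfactants), so the result is
#' an upper-end screening value rather than a calibrated uptake factor.
#'
#' @param log_kow log10 octanol-water partition coefficient (dimensionless).
#' @return Transpiration-stream concentration factor (dimensionless, max
#'   0.784 at log K_OW = 1.78).
#' @examples
#' briggs_fstar(4.81) # PFOA
#' briggs_fstar(4.49) # PFOS
#' @export
briggs_fstar <- function(log_kow) {
  stopifnot(is.numeric(log_kow), all(is.finite(log_kow)))
  0.784 * exp(-(log_kow - 1.78)^2 / 2.44)
}

# Vectorised solve of the Freundlich mass-partition equation
#   V*c + Ms*Kf*c^n = M       (c in mg/l, sorbed load Kf*c^n in mg/kg)
# f(c) is strictly increasing with f(0) = -M <= 0 and f(M/V) >= 0, so the root
# is bracketed by [0, M/V]. Newton from the upper bracket converges
# monotonically for both n < 1 (concave f) and n > 1 (convex f); a bisection
# safeguard keeps iterates inside the bracket regardless.
freundlich_solve <- function(m_mg, v_l, ms_kg, kf, n, rel_tol = 1e-12,
                             max_iter = 200L) {
  len <- max(length(m_mg), length(v_l), length(ms_kg), length(kf), length(n))
  if (length(m_mg) != len) m_mg <- rep_len(m_mg, len)
  if (length(v_l) != len) v_l <- rep_len(v_l, len)
  if (length(ms_kg) != len) ms_kg <- rep_len(ms_kg, len)
  if (length(kf) != len) kf <- rep_len(kf, len)
  if (length(n) != len) n <- rep_len(n, len)
  out <- numeric(len)
  # below 1e-12 mg per layer the partition is numerically meaningless
  # (and the nonlinear solve ill-conditioned); treat as zero concentration
  act <- m_mg > 1e-12 & v_l > 0
  if (!any(act)) return(out)
  if (!all(act)) {
    m_mg <- m_mg[act]; v_l <- v_l[act]; ms_kg <- ms_kg[act]
    kf <- kf[act]; n <- n[act]
  }

  b <- ms_kg * kf
  lin <- b == 0 | abs(n - 1) < 1e-14
  # linear isotherm / no sorbent: closed form
  cc <- m_mg / (v_l + b)
  if (!all(lin)) {
    nl <- !lin
    mi <- m_mg[nl]; vi <- v_l[nl]; bi <- b[nl]; ni <- n[nl]
    lo <- numeric(length(mi))
    # both m/V and (m/B)^(1/n) bound the root from above (f >= 0 at either)
    hi <- pmin(mi / vi, (mi / bi)^(1 / ni))
    ci <- hi
    tinyc <- .Machine$double.xmin
    for (it in seq_len(max_iter)) {
      cn_pow <- ci^ni
      f <- vi * ci + bi * cn_pow - mi
      neg <- f < 0
      lo[neg] <- ci[neg]
      pos <- f > 0
      hi[pos] <- ci[pos]
      cn <- ci - f / (vi + bi * ni * cn_pow / ci)
      bad <- !is.finite(cn) | ((cn <= lo | cn >= hi) & f != 0)
      if (any(bad)) cn[bad] <- (lo[bad] + hi[bad]) / 2
      done <- abs(cn - ci) <= rel_tol * pmax(cn, tinyc) |
        abs(f) <= 1e-13 * mi
      ci <- cn
      if (all(done)) break
    }
    if (it == max_iter && !all(done)) {
      stop("Freundlich partition solve did not converge: max residual ",
           format(max(abs(vi * ci + bi * ci^ni - mi))), call. = FALSE)
    }
    cc[nl] <- ci
  }
  out[act] <- cc
  out
}

#' Freundlich equilibrium partition of a solute mass in a soil layer
#'
#' Splits a total reversibly held mass between pore water and the sorbed phase
#' such that `s = K_f c^n` (Freundlich isotherm, `c` in mg/l, `s` in mg/kg)
#' and `V c + M_soil s = M_total` hold simultaneously. Because the isotherm is
#' nonlinear the partition has no closed form for `n != 1`; a
#' bracket-safeguarded Newton iteration solves it to a relative tolerance of
#' 1e-12.
#'
#' Units matter for nonlinear isotherms: `K_f` in ml/g applies to
#' concentrations in mg/l and loads in mg/kg, and the numeric value of `K_f`
#' is *not* transferable to other unit systems when `n != 1`.
#'
#' @param total_mass Total reversibly held mass in the layer (g).
#' @param water_volume Pore-water volume (l), > 0.
#' @param soil_mass Dry soil mass (kg), > 0.
#' @param k_f Freundlich coefficient (ml/g).
#' @param n Freundlich exponent (dimensionless, > 0).
#' @return A tibble with one row: `c_ug_l` (dissolved concentration, ug/l),
#'   `s_ug_g` (sorbed load, ug/g), `dissolved_g`, `sorbed_g`.
#' @examples
#' freundlich_partition(2e-3, 1, 1, k_f = 1, n = 1)
#' @export
freundlich_partition <- function(total_mass, water_volume, soil_mass, k_f, n) {
  if (total_mass < 0) stop("`total_mass` must be >= 0", call. = FALSE)
  if (water_volume <= 0 || soil_mass <= 0) {
    stop("`water_volume` and `soil_mass` must be > 0", call. = FALSE)
  }
  if (k_f < 0 || n <= 0) stop("`k_f` >= 0 and `n` > 0 required", call. = FALSE)
  c_mg_l <- freundlich_solve(total_mass * 1000, water_volume, soil_mass,
                             k_f, n, rel_tol = 1e-12)
  dis_g <- c_mg_l * water_volume / 1000
  tibble::tibble(
    c_ug_l = c_mg_l * 1000,
    s_ug_g = if (total_mass > 0) k_f * c_mg_l^n else 0,
    dissolved_g = dis_g,
    sorbed_g = total_mass - dis_g
  )
}

#' One first-order NER-formation step (Scenario II)
#'
#' Irreversible fixation of the sorbed phase as non-extractable residues:
#' over a step `dt` the fraction `1 - exp(-r_ner * dt)` of the equilibrium
#' sorbed pool is transferred into the NER pool. The dissolved pool is not
#' touched within this sub-step (equilibrium sorption is recomputed first in
#' the operator split), and the NER pool never decreases. No soil-moisture or
#' temperature modifier is applied.
#'
#' @param pools A list or one-row data frame with at least `sorbed_eq` and
#'   `ner` (g); extra elements are passed through.
#' @param r_ner First-order NER formation rate (1/d), >= 0.
#' @param dt Time step (d).
#' @return `pools` with mass moved from `sorbed_eq` to `ner`.
#' @export
ner_step <- function(pools, r_ner, dt = 1) {
  if (any(r_ner < 0)) stop("`r_ner` must be >= 0", call. = FALSE)
  transfer <- pools$sorbed_eq * (1 - exp(-r_ner * dt))
  pools$sorbed_eq <- pools$sorbed_eq - transfer
  pools$ner <- pools$ner + transfer
  pools
}

#' One kinetic two-site sorption step (Scenario I)
#'
#' Two-site concept: a fraction `1 - f_ne` of the Freundlich sorption capacity
#' equilibrates instantaneously, while the remaining fraction `f_ne` is a
#' kinetic pool relaxing towards its own Freundlich target
#' `f_ne * K_f * c^n` at first-order rate `alpha_k / f_ne` (the adsorption and
#' desorption rate are the same). The step is discretised implicitly over
#' `dt`, and the transferred mass is exchanged exactly with the dissolved
#' pool (capped at the mass available for adsorption).
#'
#' @param pools List/one-row frame with `dissolved` and `sorbed_kin` (g).
#' @param target_kin_g Kinetic-pool equilibrium target mass (g), i.e.
#'   `soil_mass * f_ne * K_f * c^n / 1000` at the current dissolved
#'   concentration.
#' @param alpha_k Kinetic sorption rate (1/d), >= 0.
#' @param f_ne Fraction of kinetic sorption sites (0-1).
#' @param dt Time step (d).
#' @return Updated pools; mass conserved exactly between `dissolved` and
#'   `sorbed_kin`.
#' @export
kinetic_sorption_step <- function(pools, target_kin_g, alpha_k, f_ne, dt = 1) {
  if (any(f_ne < 0) || any(f_ne > 1)) {
    stop("`f_ne` must lie in [0, 1]", call. = FALSE)
  }
  if (any(alpha_k < 0)) stop("`alpha_k` must be >= 0", call. = FALSE)
  if (all(alpha_k == 0) || all(f_ne == 0)) return(pools)
  rate <- ifelse(f_ne > 0, alpha_k / f_ne, 0)
  s_new <- (pools$sorbed_kin + dt * rate * target_kin_g) / (1 + dt * rate)
  transfer <- s_new - pools$sorbed_kin
  transfer <- pmin(transfer, pools$dissolved)      # adsorption limited by solution
  transfer <- pmax(transfer, -pools$sorbed_kin)    # desorption limited by pool
  pools$sorbed_kin <- pools$sorbed_kin + transfer
  pools$dissolved <- pools$dissolved - transfer
  pools
}

#' Convert a half-life to a first-order rate
#'
#' @param dt50 Half-life (d), > 0.
#' @return Rate `ln(2)/DT50` in 1/d.
#' @examples
#' rate_from_dt50(50) # upper bound of the NER formation prior range
#' @export
rate_from_dt50 <- function(dt50) {
  stopifnot(all(dt50 > 0))
  log(2) / dt50
}
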