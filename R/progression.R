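#' Classic fixed-percentage load progression
#'
#' The conventional progression scheme compounds the training load by a
#' fixed percentage at every progression: after `n` progressions the load is
#' `initial * (1 + pct)^n`.
#'
#' @param initial starting load in kg (> 0).
#' @param pct per-progression increase as a proportion (e.g. 0.05).
#' @param n number of progressions (>= 0).
#' @return final load in kg (unrounded).
#' @examples
#' classic_progression(50, 0.05, 5)  # 63.81 kg, ~64 kg to the nearest kg
#' @export
classic_progression <- function(initial, pct, n) {
  vl_assert(is.numeric(initial) && all(initial > 0), "initial load must be positive")
  vl_assert(is.numeric(pct) && all(pct > -1), "pct must be greater than -1")
  vl_assert(is_count(n), "n must be a non-negative integer")
  initial * (1 + pct)^n
}

#' Decay-corrected load progression
#'
#' Training trajectories flatten over an intervention, so equal (let alone
#' compounding) load jumps increasingly overshoot what the patient can
#' absorb. This scheme shrinks each successive absolute increment: the first
#' increment is `pct` of the initial load, and every later increment is the
#' previous one reduced by `decay`. After `n` progressions the load is
#' `initial + sum_{i=0}^{n-1} initial * pct * (1 - decay)^i`.
#'
#' @param initial starting load in kg (> 0).
#' @param pct first increment as a proportion of the initial load.
#' @param decay per-progression shrinkage of the absolute increment, in
#'   `[0, 1)` (e.g. 0.04 for a 4% correction).
#' @param n number of progressions (>= 0).
#' @return final load in kg (unrounded).
#' @examples
#' corrected_progression(50, 0.05, 0.04, 5)  # 61.54 kg, ~61.5 to one decimal
#' @export
corrected_progression <- function(initial, pct, decay, n) {
  vl_assert(is.numeric(initial) && all(initial > 0), "initial load must be positive")
  vl_assert(is.numeric(pct) && all(pct > -1), "pct must be greater than -1")
  vl_assert(is.numeric(decay) && all(decay >= 0 & decay < 1),
            "decay must be in [0, 1)")
  vl_assert(is_count(n), "n must be a non-negative integer")
  if (n == 0) return(initial)
  increments <- initial * pct * (1 - decay)^(0:(n - 1))
  initial + sum(increments)
}

#' Full load sequence of a progression scheme
#'
#' @param initial starting load in kg.
#' @param pct per-progression percentage (classic) or first-increment
#'   proportion (corrected).
#' @param n number of progressions.
#' @param scheme `"classic"` or `"corrected"`.
#' @param decay increment decay for the corrected scheme (default 0.04).
#' @return a tibble of class `vl_progression_plan` with columns `step`
#'   (0..n) and `load_kg`, plus attributes recording the parameters.
#' @export
progression_plan <- function(initial, pct, n, scheme = c("corrected", "classic"),
                             decay = 0.04) {
  scheme <- match.arg(scheme)
  loads <- if (scheme == "classic") {
    vapply(0:n, function(i) classic_progression(initial, pct, i), numeric(1))
  } else {
    vapply(0:n, function(i) corrected_progression(initial, pct, decay, i), numeric(1))
  }
  out <- tibble::tibble(step = 0:n, load_kg = loads)
  attr(out, "scheme") <- scheme
  attr(out, "pct") <- pct
  attr(out, "decay") <- if (scheme == "corrected") decay else NA_real_
  class(out) <- c("vl_progression_plan", class(out))
  out
}
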