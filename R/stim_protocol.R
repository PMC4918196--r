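# Trapezoidal pulse-width stimulation protocols for the identification and
# prediction phases of a torque-estimation session.

#' Stimulation protocol configuration
#'
#' A session is built from repeated trapezoidal pulse-width (PW) trains:
#' ramp-up, plateau, ramp-down, then rest. During identification the plateau
#' PW of successive cycles increases gradually over `id_range` of the maximum
#' PW; during prediction each plateau is drawn uniformly at random within
#' `pred_range` of the maximum.
#'
#' @param f_stim stimulation frequency in Hz (40 able-bodied / 30 SCI
#'   profile by convention).
#' @param pw_max maximum pulse width in microseconds; capped at `pw_cap`.
#' @param ramp_up_s,plateau_s,ramp_down_s,rest_s trapezoid segment durations
#'   in seconds (defaults 0.5, 1, 0.5, 2: a 2 s train plus 2 s rest).
#' @param n_cycles number of trapezoidal cycles (the reference protocol uses
#'   18 +/- 2 per sequence).
#' @param phase `"identification"` or `"prediction"`.
#' @param id_range plateau fraction range for identification (default
#'   0.40-1.00 of `pw_max`).
#' @param pred_range plateau fraction range for prediction (default
#'   0.50-1.00 of `pw_max`).
#' @param seed RNG seed for the random prediction plateaus.
#' @param amplitude_mA stimulation current, carried as metadata only (PW
#'   modulation is the sole model input).
#' @param pw_cap stimulator hardware limit in microseconds (default 350).
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(f_stim = 40, pw_max = 350, ramp_up_s = 0.5,
                            plateau_s = 1, ramp_down_s = 0.5, rest_s = 2,
                            n_cycles = 18,
                            phase = c("identification", "prediction"),
                            id_range = c(0.40, 1.00),
                            pred_range = c(0.50, 1.00),
                            seed = NULL, amplitude_mA = 30, pw_cap = 350) {
  phase <- match.arg(phase)
  if (f_stim < 1 || f_stim > 1000) stopf("f_stim must lie in [1, 1000] Hz")
  if (pw_max <= 0 || pw_max > pw_cap) {
    stopf("pw_max must lie in (0, %g] us", pw_cap)
  }
  for (rng in list(id_range, pred_range)) {
    if (length(rng) != 2L || any(rng <= 0) || any(rng > 1) ||
        rng[1] > rng[2]) {
      stopf("plateau fraction ranges must be ordered pairs within (0, 1]")
    }
  }
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (min(ramp_up_s, plateau_s, ramp_down_s, rest_s) < 0 ||
      ramp_up_s + plateau_s + ramp_down_s <= 0) {
    stopf("segment durations must be non-negative with a non-empty train")
  }
  structure(
    list(f_stim = f_stim, pw_max = pw_max, ramp_up_s = ramp_up_s,
         plateau_s = plateau_s, ramp_down_s = ramp_down_s, rest_s = rest_s,
         cycle_s = ramp_up_s + plateau_s + ramp_down_s + rest_s,
         n_cycles = as.integer(n_cycles), phase = phase,
         id_range = id_range, pred_range = pred_range, seed = seed,
         amplitude_mA = amplitude_mA, pw_cap = pw_cap),
    class = "protocol_config"
  )
}

#' Trapezoidal pulse-width profile within one cycle
#'
#' Linear 0 to `plateau_pw` over the ramp-up, held over the plateau, linear
#' back to 0 over the ramp-down, 0 during rest; continuous at segment joins.
#'
#' @param t time within the cycle in seconds, `0 <= t < cycle period`
#'   (vectorized).
#' @param plateau_pw plateau pulse width in microseconds.
#' @param cfg a [protocol_config()].
#' @return pulse width in microseconds.
#' @export
trapezoid_pw <- function(t, plateau_pw, cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (plateau_pw > cfg$pw_max) stopf("PW exceeds stimulator limit")
  if (any(t < 0 | t >= cfg$cycle_s)) {
    stopf("t must lie within [0, cycle period)")
  }
  t1 <- cfg$ramp_up_s
  t2 <- t1 + cfg$plateau_s
  t3 <- t2 + cfg$ramp_down_s
  pw <- numeric(length(t))
  up <- t < t1
  pw[up] <- plateau_pw * t[up] / t1
  pl <- t >= t1 & t < t2
  pw[pl] <- plateau_pw
  dn <- t >= t2 & t < t3
  pw[dn] <- plateau_pw * (t3 - t[dn]) / cfg$ramp_down_s
  pw
}

#' Build the per-loop pulse-width sequence for one protocol phase
#'
#' Plateau pulse widths per cycle: identification uses fractions linearly
#' spaced over `id_range`; prediction draws them i.i.d. uniform over
#' `pred_range` (reproducible from `seed`). The continuous trapezoid is
#' sampled at the left-edge time of each stimulation loop.
#'
#' @param cfg a [protocol_config()].
#' @return a data frame of class `fes_protocol` with columns `loop_k`, `t_s`,
#'   `pw_us`, `cycle_id`, `phase`; the configuration is attached as attribute
#'   `config`.
#' @export
build_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  fracs <- if (cfg$phase == "identification") {
    if (cfg$n_cycles == 1L) {
      cfg$id_range[2]
    } else {
      seq(cfg$id_range[1], cfg$id_range[2], length.out = cfg$n_cycles)
    }
  } else {
    with_seed(cfg$seed,
              runif(cfg$n_cycles, cfg$pred_range[1], cfg$pred_range[2]))
  }
  plateaus <- fracs * cfg$pw_max
  n_loops <- round_half_up(cfg$n_cycles * cfg$cycle_s * cfg$f_stim)
  k <- seq_len(n_loops) - 1L
  t_s <- k / cfg$f_stim
  cycle <- pmin(cfg$n_cycles - 1L, as.integer(floor(t_s / cfg$cycle_s)))
  t_in <- t_s - cycle * cfg$cycle_s
  pw <- numeric(n_loops)
  for (c_id in unique(cycle)) {
    sel <- cycle == c_id
    pw[sel] <- trapezoid_pw(t_in[sel], plateaus[c_id + 1L], cfg)
  }
  out <- data.frame(loop_k = k, t_s = t_s, pw_us = pw, cycle_id = cycle,
                    phase = cfg$phase, stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  attr(out, "plateaus_us") <- plateaus
  class(out) <- c("fes_protocol", "data.frame")
  out
}

#' @export
print.fes_protocol <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<fes_protocol> %s: %d loops @ %g Hz, %d cycles, plateaus %.0f-%.0f us\n",
    x$phase[1], nrow(x), cfg$f_stim, cfg$n_cycles,
    min(attr(x, "plateaus_us")), max(attr(x, "plateaus_us"))
  ))
  invisible(x)
}

# Concatenate identification + prediction protocols into one session-long
# loop series with a continuous time axis.
concat_protocols <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  cfg <- attr(parts[[1L]], "config")
  off_t <- 0
  off_k <- 0L
  off_c <- 0L
  rows <- lapply(parts, function(p) {
    pc <- attr(p, "config")
    if (abs(pc$f_stim - cfg$f_stim) > 1e-9) {
      stopf("all protocol parts must share f_stim")
    }
    q <- as.data.frame(p)
    q$t_s <- q$t_s + off_t
    q$loop_k <- q$loop_k + off_k
    q$cycle_id <- q$cycle_id + off_c
    off_t <<- off_t + nrow(p) / pc$f_stim
    off_k <<- off_k + nrow(p)
    off_c <<- off_c + pc$n_cycles
    q
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("fes_protocol", "data.frame")
  out
}
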