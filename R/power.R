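# Series-level simulation of replicate velocity measurements, used to study
# the sensitivity of the linear-window readout: how often a programmed
# slowdown is declared significant across seeded repetitions.

#' Simulate one noisy closure series
#'
#' Generates a closure series with a programmed constant edge speed and
#' additive Gaussian area noise (the aggregate of segmentation error and
#' edge irregularity), on the standard 10-min sampling grid.
#'
#' @param v_um_per_h True edge speed, um/h.
#' @param duration_hours Series duration (default 12).
#' @param frame_interval_hours Sampling interval (default 1/6).
#' @param wound_length_um Wound length (default 480, the synthetic benchmark
#'   field height).
#' @param initial_width_um Initial scratch width (default 500).
#' @param area_noise_um2 SD of the per-frame area noise (default 2.5% of the
#'   initial gap area, the scale of typical segmentation error).
#' @param N Smoothing window in frames.
#' @param position_id Label.
#' @return A `closure_series`.
#' @export
simulate_noisy_series <- function(v_um_per_h, duration_hours = 12,
                                  frame_interval_hours = 1 / 6,
                                  wound_length_um = 480,
                                  initial_width_um = 500,
                                  area_noise_um2 = 0.025 * initial_width_um *
                                    wound_length_um,
                                  N = 6L, position_id = "sim") {
  t <- seq(0, duration_hours, by = frame_interval_hours)
  A0 <- initial_width_um * wound_length_um
  area <- pmax(A0 - 2 * v_um_per_h * wound_length_um * t, 0) +
    rnorm(length(t), sd = area_noise_um2)
  area_series(t_hours = t, pixel_size_um = 1, wound_length_um = wound_length_um,
              area_um2 = area, N = N, position_id = position_id)
}

#' Simulate replicate velocity estimates for one condition
#'
#' Each replicate position gets a true speed drawn from
#' `Normal(v_mean, cv_between * v_mean)` (position-to-position biological
#' variation), a noisy closure series, and a window fit; the fitted slopes
#' are returned.
#'
#' @param n Number of replicate positions.
#' @param v_mean Condition mean edge speed, um/h.
#' @param cv_between Between-position coefficient of variation
#'   (default 0.10).
#' @param window Fit window in hours.
#' @param ... Forwarded to [simulate_noisy_series()].
#' @return Numeric vector of fitted velocities, um/h.
#' @export
simulate_velocity_replicates <- function(n, v_mean, cv_between = 0.10,
                                         window = c(5, 11), ...) {
  vapply(seq_len(n), function(i) {
    v_i <- rnorm(1, v_mean, cv_between * v_mean)
    fit_window(simulate_noisy_series(v_i, ...), window)$v_um_per_h
  }, numeric(1))
}

#' Power of detecting a programmed slowdown
#'
#' Repeats a two-arm study (`n_per_arm` positions each) `n_reps` times:
#' control at `v_control`, treated slowed by `slowdown_pct` percent; each
#' repetition is tested with [compare_conditions()]. Returns the fraction of
#' repetitions significant at `alpha`.
#'
#' @param slowdown_pct Programmed slowdown in percent (e.g. 15).
#' @param n_per_arm Replicate positions per arm.
#' @param n_reps Number of seeded repetitions.
#' @param v_control Control mean edge speed, um/h.
#' @param cv_between Between-position coefficient of variation.
#' @param alpha Significance level.
#' @param seed Seed for the whole simulation.
#' @param ... Forwarded to [simulate_velocity_replicates()].
#' @return List with `power`, `p_values`, `ratio_pct` (mean observed ratio).
#' @export
slowdown_power <- function(slowdown_pct = 15, n_per_arm = 12, n_reps = 50,
                           v_control = 20, cv_between = 0.10, alpha = 0.05,
                           seed = 1L, ...) {
  .with_seed(seed, {
    v_treated <- v_control * (1 - slowdown_pct / 100)
    res <- vapply(seq_len(n_reps), function(r) {
      tr <- simulate_velocity_replicates(n_per_arm, v_treated, cv_between, ...)
      ct <- simulate_velocity_replicates(n_per_arm, v_control, cv_between, ...)
      eff <- compare_conditions(tr, ct)
      c(p = eff$p_value, ratio = eff$ratio_pct)
    }, numeric(2))
    list(power = mean(res["p", ] < alpha), p_values = res["p", ],
         ratio_pct = mean(res["ratio", ]))
  })
}
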