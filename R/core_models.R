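#' Ballistic flight distance
#'
#' The simplest mechanistic model of seed dispersal by wind: a propagule
#' released at height `release_height_m` falls at its terminal velocity while
#' being carried horizontally by a height-constant wind, landing at
#' \deqn{D = h_r \bar{u} / V_t.}
#' The model assumes the propagule reaches terminal velocity immediately,
#' moves horizontally at exactly the wind speed, and that the wind does not
#' vary with height (see [gradient_distance()] for the height-varying
#' extension).
#'
#' @param release_height_m Release height \eqn{h_r} above ground (m, > 0).
#' @param wind_ms Mean horizontal wind speed \eqn{\bar{u}} at release height
#'   (m/s, >= 0). Zero wind is valid and yields zero drift.
#' @param terminal_velocity_ms Terminal (falling) velocity \eqn{V_t}
#'   (m/s, > 0).
#' @return Horizontal flight distance in metres. Vectorised over all
#'   arguments with the usual recycling.
#' @examples
#' ballistic_distance(2.68, 3, 1.62)
#' @seealso [gradient_distance()], [fall_time()]
#' @export
ballistic_distance <- function(release_height_m, wind_ms, terminal_velocity_ms) {
  check_positive(release_height_m, "release_height_m")
  check_nonneg(wind_ms, "wind_ms")
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  release_height_m * wind_ms / terminal_velocity_ms
}

#' Wind speed at another height via the Hellmann power law
#'
#' Converts a wind speed measured at one height (typically an anemometer at
#' 10 m) to another height using the power-law wind profile
#' \deqn{v_z = v_g (z / z_g)^{\alpha},}
#' where \eqn{\alpha} is the Hellmann exponent encoding surface roughness and
#' air stability. For open flat terrain values near 0.14 are typical;
#' calibration against hogweed launch experiments gives 0.29
#' (see [calibrate_alpha()]), the package-wide default.
#'
#' @param speed_ms Reference wind speed \eqn{v_g} (m/s, >= 0).
#' @param height_m Reference height \eqn{z_g} (m, > 0).
#' @param target_height_m Height \eqn{z} to convert to (m, > 0).
#' @param alpha Hellmann exponent (dimensionless, >= 0).
#' @return Wind speed at `target_height_m` (m/s).
#' @examples
#' wind_at_height(16, 10, 3.85, alpha = 0.29)
#' @export
wind_at_height <- function(speed_ms, height_m, target_height_m, alpha = 0.29) {
  check_nonneg(speed_ms, "speed_ms")
  check_positive(height_m, "height_m")
  check_positive(target_height_m, "target_height_m")
  check_nonneg(alpha, "alpha")
  speed_ms * (target_height_m / height_m)^alpha
}

#' Total fall time from release height
#'
#' Time for a propagule falling at constant terminal velocity to reach the
#' ground: \eqn{t_f = h_r / v_t}. Drop experiments from 0.8--4.3 m show
#' hogweed mericarps reach terminal velocity essentially immediately, so the
#' constant-velocity fall is a good description over the whole descent.
#'
#' @inheritParams ballistic_distance
#' @return Fall time in seconds.
#' @export
fall_time <- function(release_height_m, terminal_velocity_ms) {
  check_positive(release_height_m, "release_height_m")
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  release_height_m / terminal_velocity_ms
}

#' Instantaneous wind speed experienced by a falling propagule
#'
#' During the fall the propagule descends through the wind gradient, so the
#' horizontal wind it experiences decays from the release-height value toward
#' zero at the ground:
#' \deqn{v_h(t) = v_{hr} \left( \frac{v_t t_f - v_t t}{h_r} \right)^{\alpha}.}
#' At \eqn{t = 0} this equals the release-height wind; at \eqn{t = t_f} it is
#' zero for any \eqn{\alpha > 0}.
#'
#' @inheritParams ballistic_distance
#' @param wind_at_release_ms Wind speed \eqn{v_{hr}} at the release height
#'   (m/s, >= 0).
#' @param alpha Hellmann exponent (>= 0).
#' @param elapsed_time_s Time since release, in `[0, t_f]` (s).
#' @return Instantaneous horizontal wind speed (m/s).
#' @export
wind_during_fall <- function(release_height_m, wind_at_release_ms,
                             terminal_velocity_ms, elapsed_time_s,
                             alpha = 0.29) {
  check_positive(release_height_m, "release_height_m")
  check_nonneg(wind_at_release_ms, "wind_at_release_ms")
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  check_nonneg(alpha, "alpha")
  tf <- release_height_m / terminal_velocity_ms
  if (anyNA(elapsed_time_s) || any(elapsed_time_s < 0) ||
      any(elapsed_time_s > tf + 1e-12)) {
    stop("'elapsed_time_s' must lie in [0, fall_time]", call. = FALSE)
  }
  frac <- pmax(0, (release_height_m - terminal_velocity_ms * elapsed_time_s) /
                 release_height_m)
  wind_at_release_ms * frac^alpha
}

#' Wind-gradient flight distance
#'
#' Flight distance under the wind-gradient model: the ballistic model with
#' the height-constant wind replaced by the Hellmann profile the propagule
#' descends through. Integrating the instantaneous wind
#' ([wind_during_fall()]) over the fall gives the closed form
#' \deqn{D = \frac{h_r v_{hr}}{v_t (1 + \alpha)},}
#' i.e. the ballistic distance shrunk by the factor \eqn{1/(1+\alpha)}.
#' With `alpha = 0` this reduces exactly to [ballistic_distance()].
#'
#' @inheritParams wind_during_fall
#' @return Horizontal flight distance in metres.
#' @examples
#' gradient_distance(3.85, 12, 0.91, alpha = 0.29)
#' @export
gradient_distance <- function(release_height_m, wind_at_release_ms,
                              terminal_velocity_ms, alpha = 0.29) {
  check_positive(release_height_m, "release_height_m")
  check_nonneg(wind_at_release_ms, "wind_at_release_ms")
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  check_nonneg(alpha, "alpha")
  release_height_m * wind_at_release_ms /
    (terminal_velocity_ms * (1 + alpha))
}
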