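#' Wrap angles to \[-pi, pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval \[-pi, pi).
#' @examples
#' wrap_angle(pi)        # -> -pi
#' wrap_angle(3 * pi / 2) # -> -pi/2
#' @export
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

# clamp to [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# unit vector for a planar heading
.heading_vec <- function(heading) c(cos(heading), sin(heading))

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
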