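#' @import methods
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles in degrees to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval \code{[0, 360)}.
#' @examples
#' wrapDeg(c(-90, 360, 725))
#' @export
wrapDeg <- function(x) {
  out <- x %% 360
  # %% can return 360 - eps rounding up to 360 for tiny negative inputs
  out[out == 360] <- 0
  out
}

#' Rescale an angular difference to [-180, 180] degrees
#'
#' Adds the multiple of 360 degrees that places the difference in
#' \code{[-180, 180]}. Both endpoints are representable: a difference that is
#' an odd multiple of 180 keeps the sign of its input (+540 maps to +180,
#' -180 stays -180); the absolute value used by the error metrics is
#' unaffected by this convention.
#'
#' @param delta_deg numeric vector of angle differences in degrees.
#' @return numeric vector in \code{[-180, 180]}.
#' @examples
#' rescaleAngle(10 - 350)  # -20
#' abs(rescaleAngle(10 - 350))  # 20 degrees of circular error
#' @export
rescaleAngle <- function(delta_deg) {
  r <- ((delta_deg + 180) %% 360) - 180
  odd <- !is.na(delta_deg) & ((delta_deg + 180) %% 360) == 0
  r[odd] <- ifelse(delta_deg[odd] >= 0, 180, -180)
  r
}

# circular mean of angles in degrees; NA if no finite input
circMeanDeg <- function(x, w = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  th <- x * DEG2RAD
  if (is.null(w)) w <- rep(1, length(th))
  s <- sum(w * sin(th)); c <- sum(w * cos(th))
  if (s == 0 && c == 0) return(NA_real_)
  wrapDeg(atan2(s, c) * RAD2DEG)
}

# shortest circular distance between two angles, degrees, in [0, 180]
circDistDeg <- function(a, b) abs(rescaleAngle(a - b))

# Evaluate a local RNG scope: runs expr with a seed without disturbing the
# caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
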