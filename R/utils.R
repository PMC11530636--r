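# Small internal helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

# Angle between two vectors, degrees.
vec_angle_deg <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

# Rotation matrix for rotation by `theta` radians about unit axis `ax`
# (Rodrigues formula).
rotation_matrix <- function(ax, theta) {
  ax <- unit(ax)
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Any unit vector perpendicular to v.
perp_vector <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * v) * v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be positive and finite", name)
  invisible(x)
}
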